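#' FPKM quantification and two-genotype differential expression
#'
#' Expression is a features x samples count matrix plus a sample sheet
#' (columns `sample`, `genotype` in tolerant/sensitive, `treatment` in
#' control/cd, `replicate`). FPKM is computed per sample as
#' count * 1e9 / (length * librarySize). Differential expression contrasts
#' Cd against control within one genotype: the per-feature test pools
#' counts across replicates of each arm and asks, via an exact two-sided
#' binomial test, whether the Cd share of the pooled count deviates from
#' the share expected from the arm library sizes (a pooled two-proportion
#' test in the spirit of MA-plot random-sampling DE methods for unreplicated
#' or shallow designs). P-values are Benjamini-Hochberg adjusted per
#' genotype. Fold changes are ratios of arm-mean FPKM on the log2 scale; a
#' pseudocount of 1 FPKM unit is added to both means only when either mean
#' is zero, so exact ratios of nonzero means are preserved.
#'
#' The three-state rule calls a feature up when log2FC >= 1, down when
#' log2FC <= -1, and unchanged otherwise; an optional FDR gate additionally
#' demotes up/down calls with FDR above the threshold to unchanged.
#'
#' @name expression_de
NULL

#' Read a count matrix and sample sheet
#'
#' @param counts_path TSV, first column feature id, one column per sample.
#' @param samples_path TSV with columns `sample`, `genotype`, `treatment`,
#'   `replicate`.
#' @return list with `counts` (numeric matrix, feature ids as rownames)
#'   and `samples` (data frame, rows ordered as the count columns).
#' @export
read_counts <- function(counts_path, samples_path) {
  df <- utils::read.delim(counts_path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  counts <- as.matrix(df[, -1, drop = FALSE])
  rownames(counts) <- df[[1]]
  if (anyDuplicated(rownames(counts)))
    stop("duplicate feature ids in ", counts_path)
  samples <- utils::read.delim(samples_path, stringsAsFactors = FALSE)
  validate_design(counts, samples)
  list(counts = counts, samples = samples[match(colnames(counts),
                                                samples$sample), ])
}

validate_design <- function(counts, samples) {
  need <- c("sample", "genotype", "treatment", "replicate")
  if (!all(need %in% names(samples)))
    stop("sample sheet needs columns: ", paste(need, collapse = " "))
  if (!setequal(colnames(counts), samples$sample))
    stop("count columns and sample sheet disagree")
  if (any(counts < 0)) stop("negative counts")
  if (!all(samples$treatment %in% c("control", "cd")))
    stop("treatment must be 'control' or 'cd'")
  tab <- table(samples$genotype,
               factor(samples$treatment, c("control", "cd")))
  if (any(tab == 0L))
    stop("incomplete design: every genotype x treatment cell needs >= 1 ",
         "replicate")
  invisible(TRUE)
}

#' FPKM from raw counts
#'
#' fpkm(f, s) = count(f, s) * 1e9 / (length(f) * librarySize(s)), with
#' library size the per-sample column sum.
#'
#' @param counts numeric matrix, feature ids as rownames.
#' @param lengths named numeric vector of transcript lengths (nt) covering
#'   every feature.
#' @return matrix of FPKM values, same shape as `counts`.
#' @export
compute_fpkm <- function(counts, lengths) {
  miss <- setdiff(rownames(counts), names(lengths))
  if (length(miss))
    stop("missing length for feature(s): ",
         paste(utils::head(miss, 5), collapse = ", "))
  len <- lengths[rownames(counts)]
  if (any(len <= 0)) stop("non-positive transcript length")
  lib <- colSums(counts)
  if (any(lib <= 0)) stop("zero library size in sample(s): ",
                          paste(colnames(counts)[lib <= 0], collapse = ", "))
  sweep(counts / len, 2L, lib, "/") * 1e9
}

#' Three-state call from a log2 fold change
#'
#' @param log2fc numeric vector of finite log2 fold changes.
#' @param fdr optional FDR vector for the gate.
#' @param lfc_min fold-change threshold (default 1).
#' @param fdr_max FDR threshold (default 0.05).
#' @param fdr_gate if TRUE, up/down additionally require `fdr <= fdr_max`.
#' @return character vector in `up`/`down`/`unchanged`.
#' @export
call_state <- function(log2fc, fdr = NULL, lfc_min = 1, fdr_max = 0.05,
                       fdr_gate = FALSE) {
  stopifnot(all(is.finite(log2fc)))
  st <- ifelse(log2fc >= lfc_min, "up",
               ifelse(log2fc <= -lfc_min, "down", "unchanged"))
  if (fdr_gate) {
    stopifnot(!is.null(fdr))
    st[st != "unchanged" & fdr > fdr_max] <- "unchanged"
  }
  st
}

#' Cd-vs-control differential expression within one genotype
#'
#' @param counts count matrix.
#' @param samples sample sheet (see [read_counts()]).
#' @param genotype which genotype to contrast (a value of
#'   `samples$genotype`).
#' @param lengths transcript lengths for the FPKM-based fold change.
#' @param lfc_min,fdr_max,fdr_gate passed to [call_state()].
#' @return data frame of per-feature records: `feature_id`, `genotype`,
#'   `mean_fpkm_control`, `mean_fpkm_cd`, `log2fc`, `pvalue`, `fdr`,
#'   `state` (gated per `fdr_gate`), `state_fc` (fold-change-only rule).
#' @export
differential_expression <- function(counts, samples, genotype, lengths,
                                    lfc_min = 1, fdr_max = 0.05,
                                    fdr_gate = TRUE) {
  validate_design(counts, samples)
  sel <- samples$genotype == genotype
  if (!any(sel)) stop("unknown genotype: ", genotype)
  cd_cols <- samples$sample[sel & samples$treatment == "cd"]
  ct_cols <- samples$sample[sel & samples$treatment == "control"]
  if (length(cd_cols) == 0L || length(ct_cols) == 0L)
    stop("genotype ", genotype, " lacks a treatment arm")
  fpkm <- compute_fpkm(counts, lengths)
  m_cd <- rowMeans(fpkm[, cd_cols, drop = FALSE])
  m_ct <- rowMeans(fpkm[, ct_cols, drop = FALSE])
  eps <- ifelse(m_cd == 0 | m_ct == 0, 1, 0)
  log2fc <- log2((m_cd + eps) / (m_ct + eps))

  x_cd <- rowSums(counts[, cd_cols, drop = FALSE])
  x_ct <- rowSums(counts[, ct_cols, drop = FALSE])
  n_cd <- sum(counts[, cd_cols]); n_ct <- sum(counts[, ct_cols])
  p0 <- n_cd / (n_cd + n_ct)
  pvalue <- mapply(function(x, tot) {
    if (tot == 0) return(1)
    stats::binom.test(x, tot, p = p0, alternative = "two.sided")$p.value
  }, x_cd, x_cd + x_ct)
  fdr <- stats::p.adjust(pvalue, method = "BH")
  data.frame(feature_id = rownames(counts), genotype = genotype,
             mean_fpkm_control = m_ct, mean_fpkm_cd = m_cd,
             log2fc = log2fc, pvalue = pvalue, fdr = fdr,
             state = call_state(log2fc, fdr, lfc_min, fdr_max, fdr_gate),
             state_fc = call_state(log2fc, NULL, lfc_min),
             row.names = NULL, stringsAsFactors = FALSE)
}
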