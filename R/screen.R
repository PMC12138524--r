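#' Cross-genotype tolerance screening, enrichment and qPCR concordance
#'
#' The screen compares the three-state Cd-response call of each feature
#' between a tolerant and a sensitive genotype. Discordant patterns define
#' the tolerance-linked categories: `T_up` (up in the tolerant genotype,
#' down or unchanged in the sensitive), `T_down` (down in tolerant, up or
#' unchanged in sensitive), `S_only` (unchanged in tolerant, changed in
#' sensitive); concordant patterns -- (up, up), (down, down),
#' (unchanged, unchanged) -- are `not_linked`. Key regulatory pairs are
#' those whose lncRNA is tolerance-linked and whose target responds
#' differently in the two genotypes.
#'
#' @name tolerance_screen
NULL

TOLERANCE_CATEGORIES <- c("T_up", "T_down", "S_only", "not_linked")

#' Tolerance category from a pair of three-state calls
#'
#' @param state_tolerant,state_sensitive character vectors in
#'   `up`/`down`/`unchanged` (recycled to a common length).
#' @return character vector of categories (see module description).
#' @export
contrast_classify <- function(state_tolerant, state_sensitive) {
  n <- max(length(state_tolerant), length(state_sensitive))
  st <- rep_len(state_tolerant, n); ss <- rep_len(state_sensitive, n)
  stopifnot(all(st %in% c("up", "down", "unchanged")),
            all(ss %in% c("up", "down", "unchanged")))
  ifelse(st == ss, "not_linked",
         ifelse(st == "up", "T_up",
                ifelse(st == "down", "T_down", "S_only")))
}

#' Screen a shared feature universe across genotypes
#'
#' Features present in only one genotype's table are treated as unchanged
#' in the other and recorded in the `one_sided` attribute.
#'
#' @param de_tolerant,de_sensitive DE tables (see
#'   [differential_expression()]); the state column used is chosen by
#'   `state_col` (default `"state_fc"`, the fold-change-only rule).
#' @param state_col which state column to compare.
#' @return data frame `feature_id`, `state_tolerant`, `state_sensitive`,
#'   `log2fc_tolerant`, `log2fc_sensitive`, `category`; attributes
#'   `summary` (category counts) and `one_sided`.
#' @export
screen_features <- function(de_tolerant, de_sensitive,
                            state_col = "state_fc") {
  ids <- union(de_tolerant$feature_id, de_sensitive$feature_id)
  if (length(ids) == 0L) {
    out <- data.frame(feature_id = character(), state_tolerant = character(),
                      state_sensitive = character(),
                      log2fc_tolerant = numeric(),
                      log2fc_sensitive = numeric(), category = character(),
                      stringsAsFactors = FALSE)
    return(structure(out, summary = table(factor(character(),
                                                 TOLERANCE_CATEGORIES)),
                     one_sided = character()))
  }
  it <- match(ids, de_tolerant$feature_id)
  is_ <- match(ids, de_sensitive$feature_id)
  st <- ifelse(is.na(it), "unchanged", de_tolerant[[state_col]][it])
  ss <- ifelse(is.na(is_), "unchanged", de_sensitive[[state_col]][is_])
  out <- data.frame(
    feature_id = ids, state_tolerant = st, state_sensitive = ss,
    log2fc_tolerant = ifelse(is.na(it), NA_real_, de_tolerant$log2fc[it]),
    log2fc_sensitive = ifelse(is.na(is_), NA_real_,
                              de_sensitive$log2fc[is_]),
    category = contrast_classify(st, ss), stringsAsFactors = FALSE)
  structure(out,
            summary = table(factor(out$category, TOLERANCE_CATEGORIES)),
            one_sided = ids[xor(is.na(it), is.na(is_))])
}

#' Select key tolerance lncRNA-mRNA pairs
#'
#' Retains pairs whose lncRNA category is not `not_linked` and whose
#' target's three-state call differs between the genotypes.
#'
#' @param pairs pair table ([assign_targets()] output, or any data frame
#'   with `lncrna_id` and `target_id`).
#' @param calls screen table from [screen_features()] covering both pair
#'   members.
#' @return the retained pair rows annotated with both members' states,
#'   categories and fold changes.
#' @export
select_key_pairs <- function(pairs, calls) {
  if (nrow(pairs) == 0L) return(pairs)
  li <- match(pairs$lncrna_id, calls$feature_id)
  ti <- match(pairs$target_id, calls$feature_id)
  if (anyNA(li) || anyNA(ti))
    stop("screen calls missing for some pair members")
  keep <- calls$category[li] != "not_linked" &
    calls$state_tolerant[ti] != calls$state_sensitive[ti]
  out <- pairs[keep, , drop = FALSE]
  out$lnc_category <- calls$category[li][keep]
  out$lnc_state_tolerant <- calls$state_tolerant[li][keep]
  out$lnc_state_sensitive <- calls$state_sensitive[li][keep]
  out$lnc_log2fc_tolerant <- calls$log2fc_tolerant[li][keep]
  out$lnc_log2fc_sensitive <- calls$log2fc_sensitive[li][keep]
  out$target_state_tolerant <- calls$state_tolerant[ti][keep]
  out$target_state_sensitive <- calls$state_sensitive[ti][keep]
  out$target_log2fc_tolerant <- calls$log2fc_tolerant[ti][keep]
  out$target_log2fc_sensitive <- calls$log2fc_sensitive[ti][keep]
  rownames(out) <- NULL
  out
}

#' Hypergeometric over-representation of terms in a gene set
#'
#' @param genes character vector of selected gene ids (subset of
#'   `universe`).
#' @param term_map named list mapping term -> character vector of gene
#'   ids.
#' @param universe background gene ids.
#' @return data frame sorted by ascending p: `term`, `overlap`,
#'   `term_size`, `pvalue`, `qvalue` (BH).
#' @export
overrepresentation <- function(genes, term_map, universe) {
  stopifnot(length(term_map) > 0L)
  genes <- unique(genes); universe <- unique(universe)
  if (!all(genes %in% universe)) stop("genes must be a subset of universe")
  if (length(genes) == 0L)
    return(data.frame(term = character(), overlap = integer(),
                      term_size = integer(), pvalue = numeric(),
                      qvalue = numeric(), stringsAsFactors = FALSE))
  n <- length(genes); N <- length(universe)
  res <- lapply(names(term_map), function(tm) {
    tset <- intersect(term_map[[tm]], universe)
    k <- length(intersect(genes, tset)); K <- length(tset)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = tm, overlap = k, term_size = K, pvalue = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$qvalue <- stats::p.adjust(out$pvalue, method = "BH")
  out[order(out$pvalue), , drop = FALSE]
}

#' Relative expression by the comparative-Ct (2^-ddCt) method
#'
#' dCt = target Ct - reference Ct per sample; ddCt anchors on the mean dCt
#' of the control group (per gene), so the control-group mean ddCt is 0 by
#' construction; relative expression is 2^-ddCt.
#'
#' @param records data frame with columns `sample`, `group`
#'   (`control`/`treated`), `target_ct`, `reference_ct`, and optionally
#'   `gene` (processed per gene).
#' @return the input with `delta_ct`, `delta_delta_ct`,
#'   `relative_expression` appended.
#' @export
relative_expression_ddct <- function(records) {
  need <- c("sample", "group", "target_ct", "reference_ct")
  stopifnot(all(need %in% names(records)))
  if (anyNA(records$reference_ct))
    stop("missing reference Ct for sample(s): ",
         paste(records$sample[is.na(records$reference_ct)], collapse = ", "))
  if (anyNA(records$target_ct))
    stop("missing target Ct for sample(s): ",
         paste(records$sample[is.na(records$target_ct)], collapse = ", "))
  records$delta_ct <- records$target_ct - records$reference_ct
  grp <- if ("gene" %in% names(records)) records$gene else rep("g", nrow(records))
  anchor <- tapply(records$delta_ct[records$group == "control"],
                   grp[records$group == "control"], mean)
  if (anyNA(anchor[unique(grp)]))
    stop("every gene needs control-group records to anchor ddCt")
  records$delta_delta_ct <- as.numeric(records$delta_ct - anchor[grp])
  records$relative_expression <- 2^(-records$delta_delta_ct)
  records
}

#' Coefficient of determination between sequencing and qPCR fold changes
#'
#' Ordinary least squares of the sequencing log2 fold changes on the qPCR
#' log2 fold changes.
#'
#' @param seq_lfc,qpcr_lfc equal-length numeric vectors, length >= 3.
#' @return R-squared of the regression.
#' @export
concordance_r2 <- function(seq_lfc, qpcr_lfc) {
  stopifnot(length(seq_lfc) == length(qpcr_lfc), length(seq_lfc) >= 3L)
  if (stats::sd(seq_lfc) == 0 || stats::sd(qpcr_lfc) == 0)
    stop("zero variance: concordance undefined")
  # R^2 of simple OLS with intercept = squared Pearson correlation
  stats::cor(seq_lfc, qpcr_lfc)^2
}

#' Bundled worked example of cadmium-tolerance key pairs
#'
#' Eighteen lncRNA-mRNA pairs over twelve lncRNAs with published log2 fold
#' changes (Cd vs control) in a Cd-tolerant (X178) and a Cd-sensitive
#' (X38) hull-less barley genotype, used as a golden fixture for the
#' three-state rule and the key-pair selection rule.
#'
#' @return data frame with columns `lncrna_id`, `lnc_lfc_tolerant`,
#'   `lnc_lfc_sensitive`, `target_id`, `target_lfc_tolerant`,
#'   `target_lfc_sensitive`, `annotation`.
#' @export
load_key_pair_example <- function() {
  utils::read.delim(system.file("extdata", "barley_cd_key_pairs.tsv",
                                package = "lncscreen"),
                    stringsAsFactors = FALSE)
}
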