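#' lncRNA-mRNA target pairing
#'
#' Candidate lncRNA-mRNA pairs first pass an expression-correlation gate:
#' Pearson and Spearman coefficients computed on log2(FPKM + 1) across all
#' samples must both strictly exceed a threshold (default 0.6; signed by
#' default, absolute-value mode available). Surviving pairs on the same
#' chromosome whose spans overlap or lie within the cis window (default
#' 10 kb, gap inclusive) become cis pairs with a positional subtype; all
#' other survivors become trans pairs when their RNA-RNA hybridization
#' energy is at or below the energy ceiling (default -60 kcal/mol). A pair
#' is never both cis and trans: cis takes precedence.
#'
#' @name target_pairing
NULL

#' Nearest-neighbor stack energies (kcal/mol)
#'
#' Watson-Crick stack free energies at 37C (Turner 2004 values), indexed by
#' the top-strand dinucleotide 5'-XY-3' of two adjacent base pairs; the
#' bottom strand is the reverse complement. The table is symmetric under
#' reading the duplex from the other strand (E(XY) = E(comp(Y)comp(X))).
#'
#' @format named numeric vector of length 16.
#' @export
NN_STACK <- c(
  AA = -0.93, AC = -2.24, AG = -2.08, AU = -1.10,
  CA = -2.11, CC = -3.26, CG = -2.36, CU = -2.08,
  GA = -2.35, GC = -3.42, GG = -3.26, GU = -2.24,
  UA = -1.33, UC = -2.35, UG = -2.11, UU = -0.93)

#' Expression-correlation gate for a candidate pair
#'
#' @param x,y equal-length expression vectors (FPKM) across the same
#'   samples; length >= 3.
#' @param threshold both coefficients must strictly exceed this (default
#'   0.6).
#' @param absolute gate on |r| instead of signed r.
#' @param log2p1 transform to log2(x + 1) before correlating (default
#'   TRUE; set FALSE if the inputs are already transformed).
#' @return list `pearson`, `spearman`, `pass`, `reason` (NA when testable,
#'   `"constant_vector"` when a correlation is undefined).
#' @export
correlation_gate <- function(x, y, threshold = 0.6, absolute = FALSE,
                             log2p1 = TRUE) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (log2p1) { x <- log2(x + 1); y <- log2(y + 1) }
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(pearson = NA_real_, spearman = NA_real_, pass = FALSE,
                reason = "constant_vector"))
  pe <- stats::cor(x, y, method = "pearson")
  sp <- stats::cor(x, y, method = "spearman")
  v <- if (absolute) c(abs(pe), abs(sp)) else c(pe, sp)
  list(pearson = pe, spearman = sp, pass = all(v > threshold),
       reason = NA_character_)
}

rna_ints <- function(seq) {
  s <- chartr("acgutT", "ACGUUU", seq)
  v <- match(strsplit(s, "", fixed = TRUE)[[1]], c("A", "C", "G", "U"))
  if (anyNA(v)) stop("invalid RNA alphabet in sequence (want A/C/G/U/T)")
  v
}

#' Ungapped antisense hybridization energy between two RNAs
#'
#' A deliberately simple screening statistic, not a full RNA-RNA
#' interaction prediction: the two sequences are slid against each other in
#' antiparallel orientation without gaps; every maximal run of >= 4
#' consecutive Watson-Crick pairs at any offset is scored by the sum of
#' its [NN_STACK] stack energies (a run of L pairs has L - 1 stacks); the
#' reported energy is the minimum over all offsets and runs, or 0 when no
#' offset has a complementary run of >= 4. Symmetric in its arguments.
#'
#' @param seq_a,seq_b RNA/DNA strings (T read as U), length >= 10.
#' @return energy in kcal/mol (<= 0).
#' @export
duplex_energy <- function(seq_a, seq_b) {
  a <- rna_ints(seq_a)
  b <- rna_ints(seq_b)
  stopifnot(length(a) >= 10L, length(b) >= 10L)
  # A[i] pairs with B[j] antiparallel iff A[i] == complement(B[j]);
  # align A against the reverse complement of B so runs are contiguous.
  duplex_energy_kernel(a, rev(5L - b), NN_STACK, 4L)
}

#' Assign cis and trans targets to lncRNAs
#'
#' @param lncs,genes `transcript_set`s of lncRNAs and candidate coding
#'   targets.
#' @param fpkm FPKM matrix covering both sets (features x samples).
#' @param sequences optional named character vector of transcript
#'   sequences, used to compute trans energies when `energy_table` lacks a
#'   pair.
#' @param energy_table optional data frame `lncrna_id`, `target_id`,
#'   `energy` with precomputed energies (kcal/mol).
#' @param corr_min,corr_absolute correlation gate parameters.
#' @param cis_window cis distance window in bp (gap inclusive).
#' @param energy_max trans energy ceiling in kcal/mol.
#' @param trans_targets optional id subset restricting the trans candidate
#'   universe (e.g. differentially expressed mRNAs).
#' @param max_trans cap on the number of trans candidates evaluated for
#'   energy (correlation-passing pairs beyond the cap are dropped with a
#'   warning).
#' @return data frame of `TargetPair` records: `lncrna_id`, `target_id`,
#'   `mode` (cis/trans), `cis_subtype`, `pearson`, `spearman`,
#'   `energy_kcal_mol`, `gap_bp`. Attribute `skipped` lists trans
#'   candidates lacking both sequence and energy.
#' @export
assign_targets <- function(lncs, genes, fpkm, sequences = NULL,
                           energy_table = NULL, corr_min = 0.6,
                           corr_absolute = FALSE, cis_window = 10000L,
                           energy_max = -60, trans_targets = NULL,
                           max_trans = 20000L) {
  stopifnot(nrow(lncs) >= 1L, nrow(genes) >= 1L)
  miss <- setdiff(c(lncs$transcript_id, genes$transcript_id), rownames(fpkm))
  if (length(miss))
    stop("expression missing for: ", paste(utils::head(miss, 5),
                                           collapse = ", "))
  lx <- log2(fpkm[lncs$transcript_id, , drop = FALSE] + 1)
  gx <- log2(fpkm[genes$transcript_id, , drop = FALSE] + 1)
  ok_l <- apply(lx, 1L, stats::sd) > 0
  ok_g <- apply(gx, 1L, stats::sd) > 0
  pe <- matrix(NA_real_, nrow(lncs), nrow(genes))
  sp <- matrix(NA_real_, nrow(lncs), nrow(genes))
  if (any(ok_l) && any(ok_g)) {
    pe[ok_l, ok_g] <- stats::cor(t(lx[ok_l, , drop = FALSE]),
                                 t(gx[ok_g, , drop = FALSE]))
    sp[ok_l, ok_g] <- stats::cor(t(lx[ok_l, , drop = FALSE]),
                                 t(gx[ok_g, , drop = FALSE]),
                                 method = "spearman")
  }
  gate <- if (corr_absolute) abs(pe) > corr_min & abs(sp) > corr_min
          else pe > corr_min & sp > corr_min
  gate[is.na(gate)] <- FALSE
  idx <- which(gate, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    return(structure(empty_pairs(), skipped = character()))

  if (!is.null(energy_table))
    ekey <- stats::setNames(energy_table$energy,
                            paste(energy_table$lncrna_id,
                                  energy_table$target_id))
  rows <- vector("list", nrow(idx))
  skipped <- character()
  n_trans_seen <- 0L
  for (r in seq_len(nrow(idx))) {
    li <- idx[r, 1L]; gi <- idx[r, 2L]
    lid <- lncs$transcript_id[li]; gid <- genes$transcript_id[gi]
    if (lid == gid) next
    same_chrom <- lncs$chrom[li] == genes$chrom[gi]
    geom <- if (same_chrom)
      locus_geometry(ts_row(lncs, li), ts_row(genes, gi)) else NULL
    is_cis <- same_chrom &&
      (geom$relation == "overlap" || geom$gap_bp <= cis_window)
    if (is_cis) {
      rows[[r]] <- data.frame(
        lncrna_id = lid, target_id = gid, mode = "cis",
        cis_subtype = classify_cis_subtype(geom, cis_window),
        pearson = pe[li, gi], spearman = sp[li, gi],
        energy_kcal_mol = NA_real_, gap_bp = geom$gap_bp,
        stringsAsFactors = FALSE)
      next
    }
    if (!is.null(trans_targets) && !(gid %in% trans_targets)) next
    n_trans_seen <- n_trans_seen + 1L
    if (n_trans_seen > max_trans) next
    energy <- if (!is.null(energy_table) &&
                  !is.na(ekey[paste(lid, gid)])) ekey[[paste(lid, gid)]]
      else if (!is.null(sequences) && lid %in% names(sequences) &&
               gid %in% names(sequences))
        duplex_energy(sequences[[lid]], sequences[[gid]])
      else { skipped <- c(skipped, paste(lid, gid)); next }
    if (energy <= energy_max)
      rows[[r]] <- data.frame(
        lncrna_id = lid, target_id = gid, mode = "trans",
        cis_subtype = NA_character_, pearson = pe[li, gi],
        spearman = sp[li, gi], energy_kcal_mol = energy,
        gap_bp = NA_integer_, stringsAsFactors = FALSE)
  }
  if (n_trans_seen > max_trans)
    warning(n_trans_seen - max_trans, " trans candidate(s) beyond the ",
            "max_trans cap were dropped")
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out)) out <- empty_pairs()
  rownames(out) <- NULL
  structure(out, skipped = skipped)
}

empty_pairs <- function() {
  data.frame(lncrna_id = character(), target_id = character(),
             mode = character(), cis_subtype = character(),
             pearson = numeric(), spearman = numeric(),
             energy_kcal_mol = numeric(), gap_bp = integer(),
             stringsAsFactors = FALSE)
}

#' Positional summary of a pair table
#'
#' @param pairs output of [assign_targets()].
#' @return list with counts: `n_cis`, `n_trans`, `upstream`, `downstream`,
#'   `overlap`, and per-subtype counts of the six overlap subtypes.
#' @export
cis_partition_summary <- function(pairs) {
  cis <- pairs[pairs$mode == "cis", , drop = FALSE]
  sub <- table(factor(cis$cis_subtype, levels = CIS_SUBTYPES))
  list(n_cis = nrow(cis), n_trans = sum(pairs$mode == "trans"),
       upstream = unname(sub[["Upstream"]]),
       downstream = unname(sub[["Downstream"]]),
       overlap = sum(sub[OVERLAP_SUBTYPES]),
       subtypes = as.list(sub[OVERLAP_SUBTYPES]))
}
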