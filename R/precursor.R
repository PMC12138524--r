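#' Scan lncRNAs for embedded miRNA hairpin precursors
#'
#' Local (Smith-Waterman) alignment of each known miRNA hairpin against
#' each lncRNA, scoring match +1, mismatch -2, gap -3. A hit requires
#' identity over the aligned region and aligned hairpin coverage both at
#' or above their thresholds (defaults 0.9/0.9); both strands of the
#' hairpin are searched and the best alignment per (lncRNA, hairpin) pair
#' is kept.
#'
#' @param lnc_seqs named character vector or `XStringSet` of lncRNA
#'   sequences (A/C/G/T/U).
#' @param hairpin_seqs named character vector or `XStringSet` of hairpin
#'   sequences.
#' @param min_identity,min_coverage hit thresholds in (0, 1].
#' @param both_strands also scan the reverse complement of each hairpin.
#' @return data frame of hits: `lncrna_id`, `mirna_id`, `identity`,
#'   `hairpin_coverage`, `lnc_start`, `lnc_end`, `strand`, `score`.
#' @export
precursor_scan <- function(lnc_seqs, hairpin_seqs, min_identity = 0.9,
                           min_coverage = 0.9, both_strands = TRUE) {
  stopifnot(length(lnc_seqs) > 0L, length(hairpin_seqs) > 0L,
            min_identity > 0, min_identity <= 1,
            min_coverage > 0, min_coverage <= 1)
  as_dna <- function(x) {
    if (is(x, "XStringSet")) x <- as.character(x)
    if (is.null(names(x)) || any(names(x) == ""))
      stop("sequences must be named")
    up <- toupper(chartr("Uu", "Tt", x))
    if (any(grepl("[^ACGT]", up)))
      stop("invalid alphabet in sequence(s): ",
           paste(names(x)[grepl("[^ACGT]", up)], collapse = ", "))
    Biostrings::DNAStringSet(up)
  }
  lncs <- as_dna(lnc_seqs)
  hps <- as_dna(hairpin_seqs)
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1,
                                                     mismatch = -2)
  queries <- hps
  strand <- rep("+", length(hps))
  hp_idx <- seq_along(hps)
  if (both_strands) {
    queries <- c(hps, Biostrings::reverseComplement(hps))
    strand <- c(strand, rep("-", length(hps)))
    hp_idx <- c(hp_idx, seq_along(hps))
  }
  hits <- list()
  for (i in seq_along(lncs)) {
    aln <- Biostrings::pairwiseAlignment(
      queries, lncs[[i]], type = "local", substitutionMatrix = submat,
      gapOpening = 0, gapExtension = 3)
    alen <- nchar(as.character(Biostrings::pattern(aln)))
    p1 <- Biostrings::start(Biostrings::pattern(aln))
    p2 <- Biostrings::end(Biostrings::pattern(aln))
    cand <- data.frame(
      lncrna_id = names(lncs)[i], mirna_id = names(hps)[hp_idx],
      identity = Biostrings::nmatch(aln) / alen,
      hairpin_coverage = (p2 - p1 + 1) / Biostrings::width(hps)[hp_idx],
      lnc_start = Biostrings::start(Biostrings::subject(aln)),
      lnc_end = Biostrings::end(Biostrings::subject(aln)),
      strand = strand, score = Biostrings::score(aln),
      stringsAsFactors = FALSE)
    # best alignment per hairpin across strands, then threshold
    cand <- cand[order(cand$mirna_id, -cand$score), , drop = FALSE]
    cand <- cand[!duplicated(cand$mirna_id), , drop = FALSE]
    keep <- cand$identity >= min_identity &
      cand$hairpin_coverage >= min_coverage
    if (any(keep)) hits[[length(hits) + 1L]] <- cand[keep, , drop = FALSE]
  }
  if (length(hits) == 0L)
    return(data.frame(lncrna_id = character(), mirna_id = character(),
                      identity = numeric(), hairpin_coverage = numeric(),
                      lnc_start = integer(), lnc_end = integer(),
                      strand = character(), score = numeric(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, hits)
  rownames(out) <- NULL
  out
}
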