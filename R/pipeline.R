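#' End-to-end screening pipeline
#'
#' `run_pipeline()` executes the stages in order: length/known filtering,
#' consensus classification, FPKM and per-genotype differential
#' expression, cis/trans target pairing, cross-genotype tolerance
#' screening and key-pair selection, then the optional stages (precursor
#' scan, qPCR concordance, over-representation) when their inputs are
#' present in the bundle. All thresholds live in a [pipeline_config()]
#' whose defaults are the published values of the screening procedure.
#'
#' @name pipeline
NULL

#' Pipeline configuration
#'
#' @param min_length minimum transcript length (nt), default 200.
#' @param vote_min consensus votes required (of 5), default 3.
#' @param corr_min correlation-gate threshold, default 0.6 (both
#'   coefficients must strictly exceed it).
#' @param corr_absolute gate on absolute correlations.
#' @param cis_window cis distance window (bp), default 10000, gap
#'   inclusive.
#' @param energy_max trans hybridization-energy ceiling (kcal/mol),
#'   default -60.
#' @param fdr_max FDR threshold for differential expression, default
#'   0.05.
#' @param lfc_min |log2FC| threshold, default 1.
#' @param fdr_gate_for_states if TRUE the three-state screen calls also
#'   require FDR <= `fdr_max`; default FALSE (fold-change-only rule).
#' @param tolerant,sensitive genotype labels in the sample sheet.
#' @param max_trans cap on trans candidates evaluated for energy.
#' @return classed list of thresholds.
#' @export
pipeline_config <- function(min_length = 200L, vote_min = 3L,
                            corr_min = 0.6, corr_absolute = FALSE,
                            cis_window = 10000L, energy_max = -60,
                            fdr_max = 0.05, lfc_min = 1,
                            fdr_gate_for_states = FALSE,
                            tolerant = "tolerant",
                            sensitive = "sensitive",
                            max_trans = 20000L) {
  stopifnot(min_length >= 1, vote_min >= 1, vote_min <= 5,
            corr_min >= -1, corr_min <= 1.5, cis_window >= 0,
            fdr_max > 0, fdr_max <= 1, lfc_min >= 0)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Percentage helper used in reports
#'
#' @param x,n numerator and denominator.
#' @param digits rounding digits (default 1).
#' @return `round(100 * x / n, digits)`.
#' @export
percent_of <- function(x, n, digits = 1) round(100 * x / n, digits)

#' Run the full screening pipeline on a bundle
#'
#' @param bundle a `sim_bundle` (see [simulate_dataset()]) or a directory
#'   path readable by [read_bundle()]. Mandatory elements: `annotation`,
#'   `evidence`, `counts`, `samples`; optional: `known_ids`, `sequences`,
#'   `hairpins`, `energy_table`, `qpcr`, `term_map`.
#' @param config a [pipeline_config()].
#' @return list of class `lnc_screen_report`: stage tables (`discarded`,
#'   `classification`, `de_tolerant`, `de_sensitive`, `pairs`,
#'   `screen_calls`, `key_pairs`, `precursor_hits`, `qpcr`, `enrichment`)
#'   and a `summary` list of the partition counts.
#' @export
run_pipeline <- function(bundle, config = pipeline_config()) {
  if (is.character(bundle)) bundle <- read_bundle(bundle)
  for (need in c("annotation", "evidence", "counts", "samples"))
    if (is.null(bundle[[need]]))
      stop("bundle lacks mandatory input: ", need)
  ts <- bundle$annotation
  lengths <- stats::setNames(ts$length, ts$transcript_id)

  filt <- filter_candidates(ts, bundle$known_ids, config$min_length)
  ev <- bundle$evidence[bundle$evidence$transcript_id %in%
                          filt$retained$transcript_id, , drop = FALSE]
  cls <- consensus_classify(ev, vote_min = config$vote_min)
  lnc_ids <- cls$transcript_id[cls$call == "novel_lncRNA"]
  novel_mrna_ids <- cls$transcript_id[cls$call == "novel_mRNA"]
  mrna_ids <- intersect(c(bundle$known_ids, novel_mrna_ids),
                        ts$transcript_id)

  de_t <- differential_expression(bundle$counts, bundle$samples,
                                  config$tolerant, lengths,
                                  config$lfc_min, config$fdr_max,
                                  fdr_gate = TRUE)
  de_s <- differential_expression(bundle$counts, bundle$samples,
                                  config$sensitive, lengths,
                                  config$lfc_min, config$fdr_max,
                                  fdr_gate = TRUE)
  fpkm <- compute_fpkm(bundle$counts, lengths)

  de_any <- union(de_t$feature_id[de_t$state != "unchanged"],
                  de_s$feature_id[de_s$state != "unchanged"])
  pairs <- if (length(lnc_ids) && length(mrna_ids)) {
    assign_targets(
      new_transcript_set(ts[ts$transcript_id %in% lnc_ids, ]),
      new_transcript_set(ts[ts$transcript_id %in% mrna_ids, ]),
      fpkm, sequences = bundle$sequences,
      energy_table = bundle$energy_table, corr_min = config$corr_min,
      corr_absolute = config$corr_absolute,
      cis_window = config$cis_window, energy_max = config$energy_max,
      trans_targets = intersect(de_any, mrna_ids),
      max_trans = config$max_trans)
  } else empty_pairs()

  state_col <- if (config$fdr_gate_for_states) "state" else "state_fc"
  calls <- screen_features(de_t, de_s, state_col = state_col)
  key <- select_key_pairs(pairs, calls)

  prec <- if (!is.null(bundle$sequences) && !is.null(bundle$hairpins) &&
              length(lnc_ids))
    precursor_scan(bundle$sequences[intersect(lnc_ids,
                                              names(bundle$sequences))],
                   bundle$hairpins) else NULL

  qpcr_res <- if (!is.null(bundle$qpcr))
    qpcr_concordance(bundle$qpcr, de_t, de_s, config) else NULL

  enr <- if (!is.null(bundle$term_map) && nrow(pairs) > 0L) {
    universe <- unique(unlist(bundle$term_map, use.names = FALSE))
    genes <- intersect(unique(pairs$target_id), universe)
    if (length(genes))
      overrepresentation(genes, bundle$term_map, universe) else NULL
  } else NULL

  summ <- report_summary(ts, filt, cls, de_t, de_s, pairs, calls, key,
                         prec, qpcr_res, lnc_ids, mrna_ids)
  structure(list(config = config, discarded = filt$discarded,
                 classification = cls, de_tolerant = de_t,
                 de_sensitive = de_s, fpkm = fpkm, pairs = pairs,
                 screen_calls = calls, key_pairs = key,
                 precursor_hits = prec, qpcr = qpcr_res,
                 enrichment = enr, summary = summ),
            class = "lnc_screen_report")
}

qpcr_concordance <- function(qpcr, de_t, de_s, config) {
  per_gt <- lapply(split(qpcr, qpcr$genotype), relative_expression_ddct)
  lfc <- do.call(rbind, lapply(names(per_gt), function(gt) {
    q <- per_gt[[gt]]
    tr <- q[q$group == "treated", , drop = FALSE]
    agg <- tapply(log2(tr$relative_expression), tr$gene, mean)
    de <- if (gt == config$tolerant) de_t else de_s
    data.frame(gene = names(agg), genotype = gt,
               qpcr_log2fc = as.numeric(agg),
               seq_log2fc = de$log2fc[match(names(agg), de$feature_id)],
               stringsAsFactors = FALSE)
  }))
  lfc <- lfc[stats::complete.cases(lfc), , drop = FALSE]
  list(records = do.call(rbind, per_gt), fold_changes = lfc,
       r2 = if (nrow(lfc) >= 3L)
         concordance_r2(lfc$seq_log2fc, lfc$qpcr_log2fc) else NA_real_)
}

report_summary <- function(ts, filt, cls, de_t, de_s, pairs, calls, key,
                           prec, qpcr_res, lnc_ids, mrna_ids) {
  de_counts <- function(de) {
    lnc <- de$feature_id %in% lnc_ids
    list(lnc_up = sum(lnc & de$state == "up"),
         lnc_down = sum(lnc & de$state == "down"),
         mrna_up = sum(!lnc & de$state == "up" &
                         de$feature_id %in% mrna_ids),
         mrna_down = sum(!lnc & de$state == "down" &
                           de$feature_id %in% mrna_ids))
  }
  cat_counts <- function(ids) {
    k <- calls$feature_id %in% ids
    as.list(table(factor(calls$category[k], TOLERANCE_CATEGORIES)))
  }
  lnc_with_targets <- unique(pairs$lncrna_id)
  list(
    n_input = nrow(ts), n_discarded = nrow(filt$discarded),
    discard_reasons = as.list(table(filt$discarded$reason)),
    n_candidates = nrow(filt$retained),
    n_lncrna = sum(cls$call == "novel_lncRNA"),
    n_novel_mrna = sum(cls$call == "novel_mRNA"),
    n_ambiguous = sum(cls$call == "ambiguous"),
    de_tolerant = de_counts(de_t), de_sensitive = de_counts(de_s),
    n_pairs = nrow(pairs),
    n_lnc_with_targets = length(lnc_with_targets),
    n_unique_targets = length(unique(pairs$target_id)),
    pct_lnc_with_targets = if (length(lnc_ids))
      percent_of(length(lnc_with_targets), length(lnc_ids)) else NA_real_,
    cis = cis_partition_summary(pairs),
    tolerance_lnc = cat_counts(lnc_ids),
    tolerance_mrna = cat_counts(mrna_ids),
    n_key_pairs = nrow(key),
    n_key_lncrnas = length(unique(key$lncrna_id)),
    n_precursor_lnc = if (is.null(prec)) NA_integer_
      else length(unique(prec$lncrna_id)),
    qpcr_r2 = if (is.null(qpcr_res)) NA_real_ else qpcr_res$r2)
}

#' @export
print.lnc_screen_report <- function(x, ...) {
  s <- x$summary; cfg <- x$config
  cat("lncRNA tolerance screen\n")
  cat(sprintf("  thresholds: length >= %d nt, votes >= %d/5, r > %.2f,",
              cfg$min_length, cfg$vote_min, cfg$corr_min),
      sprintf("cis <= %d bp, energy <= %g kcal/mol, FDR <= %g, |lfc| >= %g\n",
              cfg$cis_window, cfg$energy_max, cfg$fdr_max, cfg$lfc_min))
  cat(sprintf("  input %d transcripts; %d discarded; %d candidates\n",
              s$n_input, s$n_discarded, s$n_candidates))
  cat(sprintf("  classified: %d lncRNA, %d novel mRNA, %d ambiguous\n",
              s$n_lncrna, s$n_novel_mrna, s$n_ambiguous))
  cat(sprintf("  DE (tolerant): %d/%d lncRNA up/down, %d/%d mRNA up/down\n",
              s$de_tolerant$lnc_up, s$de_tolerant$lnc_down,
              s$de_tolerant$mrna_up, s$de_tolerant$mrna_down))
  cat(sprintf("  DE (sensitive): %d/%d lncRNA up/down, %d/%d mRNA up/down\n",
              s$de_sensitive$lnc_up, s$de_sensitive$lnc_down,
              s$de_sensitive$mrna_up, s$de_sensitive$mrna_down))
  cat(sprintf("  pairs: %d (%d cis / %d trans); %d lncRNAs (%s%%) with targets\n",
              s$n_pairs, s$cis$n_cis, s$cis$n_trans,
              s$n_lnc_with_targets, s$pct_lnc_with_targets))
  cat(sprintf("  cis positions: %d upstream, %d downstream, %d overlap\n",
              s$cis$upstream, s$cis$downstream, s$cis$overlap))
  cat(sprintf("  key pairs: %d over %d lncRNAs\n",
              s$n_key_pairs, s$n_key_lncrnas))
  if (!is.na(s$n_precursor_lnc))
    cat(sprintf("  precursor lncRNAs: %d\n", s$n_precursor_lnc))
  if (!is.na(s$qpcr_r2))
    cat(sprintf("  qPCR concordance R2: %.3f\n", s$qpcr_r2))
  invisible(x)
}
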