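#' Synthetic input bundles with planted ground truth
#'
#' The generator emulates a two-genotype (Cd-tolerant / Cd-sensitive) x
#' two-treatment (control / Cd) x three-replicate root RNA-seq study at
#' desk scale: transcript annotation with planted cis geometry, a five-way
#' coding-evidence table with class-conditional scores, negative-binomial
#' counts around planted fold changes, transcript sequences with planted
#' complementary segments for trans pairs and embedded miRNA hairpins, and
#' a qPCR Ct table consistent with the planted fold changes. Every planted
#' fact is recorded in a ground-truth manifest so each pipeline stage can
#' be scored against it. The same seed reproduces the bundle exactly.
#'
#' @name synthetic_data
NULL

#' Simulation parameters
#'
#' Defaults describe the study conditions the pipeline is tested under:
#' 300 features (100 lncRNAs, 80 novel mRNAs, 120 known mRNAs), twelve
#' samples, planted |log2FC| = 3, negative-binomial dispersion 0.1 and
#' log-normal(meanlog 5, sdlog 1) baseline count means.
#'
#' @param n_lncrna,n_novel_mrna,n_known_mrna class sizes.
#' @param n_cis_pairs planted cis pairs (subtypes cycled through all
#'   eight positional labels).
#' @param n_trans_pairs planted trans pairs (different chromosomes,
#'   complementary segment planted in the target sequence).
#' @param effect_lfc planted |log2 fold change| for up/down states.
#' @param dispersion negative-binomial dispersion (0 = deterministic
#'   counts).
#' @param baseline_meanlog,baseline_sdlog log-normal baseline count-mean
#'   parameters.
#' @param score_sd SD of the class-conditional coding scores (means +2 /
#'   -2).
#' @param coding_db_prob,noncoding_db_prob Bernoulli rates of a protein
#'   database hit conditioned on class.
#' @param p_up,p_down per-genotype state probabilities for unpaired
#'   features (rest unchanged).
#' @param n_hairpins,n_precursors hairpin library size and number of
#'   lncRNAs with an embedded hairpin.
#' @param n_qpcr features carried into the qPCR table (split ~6 lncRNA /
#'   4 mRNA as in a typical validation panel).
#' @param qpcr_noise_sd Ct noise SD (cycles); `qpcr_intercept` maps
#'   log2 expression to Ct.
#' @param locus_spacing bp between unrelated loci (kept above the cis
#'   window so only planted pairs are near each other).
#' @param noiseless if TRUE, zero out all noise sources (dispersion,
#'   score SD, Ct noise; database flags become deterministic).
#' @return named parameter list of class `sim_params`.
#' @export
sim_params <- function(n_lncrna = 100L, n_novel_mrna = 80L,
                       n_known_mrna = 120L, n_cis_pairs = 24L,
                       n_trans_pairs = 12L, effect_lfc = 3,
                       dispersion = 0.1, baseline_meanlog = 5,
                       baseline_sdlog = 1, score_sd = 0.5,
                       coding_db_prob = 0.9, noncoding_db_prob = 0.02,
                       p_up = 0.15, p_down = 0.15, n_hairpins = 8L,
                       n_precursors = 6L, n_qpcr = 10L,
                       qpcr_noise_sd = 0.15, qpcr_intercept = 35,
                       locus_spacing = 25000L, noiseless = FALSE) {
  p <- as.list(environment())
  if (noiseless) {
    p$dispersion <- 0; p$score_sd <- 0; p$qpcr_noise_sd <- 0
    p$coding_db_prob <- 1; p$noncoding_db_prob <- 0
  }
  n_mrna <- p$n_novel_mrna + p$n_known_mrna
  if (p$n_cis_pairs + p$n_trans_pairs > p$n_lncrna ||
      p$n_cis_pairs + p$n_trans_pairs > n_mrna)
    stop("more planted pairs than available lncRNAs/mRNAs")
  if (p$n_precursors > p$n_hairpins)
    stop("n_precursors cannot exceed n_hairpins")
  if (p$locus_spacing <= 12000L)
    stop("locus_spacing must exceed the cis window plus locus extent")
  class(p) <- "sim_params"
  p
}

STATES <- c("up", "down", "unchanged")

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                     replace = TRUE), collapse = "")

revcomp_chr <- function(s) chartr("ACGT", "TGCA",
                                  paste(rev(strsplit(s, "")[[1]]),
                                        collapse = ""))

# exon layouts realising each cis subtype at an anchor position g;
# gene: two exons g..g+399 and g+1600..g+1999 (intron g+400..g+1599)
cis_layout <- function(subtype, g, gap) {
  gene <- list(exons = cbind(start = c(g, g + 1600L),
                             end = c(g + 399L, g + 1999L)),
               strand = "+")
  anti <- grepl("^Anti", subtype)
  lnc_strand <- if (anti) "-" else "+"
  lnc <- switch(sub("^Anti", "", subtype),
    Sense = cbind(start = g + 200L, end = g + 599L),
    Intronic = cbind(start = g + 500L, end = g + 899L),
    Overlapping = cbind(start = c(g + 500L, g + 2200L),
                        end = c(g + 699L, g + 2399L)),
    Upstream = NULL, Downstream = NULL)
  if (is.null(lnc)) {
    # non-overlap: gene beyond the lncRNA span by `gap` bases; lncRNA on
    # "+", so Downstream = gene after the lncRNA, Upstream = gene before
    if (subtype == "Downstream") {
      lnc <- cbind(start = g, end = g + 399L)
      gene$exons <- gene$exons + (g + 400L + gap - g)
    } else {
      gene$exons <- cbind(start = c(g, g + 1600L),
                          end = c(g + 399L, g + 1999L))
      lnc <- cbind(start = g + 2000L + gap, end = g + 2399L + gap)
    }
    lnc_strand <- "+"
  }
  colnames(lnc) <- c("start", "end")
  list(gene_exons = gene$exons, gene_strand = gene$strand,
       lnc_exons = lnc, lnc_strand = lnc_strand)
}

draw_states <- function(n, p_up, p_down, force_changed = FALSE) {
  draw1 <- function() {
    repeat {
      st <- sample(STATES, 2L, replace = TRUE,
                   prob = c(p_up, p_down, 1 - p_up - p_down))
      if (!force_changed || any(st != "unchanged")) return(st)
    }
  }
  t(vapply(seq_len(n), function(i) draw1(), character(2L)))
}

#' Simulate a complete input bundle with a ground-truth manifest
#'
#' @param params a [sim_params()] list.
#' @param seed integer RNG seed; the same seed reproduces the bundle
#'   exactly.
#' @return list of class `sim_bundle` with elements `annotation`
#'   (`transcript_set`), `known_ids`, `evidence`, `counts`, `samples`,
#'   `lengths`, `sequences`, `hairpins`, `qpcr`, `term_map`, and
#'   `manifest` (features, cis_pairs, trans_pairs, precursors, params,
#'   seed).
#' @export
simulate_dataset <- function(params = sim_params(), seed = 1L) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(seed)
  p <- params

  lnc_ids <- sprintf("LNC%04d", seq_len(p$n_lncrna))
  nov_ids <- sprintf("NOV%04d", seq_len(p$n_novel_mrna))
  kno_ids <- sprintf("KNO%04d", seq_len(p$n_known_mrna))
  mrna_ids <- c(nov_ids, kno_ids)
  ids <- c(lnc_ids, mrna_ids)
  class_of <- stats::setNames(
    c(rep("novel_lncRNA", p$n_lncrna), rep("novel_mRNA", p$n_novel_mrna),
      rep("known_mRNA", p$n_known_mrna)), ids)

  cis_lnc <- lnc_ids[seq_len(p$n_cis_pairs)]
  trans_lnc <- lnc_ids[p$n_cis_pairs + seq_len(p$n_trans_pairs)]
  free_lnc <- setdiff(lnc_ids, c(cis_lnc, trans_lnc))
  cis_gene <- mrna_ids[seq_len(p$n_cis_pairs)]
  trans_gene <- mrna_ids[p$n_cis_pairs + seq_len(p$n_trans_pairs)]
  free_mrna <- setdiff(mrna_ids, c(cis_gene, trans_gene))

  # --- annotation -------------------------------------------------------
  subtypes <- rep_len(CIS_SUBTYPES, p$n_cis_pairs)
  exon_rows <- list()
  add_exons <- function(tid, chrom, strand, exons) {
    exon_rows[[length(exon_rows) + 1L]] <<- data.frame(
      transcript_id = tid, gene_id = paste0(tid, ".g"), chrom = chrom,
      strand = strand, start = exons[, "start"], end = exons[, "end"],
      stringsAsFactors = FALSE)
  }
  cursor <- 10000L
  cis_gap <- integer(p$n_cis_pairs)
  for (i in seq_len(p$n_cis_pairs)) {
    gap <- if (subtypes[i] %in% c("Upstream", "Downstream"))
      sample(500:9500, 1L) else 0L
    cis_gap[i] <- gap
    lay <- cis_layout(subtypes[i], cursor, gap)
    add_exons(cis_gene[i], "chr1", lay$gene_strand, lay$gene_exons)
    add_exons(cis_lnc[i], "chr1", lay$lnc_strand, lay$lnc_exons)
    cursor <- cursor + p$locus_spacing
  }
  for (id in free_mrna) {
    len <- sample(300:800, 1L)
    add_exons(id, "chr1", sample(c("+", "-"), 1L),
              cbind(start = cursor, end = cursor + len - 1L))
    cursor <- cursor + p$locus_spacing
  }
  cursor2 <- 10000L
  for (id in c(trans_lnc, trans_gene, free_lnc)) {
    len <- sample(250:500, 1L)
    add_exons(id, if (id %in% trans_gene) "chr3" else "chr2",
              sample(c("+", "-"), 1L),
              cbind(start = cursor2, end = cursor2 + len - 1L))
    cursor2 <- cursor2 + p$locus_spacing
  }
  ex <- do.call(rbind, exon_rows)
  annotation <- transcript_set(ex$transcript_id, ex$gene_id, ex$chrom,
                               ex$strand, ex$start, ex$end)
  annotation$origin <- ifelse(annotation$transcript_id %in% kno_ids,
                              "known_mRNA", "novel_candidate")
  lengths <- stats::setNames(annotation$length, annotation$transcript_id)

  # --- planted states and counts ---------------------------------------
  st <- matrix("unchanged", length(ids), 2L,
               dimnames = list(ids, c("tolerant", "sensitive")))
  pair_lnc <- c(cis_lnc, trans_lnc)
  pair_gene <- c(cis_gene, trans_gene)
  pair_states <- draw_states(length(pair_lnc), p$p_up, p$p_down,
                             force_changed = TRUE)
  st[pair_lnc, ] <- pair_states
  st[pair_gene, ] <- pair_states
  others <- setdiff(ids, c(pair_lnc, pair_gene))
  st[others, ] <- draw_states(length(others), p$p_up, p$p_down)

  base <- stats::setNames(
    stats::rlnorm(length(ids), p$baseline_meanlog, p$baseline_sdlog), ids)
  samples <- data.frame(
    sample = paste(rep(c("tolerant", "sensitive"), each = 6L),
                   rep(rep(c("control", "cd"), each = 3L), 2L),
                   rep(1:3, 4L), sep = "_"),
    genotype = rep(c("tolerant", "sensitive"), each = 6L),
    treatment = rep(rep(c("control", "cd"), each = 3L), 2L),
    replicate = rep(1:3, 4L), stringsAsFactors = FALSE)
  dir_of <- function(s) c(up = 1, down = -1, unchanged = 0)[s]
  # split the planted fold change symmetrically across arms so the two
  # arms have matching expected library size (Cd vs control log2FC is
  # still exactly +/- effect_lfc); a one-sided effect at this feature
  # count would shift library sizes and bias FPKM ratios
  mu <- sapply(seq_len(nrow(samples)), function(j) {
    half <- if (samples$treatment[j] == "cd") 0.5 else -0.5
    base * 2^(half * p$effect_lfc * dir_of(st[, samples$genotype[j]]))
  })
  dimnames(mu) <- list(ids, samples$sample)
  counts <- if (p$dispersion > 0)
    matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / p$dispersion),
           nrow(mu), dimnames = dimnames(mu))
  else round(mu)

  # --- coding evidence --------------------------------------------------
  coding <- class_of[ids] != "novel_lncRNA"
  smean <- ifelse(coding, 2, -2)
  rb <- function(prob) stats::rbinom(length(ids), 1L, prob) == 1L
  evidence <- data.frame(
    transcript_id = ids,
    cpc_score = stats::rnorm(length(ids), smean, p$score_sd),
    cnci_score = stats::rnorm(length(ids), smean, p$score_sd),
    lgc_score = stats::rnorm(length(ids), smean, p$score_sd),
    pfam_hit = ifelse(coding, rb(p$coding_db_prob),
                      rb(p$noncoding_db_prob)),
    swissprot_hit = ifelse(coding, rb(p$coding_db_prob),
                           rb(p$noncoding_db_prob)),
    stringsAsFactors = FALSE)

  # --- sequences: planted complementarity and hairpins ------------------
  sequences <- stats::setNames(
    vapply(ids, function(id) rand_seq(lengths[[id]]), ""), ids)
  for (i in seq_along(trans_lnc)) {
    lseq <- sequences[[trans_lnc[i]]]
    seg <- substr(lseq, 11L, 60L)
    tseq <- sequences[[trans_gene[i]]]
    at <- sample(seq_len(nchar(tseq) - 50L), 1L)
    substr(tseq, at, at + 49L) <- revcomp_chr(seg)
    sequences[[trans_gene[i]]] <- tseq
  }
  hairpins <- stats::setNames(
    vapply(seq_len(p$n_hairpins), function(i) rand_seq(90L), ""),
    sprintf("hairpin%02d", seq_len(p$n_hairpins)))
  prec_lnc <- free_lnc[seq_len(p$n_precursors)]
  for (i in seq_len(p$n_precursors)) {
    lseq <- sequences[[prec_lnc[i]]]
    at <- sample(seq_len(nchar(lseq) - 90L), 1L)
    substr(lseq, at, at + 89L) <- hairpins[[i]]
    sequences[[prec_lnc[i]]] <- lseq
  }

  # --- qPCR table consistent with planted fold changes ------------------
  changed <- rowSums(st != "unchanged") > 0
  q_lnc <- utils::head(lnc_ids[changed[lnc_ids]],
                       ceiling(p$n_qpcr * 0.6))
  q_mrna <- utils::head(mrna_ids[changed[mrna_ids]],
                        p$n_qpcr - length(q_lnc))
  q_ids <- c(q_lnc, q_mrna)
  qpcr <- do.call(rbind, lapply(q_ids, function(g) {
    data.frame(sample = samples$sample, genotype = samples$genotype,
               group = ifelse(samples$treatment == "cd", "treated",
                              "control"),
               gene = g,
               target_ct = p$qpcr_intercept - log2(mu[g, ]) +
                 stats::rnorm(nrow(samples), 0, p$qpcr_noise_sd),
               reference_ct = 20 +
                 stats::rnorm(nrow(samples), 0, p$qpcr_noise_sd),
               stringsAsFactors = FALSE)
  }))
  rownames(qpcr) <- NULL

  term_map <- split(mrna_ids,
                    sample(sprintf("term%02d", 1:8), length(mrna_ids),
                           replace = TRUE))

  manifest <- list(
    seed = seed, params = unclass(p),
    features = data.frame(
      feature_id = ids, class = unname(class_of[ids]),
      type = ifelse(class_of[ids] == "novel_lncRNA", "lncRNA", "mRNA"),
      length = unname(lengths[ids]), base_mean = unname(base),
      state_tolerant = st[, "tolerant"], state_sensitive = st[, "sensitive"],
      category = contrast_classify(st[, "tolerant"], st[, "sensitive"]),
      row.names = NULL, stringsAsFactors = FALSE),
    cis_pairs = data.frame(lncrna_id = cis_lnc, target_id = cis_gene,
                           subtype = subtypes, gap_bp = cis_gap,
                           stringsAsFactors = FALSE),
    trans_pairs = data.frame(
      lncrna_id = trans_lnc, target_id = trans_gene,
      energy = vapply(seq_along(trans_lnc), function(i)
        duplex_energy(sequences[[trans_lnc[i]]],
                      sequences[[trans_gene[i]]]), 0),
      stringsAsFactors = FALSE),
    precursors = data.frame(lncrna_id = prec_lnc,
                            mirna_id = names(hairpins)[seq_len(p$n_precursors)],
                            stringsAsFactors = FALSE),
    qpcr_features = q_ids)

  structure(list(annotation = annotation, known_ids = kno_ids,
                 evidence = evidence, counts = counts, samples = samples,
                 lengths = lengths, sequences = sequences,
                 hairpins = hairpins, qpcr = qpcr, term_map = term_map,
                 manifest = manifest),
            class = "sim_bundle")
}

#' Write a simulated bundle to disk in the pipeline's file formats
#'
#' Emits `annotation.gtf`, `known_mrna_ids.txt`, `evidence.tsv`,
#' `counts.tsv`, `samples.tsv`, `transcripts.fasta`, `hairpins.fasta`,
#' `qpcr.tsv`, `term_map.tsv` and `manifest.json`. Writing the same
#' bundle twice produces identical bytes.
#'
#' @param bundle a `sim_bundle`.
#' @param out_dir output directory (created if needed).
#' @return named character vector of file paths, invisibly.
#' @export
write_fixture <- function(bundle, out_dir) {
  if (!inherits(bundle, "sim_bundle") || is.null(bundle$annotation) ||
      nrow(bundle$annotation) == 0L)
    stop("empty or invalid bundle")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create directory ", out_dir)
  path <- function(f) file.path(out_dir, f)
  tsv <- function(df, f) utils::write.table(
    df, path(f), sep = "\t", quote = FALSE, row.names = FALSE)

  ts <- bundle$annotation
  ex <- do.call(rbind, lapply(seq_len(nrow(ts)), function(i)
    data.frame(chrom = ts$chrom[i], start = ts$exons[[i]][, "start"],
               end = ts$exons[[i]][, "end"], strand = ts$strand[i],
               gene_id = ts$gene_id[i],
               transcript_id = ts$transcript_id[i],
               stringsAsFactors = FALSE)))
  gr <- GenomicRanges::GRanges(
    ex$chrom, IRanges::IRanges(ex$start, ex$end), strand = ex$strand,
    type = "exon", gene_id = ex$gene_id, transcript_id = ex$transcript_id)
  rtracklayer::export(gr, path("annotation.gtf"), format = "gtf")

  writeLines(bundle$known_ids, path("known_mrna_ids.txt"))
  evid <- bundle$evidence
  tsv(data.frame(transcript_id = evid$transcript_id,
                 cpc = evid$cpc_score, cnci = evid$cnci_score,
                 lgc = evid$lgc_score, pfam = as.integer(evid$pfam_hit),
                 swissprot = as.integer(evid$swissprot_hit)),
      "evidence.tsv")
  tsv(data.frame(feature_id = rownames(bundle$counts), bundle$counts,
                 check.names = FALSE), "counts.tsv")
  tsv(bundle$samples, "samples.tsv")
  write_fasta <- function(seqs, f)
    writeLines(paste0(">", names(seqs), "\n", unname(seqs)), path(f))
  write_fasta(bundle$sequences, "transcripts.fasta")
  write_fasta(bundle$hairpins, "hairpins.fasta")
  tsv(bundle$qpcr, "qpcr.tsv")
  tsv(data.frame(
    term = rep(names(bundle$term_map), lengths(bundle$term_map)),
    gene = unlist(bundle$term_map, use.names = FALSE)), "term_map.tsv")
  jsonlite::write_json(bundle$manifest, path("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(stats::setNames(
    path(c("annotation.gtf", "known_mrna_ids.txt", "evidence.tsv",
           "counts.tsv", "samples.tsv", "transcripts.fasta",
           "hairpins.fasta", "qpcr.tsv", "term_map.tsv", "manifest.json")),
    c("annotation", "known_ids", "evidence", "counts", "samples",
      "sequences", "hairpins", "qpcr", "term_map", "manifest")))
}

#' Read a fixture directory back into a bundle
#'
#' Counterpart of [write_fixture()]; the manifest, if present, is loaded
#' too (data frames restored from JSON).
#'
#' @param dir directory written by [write_fixture()] (or hand-assembled
#'   in the same formats).
#' @return a `sim_bundle`-shaped list.
#' @export
read_bundle <- function(dir) {
  path <- function(f) file.path(dir, f)
  known <- if (file.exists(path("known_mrna_ids.txt")))
    readLines(path("known_mrna_ids.txt")) else character()
  cs <- read_counts(path("counts.tsv"), path("samples.tsv"))
  read_fasta <- function(f) {
    if (!file.exists(path(f))) return(NULL)
    x <- Biostrings::readDNAStringSet(path(f))
    stats::setNames(as.character(x), names(x))
  }
  manifest <- if (file.exists(path("manifest.json"))) {
    m <- jsonlite::read_json(path("manifest.json"), simplifyVector = TRUE)
    m
  } else NULL
  tm <- if (file.exists(path("term_map.tsv"))) {
    df <- utils::read.delim(path("term_map.tsv"), stringsAsFactors = FALSE)
    split(df$gene, df$term)
  } else NULL
  ann <- read_gtf(path("annotation.gtf"), known_ids = known)
  structure(list(
    annotation = ann, known_ids = known,
    evidence = read_coding_evidence(path("evidence.tsv")),
    counts = cs$counts, samples = cs$samples,
    lengths = stats::setNames(ann$length, ann$transcript_id),
    sequences = read_fasta("transcripts.fasta"),
    hairpins = read_fasta("hairpins.fasta"),
    qpcr = if (file.exists(path("qpcr.tsv")))
      utils::read.delim(path("qpcr.tsv"), stringsAsFactors = FALSE)
      else NULL,
    term_map = tm, manifest = manifest), class = "sim_bundle")
}
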