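# Shared toy builders and independent oracles for the test suite.

# single-transcript builder: exons as list of c(start, end)
toy_tx <- function(id, exons, strand = "+", chrom = "chr1",
                   gene = paste0(id, ".g")) {
  ex <- do.call(rbind, exons)
  transcript_set(rep(id, nrow(ex)), rep(gene, nrow(ex)),
                 rep(chrom, nrow(ex)), rep(strand, nrow(ex)),
                 ex[, 1], ex[, 2])
}

# brute-force all-pairs exon intersection (oracle for exonic_overlap)
brute_exonic_overlap <- function(ex_a, ex_b) {
  for (i in seq_len(nrow(ex_a)))
    for (j in seq_len(nrow(ex_b)))
      if (ex_a[i, "start"] <= ex_b[j, "end"] &&
          ex_b[j, "start"] <= ex_a[i, "end"]) return(TRUE)
  FALSE
}

# independent duplex-energy oracle: enumerate antiparallel diagonals
# (i + j constant) instead of the kernel's offset-vs-reverse-complement
# formulation
naive_duplex_energy <- function(sa, sb) {
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  a <- strsplit(toupper(chartr("Tt", "UU", sa)), "")[[1]]
  b <- strsplit(toupper(chartr("Tt", "UU", sb)), "")[[1]]
  na <- length(a); nb <- length(b)
  best <- 0
  for (cst in 2:(na + nb)) {
    is <- max(1, cst - nb):min(na, cst - 1)
    if (length(is) < 1) next
    paired <- vapply(is, function(i) comp[[a[i]]] == b[cst - i], TRUE)
    r <- rle(paired); ends <- cumsum(r$lengths)
    for (q in seq_along(r$lengths)) {
      if (!r$values[q] || r$lengths[q] < 4) next
      s <- ends[q] - r$lengths[q] + 1
      idx <- is[s]:(is[ends[q]] - 1)
      best <- min(best, sum(NN_STACK[paste0(a[idx], a[idx + 1])]))
    }
  }
  unname(best)
}

rand_rna <- function(n) paste(sample(c("A", "C", "G", "U"), n,
                                     replace = TRUE), collapse = "")

# small, fast simulation preset used across files
small_params <- function(...) {
  sim_params(n_lncrna = 20L, n_novel_mrna = 15L, n_known_mrna = 15L,
             n_cis_pairs = 8L, n_trans_pairs = 4L, n_hairpins = 4L,
             n_precursors = 3L, n_qpcr = 6L, ...)
}

# bundles are expensive enough to share across tests within a session
.bundle_cache <- new.env(parent = emptyenv())
cached_bundle <- function(key, params, seed) {
  if (is.null(.bundle_cache[[key]]))
    .bundle_cache[[key]] <- simulate_dataset(params, seed = seed)
  .bundle_cache[[key]]
}
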