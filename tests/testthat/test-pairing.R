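test_that("correlation gate computes both coefficients on log2(FPKM+1)", {
  x <- c(1, 5, 20, 80, 300, 2, 9, 40)
  g <- correlation_gate(x, x)
  expect_equal(g$pearson, 1)
  expect_equal(g$spearman, 1)
  expect_true(g$pass)

  g <- correlation_gate(1:4, 4:1, log2p1 = FALSE)
  expect_equal(g$pearson, -1)
  expect_equal(g$spearman, -1)
  expect_false(g$pass)
  expect_true(correlation_gate(1:4, 4:1, log2p1 = FALSE,
                               absolute = TRUE)$pass)

  # hand-computed moment/rank oracle on an outlier fixture
  x <- c(1, 2, 3, 4, 100); y <- c(1, 2, 3, 4, -100)
  pearson_oracle <- function(a, b) {
    am <- a - mean(a); bm <- b - mean(b)
    sum(am * bm) / sqrt(sum(am^2) * sum(bm^2))
  }
  g <- correlation_gate(x, y, log2p1 = FALSE)
  expect_equal(g$pearson, pearson_oracle(x, y))
  expect_equal(g$spearman, pearson_oracle(rank(x), rank(y)))
  expect_false(g$pass)

  g <- correlation_gate(rep(2, 5), 1:5)
  expect_false(g$pass)
  expect_equal(g$reason, "constant_vector")
})

test_that("duplex energy agrees with the diagonal-enumeration oracle", {
  set.seed(21)
  for (i in 1:25) {
    a <- rand_rna(sample(30:80, 1))
    b <- rand_rna(sample(30:80, 1))
    expect_equal(duplex_energy(a, b), naive_duplex_energy(a, b))
    expect_equal(duplex_energy(a, b), duplex_energy(b, a))
  }
})

test_that("duplex energy handles the canonical limit cases", {
  expect_equal(duplex_energy(strrep("A", 30), strrep("A", 30)), 0)
  set.seed(22)
  s <- rand_rna(40)
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  rc <- paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  e <- duplex_energy(s, rc)
  expect_lt(e, -60)
  expect_equal(e, naive_duplex_energy(s, rc))
  expect_error(duplex_energy("ACGUXACGUACG", s), "alphabet")
})

# toy universe: engineered expression so only chosen pairs correlate;
# baseline values are distinct so rank correlations are well defined
mk_pair_fixture <- function() {
  exf <- function(pattern, scale) 2^pattern * scale
  up_pattern <- c(0, 0.1, 0.2, 3, 3.1, 3.2, 0.05, 0.15, 0.25, 0.3,
                  0.35, 0.4)
  dn_pattern <- -up_pattern
  lncs <- transcript_set(
    c("L1", "L2"), c("gL1", "gL2"), c("chr1", "chr2"), c("+", "+"),
    c(20000, 1000), c(20400, 1400))
  genes <- transcript_set(
    c("G1", "G2", "G3"), c("gG1", "gG2", "gG3"),
    c("chr1", "chr3", "chr3"), c("+", "+", "+"),
    c(24400, 1000, 50000), c(25400, 1800, 50800))
  fpkm <- rbind(L1 = exf(up_pattern, 100), L2 = exf(up_pattern, 80),
                G1 = exf(up_pattern, 120), G2 = exf(up_pattern, 60),
                G3 = exf(dn_pattern, 100))
  colnames(fpkm) <- paste0("s", 1:12)
  list(lncs = lncs, genes = genes, fpkm = fpkm)
}

test_that("targets split into cis and trans by window and energy", {
  fx <- mk_pair_fixture()
  energies <- data.frame(lncrna_id = c("L1", "L2", "L2"),
                         target_id = c("G2", "G2", "G3"),
                         energy = c(-65, -30, -80))
  pairs <- assign_targets(fx$lncs, fx$genes, fx$fpkm,
                          energy_table = energies)
  key <- paste(pairs$lncrna_id, pairs$target_id, pairs$mode)
  # L1-G1: same chrom, gap 3999 => cis
  expect_true("L1 G1 cis" %in% key)
  expect_equal(pairs$gap_bp[pairs$lncrna_id == "L1" &
                              pairs$target_id == "G1"], 3999L)
  # L1-G2: different chrom, correlated, energy -65 => trans
  expect_true("L1 G2 trans" %in% key)
  # L2-G2: energy -30 fails the ceiling
  expect_false(any(pairs$lncrna_id == "L2" & pairs$target_id == "G2"))
  # L2-G3: anticorrelated, dropped at the gate despite energy -80
  expect_false(any(pairs$target_id == "G3"))
  # no pair is both cis and trans
  expect_equal(anyDuplicated(paste(pairs$lncrna_id, pairs$target_id)), 0L)
})

test_that("the cis window boundary is inclusive at the gap", {
  fx <- mk_pair_fixture()
  # move G1 so the gap to L1 is exactly 10000, then 10001
  for (gap in c(10000L, 10001L)) {
    genes <- fx$genes
    genes$start[1] <- 20400 + gap + 1
    genes$end[1] <- genes$start[1] + 1000
    genes$exons[[1]] <- cbind(start = genes$start[1], end = genes$end[1])
    pairs <- assign_targets(fx$lncs, genes, fx$fpkm,
                            energy_table = data.frame(
                              lncrna_id = "L1", target_id = "G1",
                              energy = -100))
    mode <- pairs$mode[pairs$lncrna_id == "L1" & pairs$target_id == "G1"]
    expect_equal(mode, if (gap == 10000L) "cis" else "trans")
  }
})

test_that("pair sets shrink monotonically as thresholds tighten", {
  fx <- mk_pair_fixture()
  energies <- data.frame(lncrna_id = rep(c("L1", "L2"), each = 3),
                         target_id = rep(c("G1", "G2", "G3"), 2),
                         energy = c(-65, -61, -90, -30, -75, -59))
  n_at <- function(corr_min, energy_max) nrow(
    assign_targets(fx$lncs, fx$genes, fx$fpkm, energy_table = energies,
                   corr_min = corr_min, energy_max = energy_max))
  for (e in c(-50, -60, -70, -90, -120))
    expect_gte(n_at(0.6, e), n_at(0.6, e - 10))
  for (r in c(0, 0.3, 0.6, 0.9))
    expect_gte(n_at(r, -60), n_at(r + 0.1, -60))
  # a gate nobody can pass empties the table cleanly
  expect_equal(n_at(1.01, -60), 0L)
})

test_that("trans candidates without sequence or energy are skipped and reported", {
  fx <- mk_pair_fixture()
  pairs <- assign_targets(fx$lncs, fx$genes, fx$fpkm)
  expect_true("L1 G2" %in% attr(pairs, "skipped"))
  expect_false(any(pairs$mode == "trans"))
})
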