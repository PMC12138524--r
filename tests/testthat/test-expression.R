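# 2 genotypes x 2 treatments x `reps` replicates; counts built per arm
mk_design <- function(reps = 3) {
  data.frame(
    sample = paste(rep(c("tolerant", "sensitive"), each = 2 * reps),
                   rep(rep(c("control", "cd"), each = reps), 2),
                   rep(seq_len(reps), 4), sep = "_"),
    genotype = rep(c("tolerant", "sensitive"), each = 2 * reps),
    treatment = rep(rep(c("control", "cd"), each = reps), 2),
    replicate = rep(seq_len(reps), 4), stringsAsFactors = FALSE)
}

test_that("FPKM follows the closed form and its invariances", {
  counts <- matrix(c(100, 1e7 - 100), 2, 1,
                   dimnames = list(c("f1", "filler"), "s1"))
  lengths <- c(f1 = 1000, filler = 500)
  f <- compute_fpkm(counts, lengths)
  expect_equal(f["f1", "s1"], 100 * 1e9 / (1000 * 1e7))
  expect_equal(f["f1", "s1"], 10)

  counts["f1", ] <- 0
  expect_equal(compute_fpkm(counts, lengths)["f1", "s1"], 0)

  set.seed(3)
  cm <- matrix(rpois(40, 50), 10, 4,
               dimnames = list(paste0("g", 1:10), paste0("s", 1:4)))
  len <- setNames(sample(200:2000, 10), rownames(cm))
  expect_equal(compute_fpkm(2 * cm, len), compute_fpkm(cm, len))

  expect_error(compute_fpkm(cm, len[-1]), "missing length")
  cm[, 2] <- 0
  expect_error(compute_fpkm(cm, len), "zero library")
})

test_that("pooled binomial DE gives exact fold changes and BH-adjusted FDR", {
  samples <- mk_design(1)
  # tolerant arms: one sample each; balanced feature b, 4x feature a
  counts <- rbind(a = c(50, 200, 10, 10), b = c(50, 50, 10, 10),
                  c = c(900, 750, 980, 980))
  colnames(counts) <- samples$sample
  len <- c(a = 1000, b = 1000, c = 1000)
  de <- differential_expression(counts, samples, "tolerant", len,
                                fdr_gate = FALSE)
  # library sizes equal by construction
  expect_equal(sum(counts[, 1]), sum(counts[, 2]))
  expect_equal(de$log2fc[de$feature_id == "a"], 2)
  expect_equal(de$log2fc[de$feature_id == "b"], 0)
  expect_gt(de$pvalue[de$feature_id == "b"], 0.9)
  # FDR column is the BH step-up of the p-value column
  m <- length(de$pvalue)
  bh <- rev(cummin(rev(sort(de$pvalue) * m / seq_len(m))))
  expect_equal(sort(de$fdr), pmin(bh, 1))
  expect_true(all(de$fdr >= de$pvalue - 1e-12))
})

test_that("zero-mean pseudocount applies only when a mean is zero", {
  samples <- mk_design(1)
  counts <- rbind(a = c(0, 30, 5, 5), flat = c(1000, 970, 995, 995))
  colnames(counts) <- samples$sample
  len <- c(a = 1e6, flat = 1e6)  # long features -> small FPKM
  de <- differential_expression(counts, samples, "tolerant", len,
                                fdr_gate = FALSE)
  m_cd <- de$mean_fpkm_cd[de$feature_id == "a"]
  expect_equal(de$log2fc[de$feature_id == "a"], log2((m_cd + 1) / 1))
})

test_that("three-state rule uses inclusive thresholds and the FDR gate", {
  expect_equal(call_state(c(21.28, -4.23, 0.93, 1.0, -1.0, 0)),
               c("up", "down", "unchanged", "up", "down", "unchanged"))
  # gate demotes non-significant calls
  expect_equal(call_state(c(2, 2), fdr = c(0.01, 0.2), fdr_gate = TRUE),
               c("up", "unchanged"))
  expect_error(call_state(NaN), "finite")
})

test_that("designs missing an arm or a genotype are rejected", {
  samples <- mk_design(1)
  counts <- matrix(10, 2, 4, dimnames = list(c("a", "b"), samples$sample))
  len <- c(a = 100, b = 100)
  expect_error(differential_expression(counts, samples, "weird", len),
               "genotype")
  broken <- samples; broken$treatment <- "cd"
  expect_error(differential_expression(counts, broken, "tolerant", len),
               "incomplete design")
})
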