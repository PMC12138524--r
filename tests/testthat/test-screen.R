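test_that("contrast classification is total over the 3x3 state grid", {
  states <- c("up", "down", "unchanged")
  grid <- expand.grid(t = states, s = states, stringsAsFactors = FALSE)
  cat <- contrast_classify(grid$t, grid$s)
  expect_equal(length(cat), 9L)
  expect_true(all(cat %in% c("T_up", "T_down", "S_only", "not_linked")))
  expect_equal(sum(cat == "not_linked"), 3L)   # the concordant diagonal
  expect_equal(sum(cat != "not_linked"), 6L)
  expect_equal(contrast_classify("up", "down"), "T_up")
  expect_equal(contrast_classify("unchanged", "down"), "S_only")
  expect_equal(contrast_classify("up", "up"), "not_linked")
})

mk_de <- function(ids, lfc, genotype) {
  data.frame(feature_id = ids, genotype = genotype, log2fc = lfc,
             pvalue = 0.001, fdr = 0.001,
             state = call_state(lfc), state_fc = call_state(lfc),
             stringsAsFactors = FALSE)
}

test_that("screening covers the union universe and counts categories", {
  de_t <- mk_de(c("a", "b", "c"), c(2, -2, 0), "tolerant")
  de_s <- mk_de(c("a", "b", "d"), c(-2, -2, 3), "sensitive")
  out <- screen_features(de_t, de_s)
  expect_equal(sort(out$feature_id), c("a", "b", "c", "d"))
  expect_equal(sum(attr(out, "summary")), nrow(out))
  # c and d are one-sided; treated as unchanged on the missing side
  expect_setequal(attr(out, "one_sided"), c("c", "d"))
  expect_equal(out$category[out$feature_id == "a"], "T_up")
  expect_equal(out$category[out$feature_id == "b"], "not_linked")
  expect_equal(out$category[out$feature_id == "d"], "S_only")
  empty <- screen_features(de_t[0, ], de_s[0, ])
  expect_equal(nrow(empty), 0L)
})

test_that("key pairs need a linked lncRNA and a genotype-discordant target", {
  de_t <- mk_de(c("L1", "L2", "G1", "G2"), c(2, 1.5, 1.2, 2), "tolerant")
  de_s <- mk_de(c("L1", "L2", "G1", "G2"), c(-2, 1.5, -1.2, 2), "sensitive")
  calls <- screen_features(de_t, de_s)
  pairs <- data.frame(lncrna_id = c("L1", "L2", "L1"),
                      target_id = c("G1", "G1", "G2"),
                      stringsAsFactors = FALSE)
  key <- select_key_pairs(pairs, calls)
  # L2 is not_linked (up/up); G2 has equal states in both genotypes
  expect_equal(key$lncrna_id, "L1")
  expect_equal(key$target_id, "G1")
  expect_equal(key$lnc_category, "T_up")
  expect_error(select_key_pairs(
    data.frame(lncrna_id = "LX", target_id = "G1"), calls), "missing")
})

test_that("over-representation matches the hypergeometric closed form", {
  universe <- paste0("g", 1:100)
  term_map <- list(hit = paste0("g", 1:5), other = paste0("g", 50:80))
  genes <- paste0("g", 1:5)
  out <- overrepresentation(genes, term_map, universe)
  expect_equal(out$pvalue[out$term == "hit"], 1 / choose(100, 5))
  # selecting the whole universe leaves nothing enriched
  all_in <- overrepresentation(universe, term_map, universe)
  expect_true(all(all_in$pvalue == 1))
  # q-values are BH and preserve the p-value ordering
  expect_equal(out$qvalue, p.adjust(out$pvalue, "BH")[order(out$pvalue)])
  expect_true(!is.unsorted(out$qvalue))
})

test_that("hypergeometric tail matches exhaustive enumeration on a tiny universe", {
  universe <- letters[1:10]
  term <- letters[1:3]
  genes <- letters[c(1, 4, 5, 6)]
  k_obs <- length(intersect(genes, term))
  subsets <- combn(10, length(genes))
  overlaps <- apply(subsets, 2, function(ix)
    length(intersect(universe[ix], term)))
  brute_p <- mean(overlaps >= k_obs)
  out <- overrepresentation(genes, list(t = term), universe)
  expect_equal(out$pvalue, brute_p)
})

test_that("ddCt arithmetic anchors on the control-group mean", {
  rec <- data.frame(
    sample = paste0("s", 1:4),
    group = c("control", "control", "treated", "treated"),
    target_ct = c(25, 25, 23, 23), reference_ct = c(20, 20, 20, 20))
  out <- relative_expression_ddct(rec)
  expect_equal(mean(out$delta_delta_ct[out$group == "control"]), 0)
  expect_equal(out$relative_expression[out$group == "treated"], c(4, 4))
  rec$target_ct <- c(25, 25, 25, 25)
  expect_equal(relative_expression_ddct(rec)$relative_expression,
               rep(1, 4))
  rec$target_ct <- c(25, 25, 27, 27)
  expect_equal(relative_expression_ddct(rec)$relative_expression[3:4],
               c(0.25, 0.25))
  rec$reference_ct[2] <- NA
  expect_error(relative_expression_ddct(rec), "s2")
})

test_that("concordance R2 equals the least-squares closed form", {
  x <- c(1, 2, 3, 4)
  expect_equal(concordance_r2(2 * x + 1, x), 1)
  # residualized fixture: y orthogonal to x and to the intercept
  y <- c(1, -1, -1, 1)
  expect_equal(concordance_r2(y, x), 0)
  # 4-point hand-computed sums
  y <- c(1.1, 1.9, 3.4, 3.8)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  r2_hand <- sxy^2 / (sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(concordance_r2(y, x), r2_hand)
  expect_error(concordance_r2(rep(1, 4), x), "variance")
})
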