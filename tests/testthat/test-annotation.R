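test_that("GTF round trip computes closed-interval lengths and merges exons", {
  gtf <- file.path(tempdir(), "toy.gtf")
  writeLines(c(
    'chr1\ttoy\texon\t100\t300\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    'chr1\ttoy\texon\t100\t199\t.\t-\t.\tgene_id "g2"; transcript_id "t2";',
    'chr1\ttoy\texon\t300\t399\t.\t-\t.\tgene_id "g2"; transcript_id "t2";'),
    gtf)
  ts <- read_gtf(gtf)
  expect_equal(nrow(ts), 2L)
  expect_equal(ts$length[ts$transcript_id == "t1"], 201)
  expect_equal(ts$length[ts$transcript_id == "t2"], 200)
  expect_equal(ts$n_exons[ts$transcript_id == "t2"], 2L)
})

test_that("malformed records are rejected with informative errors", {
  gtf <- file.path(tempdir(), "bad.gtf")
  writeLines('chr1\ttoy\texon\t100\t300\t.\t+\t.\tgene_id "g1";', gtf)
  expect_error(read_gtf(gtf), "transcript_id")
  # unstranded records rejected at parse time
  expect_error(transcript_set("t1", "g1", "chr1", "*", 1, 10), "strand")
  # inconsistent chrom within one transcript
  expect_error(
    transcript_set(c("t1", "t1"), c("g1", "g1"), c("chr1", "chr2"),
                   c("+", "+"), c(1, 100), c(50, 150)),
    "inconsistent")
})

test_that("locus geometry matches interval arithmetic on the worked cases", {
  lnc <- toy_tx("lnc", list(c(20000, 21000)))
  gene <- toy_tx("gene", list(c(25000, 26000)))
  g <- locus_geometry(lnc, gene)
  expect_equal(g$gap_bp, 3999L)
  expect_match(g$relation, "^no_overlap_")
  # '+' lncRNA, gene after it => downstream; '-' flips the orientation
  expect_equal(g$relation, "no_overlap_downstream")
  g2 <- locus_geometry(toy_tx("lnc", list(c(20000, 21000)), strand = "-"),
                       gene)
  expect_equal(g2$relation, "no_overlap_upstream")

  ov <- locus_geometry(toy_tx("a", list(c(100, 200))),
                       toy_tx("b", list(c(150, 250))))
  expect_equal(ov$relation, "overlap")
  expect_equal(ov$gap_bp, 0L)

  intr <- locus_geometry(
    toy_tx("a", list(c(1000, 1100))),
    toy_tx("b", list(c(800, 899), c(2001, 2100))))
  expect_true(intr$fully_intronic)
  expect_false(intr$exonic_overlap)

  expect_error(locus_geometry(toy_tx("a", list(c(1, 10)), chrom = "chr1"),
                              toy_tx("b", list(c(1, 10)), chrom = "chr2")),
               "chromosome")
})

test_that("gap is symmetric and exonic overlap agrees with brute force", {
  set.seed(11)
  for (rep in 1:100) {
    mk <- function(id) {
      n <- sample(1:3, 1)
      s <- sort(sample(1:5000, n))
      w <- sample(50:400, n, replace = TRUE)
      # enforce non-overlapping exons by spacing
      s <- s + cumsum(c(0, rep(500, n - 1)))
      toy_tx(id, lapply(seq_len(n), function(i) c(s[i], s[i] + w[i])),
             strand = sample(c("+", "-"), 1))
    }
    a <- mk("a"); b <- mk("b")
    g_ab <- locus_geometry(a, b)
    g_ba <- locus_geometry(b, a)
    expect_identical(g_ab$gap_bp, g_ba$gap_bp)
    expect_identical(g_ab$exonic_overlap,
                     brute_exonic_overlap(a$exons[[1]], b$exons[[1]]))
  }
})

test_that("the six overlap subtypes partition the overlap flag space", {
  for (exonic in c(TRUE, FALSE))
    for (intronic in c(TRUE, FALSE))
      for (same in c(TRUE, FALSE)) {
        geom <- structure(list(relation = "overlap", gap_bp = 0L,
                               exonic_overlap = exonic,
                               fully_intronic = intronic,
                               same_strand = same),
                          class = "locus_geometry")
        sub <- classify_cis_subtype(geom)
        expect_length(sub, 1L)
        expect_true(sub %in% c("Sense", "AntiSense", "Intronic",
                               "AntiIntronic", "Overlapping",
                               "AntiOverlapping"))
      }
  # precedence spot checks
  g <- function(e, i, s) structure(
    list(relation = "overlap", gap_bp = 0L, exonic_overlap = e,
         fully_intronic = i, same_strand = s), class = "locus_geometry")
  expect_equal(classify_cis_subtype(g(TRUE, FALSE, TRUE)), "Sense")
  expect_equal(classify_cis_subtype(g(FALSE, TRUE, FALSE)), "AntiIntronic")
  expect_equal(classify_cis_subtype(g(FALSE, FALSE, TRUE)), "Overlapping")
})

test_that("non-overlapping subtypes respect the window and lncRNA strand", {
  near <- structure(list(relation = "no_overlap_upstream", gap_bp = 4000L,
                         exonic_overlap = FALSE, fully_intronic = FALSE,
                         same_strand = TRUE), class = "locus_geometry")
  expect_equal(classify_cis_subtype(near), "Upstream")
  near$relation <- "no_overlap_downstream"
  expect_equal(classify_cis_subtype(near), "Downstream")
  far <- near; far$gap_bp <- 10001L
  expect_error(classify_cis_subtype(far), "window")
  at_window <- near; at_window$gap_bp <- 10000L
  expect_equal(classify_cis_subtype(at_window), "Downstream")
})
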