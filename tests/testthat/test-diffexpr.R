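test_that("g-test matches closed forms and scales linearly in counts", {
  g0 <- gtest(c(10, 10), c(10, 10))
  expect_identical(g0$G, 0)
  expect_identical(g0$p_value, 1)
  g1 <- gtest(c(20, 0), c(10, 10))
  expect_equal(g1$G, 2 * 20 * log(2), tolerance = 1e-12)
  g2 <- gtest(c(40, 0), c(20, 20))
  expect_equal(g2$G, 2 * g1$G, tolerance = 1e-12)
  expect_equal(g2$G, 55.45177, tolerance = 1e-6)
  expect_error(gtest(c(5, 5), c(0, 10)), "positive")
  expect_error(gtest(c(5, 5), c(1, 2, 3)), "equal length")
})

test_that("g-test agrees with the log-domain oracle on random tables", {
  set.seed(61)
  for (i in 1:200) {
    ncat <- sample(2:5, 1)
    O <- rpois(ncat, lambda = sample(c(5, 50, 500), 1)) + 1
    E <- runif(ncat, 0.5, 2)
    got <- gtest(O, E)$G
    want <- gtest_oracle(O, E)
    # two independent double-precision routes; near-cancelling tables
    # limit cross-route agreement (the 50-digit comparison lives in the
    # acceptance suite)
    expect_equal(got, want, tolerance = 1e-7)
  }
})

test_that("unit differential categorises by significance and direction", {
  totals <- c(A = 1e6, B = 1e6)
  u <- data.frame(unit_id = c("eq", "up", "down", "small"),
                  count_A = c(100L, 250L, 50L, 3L),
                  count_B = c(100L, 50L, 250L, 1L),
                  stringsAsFactors = FALSE)
  r <- unit_differential(u, totals)
  expect_identical(r$category, c("ns", "over_A", "over_B", "ns"))
  expect_identical(r$G[1], 0)
  expect_identical(r$fold5_flag, c(FALSE, TRUE, TRUE, FALSE))
  # swapping libraries preserves G and flips direction
  u2 <- data.frame(unit_id = u$unit_id, count_A = u$count_B,
                   count_B = u$count_A, stringsAsFactors = FALSE)
  r2 <- unit_differential(u2, totals)
  expect_equal(r2$G, r$G, tolerance = 1e-12)
  expect_identical(r2$category[2:3], c("over_B", "over_A"))
  # ratio uses the pseudocount when a count is zero
  z <- unit_differential(data.frame(unit_id = "z", count_A = 10L,
                                    count_B = 0L), totals)
  expect_identical(z$ratio, (10 + 0.5) / 0.5)
  # alpha = 1 degenerates: every unit with unequal rpm is categorised
  r3 <- unit_differential(u, totals, alpha = 1)
  expect_identical(r3$category, c("ns", "over_A", "over_B", "over_A"))
})

test_that("fold categorisation is monotone in count_A", {
  totals <- c(A = 1e6, B = 1e6)
  ca <- seq(10L, 400L, by = 10L)
  r <- unit_differential(data.frame(unit_id = as.character(ca),
                                    count_A = ca, count_B = 50L), totals)
  expect_true(all(diff(r$ratio) > 0))
  expect_true(all(diff(as.integer(r$fold5_flag & r$ratio > 1)) >= 0))
})

test_that("class enrichment reproduces the frozen 2x2 contrast", {
  # 854 differential loci of which 521 carry the motif, against 38
  # non-differential loci of which 6 do: G = 31.67, p = 1.8e-8
  subset_counts <- c(motif = 521L, no_motif = 333L)
  background_counts <- c(motif = 527L, no_motif = 365L)
  enr <- class_enrichment(subset_counts, background_counts)
  expect_equal(enr$G[enr$class == "motif"], 31.67276, tolerance = 1e-5)
  expect_equal(enr$p_value[enr$class == "motif"], 1.824636e-08,
               tolerance = 1e-4)
  expect_identical(enr$direction[enr$class == "motif"], "over")
  expect_error(class_enrichment(c(a = 10L), c(a = 5L)), "exceeds")
})

test_that("uniform subsets show no class enrichment", {
  set.seed(62)
  bg <- c(miRNA = 400L, ncRNA = 300L, repeat_ = 500L, gene = 800L)
  pool <- rep(names(bg), bg)
  sub <- table(factor(sample(pool, 300), levels = names(bg)))
  enr <- class_enrichment(c(sub), bg)
  expect_true(all(enr$p_value > 1e-3))
})

test_that("miRNA family profiles aggregate lengths and overlap flags", {
  db <- data.frame(id = c("m1", "m2", "m3"),
                   family = c("famA", "famA", "famB"),
                   type = c("canonical", "canonical", "variant"),
                   stringsAsFactors = FALSE)
  d <- data.frame(sequence = c("x", "y", "z"),
                  length = c(21L, 24L, 22L),
                  count_A = c(80L, 40L, 10L), count_B = c(20L, 10L, 10L),
                  rpm_A = c(80, 40, 10), rpm_B = c(20, 10, 10),
                  annotation_class = "miRNA",
                  annotation_id = c("m1", "m2", "m3"),
                  stringsAsFactors = FALSE)
  feats <- data.frame(chrom = "chr1", start = c(100L, 500L, 900L),
                      end = c(121L, 521L, 921L), class = "miRNA",
                      subclass = NA_character_, id = c("m1", "m2", "m3"),
                      stringsAsFactors = FALSE)
  loci <- data.frame(locus_id = "PL1", chrom = "chr1", start = 880L,
                     end = 1100L, stringsAsFactors = FALSE)
  prof <- mirna_family_profile(d, db, features = feats, loci = loci)
  famA <- prof[prof$family == "famA", ]
  expect_identical(famA$modal_length, 21L)   # rpm 100 at 21 nt vs 50 at 24
  expect_identical(famA$count_A, 120L)
  expect_false(famA$phased_overlap)
  expect_true(prof$phased_overlap[prof$family == "famB"])
  # empty class gives an empty table
  empty <- mirna_family_profile(d[0, ], db)
  expect_identical(nrow(empty), 0L)
})
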