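test_that("in-phase predicate encodes the two-strand duplex geometry", {
  expect_true(in_phase(42L, "+", 0L))
  expect_true(in_phase(40L, "-", 0L))   # 40 + 2 = 42, congruent to 0
  expect_false(in_phase(43L, "+", 0L))
  expect_true(in_phase(12L + 21L * 5L, "+", 12L))
  expect_error(in_phase(42L, "+", 0L, width = 22L), "21-nt")
})

test_that("window scoring reproduces the worked hypergeometric values", {
  # empty window
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0))
  sc <- score_window(empty, "chr1", 0L, 0L)
  expect_identical(sc$n, 0L)
  expect_identical(sc$p_value, 1)
  # two cycles: N = 84, K = 4; three observed, all in phase
  aln <- data.frame(chrom = "chr1", start = c(0L, 21L, 19L),
                    end = c(21L, 42L, 40L), strand = c("+", "+", "-"),
                    stringsAsFactors = FALSE)
  sc2 <- score_window(aln, "chr1", 0L, 0L, cycles = 2L)
  expect_identical(sc2$N, 84L)
  expect_identical(sc2$K, 4L)
  expect_identical(sc2$n, 3L)
  expect_identical(sc2$k, 3L)
  expect_equal(sc2$p_value, 4 / 95284, tolerance = 1e-12)
  expect_equal(sc2$p_value, hyper_tail_oracle(3, 84, 4, 3),
               tolerance = 1e-12)
  # k = 0 with observations: the tail at zero is 1
  aln3 <- data.frame(chrom = "chr1", start = 1L, end = 22L, strand = "+")
  expect_identical(score_window(aln3, "chr1", 0L, 0L)$p_value, 1)
  expect_error(score_window(data.frame(chrom = "chr1", start = 0L,
                                       end = 24L, strand = "+"),
                            "chr1", 0L, 0L), "21-nt")
})

test_that("phasing p-value agrees with stats::phyper and is monotone in k", {
  set.seed(41)
  for (i in 1:200) {
    N <- sample(30:462, 1)
    K <- sample(2:min(25, N - 1), 1)
    n <- sample(1:min(20, N), 1)
    k <- sample(0:min(n, K), 1)
    expect_equal(phasing_pvalue(k, N, K, n),
                 phyper(k - 1, K, N - K, n, lower.tail = FALSE),
                 tolerance = 1e-10)
  }
  p <- phasing_pvalue(0:10, 462L, 22L, 10L)
  expect_true(all(diff(p) <= 0))
  expect_error(phasing_pvalue(1, 10, 2, 11), "n > N")
})

test_that("a clean planted locus is detected at its register", {
  # five sense members on register 5 of chr1 plus scattered off-phase noise
  reg <- 5L
  starts <- 1000L + reg + 21L * c(0L, 1L, 3L, 5L, 7L)
  noise <- c(3000L, 5000L, 7000L, 9000L)
  aln <- data.frame(sequence = paste0("s", 1:9),
                    chrom = "chr1",
                    start = c(starts, noise),
                    end = c(starts, noise) + 21L,
                    strand = "+", stringsAsFactors = FALSE)
  det <- detect_loci(aln)
  expect_identical(nrow(det$loci), 1L)
  # the register is the absolute residue class mod 21 of the 5' starts
  expect_identical(det$loci$register, (1000L + reg) %% 21L)
  expect_identical(det$loci$n_distinct, 5L)
  expect_false(det$loci$both_strands)
  expect_identical(sort(det$members$sequence), paste0("s", 1:5))
  # empty input
  expect_identical(nrow(detect_loci(aln[0, ])$loci), 0L)
})

test_that("false-positive loci under a uniform null are rare", {
  set.seed(42)
  n_pos <- 200L
  aln <- data.frame(sequence = paste0("n", seq_len(n_pos)),
                    chrom = "chr1",
                    start = sort(sample.int(200000L, n_pos)),
                    strand = sample(c("+", "-"), n_pos, replace = TRUE),
                    stringsAsFactors = FALSE)
  aln$end <- aln$start + 21L
  det <- detect_loci(aln)
  # ~9500 windows at this density; alpha = 1e-4 admits only scattered
  # coincidental registers
  expect_lte(nrow(det$loci), 3L)
})

test_that("post-filters remove multimappers and blacklisted loci", {
  reg <- 0L
  mk_locus <- function(chrom, offset, tag) {
    starts <- offset + 21L * (0:4)
    data.frame(sequence = paste0(tag, 1:5), chrom = chrom, start = starts,
               end = starts + 21L, strand = "+", stringsAsFactors = FALSE)
  }
  aln <- rbind(mk_locus("chr1", 1050L, "a"), mk_locus("chr1", 9030L, "b"),
               mk_locus("chr1", 20013L, "c"))
  det <- detect_loci(aln)
  expect_identical(nrow(det$loci), 3L)
  hits <- setNames(rep(1L, 15), aln$sequence)
  hits[paste0("b", 1:5)] <- 12L        # every member of locus b multimaps
  bl <- data.frame(chrom = "chr1", start = 20000L, end = 20500L)
  filt <- postfilter_loci(det, hits, blacklist = bl)
  expect_identical(nrow(filt$loci), 1L)
  expect_identical(sort(unique(filt$members$sequence)), paste0("a", 1:5))
  rem <- attr(filt, "removed")
  expect_identical(unname(rem["multimapped_members"]), 5L)
  expect_identical(unname(rem["loci_blacklisted"]), 1L)
  # pass-through for unique members and no blacklist overlap
  filt2 <- postfilter_loci(det, setNames(rep(1L, 15), aln$sequence))
  expect_identical(nrow(filt2$loci), 3L)
  expect_error(postfilter_loci(det, hits,
                               blacklist = data.frame(chrom = "chr1",
                                                      start = 10L, end = 5L)),
               "malformed")
})

test_that("two-pass recruitment applies the exact-then-relaxed thresholds", {
  set.seed(43)
  reg <- 0L
  starts <- 2100L + 21L * (0:4)
  member_seqs <- vapply(1:5, function(i) random_dna_str(21), character(1))
  aln <- data.frame(sequence = member_seqs, chrom = "chr1", start = starts,
                    end = starts + 21L, strand = "+", stringsAsFactors = FALSE)
  det <- detect_loci(aln)
  expect_identical(nrow(det$loci), 1L)
  # candidate 1: identical to member 1 except its last 3 nt -> an 18-nt
  # exact stretch, recruited in pass 1
  c1 <- member_seqs[1]
  substr(c1, 19, 21) <- chartr("ACGT", "CATG", substr(c1, 19, 21))
  # candidate 2: two internal mismatches over the full length -> 19/21
  # identity, no 18-nt exact stretch, recruited in pass 2 only
  c2 <- member_seqs[2]
  for (p in c(7, 14)) {
    substr(c2, p, p) <- chartr("ACGT", "CATG", substr(c2, p, p))
  }
  expect_identical(nrow(local_match(
    c2, setNames(member_seqs[2], "m"),
    match_params(min_identity_frac = 1, min_coverage_frac = 0.85))), 0L)
  # candidate 3: unrelated
  c3 <- "AACCAACCAACCAACCAACCA"
  out <- recruit_members(det, c(c1, c2, c3))
  got <- out$members[out$members$origin != "core", ]
  expect_identical(setNames(got$origin, got$sequence)[c(c1, c2)],
                   setNames(c("pass1", "pass2"), c(c1, c2)))
  expect_false(c3 %in% got$sequence)
})

test_that("pass-1 recruits are a subset of direct relaxed recruitment", {
  set.seed(44)
  starts <- 4200L + 21L * (0:5)
  member_seqs <- vapply(1:6, function(i) random_dna_str(21), character(1))
  aln <- data.frame(sequence = member_seqs, chrom = "chr1", start = starts,
                    end = starts + 21L, strand = "+", stringsAsFactors = FALSE)
  det <- detect_loci(aln, min_members = 3L)
  cands <- unlist(lapply(member_seqs, function(s) {
    x <- s
    for (p in sample.int(21, sample(0:3, 1))) {
      substr(x, p, p) <- sample(c("A", "C", "G", "T"), 1)
    }
    x
  }))
  cands <- setdiff(cands, member_seqs)
  strict <- local_match(cands, setNames(member_seqs, paste0("m", 1:6)),
                        match_params(min_identity_frac = 1,
                                     min_coverage_frac = 0.85))
  relaxed <- local_match(cands, setNames(member_seqs, paste0("m", 1:6)),
                         match_params(min_identity_frac = 0.85,
                                      min_coverage_frac = 0.85))
  expect_true(all(unique(strict$query) %in% unique(relaxed$query)))
})
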