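adapter <- "TGGAATTC"

test_that("adapter trimming cuts suffix overlaps and full occurrences", {
  rd <- data.frame(id = paste0("r", 1:5),
                   sequence = c(paste0("ACGTACGT", adapter),  # full adapter
                                "ACGTACGTACGTACGTACGT",        # no adapter
                                adapter,                       # adapter only
                                paste0("ACGTACGTACGT", substr(adapter, 1, 6)),
                                paste0("ACGTACGTACGT", substr(adapter, 1, 3))),
                   stringsAsFactors = FALSE)
  tr <- trim_reads(rd, adapter = adapter)
  expect_identical(tr$reads$sequence,
                   c("ACGTACGT",
                     "ACGTACGTACGTACGTACGT",
                     "ACGTACGTACGT",          # 6-nt suffix overlap removed
                     paste0("ACGTACGTACGT", substr(adapter, 1, 3))))
  # adapter-only read dropped as a zero-length insert
  expect_identical(unname(tr$dropped["empty_after_trim"]), 1L)
})

test_that("trimming without an adapter and bad parameters behave", {
  rd <- data.frame(id = "r1", sequence = "ACGTACGTACGTACGTACGTA",
                   stringsAsFactors = FALSE)
  expect_identical(trim_reads(rd)$reads$sequence, rd$sequence)
  expect_error(trim_reads(rd, adapter = ""), "non-empty")
  expect_error(trim_reads(rd, adapter = adapter, min_overlap = 2L), ">= 5")
})

test_that("mean-quality filtering drops low quality reads", {
  rd <- data.frame(id = c("ok", "bad"),
                   sequence = c("ACGTACGTACGTACGTACGTA",
                                "ACGTACGTACGTACGTACGTA"),
                   quality = c(strrep("I", 21), strrep("#", 21)),
                   stringsAsFactors = FALSE)
  tr <- trim_reads(rd, min_quality = 20)
  expect_identical(tr$reads$id, "ok")
  expect_identical(unname(tr$dropped["low_quality"]), 1L)
})

test_that("collapse counts per library and enforces the length range", {
  s21 <- strrep("ACGTACGTACGTACGTACGTA", 1)
  sets <- list(A = c(rep(s21, 3), random_dna_str(17), random_dna_str(29)),
               B = character(0))
  d <- collapse_reads(sets)
  expect_identical(nrow(d), 1L)
  expect_identical(d$count_A, 3L)
  expect_identical(d$count_B, 0L)
  expect_identical(sum(attr(d, "discarded")), 2L)
  # conservation: retained + discarded equals input
  expect_identical(sum(d$count_A) + unname(attr(d, "discarded")["A"]),
                   length(sets$A))
  expect_identical(nrow(collapse_reads(list(A = character(0)))), 0L)
})

test_that("collapse is order-independent and idempotent", {
  set.seed(5)
  pool <- vapply(1:30, function(i) random_dna_str(sample(18:28, 1)),
                 character(1))
  reads <- sample(pool, 400, replace = TRUE)
  d1 <- collapse_reads(list(A = reads, B = rev(reads)))
  d2 <- collapse_reads(list(A = sample(reads), B = reads))
  expect_identical(d1$sequence, d2$sequence)
  expect_identical(d1$count_A, d2$count_A)
  expect_identical(d1$count_A, d1$count_B)
})

test_that("rpm normalisation is exact and sums to one million", {
  d <- collapse_reads(list(A = rep("ACGTACGTACGTACGTACGTA", 50),
                           B = character(0)))
  out <- normalize_rpm(d, totals = c(A = 2e6, B = 1))
  expect_identical(out$rpm_A, 25)
  expect_identical(out$rpm_B, 0)
  sim <- default_simulation(42L)
  d2 <- normalize_rpm(collapse_reads(lapply(sim$reads, `[[`, "sequence")))
  expect_equal(sum(d2$rpm_A), 1e6, tolerance = 1e-9)
  expect_equal(sum(d2$rpm_B), 1e6, tolerance = 1e-9)
  bad <- d
  expect_error(normalize_rpm(bad, totals = c(A = 0, B = 1)), "zero total")
})
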