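# Independent oracles and fixture builders shared across the test files.
# Each oracle re-derives the quantity from first principles by a different
# route than the package implementation.

# Exhaustive hypergeometric upper tail: direct summation of the counting
# formula with choose().
hyper_tail_oracle <- function(k, N, K, n) {
  if (k <= 0) return(1)
  i <- k:min(n, K)
  i <- i[i >= max(0, n - (N - K))]
  if (length(i) == 0) return(0)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Log-domain g statistic: log O and log E summed separately.
gtest_oracle <- function(observed, expected) {
  expected <- expected * sum(observed) / sum(expected)
  nz <- observed > 0
  2 * sum(observed[nz] * (log(observed[nz]) - log(expected[nz])))
}

# High-precision g statistic: 50-digit log-domain evaluation through
# mpmath. Takes a list of (observed, expected) pairs, returns one G per
# table.
gtest_oracle_mp <- function(tables) {
  inp <- tempfile(fileext = ".tsv")
  lines <- vapply(tables, function(tb) {
    paste(paste(tb$observed, collapse = ","),
          paste(format(tb$expected, digits = 17), collapse = ","),
          sep = ";")
  }, character(1))
  writeLines(lines, inp)
  script <- paste(
    "import sys, mpmath as mp",
    "mp.mp.dps = 50",
    "for line in open(sys.argv[1]):",
    "    o_s, e_s = line.strip().split(';')",
    "    O = [mp.mpf(x) for x in o_s.split(',')]",
    "    E = [mp.mpf(x) for x in e_s.split(',')]",
    "    s = sum(O) / sum(E)",
    "    G = 2 * sum(o * (mp.log(o) - mp.log(e * s))",
    "                for o, e in zip(O, E) if o > 0)",
    "    print(mp.nstr(G, 17))",
    sep = "\n")
  out <- system2("python", c("-c", shQuote(script), shQuote(inp)),
                 stdout = TRUE)
  unlink(inp)
  as.numeric(out)
}

# Brute-force all-offsets ungapped local matcher. Mirrors the reported
# best-window tie-breaking (most identities, then longest, then leftmost
# at the scan order len-descending / start-ascending) so results are
# comparable row by row.
brute_local_match <- function(query, subject, min_ident = 0.85,
                              min_cov = 0.85, min_len = 16L) {
  m <- nchar(query)
  need <- max(min_len, as.integer(ceiling(min_cov * m - 1e-9)))
  rows <- list()
  for (strand in c("+", "-")) {
    q <- if (strand == "+") query else phasekit::revcomp(query)
    qs <- strsplit(q, "")[[1]]
    ss <- strsplit(subject, "")[[1]]
    n <- length(ss)
    for (diag in (-(m - need)):(n - need)) {
      q0 <- max(0L, -diag)
      q1 <- min(m, n - diag)
      L <- q1 - q0
      if (L < need) next
      seg <- qs[(q0 + 1):q1] == ss[(q0 + diag + 1):(q1 + diag)]
      b_id <- -1L; b_len <- 0L; b_a <- 0L
      for (len in seq(L, need)) {
        for (a in 0:(L - len)) {
          id <- sum(seg[(a + 1):(a + len)])
          if (id < ceiling(min_ident * len - 1e-9)) next
          if (id > b_id || (id == b_id && len > b_len)) {
            b_id <- id; b_len <- len; b_a <- a
          }
        }
      }
      if (b_len > 0L) {
        qo <- q0 + b_a
        rows[[length(rows) + 1L]] <- data.frame(
          strand = strand,
          query_offset = if (strand == "+") qo else m - qo - b_len,
          subject_offset = qo + diag,
          aligned_len = b_len, identities = b_id,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(strand = character(0), query_offset = integer(0),
               subject_offset = integer(0), aligned_len = integer(0),
               identities = integer(0), stringsAsFactors = FALSE)
}

# Assemble a reference_bundle directly from parts (for constructed
# annotation fixtures).
make_test_bundle <- function(genome, mirna = NULL, ncrna = NULL,
                             repeats = NULL, features = NULL,
                             blacklist = NULL, triggers = NULL) {
  db <- function(x) {
    if (is.null(x)) data.frame(id = character(0), sequence = character(0),
                               stringsAsFactors = FALSE)
    else data.frame(id = names(x), sequence = unname(x),
                    stringsAsFactors = FALSE)
  }
  mirna_db <- db(mirna)
  if (nrow(mirna_db)) {
    mirna_db$family <- mirna_db$id
    mirna_db$type <- "canonical"
    mirna_db <- mirna_db[, c("id", "family", "type", "sequence")]
  } else {
    mirna_db <- data.frame(id = character(0), family = character(0),
                           type = character(0), sequence = character(0),
                           stringsAsFactors = FALSE)
  }
  structure(list(
    genome = genome,
    features = features %||% data.frame(chrom = character(0),
                                        start = integer(0), end = integer(0),
                                        class = character(0),
                                        subclass = character(0),
                                        id = character(0),
                                        stringsAsFactors = FALSE),
    mirna_db = mirna_db, ncrna_db = db(ncrna), repeat_db = db(repeats),
    trigger_db = db(triggers),
    blacklist = blacklist %||% data.frame(chrom = character(0),
                                          start = integer(0),
                                          end = integer(0),
                                          stringsAsFactors = FALSE),
    seed = NA_integer_, config = NULL), class = "reference_bundle")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# One shared default-scale simulation for the heavier tests; built once
# per test session.
.sim_cache <- new.env(parent = emptyenv())
default_simulation <- function(seed = 42L) {
  key <- paste0("s", seed)
  if (!exists(key, envir = .sim_cache)) {
    bundle <- generate_reference(seed = seed)
    planted <- plant_phased_loci(bundle, n_loci = 60L, seed = seed + 1L)
    sim <- simulate_libraries(planted, seed = seed + 2L)
    assign(key, sim, envir = .sim_cache)
  }
  get(key, envir = .sim_cache)
}

# Detection run on a simulation: collapse, map the 21-nt distincts and
# detect + postfilter loci; returns pieces the tests interrogate.
detection_run <- function(sim) {
  sets <- lapply(sim$reads, function(r) r$sequence)
  d <- normalize_rpm(collapse_reads(sets))
  aln <- map_to_genome(d$sequence[d$length == 21L], sim$bundle$genome)
  det <- detect_loci(aln)
  hits <- attr(aln, "genome_hits")
  det <- postfilter_loci(det, hits, blacklist = sim$bundle$blacklist)
  list(distincts = d, alignments = aln, det = det)
}

# Overlap-match detected loci to truth loci; returns the truth row index
# per detected locus (NA when unmatched).
match_loci_to_truth <- function(det_loci, truth_loci) {
  vapply(seq_len(nrow(det_loci)), function(i) {
    m <- which(truth_loci$chrom == det_loci$chrom[i] &
                 truth_loci$start < det_loci$end[i] &
                 det_loci$start[i] < truth_loci$end)
    if (length(m)) m[1] else NA_integer_
  }, integer(1))
}
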