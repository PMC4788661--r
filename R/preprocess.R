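#' Trim adapters and filter reads by quality
#'
#' Removes the 3' adapter by exact suffix-prefix matching: the read is cut
#' at the first full internal occurrence of the adapter, otherwise at the
#' longest read suffix that equals an adapter prefix of at least
#' `min_overlap` nt. Reads whose mean Phred quality falls below
#' `min_quality` and reads left empty after trimming are dropped.
#'
#' @param reads data.frame with `id`, `sequence` and optional `quality`
#'   (as returned by [read_reads()])
#' @param adapter adapter sequence (A/C/G/T), or `NULL` to skip adapter
#'   trimming
#' @param min_quality minimum mean Phred quality (applied when qualities
#'   are present)
#' @param min_overlap minimum suffix-prefix overlap for adapter removal
#' @return a list with `reads` (trimmed data.frame) and `dropped` (named
#'   counts: low_quality, empty_after_trim)
#' @export
trim_reads <- function(reads, adapter = NULL, min_quality = 20,
                       min_overlap = 5L) {
  stopifnot(is.data.frame(reads), "sequence" %in% names(reads))
  if (!is.null(adapter)) {
    if (!nzchar(adapter)) stopf("adapter sequence must be non-empty")
    assert_dna(adapter, "adapter")
    if (min_overlap < 5L) stopf("min_overlap must be >= 5")
  }
  seqs <- reads$sequence
  n_in <- length(seqs)
  keep_q <- rep(TRUE, n_in)
  if (!is.null(reads$quality) && any(!is.na(reads$quality))) {
    qual <- Biostrings::PhredQuality(reads$quality)
    mq <- vapply(as(qual, "IntegerList"), mean, numeric(1))
    keep_q <- mq >= min_quality
  }
  if (!is.null(adapter) && n_in > 0L) {
    # full internal occurrence: cut at the first match
    hit <- regexpr(adapter, seqs, fixed = TRUE)
    cut_at <- ifelse(hit > 0L, hit - 1L, nchar(seqs))
    # suffix-prefix overlap: longest suffix equal to an adapter prefix
    alen <- nchar(adapter)
    rlen <- nchar(seqs)
    kmax <- min(alen - 1L, max(rlen))
    for (k in if (kmax >= min_overlap) kmax:min_overlap else integer(0)) {
      pref <- substr(adapter, 1L, k)
      cand <- cut_at == rlen & rlen >= k &
        substr(seqs, rlen - k + 1L, rlen) == pref
      cut_at[cand] <- rlen[cand] - k
    }
    seqs <- substr(seqs, 1L, cut_at)
  }
  empty <- !nzchar(seqs)
  keep <- keep_q & !empty
  out <- reads[keep, , drop = FALSE]
  out$sequence <- seqs[keep]
  if (!is.null(out$quality)) {
    out$quality <- substr(out$quality, 1L, nchar(out$sequence))
  }
  rownames(out) <- NULL
  list(reads = out,
       dropped = c(low_quality = sum(!keep_q),
                   empty_after_trim = sum(empty & keep_q)))
}

#' Collapse reads to distinct sequences with per-library counts
#'
#' @param read_sets named list (one element per library) of character
#'   vectors of trimmed read sequences
#' @param min_len,max_len retained length range in nt
#' @return a data.frame of class `distinct_reads`: `sequence`, `length`,
#'   one `count_<lib>` column per library; the attribute `discarded`
#'   holds per-library counts of reads outside the length range
#' @export
collapse_reads <- function(read_sets, min_len = 18L, max_len = 28L) {
  stopifnot(is.list(read_sets), length(names(read_sets)) == length(read_sets))
  libs <- names(read_sets)
  tabs <- list()
  discarded <- setNames(integer(length(libs)), libs)
  for (lib in libs) {
    s <- read_sets[[lib]]
    len <- nchar(s)
    ok <- len >= min_len & len <= max_len
    discarded[lib] <- sum(!ok)
    tabs[[lib]] <- table(s[ok])
  }
  all_seq <- sort(unique(unlist(lapply(tabs, names))))
  out <- data.frame(sequence = all_seq, length = nchar(all_seq),
                    stringsAsFactors = FALSE)
  for (lib in libs) {
    cnt <- integer(length(all_seq))
    idx <- match(names(tabs[[lib]]), all_seq)
    cnt[idx] <- as.integer(tabs[[lib]])
    out[[paste0("count_", lib)]] <- cnt
  }
  rownames(out) <- NULL
  attr(out, "discarded") <- discarded
  class(out) <- c("distinct_reads", "data.frame")
  out
}

#' Fill reads-per-million normalised abundances
#'
#' @param distincts a `distinct_reads` data.frame
#' @param totals named per-library totals; defaults to the column sums of
#'   the retained counts
#' @return `distincts` with one `rpm_<lib>` column per library
#' @export
normalize_rpm <- function(distincts, totals = NULL) {
  libs <- sub("^count_", "", grep("^count_", names(distincts), value = TRUE))
  if (is.null(totals)) {
    totals <- vapply(libs, function(l) sum(distincts[[paste0("count_", l)]]),
                     numeric(1))
  }
  for (lib in libs) {
    cnt <- distincts[[paste0("count_", lib)]]
    tot <- totals[[lib]]
    if (tot <= 0) {
      if (any(cnt > 0)) stopf("library %s has zero total but nonzero counts",
                              lib)
      distincts[[paste0("rpm_", lib)]] <- 0
    } else {
      distincts[[paste0("rpm_", lib)]] <- cnt * 1e6 / tot
    }
  }
  distincts
}

#' Preprocess two libraries from FASTQ to normalised distinct sequences
#'
#' Convenience wrapper: read, trim, collapse and normalise.
#'
#' @param paths named character vector of FASTQ paths (names are library
#'   labels)
#' @param adapter optional adapter sequence
#' @param min_quality minimum mean Phred quality
#' @param min_len,max_len retained length range
#' @return a normalised `distinct_reads` data.frame; attributes
#'   `discarded` and `n_input`/`n_trimmed` record conservation counts
#' @export
preprocess_libraries <- function(paths, adapter = NULL, min_quality = 20,
                                 min_len = 18L, max_len = 28L) {
  sets <- list()
  n_input <- n_trimmed <- setNames(integer(length(paths)), names(paths))
  for (lib in names(paths)) {
    rd <- read_reads(paths[[lib]])
    n_input[lib] <- nrow(rd)
    tr <- trim_reads(rd, adapter = adapter, min_quality = min_quality)
    n_trimmed[lib] <- nrow(tr$reads)
    sets[[lib]] <- tr$reads$sequence
  }
  out <- normalize_rpm(collapse_reads(sets, min_len, max_len))
  attr(out, "n_input") <- n_input
  attr(out, "n_trimmed") <- n_trimmed
  out
}
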