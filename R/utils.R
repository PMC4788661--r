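`%||%` <- function(a, b) if (is.null(a)) b else a

DNA_BASES <- c("A", "C", "G", "T")

#' Random DNA string
#' @param n length in nt
#' @return a single character string over A/C/G/T
#' @keywords internal
random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

#' Reverse complement of character sequences
#' @param x character vector of A/C/G/T sequences
#' @return character vector of reverse complements
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

assert_dna <- function(x, what = "sequence") {
  bad <- grepl("[^ACGT]", x)
  if (any(bad)) {
    stop(sprintf("%s contains non-ACGT characters (first offender: '%s')",
                 what, x[which(bad)[1]]), call. = FALSE)
  }
  invisible(TRUE)
}

# Deterministic substring extraction from a genome list (character vectors of
# full chromosome strings). 0-based half-open coordinates throughout.
genome_substr <- function(genome, chrom, start, end) {
  substr(genome[[chrom]], start + 1L, end)
}

# Overlap of 0-based half-open intervals (a_start, a_end) x (b_start, b_end)
intervals_overlap <- function(a_start, a_end, b_start, b_end) {
  a_start < b_end & b_start < a_end
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

# sample() that never falls into the scalar-x trap
resample <- function(x, n = length(x), replace = FALSE) {
  x[sample.int(length(x), n, replace = replace)]
}
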