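#' Matching thresholds for the ungapped local matcher
#'
#' The matcher accepts an ungapped local alignment when its length is at
#' least `max(min_match_len, ceiling(min_coverage_frac * query length))`
#' and its identity fraction is at least `min_identity_frac`.
#'
#' @param min_identity_frac minimum identity fraction over the aligned
#'   segment, in (0, 1]
#' @param min_coverage_frac minimum aligned fraction of the query, in
#'   (0, 1]
#' @param min_match_len minimum aligned length in nt
#' @return a list of class `match_params`
#' @export
match_params <- function(min_identity_frac = 0.85, min_coverage_frac = 0.85,
                         min_match_len = 16L) {
  if (min_identity_frac <= 0 || min_identity_frac > 1 ||
      min_coverage_frac <= 0 || min_coverage_frac > 1) {
    stopf("identity and coverage fractions must lie in (0, 1]")
  }
  if (min_match_len < 1L) stopf("min_match_len must be >= 1")
  structure(list(min_identity_frac = min_identity_frac,
                 min_coverage_frac = min_coverage_frac,
                 min_match_len = as.integer(min_match_len)),
            class = "match_params")
}

#' Ungapped all-offsets local matching of short queries against a database
#'
#' For every query/subject pair, every diagonal on both subject strands is
#' scanned and the best window (most identities, then longest, then
#' leftmost) passing the thresholds is reported; diagonals with no
#' accepted window are omitted.
#'
#' @param queries character vector of query sequences (A/C/G/T)
#' @param database character vector of subject sequences; names are used
#'   as subject identifiers
#' @param params a [match_params()]
#' @param first_only stop at the first accepted match per query (fast
#'   existence test)
#' @return a data.frame with `query` (sequence), `subject_id`,
#'   `subject_offset` (0-based), `query_offset` (0-based, plus-strand
#'   query coordinates), `strand`, `aligned_len`, `identities`,
#'   `identity_frac`, `coverage_frac`
#' @export
local_match <- function(queries, database, params = match_params(),
                        first_only = FALSE) {
  stopifnot(inherits(params, "match_params"))
  if (length(queries) == 0L || length(database) == 0L) {
    return(empty_match_table())
  }
  assert_dna(queries, "query")
  if (any(nchar(queries) < params$min_match_len)) {
    stopf("queries must be at least min_match_len (%d) nt",
          params$min_match_len)
  }
  ids <- names(database) %||% as.character(seq_along(database))
  m <- cpp_local_match(queries, unname(database),
                       params$min_identity_frac, params$min_coverage_frac,
                       params$min_match_len, first_only)
  if (nrow(m) == 0L) return(empty_match_table())
  qlen <- nchar(queries)[m$query]
  data.frame(query = queries[m$query],
             subject_id = ids[m$subject],
             subject_offset = m$subject_offset,
             query_offset = m$query_offset,
             strand = ifelse(m$strand > 0L, "+", "-"),
             aligned_len = m$aligned_len,
             identities = m$identities,
             identity_frac = m$identities / m$aligned_len,
             coverage_frac = m$aligned_len / qlen,
             stringsAsFactors = FALSE)
}

empty_match_table <- function() {
  data.frame(query = character(0), subject_id = character(0),
             subject_offset = integer(0), query_offset = integer(0),
             strand = character(0), aligned_len = integer(0),
             identities = integer(0), identity_frac = numeric(0),
             coverage_frac = numeric(0), stringsAsFactors = FALSE)
}

#' Map distinct sequences to the genome
#'
#' Reports every genomic placement on both strands. With
#' `max_mismatches = 0` (the default) all sequences are matched exactly
#' via Biostrings dictionaries; with a positive value each sequence is
#' matched individually allowing up to that many substitutions.
#' Minus-strand hits are reported with plus-strand leftmost coordinates.
#'
#' @param sequences character vector of distinct sequences
#' @param genome named list of chromosome strings (or a `reference_bundle`
#'   genome element)
#' @param max_mismatches maximum substitutions per alignment
#' @return a data.frame with `sequence`, `chrom`, `start` (0-based),
#'   `end` (half-open), `strand`, `mismatches`; the attribute
#'   `genome_hits` is a named integer vector of placement counts per
#'   sequence (0 for unmapped)
#' @export
map_to_genome <- function(sequences, genome, max_mismatches = 0L) {
  sequences <- unique(sequences)
  out <- list()
  if (length(sequences) > 0L) {
    subj <- lapply(genome, Biostrings::DNAString)
    if (max_mismatches == 0L) {
      by_len <- split(sequences, nchar(sequences))
      for (grp in by_len) {
        for (strand in c("+", "-")) {
          pat <- if (strand == "+") grp else revcomp(grp)
          pd <- Biostrings::PDict(pat)
          for (chrom in names(subj)) {
            mi <- Biostrings::matchPDict(pd, subj[[chrom]])
            nhit <- S4Vectors::elementNROWS(mi)
            if (sum(nhit) == 0L) next
            ir <- unlist(mi)
            qidx <- rep.int(seq_along(grp), nhit)
            out[[length(out) + 1L]] <- data.frame(
              sequence = grp[qidx], chrom = chrom,
              start = BiocGenerics::start(ir) - 1L,
              end = BiocGenerics::end(ir),
              strand = strand, mismatches = 0L, stringsAsFactors = FALSE)
          }
        }
      }
    } else {
      for (sq in sequences) {
        for (strand in c("+", "-")) {
          pat <- if (strand == "+") sq else revcomp(sq)
          for (chrom in names(subj)) {
            ir <- Biostrings::matchPattern(pat, subj[[chrom]],
                                           max.mismatch = max_mismatches)
            if (length(ir) == 0L) next
            mm <- vapply(as.character(ir), function(hit) {
              sum(utf8ToInt(hit) != utf8ToInt(pat))
            }, integer(1), USE.NAMES = FALSE)
            out[[length(out) + 1L]] <- data.frame(
              sequence = sq, chrom = chrom,
              start = BiocGenerics::start(ir) - 1L,
              end = BiocGenerics::end(ir),
              strand = strand, mismatches = mm, stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  aln <- if (length(out)) do.call(rbind, out) else
    data.frame(sequence = character(0), chrom = character(0),
               start = integer(0), end = integer(0), strand = character(0),
               mismatches = integer(0), stringsAsFactors = FALSE)
  aln <- aln[order(aln$sequence, aln$chrom, aln$start, aln$strand), ]
  rownames(aln) <- NULL
  hits <- setNames(integer(length(sequences)), sequences)
  tb <- table(aln$sequence)
  hits[names(tb)] <- as.integer(tb)
  attr(aln, "genome_hits") <- hits
  aln
}

# TRUE for alignments overlapping any interval of `iv` (same chromosome)
overlaps_features <- function(aln, iv) {
  if (nrow(aln) == 0L || nrow(iv) == 0L) return(rep(FALSE, nrow(aln)))
  q <- GenomicRanges::GRanges(aln$chrom,
                              IRanges::IRanges(aln$start + 1L, aln$end))
  s <- GenomicRanges::GRanges(iv$chrom,
                              IRanges::IRanges(iv$start + 1L, iv$end))
  IRanges::overlapsAny(q, s)
}

#' Hierarchical first-hit-wins classification of distinct sequences
#'
#' Sequences are tested tier by tier (miRNA database, ncRNA database,
#' repeat database, then genome placements overlapping CDS features, then
#' intron/UTR features); the first tier with an accepted match fixes the
#' class. Sequences whose only placements fall outside gene features are
#' "unannotated"; sequences matching nothing are "unmapped". CDS and
#' intron/UTR assignments share the class "gene" with the subclass
#' recorded.
#'
#' @param distincts a `distinct_reads` data.frame
#' @param bundle a `reference_bundle` providing the ordered databases,
#'   gene features and genome
#' @param params a [match_params()]
#' @param max_mismatches substitutions allowed during genome mapping
#' @return `distincts` with columns `annotation_class`,
#'   `annotation_subclass`, `annotation_id` and `genome_hits` added; the
#'   attribute `alignments` carries the genome placements of all
#'   sequences
#' @export
classify_hierarchical <- function(distincts, bundle,
                                  params = match_params(),
                                  max_mismatches = 0L) {
  stopifnot(inherits(bundle, "reference_bundle"))
  seqs <- distincts$sequence
  class <- rep(NA_character_, length(seqs))
  subclass <- rep(NA_character_, length(seqs))
  ann_id <- rep(NA_character_, length(seqs))

  tiers <- list(miRNA = setNames(bundle$mirna_db$sequence, bundle$mirna_db$id),
                ncRNA = setNames(bundle$ncrna_db$sequence, bundle$ncrna_db$id),
                "repeat" = setNames(bundle$repeat_db$sequence,
                                    bundle$repeat_db$id))
  for (tier in names(tiers)) {
    db <- tiers[[tier]]
    if (is.null(db)) stopf("missing database for tier '%s'", tier)
    todo <- which(is.na(class))
    if (length(todo) == 0L || length(db) == 0L) next
    m <- local_match(seqs[todo], db, params, first_only = TRUE)
    if (nrow(m) == 0L) next
    hit <- match(seqs[todo], m$query)
    got <- !is.na(hit)
    class[todo[got]] <- tier
    ann_id[todo[got]] <- m$subject_id[hit[got]]
  }

  aln <- map_to_genome(seqs, bundle$genome, max_mismatches)
  genome_hits <- attr(aln, "genome_hits")
  mapped <- names(genome_hits)[genome_hits > 0L]

  gene_feats <- bundle$features[bundle$features$class == "gene", ,
                                drop = FALSE]
  todo <- which(is.na(class))
  if (length(todo) > 0L) {
    sub_aln <- aln[aln$sequence %in% seqs[todo], , drop = FALSE]
    for (tier in list(c("CDS", "CDS"), c("intron/UTR", "intron"),
                      c("intron/UTR", "UTR"))) {
      iv <- gene_feats[gene_feats$subclass == tier[2], , drop = FALSE]
      ov <- overlaps_features(sub_aln, iv)
      hit_seqs <- unique(sub_aln$sequence[ov])
      idx <- todo[seqs[todo] %in% hit_seqs & is.na(class[todo])]
      class[idx] <- "gene"
      subclass[idx] <- tier[2]
    }
    todo <- which(is.na(class))
    idx <- todo[seqs[todo] %in% mapped]
    class[idx] <- "unannotated"
    class[which(is.na(class))] <- "unmapped"
  }

  distincts$annotation_class <- class
  distincts$annotation_subclass <- subclass
  distincts$annotation_id <- ann_id
  distincts$genome_hits <- as.integer(genome_hits[seqs])
  attr(distincts, "alignments") <- aln
  distincts
}

#' Per-class proportions of distinct sequences
#'
#' @param distincts a classified `distinct_reads` data.frame (or any
#'   data.frame with `annotation_class`)
#' @param include_unmapped count unmapped sequences as their own class
#' @return named numeric vector of proportions summing to 1
#' @export
class_composition <- function(distincts, include_unmapped = FALSE) {
  cls <- distincts$annotation_class
  if (!include_unmapped) cls <- cls[cls != "unmapped"]
  if (length(cls) == 0L) stopf("no classified sequences: proportions undefined")
  levels <- c("miRNA", "ncRNA", "repeat", "gene", "unannotated",
              if (include_unmapped) "unmapped")
  tb <- table(factor(cls, levels = levels))
  as.vector(tb) / sum(tb) -> p
  setNames(p, levels)
}
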