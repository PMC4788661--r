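# Plain-text readers/writers for the pipeline's external formats.
# Sequence formats go through Biostrings; tabular formats are written
# with fixed column order and "\n" line endings so that identical inputs
# give byte-identical files.

#' Write sequences to FASTA
#' @param sequences character vector of sequences
#' @param ids record identifiers
#' @param path output file
#' @export
write_fasta <- function(sequences, ids, path) {
  x <- Biostrings::DNAStringSet(setNames(sequences, ids))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a FASTA file into a data.frame of id and sequence
#' @param path FASTA file
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  data.frame(id = names(x), sequence = as.character(x),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write reads to FASTQ with constant 'I' qualities
#' @param sequences character vector of read sequences
#' @param ids read identifiers
#' @param path output file
#' @export
write_fastq <- function(sequences, ids, path) {
  x <- Biostrings::DNAStringSet(setNames(sequences, ids))
  qual <- Biostrings::BStringSet(strrep("I", nchar(sequences)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = qual)
  invisible(path)
}

#' Read a FASTQ (or FASTA) file of small-RNA reads
#' @param path input file
#' @param format "fastq" or "fasta"
#' @return a data.frame with `id`, `sequence` and (for FASTQ) `quality`
#' @export
read_reads <- function(path, format = c("fastq", "fasta")) {
  format <- match.arg(format)
  if (format == "fasta") {
    df <- read_fasta(path)
    df$quality <- NA_character_
    return(df)
  }
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  data.frame(id = names(x), sequence = as.character(x),
             quality = as.character(S4Vectors::mcols(x)$qualities),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write a data.frame as a deterministic TSV
#' @param df data.frame
#' @param path output file
#' @export
write_tsv <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, eol = "\n")
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#' @param path input file
#' @export
read_tsv <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE)
}

#' Write intervals as BED (0-based half-open)
#' @param df data.frame with chrom, start, end and optionally name, score,
#'   strand
#' @param path output file
#' @export
write_bed <- function(df, path) {
  bed <- data.frame(chrom = df$chrom, start = df$start, end = df$end,
                    name = df$name %||% df$locus_id %||% ".",
                    score = df$score %||% 0L,
                    strand = df$strand %||% ".",
                    stringsAsFactors = FALSE)
  bed <- bed[order(bed$chrom, bed$start, bed$end), ]
  con <- file(path, open = "wb")
  on.exit(close(con))
  write.table(bed, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE, eol = "\n")
  invisible(path)
}

#' Read a BED file of intervals
#' @param path BED file
#' @return data.frame with chrom, start, end (0-based half-open) and any
#'   further standard columns present
#' @export
read_bed <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                   comment.char = "#")
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  names(df) <- cols[seq_len(min(ncol(df), 6L))]
  df
}

#' Write feature intervals as GFF3 (1-based inclusive)
#' @param features data.frame with chrom, start, end (0-based half-open),
#'   class, subclass, id
#' @param path output file
#' @export
write_gff3 <- function(features, path) {
  type <- ifelse(is.na(features$subclass), features$class,
                 features$subclass)
  lines <- sprintf("%s\tphasekit\t%s\t%d\t%d\t.\t+\t.\tID=%s;class=%s",
                   features$chrom, type, features$start + 1L, features$end,
                   features$id, features$class)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c("##gff-version 3", lines), con, sep = "\n")
  invisible(path)
}

#' Read a GFF3 written by [write_gff3()]
#' @param path GFF3 file
#' @return data.frame with chrom, start, end (0-based half-open), class,
#'   subclass, id
#' @export
read_gff3 <- function(path) {
  df <- read.delim(path, header = FALSE, comment.char = "#",
                   stringsAsFactors = FALSE)
  names(df) <- c("seqid", "source", "type", "start", "end", "score",
                 "strand", "phase", "attributes")
  id <- sub(";.*$", "", sub("^ID=", "", df$attributes))
  class <- sub("^.*class=", "", df$attributes)
  subclass <- ifelse(df$type %in% c("CDS", "intron", "UTR"), df$type,
                     NA_character_)
  data.frame(chrom = df$seqid, start = df$start - 1L, end = df$end,
             class = class, subclass = subclass, id = id,
             stringsAsFactors = FALSE)
}

#' Write a reference bundle and synthetic libraries to a directory
#'
#' Produces genome FASTA, features GFF3, database FASTAs, blacklist BED,
#' trigger FASTA, per-library FASTQ and truth TSVs.
#'
#' @param sim a `synthetic_libraries` object
#' @param dir output directory (created if missing)
#' @return `dir`, invisibly
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "synthetic_libraries"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  b <- sim$bundle
  write_fasta(unlist(b$genome), names(b$genome), file.path(dir, "genome.fa"))
  write_gff3(b$features, file.path(dir, "features.gff3"))
  write_fasta(b$mirna_db$sequence, b$mirna_db$id, file.path(dir, "mirna.fa"))
  write_tsv(b$mirna_db[, c("id", "family", "type")],
            file.path(dir, "mirna_meta.tsv"))
  if (nrow(b$ncrna_db)) {
    write_fasta(b$ncrna_db$sequence, b$ncrna_db$id,
                file.path(dir, "ncrna.fa"))
  }
  if (nrow(b$repeat_db)) {
    write_fasta(b$repeat_db$sequence, b$repeat_db$id,
                file.path(dir, "repeats.fa"))
  }
  write_fasta(b$trigger_db$sequence, b$trigger_db$id,
              file.path(dir, "triggers.fa"))
  write_bed(b$blacklist, file.path(dir, "blacklist.bed"))
  for (lib in names(sim$reads)) {
    write_fastq(sim$reads[[lib]]$sequence, sim$reads[[lib]]$id,
                file.path(dir, sprintf("library_%s.fastq", lib)))
  }
  write_tsv(sim$truth$loci, file.path(dir, "truth_loci.tsv"))
  write_tsv(sim$truth$members, file.path(dir, "truth_members.tsv"))
  write_tsv(sim$truth$background, file.path(dir, "truth_background.tsv"))
  invisible(dir)
}

#' Read a reference bundle from a directory written by [write_simulation()]
#' @param dir bundle directory
#' @return a `reference_bundle`
#' @export
read_reference_bundle <- function(dir) {
  need <- file.path(dir, c("genome.fa", "features.gff3", "mirna.fa",
                           "triggers.fa"))
  missing <- need[!file.exists(need)]
  if (length(missing)) {
    stopf("reference bundle is missing: %s",
          paste(basename(missing), collapse = ", "))
  }
  gen <- read_fasta(file.path(dir, "genome.fa"))
  genome <- setNames(as.list(gen$sequence), gen$id)
  mirna <- read_fasta(file.path(dir, "mirna.fa"))
  meta_path <- file.path(dir, "mirna_meta.tsv")
  if (file.exists(meta_path)) {
    meta <- read_tsv(meta_path)
    mirna <- merge(mirna, meta, by = "id", sort = FALSE)
  } else {
    mirna$family <- mirna$id
    mirna$type <- "canonical"
  }
  read_db <- function(name) {
    p <- file.path(dir, name)
    if (file.exists(p)) read_fasta(p)
    else data.frame(id = character(0), sequence = character(0))
  }
  bl_path <- file.path(dir, "blacklist.bed")
  blacklist <- if (file.exists(bl_path)) {
    read_bed(bl_path)[, c("chrom", "start", "end")]
  } else {
    data.frame(chrom = character(0), start = integer(0), end = integer(0))
  }
  structure(list(genome = genome,
                 features = read_gff3(file.path(dir, "features.gff3")),
                 mirna_db = mirna[, c("id", "family", "type", "sequence")],
                 ncrna_db = read_db("ncrna.fa"),
                 repeat_db = read_db("repeats.fa"),
                 trigger_db = read_fasta(file.path(dir, "triggers.fa")),
                 blacklist = blacklist,
                 seed = NA_integer_, config = NULL),
            class = "reference_bundle")
}
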