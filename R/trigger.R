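#' Scan locus flanks for a trigger-miRNA recognition site
#'
#' Extracts each locus plus `flank` bp on both sides (truncated at
#' chromosome ends) and scores the complementarity of every 22-nt trigger
#' against every placement on both transcript strands. The penalty scheme
#' is the field's standard plant miRNA target-site scoring: 0 per
#' Watson-Crick pair, 0.5 per G:U wobble, 1 per mismatch, doubled at
#' trigger positions 2-13 (the seed-proximal core around the cleavage
#' site); no gaps. The best placement with penalty at most `threshold` is
#' reported.
#'
#' @param loci_obj a `phased_loci` object (or a data.frame of loci with
#'   `chrom`, `start`, `end`)
#' @param genome named list of chromosome strings
#' @param trigger_db data.frame with `id` and `sequence` (20-24 nt)
#' @param flank bp scanned on each side of the locus
#' @param threshold maximum acceptable penalty
#' @param core trigger positions (1-based, inclusive range) with doubled
#'   penalties
#' @return for a `phased_loci` input, the object with columns
#'   `trigger_name`, `trigger_position` (0-based site start),
#'   `trigger_strand`, `trigger_score`, `trigger_distance` (bp to the
#'   nearest locus end, 0 when overlapping) and `trigger_side` ("5p",
#'   "3p" or "within") added to `$loci` (NA where no placement passes)
#' @export
scan_trigger_site <- function(loci_obj, genome, trigger_db, flank = 500L,
                              threshold = 4.5, core = c(2L, 13L)) {
  loci <- if (inherits(loci_obj, "phased_loci")) loci_obj$loci else loci_obj
  if (flank < 0L) stopf("flank must be non-negative")
  tlen <- nchar(trigger_db$sequence)
  if (any(tlen < 20L | tlen > 24L)) {
    stopf("trigger sequences must be 20-24 nt")
  }
  chrom_len <- vapply(genome, nchar, integer(1))
  n <- nrow(loci)
  res <- data.frame(trigger_name = rep(NA_character_, n),
                    trigger_position = NA_integer_,
                    trigger_strand = NA_character_,
                    trigger_score = NA_real_,
                    trigger_distance = NA_integer_,
                    trigger_side = NA_character_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    chrom <- loci$chrom[i]
    if (!chrom %in% names(genome) ||
        loci$end[i] > chrom_len[chrom] || loci$start[i] < 0L) {
      stopf("locus %s coordinates fall outside the genome",
            loci$locus_id[i] %||% i)
    }
    w0 <- max(0L, loci$start[i] - flank)
    w1 <- min(chrom_len[chrom], loci$end[i] + flank)
    seq <- genome_substr(genome, chrom, w0, w1)
    sc <- cpp_trigger_scan(seq, trigger_db$sequence, core[1], core[2])
    best <- which.min(sc$score)
    if (length(best) == 0L || is.na(sc$score[best]) ||
        sc$score[best] > threshold) next
    site_start <- w0 + sc$position[best]
    site_end <- site_start + nchar(trigger_db$sequence[best])
    if (site_end <= loci$start[i]) {
      dist <- loci$start[i] - site_end
      side <- "5p"
    } else if (site_start >= loci$end[i]) {
      dist <- site_start - loci$end[i]
      side <- "3p"
    } else {
      dist <- 0L
      side <- "within"
    }
    res$trigger_name[i] <- trigger_db$id[best]
    res$trigger_position[i] <- site_start
    res$trigger_strand[i] <- if (sc$strand[best] > 0L) "+" else "-"
    res$trigger_score[i] <- sc$score[best]
    res$trigger_distance[i] <- dist
    res$trigger_side[i] <- side
  }
  if (inherits(loci_obj, "phased_loci")) {
    loci_obj$loci <- cbind(loci_obj$loci, res)
    loci_obj
  } else {
    cbind(loci, res)
  }
}

#' Complementarity penalty of a trigger at one site
#'
#' Direct scoring of a single placement, mainly for inspection and
#' testing: `site` is the transcript-strand sequence the trigger would
#' pair with, aligned end to end.
#'
#' @param site character site sequence (same length as the trigger),
#'   transcript orientation 5'->3'
#' @param trigger trigger miRNA sequence 5'->3'
#' @param core trigger positions with doubled penalties
#' @return numeric penalty
#' @export
trigger_site_score <- function(site, trigger, core = c(2L, 13L)) {
  if (nchar(site) != nchar(trigger)) {
    stopf("site and trigger must have equal length")
  }
  L <- nchar(trigger)
  t <- strsplit(trigger, "")[[1]]
  b <- strsplit(site, "")[[1]][L:1]  # antiparallel pairing
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  pen <- ifelse(b == comp[t], 0,
                ifelse((t == "G" & b == "T") | (t == "T" & b == "G"),
                       0.5, 1))
  dbl <- seq_len(L) >= core[1] & seq_len(L) <= core[2]
  sum(pen * ifelse(dbl, 2, 1))
}
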