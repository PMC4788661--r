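#' Configuration for planted phased loci
#'
#' Defaults reproduce the locus anatomy observed for 21-nt phasiRNA loci
#' in rice panicles: 3-9 distinct members per locus with one or two
#' dominant members (Zipf-weighted abundances), ~59 % of loci carrying a
#' 22-nt trigger recognition site a short distance upstream of the first
#' member, ~92.5 % of loci producing reads from both strands, and ~70 %
#' of loci planted with a 5-10x library-A/library-B fold change.
#'
#' @param n_members_range integer range of distinct members per locus
#' @param trigger_fraction fraction of loci carrying a planted trigger site
#' @param trigger_offset_range admissible distance (bp) between the trigger
#'   site and the nearest locus end; realised offsets are constrained to
#'   the 21-nt cycle geometry (21c - 10 for cleavage between trigger
#'   positions 10 and 11)
#' @param both_strands_fraction fraction of loci producing members from
#'   both strands
#' @param fold_fraction fraction of loci planted with a fold change
#' @param fold_range range the planted fold ratio (A over B) is drawn from
#' @param zipf_exponent exponent of the Zipf member-abundance weights
#' @param max_cycles maximum 21-nt cycles spanned by one locus
#' @return a list of class `locus_config`
#' @export
locus_config <- function(n_members_range = c(3L, 9L),
                         trigger_fraction = 0.593,
                         trigger_offset_range = c(2L, 452L),
                         both_strands_fraction = 0.925,
                         fold_fraction = 0.7,
                         fold_range = c(5, 10),
                         zipf_exponent = 1.5,
                         max_cycles = 10L) {
  stopifnot(n_members_range[1] >= 2L, n_members_range[2] >= n_members_range[1],
            fold_range[1] > 0)
  structure(as.list(environment()), class = "locus_config")
}

# Admissible trigger cycle offsets: the first expressed member sits c>=1
# whole 21-nt cycles downstream of the cleavage position, giving a gap of
# 21c - 10 bp between the 22-nt site and the locus end.
trigger_cycles <- function(offset_range) {
  c_all <- 1:22
  gaps <- 21L * c_all - 10L
  c_all[gaps >= offset_range[1] & gaps <= offset_range[2]]
}

#' Plant phased siRNA loci into a reference bundle
#'
#' Chooses non-overlapping locations in unannotated, non-blacklisted
#' genome space and plants phased 21-nt siRNA loci. For trigger-carrying
#' loci the reverse complement of a 22-nt trigger miRNA is written into
#' the genome flank and the phase register is anchored to the canonical
#' cleavage position between trigger positions 10 and 11; members occupy
#' in-register 21-nt slots on the sense strand (5' starts congruent to the
#' register mod 21) and, for both-strand loci, antisense slots offset by
#' the 2-nt 3'-overhang duplex geometry (leftmost coordinates congruent to
#' register - 2 mod 21).
#'
#' @param bundle a `reference_bundle` from [generate_reference()]
#' @param n_loci number of loci to plant
#' @param config a [locus_config()]
#' @param seed integer RNG seed
#' @return a list of class `planted_loci`: `bundle` (genome updated with
#'   planted trigger sites), `loci` (one row per locus: coordinates,
#'   register, orientation, strands used, trigger offset, fold ratio) and
#'   `members` (one row per member: genomic position, strand, abundance
#'   weight, sequence)
#' @export
plant_phased_loci <- function(bundle, n_loci = 60L, config = locus_config(),
                              seed = 43L) {
  stopifnot(inherits(bundle, "reference_bundle"),
            inherits(config, "locus_config"))
  set.seed(seed)
  chroms <- names(bundle$genome)
  chrom_len <- vapply(bundle$genome, nchar, integer(1))
  occupied <- rbind(bundle$features[, c("chrom", "start", "end")],
                    bundle$blacklist)
  loci <- NULL
  members <- NULL
  if (n_loci == 0L) {
    return(structure(list(bundle = bundle,
                          loci = empty_locus_table(),
                          members = empty_member_table()),
                     class = "planted_loci"))
  }
  trig_cyc <- trigger_cycles(config$trigger_offset_range)
  if (length(trig_cyc) == 0L) stopf("trigger_offset_range admits no cycle")

  for (i in seq_len(n_loci)) {
    n_mem <- resample(config$n_members_range[1]:config$n_members_range[2], 1L)
    both <- runif(1) < config$both_strands_fraction
    has_trigger <- runif(1) < config$trigger_fraction
    # both-strand loci get a random orientation; single-strand loci are
    # oriented '+' so strands_used is literally plus-only
    orientation <- if (both) sample(c("+", "-"), 1L) else "+"
    w_min <- if (both) ceiling(n_mem / 2) else n_mem
    W <- min(config$max_cycles, w_min + sample(0:2, 1L))
    W <- max(W, w_min)
    cmin <- if (has_trigger) resample(trig_cyc, 1L) else 1L
    # slots: (cycle, duplex strand); sense = transcript strand
    slots <- expand.grid(cycle = cmin:(cmin + W - 1L),
                         sense = if (both) c(TRUE, FALSE) else TRUE)
    # force a member in the first cycle so the locus end is anchored at
    # the planted trigger offset
    first_idx <- which(slots$cycle == cmin & slots$sense)
    rest <- setdiff(seq_len(nrow(slots)), first_idx)
    pick <- c(first_idx, resample(rest, n_mem - 1L))
    sl <- slots[pick, , drop = FALSE]
    if (both && all(sl$sense)) { # guarantee both strands represented
      sl$sense[nrow(sl)] <- FALSE
    }

    # genomic geometry; trigger site [t, t+22), members at whole cycles
    span_cycles <- max(sl$cycle) + 1L
    footprint <- 22L + 21L * span_cycles + 60L
    placed <- FALSE
    for (try in seq_len(2000L)) {
      chrom <- sample(chroms, 1L)
      t <- sample.int(chrom_len[chrom] - 2L * footprint, 1L) + footprint
      ext <- c(t - footprint, t + footprint)
      occ <- occupied[occupied$chrom == chrom, , drop = FALSE]
      if (!any(intervals_overlap(ext[1], ext[2], occ$start, occ$end))) {
        placed <- TRUE
        break
      }
    }
    if (!placed) stopf("insufficient unannotated space to place phased loci")

    if (orientation == "+") {
      register <- (t + 12L) %% 21L
      plus_start <- t + 12L + 21L * sl$cycle            # sense members
      minus_start <- t + 10L + 21L * sl$cycle           # antisense members
      start0 <- ifelse(sl$sense, plus_start, minus_start)
      strand <- ifelse(sl$sense, "+", "-")
    } else {
      register <- (t - 9L) %% 21L
      minus_start <- t - 11L - 21L * sl$cycle           # sense members (minus)
      plus_start <- t - 9L - 21L * sl$cycle             # antisense members
      start0 <- ifelse(sl$sense, minus_start, plus_start)
      strand <- ifelse(sl$sense, "-", "+")
    }

    # plant the recognition site (reverse complement of the trigger on the
    # transcript strand)
    trigger_name <- NA_character_
    trigger_offset <- NA_integer_
    if (has_trigger) {
      k <- sample.int(nrow(bundle$trigger_db), 1L)
      trigger_name <- bundle$trigger_db$id[k]
      trig <- bundle$trigger_db$sequence[k]
      site <- if (orientation == "+") revcomp(trig) else trig
      s <- bundle$genome[[chrom]]
      substr(s, t + 1L, t + 22L) <- site
      bundle$genome[[chrom]] <- s
      # gap between the site and the nearest edge of the realised member
      # span (antisense members sit 2 bp closer, by the overhang geometry)
      trigger_offset <- if (orientation == "+") {
        min(start0) - (t + 22L)
      } else {
        t - max(start0 + 21L)
      }
    }

    # Zipf abundance weights over members, ranks assigned at random
    ranks <- sample(seq_len(n_mem))
    w <- ranks^(-config$zipf_exponent)
    w <- w / sum(w)
    fold <- if (runif(1) < config$fold_fraction) {
      runif(1, config$fold_range[1], config$fold_range[2])
    } else 1
    seqs <- vapply(seq_len(n_mem), function(j) {
      sq <- genome_substr(bundle$genome, chrom, start0[j], start0[j] + 21L)
      if (strand[j] == "-") revcomp(sq) else sq
    }, character(1))

    lid <- sprintf("PH%03d", i)
    loci <- rbind(loci, data.frame(
      locus_id = lid, chrom = chrom,
      start = min(start0), end = max(start0) + 21L,
      register = register, orientation = orientation,
      strands_used = if (both) "both" else "plus_only",
      n_members = n_mem, fold_ratio = fold,
      trigger_name = trigger_name, trigger_offset = trigger_offset,
      trigger_site_start = if (has_trigger) t else NA_integer_,
      stringsAsFactors = FALSE))
    members <- rbind(members, data.frame(
      locus_id = lid, member = sprintf("%s_m%02d", lid, seq_len(n_mem)),
      chrom = chrom, start = start0, end = start0 + 21L, strand = strand,
      weight = w, sequence = seqs, stringsAsFactors = FALSE))
    occupied <- rbind(occupied,
                      data.frame(chrom = chrom, start = ext[1], end = ext[2],
                                 stringsAsFactors = FALSE))
  }
  ord <- order(loci$chrom, loci$start)
  loci <- loci[ord, ]
  rownames(loci) <- NULL
  members <- members[order(match(members$locus_id, loci$locus_id),
                           members$start), ]
  rownames(members) <- NULL
  structure(list(bundle = bundle, loci = loci, members = members),
            class = "planted_loci")
}

empty_locus_table <- function() {
  data.frame(locus_id = character(0), chrom = character(0),
             start = integer(0), end = integer(0), register = integer(0),
             orientation = character(0), strands_used = character(0),
             n_members = integer(0), fold_ratio = numeric(0),
             trigger_name = character(0), trigger_offset = integer(0),
             trigger_site_start = integer(0), stringsAsFactors = FALSE)
}

empty_member_table <- function() {
  data.frame(locus_id = character(0), member = character(0),
             chrom = character(0), start = integer(0), end = integer(0),
             strand = character(0), weight = numeric(0),
             sequence = character(0), stringsAsFactors = FALSE)
}

#' @export
print.planted_loci <- function(x, ...) {
  cat(sprintf("Planted phased loci: %d loci, %d members\n",
              nrow(x$loci), nrow(x$members)))
  if (nrow(x$loci)) {
    cat(sprintf("  with trigger site: %d; both strands: %d; fold > 1: %d\n",
                sum(!is.na(x$loci$trigger_name)),
                sum(x$loci$strands_used == "both"),
                sum(x$loci$fold_ratio > 1)))
  }
  invisible(x)
}
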