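#' In-phase predicate for 21-nt genome alignments
#'
#' A plus-strand alignment is in phase with a register when its 5' start
#' is congruent to the register mod 21; a minus-strand alignment when its
#' leftmost coordinate plus 2 is congruent, encoding the 2-nt 3'-overhang
#' duplex geometry of Dicer products.
#'
#' @param start 0-based leftmost alignment coordinates
#' @param strand "+" or "-" per alignment
#' @param register phase register in \[0, 21)
#' @param width alignment widths; must all be 21
#' @return logical vector
#' @export
in_phase <- function(start, strand, register, width = 21L) {
  if (any(width != 21L)) stopf("in_phase is defined for 21-nt alignments only")
  phase_pos <- ifelse(strand == "+", start, start + 2L)
  (phase_pos - register) %% 21L == 0L
}

#' Upper-tail hypergeometric phasing p-value
#'
#' P(X >= k) for X hypergeometric with population size N (eligible start
#' positions), K in-phase positions and n observed distinct starts,
#' computed by log-domain summation of `lchoose` terms.
#'
#' @param k observed in-phase starts
#' @param N eligible positions in the window
#' @param K in-phase positions in the window
#' @param n observed distinct starts
#' @return p-value in (0, 1]
#' @export
phasing_pvalue <- function(k, N, K, n) {
  stopifnot(length(N) == 1L, length(K) == 1L)
  if (any(n > N)) stopf("observed starts exceed eligible positions (n > N)")
  vapply(seq_along(k), function(j) {
    kk <- k[j]
    nn <- if (length(n) > 1L) n[j] else n
    if (kk <= 0L) return(1)
    i <- max(0L, kk):min(nn, K)
    if (length(i) == 0L || min(nn, K) < kk) return(0)
    lt <- lchoose(K, i) + lchoose(N - K, nn - i) - lchoose(N, nn)
    mx <- max(lt)
    min(1, exp(mx) * sum(exp(lt - mx)))
  }, numeric(1))
}

#' Score one phasing window
#'
#' Collects the distinct aligned 5'-start positions (both strands, minus
#' strand offset by +2) inside `[window_start, window_start + 21 * cycles)`
#' and tests how many fall on `register` against the hypergeometric null.
#'
#' @param alignments data.frame of 21-nt alignments with `chrom`, `start`,
#'   `end`, `strand`
#' @param chrom chromosome of the window
#' @param window_start 0-based window start
#' @param register phase register in \[0, 21)
#' @param cycles number of 21-nt cycles per window
#' @return a list of class `phasing_window_score` with fields `chrom`,
#'   `window_start`, `window_len`, `register`, `N`, `K`, `n`, `k`,
#'   `p_value`
#' @export
score_window <- function(alignments, chrom, window_start, register,
                         cycles = 11L) {
  window_len <- 21L * cycles
  a <- alignments[alignments$chrom == chrom &
                    alignments$start >= window_start &
                    alignments$start < window_start + window_len, ,
                  drop = FALSE]
  if (nrow(a) > 0L && any(a$end - a$start != 21L)) {
    stopf("phasing windows are scored on 21-nt alignments only")
  }
  pos <- unique(paste(a$strand, a$start))
  strand <- substr(pos, 1L, 1L)
  start <- as.integer(substring(pos, 3L))
  N <- 2L * window_len
  K <- 2L * cycles
  n <- length(pos)
  k <- if (n) sum(in_phase(start, strand, register)) else 0L
  structure(list(chrom = chrom, window_start = window_start,
                 window_len = window_len, register = as.integer(register),
                 N = N, K = K, n = n, k = k,
                 p_value = phasing_pvalue(k, N, K, n)),
            class = "phasing_window_score")
}

#' @export
print.phasing_window_score <- function(x, ...) {
  cat(sprintf("Phasing window %s:%d-%d register %d: k=%d/n=%d (K=%d/N=%d), p=%.3g\n",
              x$chrom, x$window_start, x$window_start + x$window_len,
              x$register, x$k, x$n, x$K, x$N, x$p_value))
  invisible(x)
}

#' Detect 21-nt phased siRNA loci
#'
#' Slides a `21 * cycles`-nt window along each chromosome in steps of
#' `step` nt, tests all 21 registers in windows holding at least
#' `min_members` distinct start positions, and merges overlapping
#' significant windows sharing a register into loci. A locus spans the
#' minimum to maximum coordinates of its in-phase members.
#'
#' @param alignments data.frame of genome alignments (only 21-nt rows are
#'   used) with `sequence`, `chrom`, `start`, `end`, `strand`
#' @param counts optional data.frame with `sequence` plus `count_*` /
#'   `rpm_*` columns used to fill per-locus abundance sums
#' @param cycles window length in 21-nt cycles
#' @param step window step in nt
#' @param alpha p-value threshold
#' @param min_members minimum distinct member sequences per locus
#' @return an object of class `phased_loci`: list with `loci` (one row
#'   per locus: `locus_id`, `chrom`, `start`, `end`, `register`,
#'   `n_distinct`, `both_strands`, `min_p` and abundance columns),
#'   `members` (sequence-level membership with `origin` = "core") and
#'   `params`
#' @export
detect_loci <- function(alignments, counts = NULL, cycles = 11L, step = 21L,
                        alpha = 1e-4, min_members = 3L) {
  a21 <- alignments[alignments$end - alignments$start == 21L, , drop = FALSE]
  window_len <- 21L * cycles
  N <- 2L * window_len
  K <- 2L * cycles
  hits <- NULL

  if (nrow(a21) > 0L) {
    # distinct (chrom, strand, start) positions; remember the sequences at
    # each position
    key <- paste(a21$chrom, a21$strand, a21$start)
    pos <- a21[!duplicated(key), c("chrom", "strand", "start")]
    for (chrom in unique(pos$chrom)) {
      p <- pos[pos$chrom == chrom, ]
      p <- p[order(p$start), ]
      phase_pos <- ifelse(p$strand == "+", p$start, p$start + 2L)
      # every step-grid window that can contain at least one position
      grid <- (p$start %/% step) * step
      offs <- seq(0L, window_len - step, by = step)
      starts <- sort(unique(as.vector(outer(grid, offs, `-`))))
      starts <- starts[starts >= 0L]
      # count positions per candidate window, keep dense ones
      lo <- findInterval(starts - 0.5, p$start)
      hi <- findInterval(starts + window_len - 0.5, p$start)
      dense <- which(hi - lo >= min_members)
      for (wi in dense) {
        ws <- starts[wi]
        inw <- p$start >= ws & p$start < ws + window_len
        n <- sum(inw)
        reg <- phase_pos[inw] %% 21L
        tab <- table(reg)
        cand <- as.integer(names(tab)[tab >= min_members])
        for (r in cand) {
          k <- as.integer(tab[as.character(r)])
          pv <- phasing_pvalue(k, N, K, n)
          if (pv <= alpha) {
            hits <- rbind(hits, data.frame(chrom = chrom, ws = ws,
                                           register = r, p = pv,
                                           stringsAsFactors = FALSE))
          }
        }
      }
    }
  }

  loci <- NULL
  members <- NULL
  if (!is.null(hits)) {
    grp_key <- paste(hits$chrom, hits$register)
    for (g in unique(grp_key)) {
      h <- hits[grp_key == g, ]
      h <- h[order(h$ws), ]
      # merge windows whose spans overlap
      brk <- c(0L, cumsum(diff(h$ws) >= window_len))
      for (b in unique(brk)) {
        hh <- h[brk == b, ]
        span <- c(min(hh$ws), max(hh$ws) + window_len)
        r <- hh$register[1]
        inl <- a21$chrom == hh$chrom[1] &
          a21$start >= span[1] & a21$start < span[2] &
          in_phase(a21$start, a21$strand, r)
        mem <- a21[inl, , drop = FALSE]
        if (length(unique(mem$sequence)) < min_members) next
        loci <- rbind(loci, data.frame(
          chrom = hh$chrom[1],
          start = min(mem$start), end = max(mem$end),
          register = r,
          n_distinct = length(unique(mem$sequence)),
          both_strands = length(unique(mem$strand)) == 2L,
          min_p = min(hh$p), stringsAsFactors = FALSE))
        members <- rbind(members, data.frame(
          locus_index = nrow(loci), sequence = mem$sequence,
          chrom = mem$chrom, start = mem$start, end = mem$end,
          strand = mem$strand, origin = "core", ambiguous = FALSE,
          stringsAsFactors = FALSE))
      }
    }
  }

  if (is.null(loci)) {
    loci <- data.frame(locus_id = character(0), chrom = character(0),
                       start = integer(0), end = integer(0),
                       register = integer(0), n_distinct = integer(0),
                       both_strands = logical(0), min_p = numeric(0),
                       stringsAsFactors = FALSE)
    members <- data.frame(locus_id = character(0), sequence = character(0),
                          chrom = character(0), start = integer(0),
                          end = integer(0), strand = character(0),
                          origin = character(0), ambiguous = logical(0),
                          stringsAsFactors = FALSE)
  } else {
    ord <- order(loci$chrom, loci$start)
    loci <- loci[ord, ]
    loci$locus_id <- sprintf("PL%04d", seq_len(nrow(loci)))
    members$locus_id <- loci$locus_id[match(members$locus_index, ord)]
    members$locus_index <- NULL
    members <- members[order(members$locus_id, members$start), ]
    loci <- loci[, c("locus_id", "chrom", "start", "end", "register",
                     "n_distinct", "both_strands", "min_p")]
    rownames(loci) <- rownames(members) <- NULL
  }

  out <- structure(list(loci = loci, members = members,
                        params = list(cycles = cycles, step = step,
                                      alpha = alpha,
                                      min_members = min_members)),
                   class = "phased_loci")
  if (!is.null(counts)) out <- sum_locus_abundance(out, counts)
  out
}

#' Per-locus abundance sums over member sequences
#'
#' @param loci_obj a `phased_loci` object
#' @param counts data.frame with `sequence` and `count_*` / `rpm_*`
#'   columns
#' @param include_recruited include recruited members in the sums
#' @return the `phased_loci` object with abundance columns on `$loci`
#' @export
sum_locus_abundance <- function(loci_obj, counts, include_recruited = TRUE) {
  cols <- grep("^(count|rpm)_", names(counts), value = TRUE)
  mem <- loci_obj$members
  if (!include_recruited) mem <- mem[mem$origin == "core", , drop = FALSE]
  mem <- mem[!duplicated(paste(mem$locus_id, mem$sequence)), , drop = FALSE]
  idx <- match(mem$sequence, counts$sequence)
  for (col in cols) {
    v <- counts[[col]][idx]
    v[is.na(v)] <- 0
    s <- tapply(v, mem$locus_id, sum)
    loci_obj$loci[[col]] <- as.vector(s[loci_obj$loci$locus_id])
    loci_obj$loci[[col]][is.na(loci_obj$loci[[col]])] <- 0
  }
  loci_obj
}

#' @export
print.phased_loci <- function(x, ...) {
  cat(sprintf("Phased loci: %d loci, %d member records\n",
              nrow(x$loci), nrow(x$members)))
  if (nrow(x$loci)) {
    cat(sprintf("  both strands: %d (%.1f%%); median members: %g\n",
                sum(x$loci$both_strands),
                100 * mean(x$loci$both_strands),
                stats::median(x$loci$n_distinct)))
    if ("trigger_score" %in% names(x$loci)) {
      cat(sprintf("  trigger site found: %d\n",
                  sum(!is.na(x$loci$trigger_score))))
    }
  }
  invisible(x)
}

#' Post-filter phased loci
#'
#' Removes member sequences placed at more than `max_hits` genomic
#' positions, drops loci left with fewer than `min_members` members, and
#' drops loci overlapping blacklist intervals (e.g. telomere-associated
#' regions).
#'
#' @param loci_obj a `phased_loci` object
#' @param genome_hits named integer vector of genomic placement counts
#'   per sequence (as attached by [map_to_genome()])
#' @param blacklist optional data.frame of 0-based half-open intervals
#'   with `chrom`, `start`, `end`
#' @param max_hits maximum allowed genomic placements per member
#' @param min_members minimum members for a locus to survive
#' @return the filtered `phased_loci` object; attribute `removed` lists
#'   counts by reason
#' @export
postfilter_loci <- function(loci_obj, genome_hits, blacklist = NULL,
                            max_hits = 10L, min_members = NULL) {
  min_members <- min_members %||% loci_obj$params$min_members
  if (!is.null(blacklist)) {
    if (!all(c("chrom", "start", "end") %in% names(blacklist)) ||
        any(blacklist$end <= blacklist$start)) {
      stopf("malformed blacklist: need chrom/start/end half-open intervals")
    }
  }
  mem <- loci_obj$members
  hits <- genome_hits[mem$sequence]
  hits[is.na(hits)] <- 1L
  keep_mem <- hits <= max_hits
  n_multi <- sum(!keep_mem)
  mem <- mem[keep_mem, , drop = FALSE]

  n_mem <- tapply(mem$sequence, mem$locus_id,
                  function(s) length(unique(s)))
  loci <- loci_obj$loci
  keep <- loci$locus_id %in% names(n_mem)[n_mem >= min_members]
  removed_sparse <- sum(!keep)

  removed_bl <- 0L
  if (!is.null(blacklist) && nrow(blacklist) > 0L && any(keep)) {
    ov <- overlaps_features(loci, blacklist)
    removed_bl <- sum(keep & ov)
    keep <- keep & !ov
  }
  loci <- loci[keep, , drop = FALSE]
  mem <- mem[mem$locus_id %in% loci$locus_id, , drop = FALSE]
  # refresh spans and member counts after member removal
  if (nrow(loci)) {
    core <- mem[mem$origin == "core", ]
    loci$start <- as.vector(tapply(core$start, core$locus_id, min)[loci$locus_id])
    loci$end <- as.vector(tapply(core$end, core$locus_id, max)[loci$locus_id])
    loci$n_distinct <- as.vector(
      tapply(core$sequence, core$locus_id,
             function(s) length(unique(s)))[loci$locus_id])
    loci$both_strands <- as.vector(
      tapply(core$strand, core$locus_id,
             function(s) length(unique(s)) == 2L)[loci$locus_id])
  }
  rownames(loci) <- rownames(mem) <- NULL
  out <- loci_obj
  out$loci <- loci
  out$members <- mem
  attr(out, "removed") <- c(multimapped_members = n_multi,
                            loci_below_min_members = removed_sparse,
                            loci_blacklisted = removed_bl)
  out
}

#' Two-pass recruitment of additional locus members
#'
#' Matches unassigned 21-nt sequences against the core member sequences:
#' pass 1 requires an exact (100 % identity) ungapped match covering 85 %
#' of the sequence length (minimum 16 nt), pass 2 relaxes identity to
#' 85 %. A sequence recruited in pass 1 is not re-tested in pass 2;
#' sequences matching members of several loci are attached to all of them
#' and flagged ambiguous.
#'
#' @param loci_obj a `phased_loci` object with core members
#' @param candidates character vector of unassigned 21-nt sequences
#' @param min_coverage_frac coverage threshold shared by both passes
#' @param pass2_identity identity threshold of the relaxed second pass
#' @return the `phased_loci` object with recruited members appended
#'   (`origin` = "pass1"/"pass2"); locus `n_distinct` is left as the core
#'   member count
#' @export
recruit_members <- function(loci_obj, candidates,
                            min_coverage_frac = 0.85,
                            pass2_identity = 0.85) {
  candidates <- setdiff(unique(candidates), loci_obj$members$sequence)
  if (length(candidates) == 0L || nrow(loci_obj$members) == 0L) {
    return(loci_obj)
  }
  core <- loci_obj$members[loci_obj$members$origin == "core", ]
  db <- setNames(core$sequence, paste0("m", seq_len(nrow(core))))
  recruit_pass <- function(cands, identity, origin) {
    m <- local_match(cands, db,
                     match_params(min_identity_frac = identity,
                                  min_coverage_frac = min_coverage_frac,
                                  min_match_len = 16L))
    if (nrow(m) == 0L) return(NULL)
    m$locus_id <- core$locus_id[match(m$subject_id, names(db))]
    m <- m[!duplicated(paste(m$query, m$locus_id)), ]
    n_loci <- tapply(m$locus_id, m$query, function(x) length(unique(x)))
    data.frame(locus_id = m$locus_id, sequence = m$query,
               chrom = NA_character_, start = NA_integer_,
               end = NA_integer_, strand = NA_character_,
               origin = origin,
               ambiguous = as.vector(n_loci[m$query]) > 1L,
               stringsAsFactors = FALSE)
  }
  p1 <- recruit_pass(candidates, 1.0, "pass1")
  rest <- setdiff(candidates, p1$sequence)
  p2 <- if (length(rest)) recruit_pass(rest, pass2_identity, "pass2") else NULL
  loci_obj$members <- rbind(loci_obj$members, p1, p2)
  loci_obj
}
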