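#' Configuration for the synthetic library simulator
#'
#' Defaults emulate two bulked small-RNA libraries: a background of
#' miRNA reads dominated by one family (64 % of the miRNA class),
#' 24-nt repeat-derived siRNAs, gene-derived fragments, unphased 21-nt
#' noise, and the planted phased-locus reads with their fold changes.
#'
#' @param library_sizes named integer vector of reads per library
#' @param class_mix expected read-share per class; must sum to 1 and
#'   contain names phased, miRNA, ncRNA, repeat, gene, noise
#' @param dominant_family_weight share of the miRNA class carried by the
#'   dominant family
#' @param dominant_family family id to dominate; default the first family
#'   in the bundle
#' @param mirna_variant_weights proportions of miRNA reads emitted as the
#'   exact mature sequence, a 1-nt-shorter variant and a 1-nt-longer
#'   variant
#' @param n_noise_units number of distinct unphased 21-nt noise sequences
#' @param fragments_per_record distinct fragments sampled per ncRNA,
#'   repeat and gene record
#' @param error_rate per-base substitution sequencing error rate, in
#'   \[0, 0.1\]
#' @return a list of class `library_config`
#' @export
library_config <- function(library_sizes = c(A = 50000L, B = 50000L),
                           class_mix = c(phased = 0.25, miRNA = 0.20,
                                         ncRNA = 0.10, "repeat" = 0.20,
                                         gene = 0.15, noise = 0.10),
                           dominant_family_weight = 0.64,
                           dominant_family = NULL,
                           mirna_variant_weights = c(exact = 0.85,
                                                     short = 0.10,
                                                     long = 0.05),
                           n_noise_units = 600L,
                           fragments_per_record = 5L,
                           error_rate = 0.001) {
  if (error_rate < 0 || error_rate > 0.1) {
    stopf("error_rate must lie in [0, 0.1], got %g", error_rate)
  }
  if (any(library_sizes <= 0L)) stopf("library sizes must be positive")
  need <- c("phased", "miRNA", "ncRNA", "repeat", "gene", "noise")
  if (!all(need %in% names(class_mix))) {
    stopf("class_mix must name classes: %s", paste(need, collapse = ", "))
  }
  class_mix <- class_mix / sum(class_mix)
  structure(list(library_sizes = library_sizes, class_mix = class_mix,
                 dominant_family_weight = dominant_family_weight,
                 dominant_family = dominant_family,
                 mirna_variant_weights = mirna_variant_weights,
                 n_noise_units = as.integer(n_noise_units),
                 fragments_per_record = as.integer(fragments_per_record),
                 error_rate = error_rate),
            class = "library_config")
}

# Build the unit table (one row per distinct emitted sequence) with
# per-library expected read shares. Locus members get shares in exact
# ratio fold_ratio between libraries; background units are rescaled per
# library to fill the remaining share.
build_units <- function(planted, config) {
  bundle <- planted$bundle
  mix <- config$class_mix
  units <- NULL
  add <- function(df) units <<- rbind(units, df)

  # phased members
  if (nrow(planted$loci) > 0L) {
    lw <- runif(nrow(planted$loci), 0.5, 1.5)
    lw <- lw / sum(lw) * mix[["phased"]]
    for (i in seq_len(nrow(planted$loci))) {
      li <- planted$loci[i, ]
      mem <- planted$members[planted$members$locus_id == li$locus_id, ]
      f <- li$fold_ratio
      s <- lw[i] * mem$weight
      add(data.frame(unit = mem$member, class = "phased",
                     source = li$locus_id, sequence = mem$sequence,
                     share_A = s * 2 * f / (1 + f),
                     share_B = s * 2 / (1 + f),
                     stringsAsFactors = FALSE))
    }
  } else {
    mix <- mix[names(mix) != "phased"]
    mix <- mix / sum(mix)
  }

  # miRNA units: mature sequence plus length variants, family-weighted
  db <- bundle$mirna_db
  fams <- unique(db$family)
  dom <- config$dominant_family %||% fams[1]
  fam_w <- setNames(rep((1 - config$dominant_family_weight) /
                          max(1L, length(fams) - 1L), length(fams)), fams)
  if (dom %in% fams) fam_w[dom] <- config$dominant_family_weight
  fam_w <- fam_w / sum(fam_w)
  per_rec <- fam_w[db$family] / as.vector(table(db$family)[db$family])
  vw <- config$mirna_variant_weights / sum(config$mirna_variant_weights)
  mir_feat <- bundle$features[bundle$features$class == "miRNA", ]
  rownames(mir_feat) <- mir_feat$id
  for (i in seq_len(nrow(db))) {
    sq <- db$sequence[i]
    fe <- mir_feat[db$id[i], ]
    long_sq <- genome_substr(bundle$genome, fe$chrom, fe$start, fe$end + 1L)
    variants <- c(exact = sq, short = substr(sq, 1L, nchar(sq) - 1L),
                  long = long_sq)
    add(data.frame(unit = sprintf("%s_%s", db$id[i], names(variants)),
                   class = "miRNA", source = db$id[i], sequence = variants,
                   share_A = mix[["miRNA"]] * per_rec[i] * vw,
                   share_B = mix[["miRNA"]] * per_rec[i] * vw,
                   stringsAsFactors = FALSE))
  }

  # fragment units from ncRNA / repeat records
  frag_units <- function(db, class, len_choices) {
    if (nrow(db) == 0L) return()
    nf <- config$fragments_per_record
    s <- mix[[class]] / (nrow(db) * nf)
    for (i in seq_len(nrow(db))) {
      full <- db$sequence[i]
      lens <- resample(len_choices, nf, replace = TRUE)
      starts <- vapply(lens, function(l) sample.int(nchar(full) - l + 1L, 1L),
                       integer(1))
      add(data.frame(unit = sprintf("%s_f%d", db$id[i], seq_len(nf)),
                     class = class, source = db$id[i],
                     sequence = substring(full, starts, starts + lens - 1L),
                     share_A = s, share_B = s, stringsAsFactors = FALSE))
    }
  }
  frag_units(bundle$ncrna_db, "ncRNA", 20:24)
  frag_units(bundle$repeat_db, "repeat", 24L)

  # gene fragments: sampled from gene spans on the genome
  genes <- bundle$features[bundle$features$class == "gene", ]
  if (nrow(genes) > 0L) {
    nf <- config$fragments_per_record
    gid <- unique(sub("_(utr5|cds1|intron1|cds2|utr3)$", "", genes$id))
    s <- mix[["gene"]] / (length(gid) * nf)
    for (g in gid) {
      sub <- genes[startsWith(genes$id, g), ]
      lo <- min(sub$start); hi <- max(sub$end)
      lens <- resample(21:24, nf, replace = TRUE)
      starts <- lo + vapply(lens, function(l) sample.int(hi - lo - l, 1L),
                            integer(1))
      add(data.frame(unit = sprintf("%s_f%d", g, seq_len(nf)),
                     class = "gene", source = g,
                     sequence = vapply(seq_len(nf), function(j) {
                       genome_substr(bundle$genome, sub$chrom[1],
                                     starts[j], starts[j] + lens[j])
                     }, character(1)),
                     share_A = s, share_B = s, stringsAsFactors = FALSE))
    }
  }

  # unphased 21-nt noise from random genome positions, random strand
  if (config$n_noise_units > 0L) {
    chroms <- names(bundle$genome)
    lens <- vapply(bundle$genome, nchar, integer(1))
    ch <- sample(chroms, config$n_noise_units, replace = TRUE,
                 prob = lens / sum(lens))
    st <- vapply(ch, function(x) sample.int(lens[x] - 21L, 1L), integer(1))
    sq <- vapply(seq_len(config$n_noise_units), function(j) {
      genome_substr(bundle$genome, ch[j], st[j], st[j] + 21L)
    }, character(1))
    flip <- runif(config$n_noise_units) < 0.5
    sq[flip] <- revcomp(sq[flip])
    s <- mix[["noise"]] / config$n_noise_units
    add(data.frame(unit = sprintf("noise%04d", seq_len(config$n_noise_units)),
                   class = "noise", source = ch, sequence = sq,
                   share_A = s, share_B = s, stringsAsFactors = FALSE))
  }

  # renormalise: planted locus shares are kept exact (their A/B ratio is
  # the planted fold); background fills the per-library remainder
  bg <- units$class != "phased"
  for (lib in c("A", "B")) {
    col <- paste0("share_", lib)
    rem <- 1 - sum(units[[col]][!bg])
    units[[col]][bg] <- units[[col]][bg] / sum(units[[col]][bg]) * rem
  }
  rownames(units) <- NULL
  units
}

#' Simulate two small-RNA libraries from planted loci
#'
#' Draws per-library read counts multinomially over the unit table built
#' from the planted loci and the background classes, applies i.i.d.
#' substitution sequencing errors, and returns the reads together with a
#' machine-readable truth object. Per-locus expected counts are in exact
#' ratio `fold_ratio` between the two libraries; member counts are
#' multinomial over the planted Zipf weights.
#'
#' @param planted a `planted_loci` object from [plant_phased_loci()]
#' @param config a [library_config()]
#' @param seed integer RNG seed
#' @return a list of class `synthetic_libraries`: `reads` (per-library
#'   list with `id` and `sequence` vectors), `truth` (list with `units`,
#'   `loci`, `members`, `background` count tables, `library_sizes`,
#'   `seed`), and `bundle`
#' @export
simulate_libraries <- function(planted, config = library_config(),
                               seed = 44L) {
  stopifnot(inherits(planted, "planted_loci"),
            inherits(config, "library_config"))
  set.seed(seed)
  units <- build_units(planted, config)
  libs <- names(config$library_sizes)
  counts <- list()
  for (lib in libs) {
    sh <- units[[paste0("share_", lib)]]
    counts[[lib]] <- as.vector(rmultinom(1, config$library_sizes[[lib]],
                                         prob = sh))
  }
  units$count_A <- counts[["A"]]
  units$count_B <- counts[["B"]]

  p_err_of <- function(len) 1 - (1 - config$error_rate)^len
  reads <- list()
  for (lib in libs) {
    cnt <- units[[paste0("count_", lib)]]
    idx <- rep.int(seq_len(nrow(units)), cnt)
    seqs <- units$sequence[idx]
    ids <- sprintf("%s_%07d|%s", lib, seq_along(idx), units$unit[idx])
    if (config$error_rate > 0 && length(seqs)) {
      lens <- nchar(seqs)
      hit <- runif(length(seqs)) < p_err_of(lens)
      for (j in which(hit)) {
        pos <- sample.int(lens[j], 1L)
        old <- substr(seqs[j], pos, pos)
        substr(seqs[j], pos, pos) <- sample(setdiff(DNA_BASES, old), 1L)
      }
    }
    reads[[lib]] <- list(id = ids, sequence = seqs)
  }

  member_truth <- merge(planted$members,
                        units[units$class == "phased",
                              c("unit", "count_A", "count_B")],
                        by.x = "member", by.y = "unit", sort = FALSE)
  loci_truth <- planted$loci
  agg <- function(col) {
    v <- tapply(member_truth[[col]], member_truth$locus_id, sum)
    as.vector(v[loci_truth$locus_id])
  }
  if (nrow(loci_truth) > 0L) {
    loci_truth$count_A <- agg("count_A")
    loci_truth$count_B <- agg("count_B")
  }
  truth <- list(units = units,
                loci = loci_truth,
                members = member_truth,
                background = units[units$class != "phased",
                                   c("unit", "class", "source", "sequence",
                                     "count_A", "count_B")],
                library_sizes = config$library_sizes,
                seed = seed)
  structure(list(reads = reads, truth = truth, bundle = planted$bundle),
            class = "synthetic_libraries")
}

#' @export
print.synthetic_libraries <- function(x, ...) {
  cat("Synthetic small-RNA libraries\n")
  for (lib in names(x$reads)) {
    cat(sprintf("  library %s: %d reads\n", lib, length(x$reads[[lib]]$id)))
  }
  cat(sprintf("  truth: %d loci, %d members, %d background units\n",
              nrow(x$truth$loci), nrow(x$truth$members),
              nrow(x$truth$background)))
  invisible(x)
}
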