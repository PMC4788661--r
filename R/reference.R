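#' Configuration for the synthetic reference bundle
#'
#' Defaults describe a compact two-chromosome genome carrying planted
#' feature classes at densities that leave most of the sequence
#' unannotated, mirroring the compartment structure the annotation
#' hierarchy expects (miRNA, ncRNA, repeat, gene, unannotated).
#'
#' @param n_chrom number of chromosomes
#' @param chrom_len length of each chromosome in bp (minimum 100 kb)
#' @param n_mirna number of mature miRNA records planted (grouped into
#'   families of 1-3 members)
#' @param n_ncrna number of ncRNA records (80-300 nt)
#' @param n_repeat_families number of repeat families; each consensus is
#'   planted at `repeat_copies` genomic copies so repeat-derived reads
#'   multimap
#' @param repeat_copies copies planted per repeat family
#' @param n_genes number of gene models (UTR/CDS/intron sub-features)
#' @param telomere_len length of the terminal blacklist interval at each
#'   chromosome end (telomere-associated regions)
#' @param trigger_names names of 22-nt trigger miRNAs to generate
#' @return a list of class `reference_config`
#' @export
reference_config <- function(n_chrom = 2L, chrom_len = 500000L,
                             n_mirna = 40L, n_ncrna = 20L,
                             n_repeat_families = 8L, repeat_copies = 4L,
                             n_genes = 30L, telomere_len = 5000L,
                             trigger_names = "miR2118") {
  if (chrom_len < 100000L) stopf("chromosome length must be >= 100 kb")
  structure(list(n_chrom = as.integer(n_chrom),
                 chrom_len = as.integer(chrom_len),
                 n_mirna = as.integer(n_mirna),
                 n_ncrna = as.integer(n_ncrna),
                 n_repeat_families = as.integer(n_repeat_families),
                 repeat_copies = as.integer(repeat_copies),
                 n_genes = as.integer(n_genes),
                 telomere_len = as.integer(telomere_len),
                 trigger_names = trigger_names),
            class = "reference_config")
}

# Rejection-sample non-overlapping intervals of the given widths inside
# [lo, hi) per chromosome, away from already occupied intervals.
# occupied: data.frame(chrom, start, end). Errors with the class name on
# capacity exhaustion.
place_intervals <- function(widths, chroms, chrom_len, occupied, lo, hi,
                            class_name, margin = 30L, max_tries = 2000L) {
  out <- data.frame(chrom = character(0), start = integer(0),
                    end = integer(0), stringsAsFactors = FALSE)
  for (w in widths) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      chrom <- sample(chroms, 1L)
      start <- sample.int(hi - lo - w, 1L) + lo - 1L
      end <- start + w
      occ <- occupied[occupied$chrom == chrom, , drop = FALSE]
      if (!any(intervals_overlap(start - margin, end + margin,
                                 occ$start, occ$end))) {
        occupied <- rbind(occupied,
                          data.frame(chrom = chrom, start = start, end = end,
                                     stringsAsFactors = FALSE))
        out <- rbind(out,
                     data.frame(chrom = chrom, start = start, end = end,
                                stringsAsFactors = FALSE))
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stopf("insufficient genome capacity to place features of class '%s'",
            class_name)
    }
  }
  list(intervals = out, occupied = occupied)
}

#' Generate a synthetic reference bundle
#'
#' Builds a random genome, plants feature intervals for each annotation
#' class, and derives the annotation databases by copying the planted
#' sequences, so that every database record has a genomic source. The
#' blacklist marks the telomere-like terminal interval of every
#' chromosome. Deterministic given `seed`.
#'
#' @param config a [reference_config()]
#' @param seed integer RNG seed
#' @return a list of class `reference_bundle` with elements `genome`
#'   (named list of chromosome strings), `features` (data.frame with
#'   0-based half-open `start`/`end`, `class`, `subclass`, `id`),
#'   `mirna_db`, `ncrna_db`, `repeat_db`, `trigger_db` (data.frames with
#'   `id` and `sequence`; `mirna_db` also has `family` and `type`),
#'   `blacklist` (data.frame of intervals), `seed`, and `config`.
#' @export
generate_reference <- function(config = reference_config(), seed = 42L) {
  stopifnot(inherits(config, "reference_config"))
  set.seed(seed)
  chroms <- paste0("chr", seq_len(config$n_chrom))
  genome <- setNames(lapply(chroms, function(x) random_dna(config$chrom_len)),
                     chroms)

  blacklist <- do.call(rbind, lapply(chroms, function(ch) {
    data.frame(chrom = ch,
               start = c(0L, config$chrom_len - config$telomere_len),
               end = c(config$telomere_len, config$chrom_len),
               stringsAsFactors = FALSE)
  }))
  occupied <- blacklist
  lo <- config$telomere_len
  hi <- config$chrom_len - config$telomere_len
  features <- NULL

  plant <- function(iv, seqs) {
    for (i in seq_len(nrow(iv))) {
      s <- genome[[iv$chrom[i]]]
      substr(s, iv$start[i] + 1L, iv$end[i]) <- seqs[i]
      genome[[iv$chrom[i]]] <<- s
    }
  }

  # miRNA loci: mature sequences 20-22 nt, grouped into families
  mirna_db <- NULL
  if (config$n_mirna > 0L) {
    lens <- sample(c(20L, 21L, 22L), config$n_mirna, replace = TRUE,
                   prob = c(0.15, 0.7, 0.15))
    pl <- place_intervals(lens, chroms, config$chrom_len, occupied, lo, hi,
                          "miRNA")
    occupied <- pl$occupied
    seqs <- vapply(lens, random_dna, character(1))
    plant(pl$intervals, seqs)
    fam_sizes <- integer(0)
    while (sum(fam_sizes) < config$n_mirna) {
      fam_sizes <- c(fam_sizes, sample(1:3, 1L))
    }
    fam_sizes[length(fam_sizes)] <-
      fam_sizes[length(fam_sizes)] - (sum(fam_sizes) - config$n_mirna)
    fam_sizes <- fam_sizes[fam_sizes > 0L]
    families <- rep(sprintf("FAM%02d", seq_along(fam_sizes)), fam_sizes)
    # family-level type labels, mixing canonical/variant/siRNA-like
    fam_type <- sample(c("canonical", "variant", "siRNA-like"),
                       length(fam_sizes), replace = TRUE,
                       prob = c(62, 20, 64) / 146)
    types <- rep(fam_type, fam_sizes)
    ids <- sprintf("mir%03d", seq_len(config$n_mirna))
    mirna_db <- data.frame(id = ids, family = families, type = types,
                           sequence = seqs, stringsAsFactors = FALSE)
    features <- rbind(features,
                      cbind(pl$intervals,
                            data.frame(class = "miRNA", subclass = NA_character_,
                                       id = ids, stringsAsFactors = FALSE)))
  }

  # trigger miRNAs: 22-nt, appended to the miRNA database as their own
  # canonical families so trigger-derived reads classify as miRNA
  trig_seqs <- vapply(config$trigger_names, function(x) random_dna(22L),
                      character(1))
  trigger_db <- data.frame(id = config$trigger_names, sequence = unname(trig_seqs),
                           stringsAsFactors = FALSE)
  pl <- place_intervals(rep(22L, nrow(trigger_db)), chroms, config$chrom_len,
                        occupied, lo, hi, "miRNA")
  occupied <- pl$occupied
  plant(pl$intervals, trigger_db$sequence)
  mirna_db <- rbind(mirna_db,
                    data.frame(id = trigger_db$id, family = trigger_db$id,
                               type = "canonical", sequence = trigger_db$sequence,
                               stringsAsFactors = FALSE))
  features <- rbind(features,
                    cbind(pl$intervals,
                          data.frame(class = "miRNA", subclass = NA_character_,
                                     id = trigger_db$id, stringsAsFactors = FALSE)))

  # ncRNA loci
  ncrna_db <- data.frame(id = character(0), sequence = character(0))
  if (config$n_ncrna > 0L) {
    lens <- sample(80:300, config$n_ncrna, replace = TRUE)
    pl <- place_intervals(lens, chroms, config$chrom_len, occupied, lo, hi,
                          "ncRNA")
    occupied <- pl$occupied
    seqs <- vapply(lens, random_dna, character(1))
    plant(pl$intervals, seqs)
    ids <- sprintf("ncrna%03d", seq_len(config$n_ncrna))
    ncrna_db <- data.frame(id = ids, sequence = seqs, stringsAsFactors = FALSE)
    features <- rbind(features,
                      cbind(pl$intervals,
                            data.frame(class = "ncRNA", subclass = NA_character_,
                                       id = ids, stringsAsFactors = FALSE)))
  }

  # repeat families: one consensus planted at several copies
  repeat_db <- data.frame(id = character(0), sequence = character(0))
  if (config$n_repeat_families > 0L) {
    cons_len <- sample(150:400, config$n_repeat_families, replace = TRUE)
    cons <- vapply(cons_len, random_dna, character(1))
    ids <- sprintf("rep%02d", seq_len(config$n_repeat_families))
    repeat_db <- data.frame(id = ids, sequence = cons, stringsAsFactors = FALSE)
    for (i in seq_len(config$n_repeat_families)) {
      pl <- place_intervals(rep(cons_len[i], config$repeat_copies), chroms,
                            config$chrom_len, occupied, lo, hi, "repeat")
      occupied <- pl$occupied
      plant(pl$intervals, rep(cons[i], config$repeat_copies))
      features <- rbind(features,
                        cbind(pl$intervals,
                              data.frame(class = "repeat", subclass = NA_character_,
                                         id = sprintf("%s_c%d", ids[i],
                                                      seq_len(config$repeat_copies)),
                                         stringsAsFactors = FALSE)))
    }
  }

  # gene models: UTR5 / CDS / intron / CDS / UTR3 partition of the span
  if (config$n_genes > 0L) {
    lens <- sample(1200:3000, config$n_genes, replace = TRUE)
    pl <- place_intervals(lens, chroms, config$chrom_len, occupied, lo, hi,
                          "gene")
    occupied <- pl$occupied
    for (i in seq_len(config$n_genes)) {
      iv <- pl$intervals[i, ]
      gid <- sprintf("gene%03d", i)
      L <- iv$end - iv$start
      cuts <- iv$start + round(L * cumsum(c(0.10, 0.25, 0.20, 0.25)))
      sub <- data.frame(
        chrom = iv$chrom,
        start = c(iv$start, cuts),
        end = c(cuts, iv$end),
        class = "gene",
        subclass = c("UTR", "CDS", "intron", "CDS", "UTR"),
        id = sprintf("%s_%s", gid, c("utr5", "cds1", "intron1", "cds2", "utr3")),
        stringsAsFactors = FALSE)
      features <- rbind(features, sub)
    }
  }

  rownames(features) <- NULL
  bundle <- structure(list(genome = genome, features = features,
                           mirna_db = mirna_db, ncrna_db = ncrna_db,
                           repeat_db = repeat_db, trigger_db = trigger_db,
                           blacklist = blacklist, seed = seed, config = config),
                      class = "reference_bundle")
  validate_bundle(bundle)
  bundle
}

#' Validate a reference bundle's invariants
#'
#' Checks chromosome name uniqueness, interval bounds, sequence alphabets
#' and blacklist validity; errors on the first violation.
#'
#' @param bundle a `reference_bundle`
#' @return the bundle, invisibly
#' @export
validate_bundle <- function(bundle) {
  stopifnot(inherits(bundle, "reference_bundle"))
  chroms <- names(bundle$genome)
  if (anyDuplicated(chroms)) stopf("duplicate chromosome names")
  lens <- vapply(bundle$genome, nchar, integer(1))
  for (tab in c("features", "blacklist")) {
    df <- bundle[[tab]]
    if (is.null(df) || nrow(df) == 0L) next
    if (any(!df$chrom %in% chroms)) stopf("%s references unknown chromosome", tab)
    if (any(df$start < 0L | df$end > lens[df$chrom] | df$start >= df$end)) {
      stopf("%s has intervals outside chromosome bounds", tab)
    }
  }
  for (db in c("mirna_db", "ncrna_db", "repeat_db", "trigger_db")) {
    if (nrow(bundle[[db]]) > 0L) assert_dna(bundle[[db]]$sequence, db)
  }
  invisible(bundle)
}

#' @export
print.reference_bundle <- function(x, ...) {
  lens <- vapply(x$genome, nchar, integer(1))
  cat("Synthetic reference bundle\n")
  cat(sprintf("  genome: %d chromosome(s), %s bp total\n",
              length(lens), format(sum(lens), big.mark = ",")))
  cat(sprintf("  features: %d (%s)\n", nrow(x$features),
              paste(sprintf("%s=%d", names(table(x$features$class)),
                            table(x$features$class)), collapse = ", ")))
  cat(sprintf("  databases: %d miRNA / %d ncRNA / %d repeat / %d trigger\n",
              nrow(x$mirna_db), nrow(x$ncrna_db), nrow(x$repeat_db),
              nrow(x$trigger_db)))
  cat(sprintf("  blacklist: %d interval(s)\n", nrow(x$blacklist)))
  invisible(x)
}
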