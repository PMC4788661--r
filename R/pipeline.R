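#' Pipeline configuration
#'
#' Bundles every stage parameter of the end-to-end run. With
#' `simulate = TRUE` (the default) the reference bundle, planted loci and
#' libraries are generated into `outdir/sim`; otherwise `input_dir` must
#' contain a bundle and `library_A.fastq` / `library_B.fastq` as written
#' by [write_simulation()].
#'
#' @param outdir output directory
#' @param seed master RNG seed; stage seeds are derived from it
#' @param simulate generate synthetic inputs
#' @param input_dir directory of existing inputs when `simulate = FALSE`
#' @param n_loci planted loci (simulation)
#' @param reference,locus,library stage configs ([reference_config()],
#'   [locus_config()], [library_config()])
#' @param adapter optional 3' adapter for trimming
#' @param min_quality minimum mean Phred quality
#' @param min_len,max_len retained read-length range
#' @param match a [match_params()] for annotation and recruitment
#' @param max_mismatches genome-mapping substitution allowance
#' @param cycles,step,alpha_phasing,min_members phasing-detector settings
#' @param max_hits multimapping post-filter threshold
#' @param flank,trigger_threshold trigger-site scan settings
#' @param alpha,fold,pseudocount differential-analysis settings
#' @return a list of class `pipeline_config`
#' @export
pipeline_config <- function(outdir, seed = 42L, simulate = TRUE,
                            input_dir = NULL, n_loci = 60L,
                            reference = reference_config(),
                            locus = locus_config(),
                            library = library_config(),
                            adapter = NULL, min_quality = 20,
                            min_len = 18L, max_len = 28L,
                            match = match_params(), max_mismatches = 0L,
                            cycles = 11L, step = 21L, alpha_phasing = 1e-4,
                            min_members = 3L, max_hits = 10L,
                            flank = 500L, trigger_threshold = 4.5,
                            alpha = 1e-3, fold = 5, pseudocount = 0.5) {
  if (!simulate) {
    if (is.null(input_dir) || !dir.exists(input_dir)) {
      stopf("simulate = FALSE requires an existing input_dir")
    }
  }
  structure(list(outdir = outdir, seed = as.integer(seed),
                 simulate = simulate, input_dir = input_dir,
                 n_loci = as.integer(n_loci), reference = reference,
                 locus = locus, library = library, adapter = adapter,
                 min_quality = min_quality, min_len = min_len,
                 max_len = max_len, match = match,
                 max_mismatches = max_mismatches, cycles = cycles,
                 step = step, alpha_phasing = alpha_phasing,
                 min_members = min_members, max_hits = max_hits,
                 flank = flank, trigger_threshold = trigger_threshold,
                 alpha = alpha, fold = fold, pseudocount = pseudocount),
            class = "pipeline_config")
}

#' Run the full pipeline
#'
#' Executes simulate (optional) -> preprocess -> annotate -> phasing ->
#' differential analysis, writing every stage output under
#' `config$outdir`. Identical config and seed give byte-identical text
#' outputs.
#'
#' @param config a [pipeline_config()]
#' @return a `pipeline_report` (per-stage record counts, timings and
#'   the parameter echo), invisibly; outputs are on disk
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  report <- list(parameters = config, stages = list())
  tic <- function() proc.time()[["elapsed"]]
  stage_names <- character(0)

  run_stage <- function(name, fun) {
    t0 <- tic()
    res <- tryCatch(fun(), error = function(e) {
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
    report$stages[[name]] <<- c(res, list(seconds = round(tic() - t0, 2)))
    res
  }

  # --- simulate ------------------------------------------------------
  sim_dir <- if (config$simulate) file.path(config$outdir, "sim") else
    config$input_dir
  if (config$simulate) {
    run_stage("simulate", function() {
      bundle <- generate_reference(config$reference, seed = config$seed)
      planted <- plant_phased_loci(bundle, n_loci = config$n_loci,
                                   config = config$locus,
                                   seed = config$seed + 1L)
      sim <- simulate_libraries(planted, config = config$library,
                                seed = config$seed + 2L)
      write_simulation(sim, sim_dir)
      list(n_loci_planted = nrow(sim$truth$loci),
           reads_per_library = vapply(sim$reads,
                                      function(r) length(r$id), integer(1)))
    })
  }

  # --- preprocess ----------------------------------------------------
  bundle <- read_reference_bundle(sim_dir)
  libs <- c(A = file.path(sim_dir, "library_A.fastq"),
            B = file.path(sim_dir, "library_B.fastq"))
  distincts <- NULL
  run_stage("preprocess", function() {
    distincts <<- preprocess_libraries(libs, adapter = config$adapter,
                                       min_quality = config$min_quality,
                                       min_len = config$min_len,
                                       max_len = config$max_len)
    list(reads_in = sum(attr(distincts, "n_input")),
         reads_trimmed = sum(attr(distincts, "n_trimmed")),
         reads_discarded_length = sum(attr(distincts, "discarded")),
         n_distinct = nrow(distincts))
  })

  # --- annotate ------------------------------------------------------
  alignments <- NULL
  run_stage("annotate", function() {
    distincts <<- classify_hierarchical(distincts, bundle,
                                        params = config$match,
                                        max_mismatches = config$max_mismatches)
    alignments <<- attr(distincts, "alignments")
    write_tsv(distincts, file.path(config$outdir, "distincts.tsv"))
    write_tsv(alignments, file.path(config$outdir, "alignments.tsv"))
    comp <- class_composition(distincts)
    list(n_mapped = sum(distincts$genome_hits > 0L),
         n_alignments = nrow(alignments),
         class_composition = round(comp, 4))
  })

  # --- phasing -------------------------------------------------------
  loci <- NULL
  run_stage("phasing", function() {
    seq21 <- distincts$sequence[distincts$length == 21L]
    aln21 <- alignments[alignments$sequence %in% seq21, , drop = FALSE]
    det <- detect_loci(aln21, cycles = config$cycles, step = config$step,
                       alpha = config$alpha_phasing,
                       min_members = config$min_members)
    n_initial <- nrow(det$loci)
    hits <- setNames(distincts$genome_hits, distincts$sequence)
    det <- postfilter_loci(det, hits, blacklist = bundle$blacklist,
                           max_hits = config$max_hits,
                           min_members = config$min_members)
    candidates <- setdiff(seq21, det$members$sequence)
    det <- recruit_members(det, candidates,
                           min_coverage_frac = config$match$min_coverage_frac,
                           pass2_identity = config$match$min_identity_frac)
    det <- sum_locus_abundance(det, distincts)
    det <- scan_trigger_site(det, bundle$genome, bundle$trigger_db,
                             flank = config$flank,
                             threshold = config$trigger_threshold)
    loci <<- det
    write_tsv(det$loci, file.path(config$outdir, "loci.tsv"))
    write_tsv(det$members, file.path(config$outdir, "members.tsv"))
    if (nrow(det$loci)) {
      bed <- det$loci
      bed$name <- bed$locus_id
      write_bed(bed, file.path(config$outdir, "loci.bed"))
    } else {
      file.create(file.path(config$outdir, "loci.bed"))
    }
    list(loci_initial = n_initial,
         loci_postfilter = nrow(det$loci),
         removed = attr(det, "removed") %||%
           c(multimapped_members = 0L, loci_below_min_members = 0L,
             loci_blacklisted = 0L),
         n_members = nrow(det$members),
         n_recruited = sum(det$members$origin != "core"),
         loci_with_trigger = sum(!is.na(det$loci$trigger_score)))
  })

  # --- differential --------------------------------------------------
  run_stage("differential", function() {
    totals <- c(A = sum(distincts$count_A), B = sum(distincts$count_B))
    seq_diff <- unit_differential(
      data.frame(unit_id = distincts$sequence,
                 count_A = distincts$count_A,
                 count_B = distincts$count_B, stringsAsFactors = FALSE),
      totals, alpha = config$alpha, fold = config$fold,
      pseudocount = config$pseudocount)
    write_tsv(seq_diff, file.path(config$outdir, "differential_sequence.tsv"))

    loci_diff <- NULL
    if (nrow(loci$loci)) {
      loci_diff <- unit_differential(loci$loci, totals,
                                     alpha = config$alpha,
                                     fold = config$fold,
                                     pseudocount = config$pseudocount)
      write_tsv(loci_diff, file.path(config$outdir, "differential_locus.tsv"))
    }

    # class-enrichment contrast: 21-nt sequences five-fold over in A
    is21 <- distincts$length == 21L & distincts$annotation_class != "unmapped"
    bg <- table(factor(distincts$annotation_class[is21],
                       levels = c("miRNA", "ncRNA", "repeat", "gene",
                                  "unannotated")))
    over <- is21 & seq_diff$fold5_flag & seq_diff$rpm_A > seq_diff$rpm_B
    sub <- table(factor(distincts$annotation_class[over],
                        levels = names(bg)))
    enr <- class_enrichment(c(sub), c(bg))
    write_tsv(enr, file.path(config$outdir, "class_enrichment.tsv"))

    fam <- mirna_family_profile(distincts, bundle$mirna_db,
                                features = bundle$features, loci = loci)
    if (nrow(fam)) {
      fam_diff <- unit_differential(
        data.frame(unit_id = fam$family, count_A = fam$count_A,
                   count_B = fam$count_B, stringsAsFactors = FALSE),
        totals, alpha = config$alpha, fold = config$fold,
        pseudocount = config$pseudocount)
      fam <- cbind(fam, fam_diff[, c("ratio", "G", "p_value", "category",
                                     "fold5_flag")])
    }
    write_tsv(fam, file.path(config$outdir, "mirna_families.tsv"))

    list(n_sequences_tested = nrow(seq_diff),
         n_sequences_significant = sum(seq_diff$category != "ns"),
         n_loci_significant = if (is.null(loci_diff)) 0L else
           sum(loci_diff$category != "ns"),
         n_loci_fold5 = if (is.null(loci_diff)) 0L else
           sum(loci_diff$fold5_flag),
         n_families = nrow(fam))
  })

  report$stages <- report$stages
  structure(report, class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("phasekit pipeline report\n")
  for (nm in names(x$stages)) {
    st <- x$stages[[nm]]
    cat(sprintf("  %s (%.2fs):\n", nm, st$seconds))
    for (f in setdiff(names(st), "seconds")) {
      v <- st[[f]]
      cat(sprintf("    %s: %s\n", f,
                  paste(sprintf("%s", format(v)), collapse = " ")))
    }
  }
  invisible(x)
}

#' Validate pipeline output files
#'
#' Checks BED sortedness and coordinate validity, GFF3 syntax, TSV
#' schemas, and cross-file referential integrity (members reference
#' existing loci and distinct sequences).
#'
#' @param outdir a directory written by [run_pipeline()]
#' @return a data.frame of violations (`file`, `line`, `message`); zero
#'   rows when the output is pristine
#' @export
validate_outputs <- function(outdir) {
  v <- list()
  bad <- function(file, line, message) {
    v[[length(v) + 1L]] <<- data.frame(file = file, line = line,
                                       message = message,
                                       stringsAsFactors = FALSE)
  }

  bed_path <- file.path(outdir, "loci.bed")
  if (file.exists(bed_path) && file.size(bed_path) > 0L) {
    bed <- read_bed(bed_path)
    if (any(bed$end <= bed$start)) {
      for (i in which(bed$end <= bed$start)) {
        bad("loci.bed", i, sprintf("end (%d) <= start (%d)",
                                   bed$end[i], bed$start[i]))
      }
    }
    if (any(bed$start < 0)) bad("loci.bed", which(bed$start < 0)[1],
                                "negative start coordinate")
    o <- order(bed$chrom, bed$start, bed$end)
    if (!identical(o, seq_len(nrow(bed)))) {
      bad("loci.bed", which(o != seq_len(nrow(bed)))[1],
          "records not sorted by (chrom, start)")
    }
  }

  gff_path <- file.path(outdir, "sim", "features.gff3")
  if (file.exists(gff_path)) {
    lines <- readLines(gff_path)
    if (length(lines) == 0L || lines[1] != "##gff-version 3") {
      bad("features.gff3", 1L, "missing ##gff-version 3 header")
    }
    body <- lines[!startsWith(lines, "#")]
    fields <- strsplit(body, "\t", fixed = TRUE)
    nf <- lengths(fields)
    for (i in which(nf != 9L)) {
      bad("features.gff3", i, sprintf("expected 9 columns, found %d", nf[i]))
    }
    ok <- nf == 9L
    st <- suppressWarnings(as.integer(vapply(fields[ok], `[[`, "", 4L)))
    en <- suppressWarnings(as.integer(vapply(fields[ok], `[[`, "", 5L)))
    for (i in which(is.na(st) | is.na(en) | st < 1L | en < st)) {
      bad("features.gff3", which(ok)[i], "invalid 1-based coordinates")
    }
  }

  schemas <- list(
    "distincts.tsv" = c("sequence", "length", "count_A", "count_B",
                        "rpm_A", "rpm_B", "annotation_class", "genome_hits"),
    "alignments.tsv" = c("sequence", "chrom", "start", "end", "strand"),
    "loci.tsv" = c("locus_id", "chrom", "start", "end", "register",
                   "n_distinct", "both_strands", "min_p"),
    "members.tsv" = c("locus_id", "sequence", "origin"),
    "differential_sequence.tsv" = c("unit_id", "count_A", "count_B",
                                    "ratio", "G", "p_value", "category"))
  tabs <- list()
  for (f in names(schemas)) {
    p <- file.path(outdir, f)
    if (!file.exists(p)) {
      bad(f, 0L, "file missing")
      next
    }
    tb <- read_tsv(p)
    tabs[[f]] <- tb
    miss <- setdiff(schemas[[f]], names(tb))
    if (length(miss)) {
      bad(f, 1L, sprintf("missing columns: %s", paste(miss, collapse = ", ")))
    }
  }

  if (!is.null(tabs[["members.tsv"]]) && !is.null(tabs[["loci.tsv"]])) {
    mem <- tabs[["members.tsv"]]
    loci <- tabs[["loci.tsv"]]
    orphan <- !(mem$locus_id %in% loci$locus_id)
    for (i in head(which(orphan), 10L)) {
      bad("members.tsv", i + 1L,
          sprintf("locus_id '%s' not present in loci.tsv", mem$locus_id[i]))
    }
    if (!is.null(tabs[["distincts.tsv"]])) {
      unknown <- !(mem$sequence %in% tabs[["distincts.tsv"]]$sequence)
      for (i in head(which(unknown), 10L)) {
        bad("members.tsv", i + 1L,
            "member sequence not present in distincts.tsv")
      }
    }
  }

  if (length(v)) do.call(rbind, v) else
    data.frame(file = character(0), line = integer(0),
               message = character(0), stringsAsFactors = FALSE)
}
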