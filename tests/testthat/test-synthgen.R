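test_that("reference generation is deterministic and obeys its config", {
  cfg <- reference_config(n_chrom = 2L, chrom_len = 120000L, n_mirna = 10L,
                          n_ncrna = 5L, n_repeat_families = 2L, n_genes = 5L)
  b1 <- generate_reference(cfg, seed = 7L)
  b2 <- generate_reference(cfg, seed = 7L)
  expect_identical(b1$genome, b2$genome)
  expect_identical(b1$features, b2$features)
  expect_identical(b1$mirna_db, b2$mirna_db)
  expect_length(b1$genome, 2L)
  expect_true(all(nchar(unlist(b1$genome)) == 120000L))
  # database sequences are copies of the planted genomic intervals
  feat <- b1$features[b1$features$class == "ncRNA", ]
  for (i in seq_len(nrow(feat))) {
    planted <- substr(b1$genome[[feat$chrom[i]]], feat$start[i] + 1L,
                      feat$end[i])
    expect_identical(planted,
                     b1$ncrna_db$sequence[b1$ncrna_db$id == feat$id[i]])
  }
})

test_that("zero feature density yields empty database and intervals", {
  cfg <- reference_config(n_chrom = 1L, chrom_len = 120000L, n_mirna = 5L,
                          n_ncrna = 3L, n_repeat_families = 0L, n_genes = 3L)
  b <- generate_reference(cfg, seed = 1L)
  expect_identical(nrow(b$repeat_db), 0L)
  expect_false("repeat" %in% b$features$class)
})

test_that("feature densities beyond genome capacity raise a class-named error", {
  cfg <- reference_config(n_chrom = 1L, chrom_len = 100000L, n_mirna = 5L,
                          n_ncrna = 3L, n_repeat_families = 40L,
                          repeat_copies = 8L, n_genes = 200L)
  expect_error(generate_reference(cfg, seed = 1L), "capacity.*'(gene|repeat)'")
})

test_that("planted loci respect trigger-offset range and phase geometry", {
  b <- generate_reference(reference_config(n_chrom = 1L, chrom_len = 300000L,
                                           n_mirna = 8L, n_ncrna = 4L,
                                           n_repeat_families = 2L,
                                           n_genes = 6L), seed = 11L)
  pl <- plant_phased_loci(b, n_loci = 25L,
                          config = locus_config(n_members_range = c(3L, 5L)),
                          seed = 12L)
  expect_identical(nrow(pl$loci), 25L)
  expect_true(all(pl$loci$n_members >= 3L & pl$loci$n_members <= 5L))
  off <- pl$loci$trigger_offset
  expect_true(all(is.na(off) | (off >= 2L & off <= 452L)))
  # every member satisfies the downstream in-phase predicate at the
  # planted register, and member sequences match the genome
  for (lid in pl$loci$locus_id) {
    li <- pl$loci[pl$loci$locus_id == lid, ]
    mem <- pl$members[pl$members$locus_id == lid, ]
    expect_true(all(nchar(mem$sequence) == 21L))
    expect_true(all(in_phase(mem$start, mem$strand, li$register)))
    for (j in seq_len(nrow(mem))) {
      g <- substr(pl$bundle$genome[[mem$chrom[j]]], mem$start[j] + 1L,
                  mem$end[j])
      expect_identical(mem$sequence[j],
                       if (mem$strand[j] == "-") revcomp(g) else g)
    }
  }
  # the planted recognition site is the reverse complement of the trigger
  # on the transcript strand
  tr <- pl$loci[!is.na(pl$loci$trigger_name), ]
  for (i in seq_len(nrow(tr))) {
    site <- substr(pl$bundle$genome[[tr$chrom[i]]],
                   tr$trigger_site_start[i] + 1L,
                   tr$trigger_site_start[i] + 22L)
    trig <- pl$bundle$trigger_db$sequence[
      pl$bundle$trigger_db$id == tr$trigger_name[i]]
    expect_identical(if (tr$orientation[i] == "+") revcomp(site) else site,
                     trig)
  }
})

test_that("planting zero loci leaves the genome unchanged", {
  b <- generate_reference(reference_config(n_chrom = 1L, chrom_len = 100000L,
                                           n_mirna = 4L, n_ncrna = 2L,
                                           n_repeat_families = 1L,
                                           n_genes = 2L), seed = 3L)
  pl <- plant_phased_loci(b, n_loci = 0L, seed = 4L)
  expect_identical(pl$bundle$genome, b$genome)
  expect_identical(nrow(pl$loci), 0L)
})

test_that("library simulation conserves counts and is deterministic", {
  sim <- default_simulation(42L)
  sizes <- sim$truth$library_sizes
  for (lib in names(sizes)) {
    expect_identical(length(sim$reads[[lib]]$id), as.integer(sizes[[lib]]))
    expect_identical(sum(sim$truth$units[[paste0("count_", lib)]]),
                     as.integer(sizes[[lib]]))
  }
  # every emitted read is traceable to exactly one truth unit, and
  # grouping reads by unit reproduces the realised count table
  for (lib in names(sizes)) {
    unit_of <- sub("^[^|]*\\|", "", sim$reads[[lib]]$id)
    tab <- table(unit_of)
    cnt <- sim$truth$units[[paste0("count_", lib)]]
    names(cnt) <- sim$truth$units$unit
    expect_true(all(names(tab) %in% names(cnt)))
    expect_identical(as.integer(tab[names(tab)]),
                     as.integer(cnt[names(tab)]))
    expect_identical(sum(cnt[setdiff(names(cnt), names(tab))]), 0L)
  }
  # determinism: regenerating from the same seeds gives identical reads
  b2 <- generate_reference(seed = 42L)
  pl2 <- plant_phased_loci(b2, n_loci = 60L, seed = 43L)
  sim2 <- simulate_libraries(pl2, seed = 44L)
  expect_identical(sim$reads, sim2$reads)
  tmp1 <- tempfile(); tmp2 <- tempfile()
  write_fastq(sim$reads$A$sequence, sim$reads$A$id, tmp1)
  write_fastq(sim2$reads$A$sequence, sim2$reads$A$id, tmp2)
  expect_identical(unname(tools::md5sum(tmp1)), unname(tools::md5sum(tmp2)))
  unlink(c(tmp1, tmp2))
})

test_that("per-locus expected counts follow the planted fold ratio", {
  sim <- default_simulation(42L)
  tl <- sim$truth$loci
  big <- tl[tl$count_A + tl$count_B >= 100L, ]
  ratio <- big$count_A / pmax(big$count_B, 1L)
  # realised count ratios concentrate around the planted fold
  expect_true(mean(abs(log(ratio / big$fold_ratio)) < log(2)) > 0.9)
  # fold-1 loci are near symmetric overall
  nullr <- ratio[big$fold_ratio == 1]
  if (length(nullr) >= 5L) {
    expect_lt(abs(mean(log(nullr))), 0.3)
  }
})

test_that("the dominant miRNA family takes its configured share", {
  sim <- default_simulation(42L)
  bg <- sim$truth$background
  mir <- bg[bg$class == "miRNA", ]
  fam <- sim$bundle$mirna_db$family[match(mir$source, sim$bundle$mirna_db$id)]
  share <- tapply(mir$count_A + mir$count_B, fam, sum)
  share <- share / sum(share)
  dom <- sim$bundle$mirna_db$family[1]
  expect_equal(unname(share[dom]), 0.64, tolerance = 0.05)
})

test_that("invalid simulator parameters are rejected", {
  b <- generate_reference(reference_config(n_chrom = 1L, chrom_len = 100000L,
                                           n_mirna = 4L, n_ncrna = 2L,
                                           n_repeat_families = 1L,
                                           n_genes = 2L), seed = 3L)
  pl <- plant_phased_loci(b, n_loci = 0L, seed = 4L)
  expect_error(library_config(error_rate = 0.5), "error_rate")
  expect_error(library_config(library_sizes = c(A = 0L, B = 10L)),
               "positive")
})
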