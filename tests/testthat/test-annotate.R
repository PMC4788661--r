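# A constructed bundle where sequences hit known combinations of tiers.
hierarchy_fixture <- function() {
  set.seed(31)
  genome <- list(chr1 = random_dna_str(5000))
  mir <- substr(genome$chr1, 101, 121)       # in miRNA db AND genome
  rep_seq <- substr(genome$chr1, 301, 330)   # in repeat db AND genome
  genome_only <- substr(genome$chr1, 1001, 1021)
  nowhere <- "AACCCACACCCACCCAACCCA"         # matches nothing (A/C only)
  gene_feat <- data.frame(chrom = "chr1", start = 2000L, end = 2600L,
                          class = "gene", subclass = "CDS", id = "g1_cds",
                          stringsAsFactors = FALSE)
  in_cds <- substr(genome$chr1, 2101, 2121)
  bundle <- make_test_bundle(genome,
                             mirna = c(mirX = mir),
                             repeats = c(repX = rep_seq),
                             features = gene_feat)
  list(bundle = bundle, mir = mir, rep_seq = substr(rep_seq, 1, 21),
       genome_only = genome_only, nowhere = nowhere, in_cds = in_cds)
}

test_that("hierarchical classification is first-hit-wins over the tiers", {
  fx <- hierarchy_fixture()
  d <- collapse_reads(list(A = c(fx$mir, fx$rep_seq, fx$genome_only,
                                 fx$nowhere, fx$in_cds),
                           B = character(0)))
  d <- normalize_rpm(d, totals = c(A = 5, B = 1))
  out <- classify_hierarchical(d, fx$bundle)
  got <- setNames(out$annotation_class, out$sequence)
  expect_identical(unname(got[fx$mir]), "miRNA")
  expect_identical(unname(got[fx$rep_seq]), "repeat")
  expect_identical(unname(got[fx$genome_only]), "unannotated")
  expect_identical(unname(got[fx$nowhere]), "unmapped")
  expect_identical(unname(got[fx$in_cds]), "gene")
  expect_identical(out$annotation_subclass[out$sequence == fx$in_cds], "CDS")
})

test_that("classification is independent of record order within a tier", {
  fx <- hierarchy_fixture()
  d <- normalize_rpm(collapse_reads(list(A = c(fx$mir, fx$rep_seq),
                                         B = character(0))),
                     totals = c(A = 2, B = 1))
  b2 <- fx$bundle
  b2$mirna_db <- b2$mirna_db[rev(seq_len(nrow(b2$mirna_db))), ]
  pad <- make_test_bundle(fx$bundle$genome,
                          mirna = c(decoy = random_dna_str(21),
                                    mirX = fx$mir))$mirna_db
  b2$mirna_db <- pad
  out1 <- classify_hierarchical(d, fx$bundle)
  out2 <- classify_hierarchical(d, b2)
  expect_identical(out1$annotation_class, out2$annotation_class)
})

test_that("genome mapping reports every placement and hit counts", {
  set.seed(32)
  core <- random_dna_str(21)
  spacer <- function() random_dna_str(60)
  chr <- paste0(spacer(), core, spacer(), core, spacer(),
                revcomp(core), spacer())
  genome <- list(chr1 = chr, chr2 = paste0(spacer(), core, spacer()))
  aln <- map_to_genome(core, genome)
  expect_identical(nrow(aln), 4L)
  expect_setequal(aln$strand[aln$chrom == "chr1"], c("+", "-"))
  hits <- attr(aln, "genome_hits")
  expect_identical(unname(hits[core]), 4L)
  # absent sequence: no alignments, zero hits
  missing <- "AACCAACCAACCAACCAACCA"
  aln2 <- map_to_genome(missing, genome)
  expect_identical(nrow(aln2), 0L)
  expect_identical(unname(attr(aln2, "genome_hits")[missing]), 0L)
  # planted positions are recovered exactly
  expect_true(all(vapply(seq_len(nrow(aln)), function(i) {
    g <- substr(genome[[aln$chrom[i]]], aln$start[i] + 1L, aln$end[i])
    s <- if (aln$strand[i] == "-") revcomp(g) else g
    identical(s, core)
  }, logical(1))))
})

test_that("mismatch-tolerant mapping finds near-exact placements", {
  set.seed(33)
  chr <- random_dna_str(400)
  q <- substr(chr, 100, 120)
  substr(q, 11, 11) <- setdiff(c("A", "C", "G", "T"), substr(q, 11, 11))[1]
  aln0 <- map_to_genome(q, list(chr1 = chr), max_mismatches = 0L)
  aln1 <- map_to_genome(q, list(chr1 = chr), max_mismatches = 1L)
  expect_identical(nrow(aln0), 0L)
  expect_identical(aln1$start[1], 99L)
  expect_identical(aln1$mismatches[1], 1L)
})

test_that("class composition sums to one and handles edge cases", {
  d <- data.frame(annotation_class = c("miRNA", "ncRNA", "repeat", "gene"))
  expect_equal(unname(class_composition(d)[1:4]), rep(0.25, 4))
  d2 <- data.frame(annotation_class = rep("miRNA", 3))
  expect_identical(unname(class_composition(d2)[["miRNA"]]), 1)
  expect_error(class_composition(data.frame(annotation_class = character(0))),
               "undefined")
  # synthetic run: recovered composition is close to the planted truth mix
  sim <- default_simulation(42L)
  sets <- lapply(sim$reads, `[[`, "sequence")
  d3 <- normalize_rpm(collapse_reads(sets))
  d3 <- classify_hierarchical(d3, sim$bundle)
  # every planted locus member that mapped should be unannotated
  mem <- unique(sim$truth$members$sequence)
  cls <- d3$annotation_class[match(mem, d3$sequence)]
  expect_gt(mean(cls == "unannotated", na.rm = TRUE), 0.95)
})
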