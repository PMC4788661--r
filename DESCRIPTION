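Package: phasekit
Title: Detection and Differential Analysis of 21-nt Phased siRNA Loci from
    Small RNA-Seq Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for discovering 21-nucleotide phased
    secondary siRNA (phasiRNA) loci from two small RNA sequencing libraries
    and quantifying their differential accumulation. Implements adapter
    trimming and read collapsing, hierarchical first-hit-wins annotation
    against ordered sequence databases, genome mapping, a sliding-window
    hypergeometric phasing statistic with two-strand 2-nt offset geometry,
    multimapping and blacklist post-filters, two-pass member recruitment,
    complementarity scanning for 22-nt trigger miRNA recognition sites in
    locus flanks, and g-test based two-library differential analysis at the
    sequence, locus, class and miRNA-family level. A synthetic-data module
    generates reference bundles and paired libraries with planted phased
    loci, trigger sites and known fold changes, plus machine-readable truth
    tables, so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    BiocGenerics,
    Rcpp,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
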