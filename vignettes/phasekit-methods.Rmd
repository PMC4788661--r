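---
title: "Detecting 21-nt phased siRNA loci: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting 21-nt phased siRNA loci: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phasekit)
```

## The biological model

21-nt phasiRNAs are secondary siRNAs produced from long non-coding
precursor transcripts. A 22-nt trigger miRNA (canonically miR2118 in
grass panicles) guides cleavage of the precursor between the bases
pairing trigger positions 10 and 11; the 3' fragment is made
double-stranded by RDR6 and processively diced by DCL4 into 21-nt
duplexes with 2-nt 3' overhangs. Mapped back to the genome, the
products of one locus share a *register*: plus-strand 5' starts are
congruent to a constant mod 21, and minus-strand reads (reported by
their plus-strand leftmost coordinate) are congruent to that constant
minus 2. Everything phasekit detects and simulates follows from this
geometry.

Coordinates are 0-based half-open everywhere inside the package; BED
output is 0-based, GFF3 output 1-based.

## The phasing statistic

Detection scans each chromosome with a window of `cycles` 21-nt cycles
(default 11, window length 231 nt) advanced in steps of 21 nt. A window
holds `N = 2 * 231` eligible distinct 5'-start positions (both strands)
of which `K = 2 * cycles` lie on a candidate register. With `n`
observed distinct start positions in the window, of which `k` are in
register, the p-value is the hypergeometric upper tail `P(X >= k)` for
`X ~ Hypergeometric(N, K, n)`. All 21 registers are tested; windows
with `p <= alpha` (default `1e-4`) and at least `min_members`
(default 3) distinct member sequences are kept, and overlapping
significant windows with the same register are merged into one locus
whose span runs from the leftmost to the rightmost member coordinate.

Implementation notes:

* The tail is computed by log-domain summation of `lchoose` terms with
  the maximum factored out. Binomial coefficients in the admissible
  range exceed 2^53 (e.g. `choose(100, 15)` is about 2.5e17), so exact
  integer arithmetic is not representable in doubles; the test suite
  certifies agreement with a direct enumeration oracle to 1e-12
  relative, and with `stats::phyper` as an independent cross-check.
* `n` counts *distinct* start positions, not reads, making the
  statistic insensitive to the strong abundance skew within a locus.
* Merging requires an identical register; adjacent loci on different
  registers stay distinct. Overlap of merged windows is the merge
  criterion, so one locus never spans a gap of more than a window.

Defaults (`alpha = 1e-4`, `min_members = 3`, `step = 21`) are
conservative values consistent with loci that typically carry 3-9
distinct members; all are exposed as arguments.

## Annotation hierarchy and the local matcher

Distinct sequences are classified first-hit-wins against ordered tiers:
miRNA database, ncRNA database, repeat database, then genome placements
overlapping CDS features, then intron/UTR features; sequences whose
placements fall outside gene features are "unannotated", and sequences
matching nothing are "unmapped". CDS and intron/UTR assignments share
the class "gene" with the subclass recorded.

Database tiers use an ungapped all-offsets local matcher written in
C++: for every diagonal of every query/subject pair (both strands) it
reports the best window with identity fraction at least
`min_identity_frac` (default 0.85) and length at least
`max(min_match_len, ceiling(min_coverage_frac * query length))`
(defaults 16 nt and 0.85). These thresholds are the operative filter of
the classical BLAST-based annotation cascade for 18-28-nt queries;
e-values are deliberately not computed because they depend on database
size while the identity/coverage/length thresholds do not. Gapped
alignments are not considered: at 85 % coverage of a 21-nt query an
indel consumes most of the mismatch budget, so the added complexity
has no practical effect at these scales.

Genome mapping defaults to exact placement (Biostrings `PDict`
dictionaries, both strands); a substitution-tolerant path
(`max_mismatches > 0`) exists for divergent references. With exact
mapping, reads carrying sequencing errors simply fall into the
"unmapped" class, as they do in practice with near-isogenic
references.

## Post-filters and recruitment

After detection, member sequences placed at more than `max_hits`
(default 10) genomic positions are removed, loci falling below
`min_members` are dropped, and loci overlapping the blacklist
(telomere-like terminal intervals in the synthetic bundle) are
discarded. Remaining 21-nt sequences are then recruited to loci by
similarity to the core members in two passes: pass 1 requires 100 %
identity over 85 % of the length (minimum 16 nt), pass 2 relaxes
identity to 85 %. A pass-1 recruit is not re-tested in pass 2;
sequences matching members of several loci join all of them and are
flagged ambiguous. Recruited members contribute to locus abundance
sums (disable with `include_recruited = FALSE`); they carry no genomic
coordinates of their own and never extend the locus span.

## Trigger-site scanning

Each locus ± `flank` bp (default 500, truncated at chromosome ends) is
scanned on both transcript strands for the best placement of each
22-nt trigger. Penalties per trigger position: 0 for a Watson-Crick
pair, 0.5 for a G:U wobble, 1 for a mismatch, doubled at positions
2-13 — the standard plant miRNA target-site scoring, which replaces
de-novo motif discovery with a deterministic, testable criterion. A
placement is reported when its total penalty is at most `threshold`
(default 4.5). The reported distance is the gap between the site and
the nearest locus edge (0 when they overlap); because the locus edge
is the outermost *expressed* member, the distance to the cleavage
position can be recovered from the reported site coordinate when
needed.

## The g-test

Two-library comparisons use the likelihood-ratio goodness-of-fit test
`G = 2 * sum(O * ln(O / E))` with expected counts proportional to the
library totals (1 df), at a fixed `p <= 1e-3` and no multiple-testing
correction; a Benjamini-Hochberg adjustment can be applied downstream
by the user but is deliberately not the default, keeping the fixed
threshold semantics. Raw counts are tested; RPM values are used only
for the fold ratio, with a 0.5 pseudocount added to both RPM values
when either count is zero. Numerically, G is evaluated as
`-2 * sum(O * log1p((E - O)/O))` split into its second-order part and
an analytically reduced first-order part, so nearly proportional
tables do not lose precision to cancellation; the suite certifies
1e-9 relative agreement with a 50-digit reference evaluation.

The chi-square approximation is anti-conservative for very small
counts; calibration is therefore asserted only for units with at least
20 reads, where simulated null data places the false-positive rate
inside the 99 % binomial band around the nominal level.

## The synthetic-data generator

The generator is first-class, tested code: it defines the study
conditions under which every downstream claim is checked.

* **Reference bundle** — 2 chromosomes x 500 kb of uniform random
  sequence; planted miRNA loci (mature sequences copied into the
  genome, grouped into families typed canonical/variant/siRNA-like),
  ncRNA and repeat loci (repeat consensi planted at several copies so
  repeat reads multimap), gene models partitioned into UTR/CDS/intron,
  and a telomere-like 5-kb blacklist at every chromosome end.
* **Loci** — 60 planted phased loci: 3-9 members each (uniform;
  observed loci carry 2-91 distinct members with a mean of 6 and a
  majority of 3-5, and the floor of 3 matches the detector's
  min-member default); 59.3 % carry a trigger site whose reverse
  complement is written into the flank, with the register anchored to
  cleavage between trigger positions 10/11; 92.5 % produce members
  from both strands; member abundances follow a Zipf law with exponent
  1.5, reproducing the predominance of one or two members per locus;
  70 % of loci carry a fold change drawn uniformly from [5, 10]
  (A over B), the rest are null.
* **Libraries** — 50 000 reads per library, multinomial over a unit
  table mixing locus members (25 % of reads), miRNAs (20 %, one family
  holding 64 % of the class, plus 1-nt length variants), ncRNA
  fragments (10 %), 24-nt repeat fragments (20 %), gene fragments
  (15 %) and unphased 21-nt noise from random genome positions (10 %).
  Locus expected counts are held in exact ratio `fold_ratio` between
  libraries; the background absorbs the normalisation remainder, which
  mirrors the compositional shift a genuinely asymmetric library pair
  shows. Sequencing errors are i.i.d. substitutions at 0.001 per base;
  qualities are constant `I`.
* **Truth** — every read id carries its unit; unit tables give
  realised per-library counts per member, locus and background unit.

What the generator does *not* emulate: ligation and base-composition
biases, indel errors, multi-genotype bulk structure (each library is a
single pool), 24-nt phasiRNA loci and their trigger, and genuine
sequence divergence between the two libraries' genomes. Passing tests
therefore demonstrate correctness of the algorithms under the stated
statistical structure, not robustness to every artefact of real
libraries.

## Problem sizes and determinism

The default study conditions (1 Mb genome, 60 loci, 100 000 reads) run
end to end in about a minute on one core; the test-suite fixtures are
smaller where the full scale adds nothing. Every stochastic step takes
an explicit seed, derived from one master seed in the pipeline driver,
and all writers emit fixed column orders with `\n` line endings, so a
config plus seed reproduces every output file byte for byte.

## Known limitations

* Phasing is detected in genome coordinates; loci split across a
  spliced precursor would be fragmented.
* The recruitment passes attach sequences by similarity only; a
  recruited sequence contributes abundance but no positional evidence.
* The g-test models two libraries without replicates, as in a
  two-bulk design; it measures difference, not biological variance.
* With exact genome mapping, error-carrying reads are invisible to
  detection; at the default error rate this costs about 2 % of reads
  and is negligible for locus-level calls, but with divergent
  references `max_mismatches` should be raised.
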