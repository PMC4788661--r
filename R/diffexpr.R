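#' Likelihood-ratio goodness-of-fit test (g-test)
#'
#' G = 2 * sum(O * ln(O / E)) with the 0 * ln 0 terms defined as 0;
#' expected counts are rescaled to the observed total. The p-value is the
#' chi-square upper tail at `df` degrees of freedom.
#'
#' @param observed non-negative observed counts
#' @param expected positive expected counts (rescaled internally)
#' @param df degrees of freedom; defaults to `length(observed) - 1`
#' @return a list of class `gtest_result` with `G`, `df`, `p_value`
#' @export
gtest <- function(observed, expected, df = NULL) {
  if (length(observed) != length(expected)) {
    stopf("observed and expected must have equal length")
  }
  if (any(observed < 0)) stopf("observed counts must be non-negative")
  if (any(expected <= 0 & observed > 0)) {
    stopf("expected counts must be positive where observed is nonzero")
  }
  df <- df %||% (length(observed) - 1L)
  # G/2 = -Σ O·log1p(δ) with δ = (E·s − O)/O and s = ΣO/ΣE, split into
  # Σ O·(δ − log1p(δ)) (second order in δ) plus the first-order part
  # -Σ O·δ, which reduces analytically to ΣO · (zero-cell expected mass
  # fraction); nearly proportional tables therefore lose no precision to
  # cancellation
  s <- sum(observed) / sum(expected)
  nz <- observed > 0
  P <- expected[nz] * s
  delta <- (P - observed[nz]) / observed[nz]
  zero_mass <- sum(expected[!nz]) / sum(expected)
  G <- 2 * (sum(observed[nz] * (delta - log1p(delta))) +
              sum(observed) * zero_mass)
  G <- max(G, 0)
  structure(list(G = G, df = df,
                 p_value = pchisq(G, df, lower.tail = FALSE)),
            class = "gtest_result")
}

#' @export
print.gtest_result <- function(x, ...) {
  cat(sprintf("g-test: G = %.4g, df = %d, p = %.3g\n", x$G, x$df, x$p_value))
  invisible(x)
}

# Vectorised two-library G statistic against expected counts proportional
# to the library totals.
g_two_library <- function(count_A, count_B, total_A, total_B) {
  tot <- count_A + count_B
  eA <- tot * total_A / (total_A + total_B)
  eB <- tot * total_B / (total_A + total_B)
  term <- function(o, e) ifelse(o > 0, o * log(o / e), 0)
  pmax(0, 2 * (term(count_A, eA) + term(count_B, eB)))
}

#' Two-library differential analysis of count units
#'
#' Tests each unit's (count_A, count_B) against expected counts
#' proportional to the library totals with a 1-df g-test, and categorises
#' units by significance and the direction of the normalised-abundance
#' ratio. The fold flag marks units whose rpm ratio is at least `fold`
#' in either direction; a pseudocount keeps the ratio defined when one
#' count is zero.
#'
#' @param units data.frame with `unit_id` (or `locus_id`/`sequence`),
#'   `count_A`, `count_B`
#' @param totals named numeric vector with library totals `A` and `B`
#' @param alpha significance threshold on the g-test p-value
#' @param fold fold-ratio threshold
#' @param pseudocount rpm pseudocount applied when either count is zero
#' @return a data.frame of class `differential_records`: `unit_id`,
#'   counts, rpm, `ratio` (A over B), `G`, `p_value`, `category`
#'   (over_A/over_B/ns), `fold5_flag`
#' @export
unit_differential <- function(units, totals, alpha = 1e-3, fold = 5,
                              pseudocount = 0.5) {
  if (any(totals <= 0)) stopf("library totals must be positive")
  id <- units$unit_id %||% units$locus_id %||% units$sequence
  cA <- units$count_A
  cB <- units$count_B
  rpmA <- cA * 1e6 / totals[["A"]]
  rpmB <- cB * 1e6 / totals[["B"]]
  zero <- cA == 0 | cB == 0
  rA <- ifelse(zero, rpmA + pseudocount, rpmA)
  rB <- ifelse(zero, rpmB + pseudocount, rpmB)
  ratio <- rA / rB
  G <- g_two_library(cA, cB, totals[["A"]], totals[["B"]])
  p <- pchisq(G, df = 1, lower.tail = FALSE)
  category <- ifelse(p > alpha | rpmA == rpmB, "ns",
                     ifelse(rpmA > rpmB, "over_A", "over_B"))
  out <- data.frame(unit_id = id, count_A = cA, count_B = cB,
                    rpm_A = rpmA, rpm_B = rpmB, ratio = ratio,
                    G = G, p_value = p, category = category,
                    fold5_flag = ratio >= fold | ratio <= 1 / fold,
                    stringsAsFactors = FALSE)
  class(out) <- c("differential_records", "data.frame")
  out
}

#' Class enrichment of a sequence subset against its background
#'
#' For each class, a 2x2 g-test (1 df) of class membership against
#' subset membership, with the direction of the deviation.
#'
#' @param subset_counts named integer vector: distinct sequences per
#'   class inside the subset
#' @param background_counts named integer vector over the same classes
#'   for the full background (the subset must be contained in it)
#' @return data.frame with per-class counts, fractions, `G`, `p_value`
#'   and `direction` (over/under/none)
#' @export
class_enrichment <- function(subset_counts, background_counts) {
  classes <- names(background_counts)
  subset_counts <- subset_counts[classes]
  subset_counts[is.na(subset_counts)] <- 0L
  names(subset_counts) <- classes
  if (any(subset_counts > background_counts)) {
    stopf("subset exceeds background for some class")
  }
  s_tot <- sum(subset_counts)
  b_tot <- sum(background_counts)
  out <- do.call(rbind, lapply(classes, function(cl) {
    a <- subset_counts[[cl]]               # subset, this class
    b <- s_tot - a                         # subset, other classes
    c_ <- background_counts[[cl]] - a      # rest of background, this class
    d <- (b_tot - background_counts[[cl]]) - b
    O <- c(a, b, c_, d)
    rowm <- c(a + b, c_ + d)
    colm <- c(a + c_, b + d)
    E <- c(rowm[1] * colm[1], rowm[1] * colm[2],
           rowm[2] * colm[1], rowm[2] * colm[2]) / sum(O)
    gt <- gtest(O, ifelse(E <= 0, 1e-12, E), df = 1L)
    data.frame(class = cl, subset_n = a,
               subset_frac = if (s_tot > 0) a / s_tot else NA_real_,
               background_n = background_counts[[cl]],
               background_frac = background_counts[[cl]] / b_tot,
               G = gt$G, p_value = gt$p_value,
               direction = if (s_tot == 0) "none"
               else if (a / s_tot > background_counts[[cl]] / b_tot) "over"
               else if (a / s_tot < background_counts[[cl]] / b_tot) "under"
               else "none",
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Per-family miRNA profile
#'
#' Aggregates miRNA-class sequences by family, builds the per-length
#' abundance histogram (19-25 nt), derives the modal length (length of
#' the highest accumulated member), carries the family type over from the
#' database metadata, and flags families whose annotated loci overlap a
#' detected phased locus.
#'
#' @param distincts classified `distinct_reads` with `annotation_class`,
#'   `annotation_id`, counts and rpm columns
#' @param mirna_db data.frame with `id`, `family`, `type`
#' @param features optional feature table with the genomic interval of
#'   each miRNA record (class "miRNA", `id` matching `mirna_db$id`)
#' @param loci optional `phased_loci` object (or loci data.frame) for
#'   overlap flags
#' @return data.frame with `family`, `type`, `n_members`, `count_A`,
#'   `count_B`, length-histogram columns `len_19` .. `len_25`,
#'   `modal_length`, `phased_overlap`; sequences with no family are
#'   aggregated under family "unassigned"
#' @export
mirna_family_profile <- function(distincts, mirna_db, features = NULL,
                                 loci = NULL) {
  mir <- distincts[distincts$annotation_class == "miRNA", , drop = FALSE]
  empty <- data.frame(family = character(0), type = character(0),
                      n_members = integer(0), count_A = integer(0),
                      count_B = integer(0), stringsAsFactors = FALSE)
  if (nrow(mir) == 0L) return(empty)
  fam <- mirna_db$family[match(mir$annotation_id, mirna_db$id)]
  fam[is.na(fam)] <- "unassigned"
  mir$family <- fam
  abundance <- mir$rpm_A + mir$rpm_B

  loci_df <- if (inherits(loci, "phased_loci")) loci$loci else loci
  fam_overlap <- character(0)
  if (!is.null(loci_df) && !is.null(features) && nrow(loci_df) > 0L) {
    mf <- features[features$class == "miRNA", , drop = FALSE]
    ov <- overlaps_features(mf, loci_df)
    fam_overlap <- unique(mirna_db$family[match(mf$id[ov], mirna_db$id)])
    fam_overlap <- fam_overlap[!is.na(fam_overlap)]
  }

  fams <- sort(unique(mir$family))
  out <- do.call(rbind, lapply(fams, function(f) {
    sub <- mir[mir$family == f, , drop = FALSE]
    ab <- abundance[mir$family == f]
    hist <- vapply(19:25, function(L) sum(ab[sub$length == L]), numeric(1))
    modal <- (19:25)[which.max(hist)]
    ty <- mirna_db$type[match(f, mirna_db$family)]
    data.frame(family = f,
               type = if (is.na(ty)) "unassigned" else ty,
               n_members = nrow(sub),
               count_A = sum(sub$count_A), count_B = sum(sub$count_B),
               rpm_A = sum(sub$rpm_A), rpm_B = sum(sub$rpm_B),
               setNames(as.data.frame(t(hist)), paste0("len_", 19:25)),
               modal_length = modal,
               phased_overlap = f %in% fam_overlap,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
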