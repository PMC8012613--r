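#' Pearson chi-square for 2x2 allele-count tables, vectorised
#'
#' Closed-form Pearson statistic (1 df, no continuity correction) for tables
#' of the form rows = groups, columns = (ref, alt) counts. This is the core
#' statistic of the association scan, so it is computed directly rather than
#' through [stats::chisq.test()] (which serves as an independent cross-check
#' in the test suite).
#'
#' Conventions: a zero column total (an allele absent from both groups) is
#' no differentiation, so chi2 = 0 and p = 1. A zero row total violates the
#' contract (no reads in one group) and raises a validation error.
#'
#' @param a,b ref and alt counts in group 1 (vectors allowed).
#' @param c,d ref and alt counts in group 2.
#' @return list with numeric vectors `chi2` and `p`.
#' @noRd
chi2_2x2 <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) {
    ps_validation_error("negative cell count in 2x2 table")
  }
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  r1 <- a + b
  r2 <- c + d
  if (any(r1 == 0) || any(r2 == 0)) {
    ps_validation_error("zero row total in 2x2 table (no reads in one group)")
  }
  c1 <- a + c
  c2 <- b + d
  n <- r1 + r2
  chi2 <- ifelse(c1 == 0 | c2 == 0, 0,
                 n * (a * d - b * c)^2 / (r1 * r2 * c1 * c2))
  p <- ifelse(chi2 == 0, 1, pchisq(chi2, df = 1, lower.tail = FALSE))
  list(chi2 = chi2, p = p)
}

#' Per-site strain-differentiation chi-square score
#'
#' Compares pooled ref/alt read counts between the resistant and susceptible
#' strains with a Pearson contingency chi-square on the 2x2 table
#' (strains x alleles), 1 degree of freedom, no continuity correction.
#' Counts should already be summed across a strain's replicate libraries;
#' replicate discordance is handled separately by
#' [replicate_consistency_filter()].
#'
#' The association score is `-log10(p)`, with p floored at 1e-300 so scores
#' stay finite. By construction the score is invariant to swapping the
#' ref/alt labels and to exchanging the two strains.
#'
#' @param counts_R length-2 numeric `(ref, alt)` pooled counts for the
#'   resistant strain, or a vector of ref counts when used vectorised
#'   together with `alt_R`/`counts_S`/`alt_S`.
#' @param counts_S length-2 numeric `(ref, alt)` pooled counts for the
#'   susceptible strain.
#' @return list with `chi2`, `p` and `neg_log10_p`.
#' @examples
#' site_chi2(c(70, 30), c(30, 70))  # chi2 = 32, score ~ 7.81
#' @export
site_chi2 <- function(counts_R, counts_S) {
  if (length(counts_R) != 2L || length(counts_S) != 2L) {
    ps_validation_error("site_chi2() expects length-2 (ref, alt) count pairs")
  }
  res <- chi2_2x2(counts_R[1], counts_R[2], counts_S[1], counts_S[2])
  list(chi2 = unname(res$chi2), p = unname(res$p),
       neg_log10_p = unname(-log10(pmax(res$p, P_FLOOR))))
}

#' Between-replicate consistency filter
#'
#' Pearson chi-square (1 df, no continuity correction) between the two
#' replicate libraries of one strain at one site. A site is kept when the
#' replicates are consistent, i.e. `p >= rep_p_cutoff`; a p value strictly
#' below the cutoff drops the site (so p exactly at the cutoff is kept).
#' A site must be kept in both strains to enter any gene score.
#'
#' @param rep1,rep2 length-2 `(ref, alt)` read counts of the two replicates.
#' @param rep_p_cutoff drop threshold, default 0.10.
#' @return list with `chi2`, `p` and logical `keep`.
#' @export
replicate_consistency_filter <- function(rep1, rep2, rep_p_cutoff = 0.10) {
  if (length(rep1) != 2L || length(rep2) != 2L) {
    ps_validation_error("replicate_consistency_filter() expects length-2 (ref, alt) pairs")
  }
  if (!is_prob(rep_p_cutoff)) {
    ps_validation_error("rep_p_cutoff must be a probability in (0, 1)")
  }
  res <- chi2_2x2(rep1[1], rep1[2], rep2[1], rep2[2])
  list(chi2 = unname(res$chi2), p = unname(res$p),
       keep = unname(res$p >= rep_p_cutoff))
}

#' Benjamini-Hochberg adjustment with a significance cutoff
#'
#' Standard step-up adjusted values (monotone, capped at 1) via
#' [stats::p.adjust()], plus the significance call at `bh_cutoff`. The
#' adjustment is stable under reordering of the input.
#'
#' @param p numeric vector of p values in \[0, 1\].
#' @param bh_cutoff adjusted-p significance threshold, default 0.001.
#' @return data.frame with columns `p`, `p_adjusted`, `significant`.
#' @export
bh_adjust <- function(p, bh_cutoff = 0.001) {
  if (length(p) == 0) {
    return(data.frame(p = numeric(0), p_adjusted = numeric(0),
                      significant = logical(0)))
  }
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    ps_validation_error("p values must lie in [0, 1]")
  }
  if (!is_prob(bh_cutoff)) {
    ps_validation_error("bh_cutoff must be a probability in (0, 1)")
  }
  adj <- p.adjust(p, method = "BH")
  data.frame(p = p, p_adjusted = adj, significant = adj <= bh_cutoff)
}
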