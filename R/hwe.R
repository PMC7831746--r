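# Hardy-Weinberg equilibrium tests on biallelic genotype counts.

#' Chi-square test of Hardy-Weinberg equilibrium
#'
#' Pearson goodness-of-fit test of the observed genotype triple against the
#' HWE expectation computed from the sample allele frequency: with
#' \eqn{\hat p = (2 n_{hom} + n_{het}) / 2n}, expected counts are
#' \eqn{(n\hat p^2, 2n\hat p\hat q, n\hat q^2)} and
#' \eqn{\chi^2 = \sum (O-E)^2/E} on 1 df. No continuity correction is
#' applied, so \eqn{\chi^2 = 0} is attainable at exact HWE proportions.
#'
#' @param counts a [geno_counts()] triple (or numeric length-3 vector of
#'   hom-risk, het, hom-other counts).
#' @return list of class `hwe_test`: `chi2`, `df`, `p`, `allele_freq` (risk
#'   allele), `expected` (triple), `n`.
#' @examples
#' hwe_chisq(geno_counts(25, 50, 25)) # chi2 = 0, p = 1
#' @export
hwe_chisq <- function(counts) {
  counts <- as_geno_triple(counts)
  n <- sum(counts)
  p <- (2 * counts[1] + counts[2]) / (2 * n)
  if (p == 0 || p == 1)
    stopf("HWE test undefined for a monomorphic SNP")
  q <- 1 - p
  expected <- n * c(p^2, 2 * p * q, q^2)
  chi2 <- sum((counts - expected)^2 / expected)
  structure(list(chi2 = chi2, df = 1L,
                 p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
                 allele_freq = unname(p), expected = unname(expected),
                 n = n),
            class = "hwe_test")
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact test: conditional on the observed allele counts, the
#' probability of each possible heterozygote count is computed from the
#' Levene distribution and the p-value is the sum of probabilities of all
#' configurations no more probable than the observed one. Preferable to the
#' chi-square test when any expected cell count is small.
#'
#' @inheritParams hwe_chisq
#' @return the exact p-value.
#' @export
hwe_exact <- function(counts) {
  counts <- as_geno_triple(counts)
  n <- sum(counts)
  n_a <- 2 * counts[1] + counts[2]     # risk-allele copies
  n_b <- 2 * n - n_a
  if (n_a == 0 || n_b == 0)
    stopf("HWE test undefined for a monomorphic SNP")
  rare <- min(n_a, n_b)
  het_obs <- unname(counts[2])
  hets <- seq(rare %% 2, rare, by = 2)  # parity-compatible het counts
  # log P(het) under Levene's conditional distribution
  logp <- vapply(hets, function(h) {
    homr <- (n_a - h) / 2
    homo <- (n_b - h) / 2
    h * log(2) + lfactorial(n) - lfactorial(homr) - lfactorial(h) -
      lfactorial(homo) + lfactorial(n_a) + lfactorial(n_b) -
      lfactorial(2 * n)
  }, 0)
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  obs_i <- match(het_obs, hets)
  if (is.na(obs_i))
    stopf("genotype counts inconsistent with allele totals")
  min(1, sum(pr[pr <= pr[obs_i] * (1 + 1e-12)]))
}

as_geno_triple <- function(counts) {
  x <- as.numeric(counts)
  if (length(x) != 3L || any(is.na(x)) || any(x < 0))
    stopf("expected a triple of non-negative genotype counts")
  if (sum(x) < 1) stopf("HWE test needs at least one genotype")
  x
}

#' @export
print.hwe_test <- function(x, ...) {
  cat(sprintf("HWE chi-square test: chi2 = %.4f (df = %d), p = %s\n",
              x$chi2, x$df, format_pvalue(x$p)))
  cat(sprintf("  risk-allele frequency %.4f; expected counts %.2f / %.2f / %.2f (n = %d)\n",
              x$allele_freq, x$expected[1], x$expected[2], x$expected[3],
              as.integer(x$n)))
  invisible(x)
}
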