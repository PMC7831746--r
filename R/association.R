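# Case-control contingency-table association statistics.

#' 2x2 contingency table for case-control association
#'
#' Cell layout: `a` = cases exposed, `b` = cases unexposed, `c` = controls
#' exposed, `d` = controls unexposed ("exposed" = carrying the risk allele /
#' genotype class under the chosen model).
#'
#' @param a,b,c,d non-negative counts.
#' @return named numeric vector of class `table2x2`.
#' @export
table2x2 <- function(a, b, c, d) {
  x <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(x)) || any(x < 0)) stopf("table cells must be >= 0")
  if (sum(x) <= 0) stopf("table is empty")
  structure(x, class = "table2x2")
}

#' Allele-count 2x2 table from case/control genotype counts
#'
#' Each sample contributes two alleles: risk-allele count = 2 x hom-risk +
#' het per group.
#'
#' @param case_counts,control_counts [geno_counts()] triples.
#' @return a [table2x2()] of allele counts (rows cases/controls, columns
#'   risk/other allele).
#' @export
allele_table <- function(case_counts, control_counts) {
  cc <- as_geno_triple(case_counts)
  uu <- as_geno_triple(control_counts)
  table2x2(a = 2 * cc[1] + cc[2], b = 2 * cc[3] + cc[2],
           c = 2 * uu[1] + uu[2], d = 2 * uu[3] + uu[2])
}

#' Dominant / recessive 2x2 table from case/control genotype counts
#'
#' Dominant model: exposed = carriers (het + hom-risk). Recessive model:
#' exposed = risk homozygotes only.
#'
#' @inheritParams allele_table
#' @param model `"dominant"` or `"recessive"`.
#' @return a [table2x2()].
#' @export
model_table <- function(case_counts, control_counts,
                        model = c("dominant", "recessive")) {
  model <- match.arg(model)
  cc <- as_geno_triple(case_counts)
  uu <- as_geno_triple(control_counts)
  if (model == "dominant") {
    table2x2(cc[1] + cc[2], cc[3], uu[1] + uu[2], uu[3])
  } else {
    table2x2(cc[1], cc[2] + cc[3], uu[1], uu[2] + uu[3])
  }
}

#' Pearson chi-square test on a contingency table
#'
#' Pearson chi-square without continuity correction; degrees of freedom
#' `(rows - 1)(cols - 1)`. A warning is raised when any expected cell count
#' is below 5; a zero row or column margin is an error.
#'
#' @param tab a [table2x2()] (allelic/dominant/recessive coding) or a 2x3
#'   matrix of genotype counts (rows cases/controls) for the genotypic test.
#' @return list with `chi2`, `df`, `p`, `expected`.
#' @export
chisq_assoc <- function(tab) {
  m <- if (inherits(tab, "table2x2"))
    matrix(as.numeric(tab), nrow = 2, byrow = TRUE) else as.matrix(tab)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stopf("chi-square test undefined: zero row or column margin")
  res <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  if (any(res$expected < 5))
    warnf("chi-square approximation may be poor: expected cell count < 5")
  list(chi2 = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value, expected = res$expected)
}

#' Odds ratio with Woolf 95% confidence interval
#'
#' Cross-product odds ratio `ad/bc` with the Woolf (log-scale normal)
#' interval \eqn{\exp(\ln OR \pm 1.959964 \sqrt{1/a + 1/b + 1/c + 1/d})}.
#' If any single cell is zero, the Haldane-Anscombe correction (+0.5 to all
#' four cells) is applied and flagged; two zero cells on a diagonal leave
#' the OR undefined and raise an error.
#'
#' @param tab a [table2x2()].
#' @param model label recorded in the result (`"allelic"`, `"dominant"`,
#'   `"recessive"`, ...).
#' @param conf_z normal quantile for the interval (default 1.959964, i.e.
#'   95%).
#' @return list of class `assoc_or`: `model`, `or`, `ci_low`, `ci_high`,
#'   `chi2`, `df`, `p`, `n_effective`, `haldane` flag.
#' @examples
#' odds_ratio_woolf(table2x2(51, 39, 82, 208)) # MTHFR-style allele table
#' @export
odds_ratio_woolf <- function(tab, model = "allelic", conf_z = Z975) {
  stopifnot(inherits(tab, "table2x2"))
  x <- as.numeric(tab)
  if ((x[1] == 0 && x[4] == 0) || (x[2] == 0 && x[3] == 0))
    stopf("OR undefined: two zero cells on a diagonal")
  haldane <- any(x == 0)
  xx <- if (haldane) x + 0.5 else x
  or <- (xx[1] * xx[4]) / (xx[2] * xx[3])
  se <- sqrt(sum(1 / xx))
  ci <- exp(log(or) + c(-1, 1) * conf_z * se)
  ct <- chisq_assoc(tab)
  structure(list(model = model, or = or, ci_low = ci[1], ci_high = ci[2],
                 chi2 = ct$chi2, df = ct$df, p = ct$p,
                 n_effective = sum(x), haldane = haldane),
            class = "assoc_or")
}

#' @export
print.assoc_or <- function(x, ...) {
  cat(sprintf("%s model: OR = %.3f (95%% CI %.3f-%.3f), chi2 = %.3f (df %d), p = %s%s\n",
              x$model, x$or, x$ci_low, x$ci_high, x$chi2, x$df,
              format_pvalue(x$p),
              if (isTRUE(x$haldane)) " [Haldane-Anscombe +0.5]" else ""))
  invisible(x)
}

#' Reconstruct a count from a printed frequency
#'
#' Converts a percentage printed in a results table back into the integer
#' count it came from: `round(freq/100 * denominator)` with half rounded
#' away from zero, where the denominator is `2n` for allele frequencies or
#' `n` for genotype frequencies.
#'
#' @param freq_percent frequency in percent (0-100).
#' @param n_samples number of samples in the group.
#' @param per_allele if `TRUE` (default) the denominator is `2 * n_samples`.
#' @return integer count.
#' @examples
#' counts_from_freq(56.7, 45)   # 51 of 90 case alleles
#' counts_from_freq(28.3, 145)  # 82 of 290 control alleles
#' @export
counts_from_freq <- function(freq_percent, n_samples, per_allele = TRUE) {
  if (any(freq_percent < 0 | freq_percent > 100))
    stopf("frequency must be within [0, 100] percent")
  denom <- if (per_allele) 2 * n_samples else n_samples
  as.integer(round_half_up(freq_percent / 100 * denom))
}

#' One-way ANOVA with Tukey HSD post hoc comparisons
#'
#' Tests a quantitative trait (grip strength, SMI, gait speed, ...) for
#' differences across genotype groups, then compares all genotype pairs with
#' Tukey's honest significant difference. Sexes should be analyzed
#' separately by the caller. Groups with fewer than 2 observations are
#' dropped with a warning.
#'
#' @param values numeric trait values.
#' @param genotype genotype group labels (factor or character).
#' @return list with `f`, `df`, `p`, and `tukey` (data frame of pairwise
#'   mean differences, interval bounds and adjusted p-values).
#' @export
anova_tukey <- function(values, genotype) {
  keep <- !is.na(values) & !is.na(genotype)
  values <- values[keep]
  genotype <- as.character(genotype)[keep]
  sizes <- table(genotype)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warnf("dropping genotype group(s) with < 2 values: %s",
          paste(small, collapse = ", "))
    sel <- !(genotype %in% small)
    values <- values[sel]; genotype <- genotype[sel]
  }
  if (length(unique(genotype)) < 2)
    stopf("ANOVA needs at least two genotype groups with >= 2 values")
  g <- factor(genotype)
  fit <- stats::aov(values ~ g)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$g
  tukey <- data.frame(contrast = rownames(tk), diff = tk[, "diff"],
                      lwr = tk[, "lwr"], upr = tk[, "upr"],
                      p_adj = tk[, "p adj"], row.names = NULL,
                      stringsAsFactors = FALSE)
  list(f = an[["F value"]][1], df = c(an[["Df"]][1], an[["Df"]][2]),
       p = an[["Pr(>F)"]][1], tukey = tukey)
}
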