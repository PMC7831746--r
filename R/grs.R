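# Unweighted additive genetic risk score (0-100 scale), ROC analysis and
# Youden-index cutoff selection.

#' Total sarcopenia genetic risk score from genotype scores
#'
#' Each risk-oriented genotype contributes 0, 1 or 2 (copies of the risk
#' allele); the raw sum over K SNPs is rescaled to percent by `100 / (2K)`,
#' so for the study's three-SNP score the formula is
#' `SGS = 100/6 x (score_MTHFR + score_ACTN3 + score_NRF2)`: 100 is the
#' fully risk-homozygous profile, 0 carries no risk allele.
#'
#' @param scores integer matrix (samples x SNPs) or vector (one sample) of
#'   0/1/2 genotype scores.
#' @param missing `"strict"` (default): samples with any missing score are
#'   excluded and reported; `"mean"`: a missing cell is imputed with that
#'   SNP's mean observed score (the raw score is then non-integer).
#' @return list of class `grs_result`: `raw` (0..2K), `scaled` (percent),
#'   `n_snps` (K), `excluded` (sample indices dropped for missing scores,
#'   with reasons).
#' @examples
#' sgs(c(2, 2, 2))$scaled  # 100
#' sgs(c(2, 1, 0))$scaled  # 50
#' @export
sgs <- function(scores, missing = c("strict", "mean")) {
  missing <- match.arg(missing)
  m <- if (is.matrix(scores)) scores else matrix(scores, nrow = 1)
  if (!all(m %in% c(0L, 1L, 2L) | is.na(m)))
    stopf("genotype scores must be 0, 1 or 2")
  k <- ncol(m)
  if (k < 1) stopf("need at least one SNP")
  if (missing == "mean" && anyNA(m)) {
    for (j in seq_len(k)) {
      nas <- is.na(m[, j])
      if (any(nas)) m[nas, j] <- mean(m[!nas, j])
    }
  }
  complete <- rowSums(is.na(m)) == 0
  raw <- rep(NA_real_, nrow(m))
  raw[complete] <- rowSums(m[complete, , drop = FALSE])
  excluded <- which(!complete)
  structure(list(raw = raw, scaled = 100 / (2 * k) * raw, n_snps = k,
                 excluded = excluded,
                 excluded_reason = if (length(excluded))
                   rep("missing genotype score", length(excluded))
                 else character(0)),
            class = "grs_result")
}

#' Genetic risk score for every cohort sample
#'
#' @param cohort a cohort data frame.
#' @param panel a [snp_panel()]; the `snps` used must have risk alleles set.
#' @param snps SNPs entering the score (default: panel SNPs with a
#'   determined risk allele).
#' @param missing missingness handling, see [sgs()].
#' @return data frame `sample_id`, `raw`, `scaled` (NA rows = excluded for
#'   missing genotypes), with the `grs_result` in attribute `"grs"`.
#' @export
sgs_cohort <- function(cohort, panel,
                       snps = panel$snp_id[!is.na(panel$risk_allele)],
                       missing = c("strict", "mean")) {
  if (!length(snps)) stopf("no SNPs with a determined risk allele")
  m <- dosage_matrix(cohort, panel, snps)
  g <- sgs(m, missing = missing)
  out <- data.frame(sample_id = cohort$sample_id, raw = g$raw,
                    scaled = g$scaled, stringsAsFactors = FALSE)
  attr(out, "grs") <- g
  out
}

#' ROC curve for a score against case status
#'
#' Candidate thresholds are the midpoints between consecutive distinct
#' observed scores plus two sentinels (below the minimum and above the
#' maximum); a sample is called positive when `score >= threshold`.
#'
#' @param scores numeric score per sample (higher = more case-like).
#' @param labels logical / 0-1 vector, `TRUE` = case.
#' @return data frame of class `roc_points` with columns `threshold`,
#'   `sensitivity`, `specificity`, `fpr`, ordered by increasing threshold
#'   (so from ROC corner (1,1) down to (0,0)).
#' @export
roc_curve <- function(scores, labels) {
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]
  labels <- as.logical(labels[keep])
  if (!any(labels) || all(labels))
    stopf("ROC needs both cases and controls")
  s <- sort(unique(scores))
  thr <- c(s[1] - 1, if (length(s) > 1) (s[-1] + s[-length(s)]) / 2,
           s[length(s)] + 1)
  sens <- vapply(thr, function(t) mean(scores[labels] >= t), 0)
  fpr <- vapply(thr, function(t) mean(scores[!labels] >= t), 0)
  structure(data.frame(threshold = thr, sensitivity = sens,
                       specificity = 1 - fpr, fpr = fpr),
            class = c("roc_points", "data.frame"))
}

#' Area under the ROC curve with Hanley-McNeil confidence interval
#'
#' AUC by the rank (Mann-Whitney) formulation with ties counted 1/2; the
#' 95% CI uses the Hanley-McNeil normal approximation
#' (`Q1 = A/(2-A)`, `Q2 = 2A^2/(1+A)`), truncated to `[0, 1]`.
#'
#' @inheritParams roc_curve
#' @return list of class `auc_result`: `auc`, `ci_low`, `ci_high`, `se`,
#'   `n_cases`, `n_controls`, `method`.
#' @export
roc_auc <- function(scores, labels) {
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]
  labels <- as.logical(labels[keep])
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stopf("AUC needs both cases and controls")
  r <- rank(scores)
  a <- (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  q1 <- a / (2 - a)
  q2 <- 2 * a^2 / (1 + a)
  se <- sqrt((a * (1 - a) + (n1 - 1) * (q1 - a^2) +
                (n0 - 1) * (q2 - a^2)) / (n1 * n0))
  structure(list(auc = a, ci_low = max(0, a - Z975 * se),
                 ci_high = min(1, a + Z975 * se), se = se,
                 n_cases = n1, n_controls = n0,
                 method = "Mann-Whitney AUC, Hanley-McNeil CI"),
            class = "auc_result")
}

#' @export
print.auc_result <- function(x, ...) {
  cat(sprintf("AUC = %.3f (95%% CI %.3f-%.3f); %d cases / %d controls\n",
              x$auc, x$ci_low, x$ci_high, x$n_cases, x$n_controls))
  invisible(x)
}

#' Youden-index optimal cutoff
#'
#' Picks the threshold maximizing `J = sensitivity + specificity - 1`.
#' Ties are broken toward higher sensitivity, then toward the lower
#' threshold (a screening-oriented convention).
#'
#' @param roc a [roc_curve()] result.
#' @return list of class `cutoff_result`: `threshold`, `youden_j`,
#'   `sensitivity`, `specificity`.
#' @export
youden_cutoff <- function(roc) {
  stopifnot(inherits(roc, "roc_points"))
  j <- roc$sensitivity + roc$specificity - 1
  ord <- order(-j, -roc$sensitivity, roc$threshold)
  best <- ord[1]
  structure(list(threshold = roc$threshold[best], youden_j = j[best],
                 sensitivity = roc$sensitivity[best],
                 specificity = roc$specificity[best]),
            class = "cutoff_result")
}

#' @export
print.cutoff_result <- function(x, ...) {
  cat(sprintf("Youden cutoff: score >= %.4g (J = %.3f; sens %.3f, spec %.3f)\n",
              x$threshold, x$youden_j, x$sensitivity, x$specificity))
  invisible(x)
}

#' @export
plot.roc_points <- function(x, ...) {
  graphics::plot(x$fpr, x$sensitivity, type = "s",
                 xlab = "False positive rate", ylab = "Sensitivity",
                 xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 3, col = "grey50")
  invisible(x)
}

#' Orient panel risk alleles from case-control data
#'
#' For each requested SNP, labels as the risk allele the allele enriched in
#' cases (allelic odds ratio above 1 for that allele). An allelic OR of
#' exactly 1 leaves the orientation undetermined and raises an error asking
#' for manual orientation.
#'
#' @param cohort a classified cohort data frame (status filled in).
#' @param panel a [snp_panel()].
#' @param snps SNPs to orient (default: panel SNPs without a risk allele).
#' @return the panel with `risk_allele` set for `snps`; the allelic OR used
#'   per SNP is recorded in attribute `"orientation_or"`.
#' @export
orient_risk_alleles <- function(cohort, panel,
                                snps = panel$snp_id[is.na(panel$risk_allele)]) {
  ors <- numeric(0)
  for (s in snps) {
    i <- match(s, panel$snp_id)
    # tally with respect to allele2 (the conventional alternate allele)
    tmp <- panel
    tmp$risk_allele[i] <- tmp$allele2[i]
    gc <- genotype_counts(cohort, s, tmp, by_status = TRUE)
    tab <- allele_table(gc$sarcopenic, gc$non_sarcopenic)
    or <- (tab[1] * tab[4]) / (tab[2] * tab[3])
    if (or == 1)
      stopf("SNP %s: allelic OR exactly 1; orient the risk allele manually", s)
    panel$risk_allele[i] <- if (or > 1) panel$allele2[i] else panel$allele1[i]
    ors[s] <- if (or > 1) or else 1 / or
  }
  attr(panel, "orientation_or") <- ors
  panel
}
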