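test_that("genetic risk score scales genotype sums to percent", {
  expect_equal(sgs(c(2, 2, 2))$scaled, 100)
  expect_equal(sgs(c(0, 0, 0))$scaled, 0)
  expect_equal(sgs(c(2, 1, 0))$scaled, 50)
  # scores live on the 100/(2K) lattice
  m <- as.matrix(expand.grid(0:2, 0:2, 0:2))
  g <- sgs(m)
  expect_true(all(g$scaled %in% (100 / 6 * 0:6)))
  expect_equal(g$scaled, 100 / 6 * g$raw)
  # strict missingness: the sample is excluded with a reason
  g2 <- sgs(rbind(c(2, 1, 0), c(2, NA, 0)))
  expect_equal(g2$excluded, 2L)
  expect_true(is.na(g2$scaled[2]))
  expect_match(g2$excluded_reason, "missing")
  # optional mean imputation keeps the sample, using the SNP's mean score
  g3 <- sgs(rbind(c(2, 1, 0), c(2, NA, 0)), missing = "mean")
  expect_equal(g3$raw[2], 3)
  expect_length(g3$excluded, 0)
})

test_that("ROC thresholds sit midway between distinct scores", {
  scores <- c(50, 50, 200 / 3, 200 / 3)
  labels <- c(FALSE, FALSE, TRUE, TRUE)
  roc <- roc_curve(scores, labels)
  expect_true(any(abs(roc$threshold - 58 - 1 / 3) < 1e-9))
  # endpoints of ROC space always present
  expect_true(any(roc$sensitivity == 1 & roc$fpr == 1))
  expect_true(any(roc$sensitivity == 0 & roc$fpr == 0))
  # monotone: raising the threshold can only lower sens and fpr
  expect_true(all(diff(roc$sensitivity) <= 0))
  expect_true(all(diff(roc$fpr) <= 0))

  # perfectly separated classes pass through (fpr 0, sens 1)
  roc2 <- roc_curve(c(1, 2, 8, 9), c(FALSE, FALSE, TRUE, TRUE))
  expect_true(any(roc2$fpr == 0 & roc2$sensitivity == 1))
  # degenerate scores leave only the two corner points
  roc3 <- roc_curve(rep(5, 6), c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE))
  expect_equal(nrow(roc3), 2)
  expect_error(roc_curve(1:4, rep(TRUE, 4)), "both")
})

test_that("rank AUC equals trapezoidal ROC integration and reference AUC", {
  set.seed(41)
  for (i in 1:10) {
    n <- 60
    labels <- rbinom(n, 1, 0.4) == 1
    if (!any(labels) || all(labels)) next
    scores <- round(rnorm(n, mean = labels), 1)  # induces ties
    a <- roc_auc(scores, labels)
    expect_equal(a$auc, auc_trapezoid_oracle(roc_curve(scores, labels)),
                 tolerance = 1e-9)
    # AUC invariant under strictly monotone transforms of the score
    expect_equal(roc_auc(exp(scores / 10), labels)$auc, a$auc,
                 tolerance = 1e-12)
  }
  if (requireNamespace("pROC", quietly = TRUE)) {
    set.seed(42)
    labels <- rbinom(80, 1, 0.35) == 1
    scores <- rnorm(80, mean = labels)
    ours <- roc_auc(scores, labels)
    ref <- pROC::roc(labels, scores, quiet = TRUE, direction = "<")
    expect_equal(ours$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-9)
  }
  expect_equal(roc_auc(c(100, 83.3, 50, 33.3),
                       c(TRUE, TRUE, FALSE, FALSE))$auc, 1)
  set.seed(43)
  shuffled <- roc_auc(rnorm(4000), rbinom(4000, 1, 0.5) == 1)
  expect_equal(shuffled$auc, 0.5, tolerance = 0.05)
})

test_that("Youden cutoff equals exhaustive search and is duplication-invariant", {
  set.seed(44)
  for (i in 1:10) {
    labels <- rbinom(40, 1, 0.4) == 1
    if (!any(labels) || all(labels)) next
    scores <- sample(seq(0, 100, by = 100 / 6), 40, replace = TRUE)
    roc <- roc_curve(scores, labels)
    cut <- youden_cutoff(roc)
    oracle <- youden_oracle(scores, labels, roc$threshold)
    expect_equal(cut$threshold, oracle$t)
    expect_equal(cut$youden_j, oracle$j, tolerance = 1e-12)
    # duplicating every sample changes nothing
    cut2 <- youden_cutoff(roc_curve(rep(scores, 2), rep(labels, 2)))
    expect_equal(cut2$threshold, cut$threshold)
  }
  # perfect separation: J = 1 at the midpoint between the class ranges
  cutp <- youden_cutoff(roc_curve(c(1, 2, 8, 9), c(FALSE, FALSE, TRUE, TRUE)))
  expect_equal(cutp$youden_j, 1)
  expect_equal(cutp$threshold, 5)
  cut0 <- youden_cutoff(roc_curve(rep(5, 4), c(TRUE, FALSE, TRUE, FALSE)))
  expect_equal(cut0$youden_j, 0)
})

test_that("risk alleles orient toward the case-enriched allele", {
  panel <- two_snp_panel()
  panel$risk_allele <- NA_character_
  # MTHFR-style counts: C enriched in cases; NRF2-style: C enriched too
  co <- cohort_from_counts(two_snp_panel(),
                           list(c(10, 31, 4), c(13, 32, 0)),
                           list(c(12, 58, 75), c(30, 81, 34)))
  oriented <- orient_risk_alleles(co, panel)
  expect_equal(oriented$risk_allele, c("C", "C"))
  expect_true(all(attr(oriented, "orientation_or") > 1))

  # exact balance cannot be oriented
  bal <- cohort_from_counts(two_snp_panel()[1, ],
                            list(c(5, 10, 5)), list(c(10, 20, 10)))
  expect_error(orient_risk_alleles(bal, panel[1, ]), "manually")
})

test_that("simulated risk-allele effects raise the mean case score", {
  spec <- study_default_spec()
  spec$n_cases <- 250
  spec$n_controls <- 750
  sim <- simulate_cohort(spec, seed = 10, method = "conditional")
  scores <- sgs_cohort(sim$cohort, study_panel())
  case <- sim$cohort$status == "sarcopenic"
  expect_gt(mean(scores$scaled[case], na.rm = TRUE),
            mean(scores$scaled[!case], na.rm = TRUE))
})
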