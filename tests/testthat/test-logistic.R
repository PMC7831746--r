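# expand a 2x2 table into per-sample predictor/outcome vectors
expand_2x2 <- function(tab) {
  x <- as.numeric(tab)
  list(pred = rep(c(1, 0, 1, 0), x), y = rep(c(1, 1, 0, 0), x))
}

test_that("saturated logistic fit reproduces the cross-product odds ratio", {
  d <- expand_2x2(table2x2(54, 36, 123, 167))
  fit <- fit_logistic(matrix(d$pred, ncol = 1, dimnames = list(NULL, "x")),
                      d$y)
  expect_true(fit$converged)
  expect_equal(unname(fit$or["x"]), (54 * 167) / (36 * 123),
               tolerance = 1e-6)
})

test_that("IRLS agrees with the reference GLM fitter", {
  set.seed(21)
  n <- 400
  x1 <- rnorm(n); x2 <- rbinom(n, 1, 0.4)
  y <- rbinom(n, 1, plogis(-0.5 + 0.8 * x1 - 0.6 * x2))
  X <- cbind(x1 = x1, x2 = x2)
  fit <- fit_logistic(X, y)
  ref <- glm(y ~ x1 + x2, family = binomial())
  expect_equal(unname(fit$coefficients), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(unname(fit$se),
               unname(summary(ref)$coefficients[, "Std. Error"]),
               tolerance = 1e-6)
  expect_equal(fit$log_lik, as.numeric(logLik(ref)), tolerance = 1e-6)
  expect_equal(fit$null_deviance, ref$null.deviance, tolerance = 1e-6)
})

test_that("deviance is non-increasing across IRLS iterations", {
  set.seed(22)
  for (i in 1:5) {
    n <- 120
    x <- cbind(a = rnorm(n), b = rbinom(n, 2, 0.3))
    y <- rbinom(n, 1, plogis(0.2 + 0.5 * x[, "a"] - 0.4 * x[, "b"]))
    fit <- fit_logistic(x, y)
    expect_true(all(diff(fit$deviance_path) <= 1e-8))
  }
})

test_that("degenerate designs are detected", {
  y <- rep(c(1, 0), each = 20)
  x_sep <- matrix(rep(c(1, 0), each = 20), ncol = 1,
                  dimnames = list(NULL, "x"))
  expect_error(fit_logistic(x_sep, y), "separation.*x")
  x_coll <- cbind(a = rnorm(40))
  x_coll <- cbind(x_coll, b = 2 * x_coll[, "a"])
  expect_error(fit_logistic(x_coll, y), "collinear")
  # balanced independent predictor: beta exactly 0, OR exactly 1
  fit <- fit_logistic(matrix(c(0, 1, 0, 1), ncol = 1,
                             dimnames = list(NULL, "x")),
                      c(0, 0, 1, 1))
  expect_equal(unname(fit$or["x"]), 1, tolerance = 1e-9)
})

test_that("Nagelkerke R2 matches longhand Bernoulli likelihoods", {
  # intercept-only model explains nothing
  f0 <- fit_logistic(matrix(numeric(0), nrow = 6, ncol = 0),
                     c(1, 0, 1, 0, 1, 0))
  expect_equal(nagelkerke(f0), 0, tolerance = 1e-9)

  # 6-observation worked fixture (mixed outcomes at both extreme dosages so
  # the MLE is finite), likelihoods evaluated directly
  x <- matrix(c(0, 0, 1, 1, 2, 2), ncol = 1, dimnames = list(NULL, "g"))
  y <- c(1, 0, 0, 1, 0, 1)
  fit <- fit_logistic(x, y)
  mu <- plogis(fit$coefficients[1] + fit$coefficients[2] * x[, 1])
  ll1 <- sum(y * log(mu) + (1 - y) * log(1 - mu))
  ll0 <- 6 * (0.5 * log(0.5) + 0.5 * log(0.5))
  r2_cs <- 1 - exp((2 / 6) * (ll0 - ll1))
  expect_equal(nagelkerke(fit), r2_cs / (1 - exp((2 / 6) * ll0)),
               tolerance = 1e-9)
  expect_gte(nagelkerke(fit), 0)
  expect_lte(nagelkerke(fit), 1)

  # near-perfect in-sample prediction pushes R2 toward 1
  set.seed(30)
  n <- 200
  xx <- rnorm(n)
  yy <- rbinom(n, 1, plogis(8 * xx))
  fitp <- fit_logistic(matrix(xx, ncol = 1, dimnames = list(NULL, "x")), yy)
  expect_gt(nagelkerke(fitp), 0.8)
})

test_that("cohort model ORs equal the contingency-table ORs exactly", {
  panel <- two_snp_panel()[1, ]
  co <- cohort_from_counts(panel, list(c(10, 20, 15)), list(c(8, 40, 52)))
  counts <- genotype_counts(co, "rs1801131", panel, by_status = TRUE)
  for (m in c("dominant", "recessive")) {
    tab_or <- odds_ratio_woolf(
      model_table(counts$sarcopenic, counts$non_sarcopenic, m))$or
    fit <- fit_model(co, panel, "rs1801131", m)
    expect_equal(unname(fit$or["rs1801131"]), tab_or, tolerance = 1e-6)
  }
})

test_that("an independent noise covariate barely moves the genetic OR", {
  spec <- sim_spec(2000, 2000, 0.25,
                   data.frame(snp_id = "rs1801131", gene = "MTHFR",
                              alleles = "A/C", risk_allele = "C",
                              freq = 0.35, grr_het = 1.6, grr_hom = 2.56,
                              stringsAsFactors = FALSE),
                   missing_rate = 0, error_rate = 0)
  sim <- simulate_cohort(spec, seed = 99, method = "conditional")
  panel <- two_snp_panel()[1, ]
  plain <- fit_model(sim$cohort, panel, "rs1801131", "dominant")
  adj <- fit_model(sim$cohort, panel, "rs1801131", "dominant",
                   covariates = "physical_activity")
  expect_lt(abs(adj$or["rs1801131"] / plain$or["rs1801131"] - 1), 0.05)
})

test_that("a null continuous risk score yields OR near 1 per unit", {
  set.seed(17)
  n <- 3000
  scores <- sample(seq(0, 100, by = 100 / 6), n, replace = TRUE)
  y <- rbinom(n, 1, 0.25)
  fit <- fit_logistic(matrix(scores, ncol = 1,
                             dimnames = list(NULL, "sgs")), y)
  expect_equal(unname(fit$or["sgs"]), 1, tolerance = 0.01)
})
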