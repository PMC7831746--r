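# Binary logistic regression by iteratively reweighted least squares,
# with Wald odds ratios and Nagelkerke pseudo-R2.

#' Fit a binary logistic regression by IRLS
#'
#' Maximum-likelihood logistic regression fitted by iteratively reweighted
#' least squares, starting from beta = 0 and iterating until the largest
#' coefficient change is below `tolerance` or the deviance change is below
#' `1e-10`. Wald statistics (`z = beta/SE`), odds ratios `exp(beta)` and
#' 95% Wald intervals are reported per term.
#'
#' @param x numeric design matrix (an intercept column is added unless one
#'   is already present as a constant column named `(Intercept)`).
#' @param y binary outcome vector (0/1 or logical).
#' @param tolerance convergence threshold on `max |delta beta|`
#'   (default 1e-8).
#' @param max_iterations IRLS iteration cap (default 50).
#' @return object of class `logit_fit`: `coefficients`, `se`, `z`, `p`,
#'   `or`, `ci_low`, `ci_high` (per term), `log_lik`, `null_log_lik`,
#'   `deviance`, `null_deviance`, `deviance_path`, `nagelkerke_r2`,
#'   `cox_snell_r2`, `n_used`, `n_iterations`, `converged`.
#' @details Complete cases only: rows with any missing value in `x` or `y`
#'   are dropped and counted in `n_dropped`. Quasi-complete separation is
#'   detected as a coefficient exceeding 15 in absolute value while still
#'   growing, and raises an error naming the term; exactly collinear columns
#'   are an error.
#' @export
fit_logistic <- function(x, y, tolerance = 1e-8, max_iterations = 50L) {
  x <- as.matrix(x)
  if (is.logical(y)) y <- as.integer(y)
  if (!all(y %in% c(0, 1) | is.na(y)))
    stopf("outcome must be binary (0/1)")
  keep <- if (ncol(x) > 0) stats::complete.cases(x) & !is.na(y) else !is.na(y)
  n_dropped <- sum(!keep)
  x <- x[keep, , drop = FALSE]
  y <- y[keep]
  n <- length(y)
  if (n < 2 || length(unique(y)) < 2)
    stopf("need both outcome classes among complete cases")

  if (!"(Intercept)" %in% colnames(x))
    x <- cbind(`(Intercept)` = 1, x)
  p <- ncol(x)
  if (qr(x)$rank < p)
    stopf("design matrix has collinear columns")

  beta <- rep(0, p)
  dev_path <- numeric(0)
  dev_old <- Inf
  converged <- FALSE
  it <- 0L
  max_db <- Inf
  while (it < max_iterations) {
    it <- it + 1L
    eta <- drop(x %*% beta)
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    w <- pmax(w, 1e-10)
    z <- eta + (y - mu) / w
    fit <- stats::lm.wfit(x, z, w)
    beta_new <- fit$coefficients
    max_db <- max(abs(beta_new - beta))
    beta <- beta_new
    mu <- stats::plogis(drop(x %*% beta))
    mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
    dev <- -2 * sum(y * log(mu) + (1 - y) * log(1 - mu))
    dev_path <- c(dev_path, dev)
    growing <- max(abs(beta)) > 15 && max_db > tolerance
    if (growing) {
      worst <- colnames(x)[which.max(abs(beta))]
      stopf("separation detected: coefficient for '%s' diverging", worst)
    }
    if (max_db < tolerance || abs(dev_old - dev) < 1e-10) {
      converged <- TRUE
      break
    }
    dev_old <- dev
  }

  mu <- stats::plogis(drop(x %*% beta))
  w <- pmax(mu * (1 - mu), 1e-10)
  xtwx <- crossprod(x * sqrt(w))
  vcov <- solve(xtwx)
  se <- sqrt(diag(vcov))
  zstat <- beta / se
  pval <- 2 * stats::pnorm(-abs(zstat))

  mu_c <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
  ll <- sum(y * log(mu_c) + (1 - y) * log(1 - mu_c))
  p0 <- mean(y)
  ll0 <- n * (p0 * log(p0) + (1 - p0) * log(1 - p0))
  r2_cs <- 1 - exp((2 / n) * (ll0 - ll))
  r2_max <- 1 - exp((2 / n) * ll0)
  r2_n <- r2_cs / r2_max

  structure(list(coefficients = beta, se = se, z = zstat, p = pval,
                 or = exp(beta),
                 ci_low = exp(beta - Z975 * se),
                 ci_high = exp(beta + Z975 * se),
                 vcov = vcov,
                 log_lik = ll, null_log_lik = ll0,
                 deviance = -2 * ll, null_deviance = -2 * ll0,
                 deviance_path = dev_path,
                 nagelkerke_r2 = r2_n, cox_snell_r2 = r2_cs,
                 fitted = mu, n_used = n, n_dropped = n_dropped,
                 n_iterations = it, converged = converged,
                 terms = colnames(x)),
            class = "logit_fit")
}

#' Nagelkerke pseudo-R2 of a logistic fit
#'
#' Cox-Snell \eqn{R^2_{CS} = 1 - \exp((2/n)(LL_0 - LL_1))} rescaled to the
#' unit interval by its attainable maximum:
#' \eqn{R^2_N = R^2_{CS} / (1 - \exp((2/n) LL_0))}.
#'
#' @param fit a [fit_logistic()] result.
#' @return numeric in `[0, 1]`.
#' @export
nagelkerke <- function(fit) {
  stopifnot(inherits(fit, "logit_fit"))
  if (fit$n_used == 0) stopf("empty fit")
  fit$nagelkerke_r2
}

#' @export
print.logit_fit <- function(x, ...) {
  cat(sprintf("Logistic regression (IRLS, %d iterations%s), n = %d (%d dropped)\n",
              x$n_iterations, if (x$converged) "" else ", NOT converged",
              x$n_used, x$n_dropped))
  tab <- data.frame(beta = x$coefficients, se = x$se,
                    OR = x$or, ci_low = x$ci_low, ci_high = x$ci_high,
                    z = x$z, p = format_pvalue(x$p), row.names = x$terms)
  print(round_df(tab, 4))
  cat(sprintf("Nagelkerke R2 = %.4f (Cox-Snell %.4f); deviance %.3f (null %.3f)\n",
              x$nagelkerke_r2, x$cox_snell_r2, x$deviance, x$null_deviance))
  invisible(x)
}

round_df <- function(df, digits) {
  for (i in seq_along(df)) if (is.numeric(df[[i]])) df[[i]] <- round(df[[i]], digits)
  df
}

#' @export
coef.logit_fit <- function(object, ...) object$coefficients

#' @export
summary.logit_fit <- function(object, ...) object

#' Fit an unadjusted or covariate-adjusted genetic model on a cohort
#'
#' Builds the genetic predictor for one SNP under the requested coding —
#' dominant (carrier indicator), recessive (risk-homozygote indicator),
#' additive (0/1/2 dosage) or a continuous genetic risk score on the 0-100
#' scale — optionally adds covariates (age in years, sex indicator with
#' male = 1, physical activity as-is), and fits [fit_logistic()] on the
#' complete cases with outcome `status == "sarcopenic"`.
#'
#' @param cohort classified cohort data frame.
#' @param panel a [snp_panel()] with the SNP's risk allele set.
#' @param snp_id SNP to model; ignored for `coding = "grs_continuous"`.
#' @param coding `"dominant"`, `"recessive"`, `"additive"` or
#'   `"grs_continuous"`.
#' @param covariates character subset of
#'   `c("age", "sex", "physical_activity")`.
#' @param grs_snps SNPs entering the risk score for `"grs_continuous"`
#'   (default: the panel SNPs with a determined risk allele).
#' @return a `logit_fit`; the genetic term is named after the SNP (or
#'   `"sgs"`).
#' @export
fit_model <- function(cohort, panel, snp_id = NULL,
                      coding = c("dominant", "recessive", "additive",
                                 "grs_continuous"),
                      covariates = character(),
                      grs_snps = NULL) {
  coding <- match.arg(coding)
  ok_cov <- c("age", "sex", "physical_activity")
  if (anyDuplicated(covariates) || !all(covariates %in% ok_cov))
    stopf("covariates must be a subset of %s without duplicates",
          paste(ok_cov, collapse = ", "))
  use <- cohort$status %in% c("sarcopenic", "non_sarcopenic")
  dat <- as.data.frame(cohort)[use, , drop = FALSE]
  y <- as.integer(dat$status == "sarcopenic")

  if (coding == "grs_continuous") {
    if (is.null(grs_snps))
      grs_snps <- panel$snp_id[!is.na(panel$risk_allele)]
    g <- sgs_cohort(dat, panel, snps = grs_snps)$scaled
    gname <- "sgs"
  } else {
    if (is.null(snp_id)) stopf("snp_id required for coding '%s'", coding)
    e <- panel_entry(panel, snp_id)
    d <- genotype_dosage(dat[[snp_id]], e$risk_allele)
    g <- switch(coding,
                dominant = as.numeric(d >= 1),
                recessive = as.numeric(d == 2),
                additive = as.numeric(d))
    gname <- snp_id
  }

  X <- matrix(g, ncol = 1, dimnames = list(NULL, gname))
  for (cv in covariates) {
    col <- switch(cv,
                  age = dat$age,
                  sex = as.numeric(dat$sex == "male"),
                  physical_activity = dat$physical_activity)
    X <- cbind(X, col)
    colnames(X)[ncol(X)] <- cv
  }
  if (sum(stats::complete.cases(X) & !is.na(y)) < 10)
    stopf("fewer than 10 usable rows for this model")
  fit <- fit_logistic(X, y)
  fit$genetic_term <- gname
  fit$coding <- coding
  fit$covariates <- covariates
  fit
}
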