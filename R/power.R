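# Case-control genetic power calculation from genotype relative risks,
# in the Genetic Power Calculator parameterization: risk-allele frequency,
# disease prevalence, heterozygote/homozygote genotype relative risks.

#' Specify a case-control genetic power calculation
#'
#' @param risk_allele_freq population risk-allele frequency `p` in (0,1).
#' @param prevalence disease prevalence `K` in (0,1).
#' @param grr_het genotype relative risk of heterozygotes vs baseline
#'   homozygotes.
#' @param grr_hom genotype relative risk of risk homozygotes.
#' @param n_cases,n_controls group sample sizes.
#' @param alpha type-I error rate (default 0.05).
#' @param test `"allelic_1df"` (default) or `"genotypic_2df"`.
#' @param variance `"unpooled"` (default) or `"pooled"` variance in the
#'   allelic non-centrality.
#' @return validated list of class `power_spec`.
#' @export
power_spec <- function(risk_allele_freq, prevalence, grr_het, grr_hom,
                       n_cases, n_controls, alpha = 0.05,
                       test = c("allelic_1df", "genotypic_2df"),
                       variance = c("unpooled", "pooled")) {
  test <- match.arg(test)
  variance <- match.arg(variance)
  if (risk_allele_freq <= 0 || risk_allele_freq >= 1)
    stopf("risk_allele_freq must be in (0,1)")
  if (prevalence <= 0 || prevalence >= 1)
    stopf("prevalence must be in (0,1)")
  if (grr_het < 0 || grr_hom < 0) stopf("genotype relative risks must be >= 0")
  if (alpha <= 0 || alpha >= 1) stopf("alpha must be in (0,1)")
  if (n_cases < 1 || n_controls < 1) stopf("group sizes must be >= 1")
  spec <- structure(list(risk_allele_freq = risk_allele_freq,
                         prevalence = prevalence, grr_het = grr_het,
                         grr_hom = grr_hom, n_cases = as.integer(n_cases),
                         n_controls = as.integer(n_controls), alpha = alpha,
                         test = test, variance = variance),
                    class = "power_spec")
  f <- penetrances(spec)
  if (any(f > 1))
    stopf("spec invalid: implied penetrance exceeds 1 (f2 = %.4f)", f[3])
  spec
}

#' Penetrances implied by GRRs and prevalence
#'
#' Solves the baseline penetrance from the population prevalence under HWE:
#' \deqn{f_0 = K / (q^2 + 2pq g_1 + p^2 g_2), \quad f_1 = g_1 f_0, \quad
#'   f_2 = g_2 f_0.}
#'
#' @param spec a [power_spec()].
#' @return numeric triple `c(f0, f1, f2)` (baseline, het, hom penetrance).
#' @export
penetrances <- function(spec) {
  p <- spec$risk_allele_freq; q <- 1 - p
  f0 <- spec$prevalence / (q^2 + 2 * p * q * spec$grr_het +
                             p^2 * spec$grr_hom)
  c(f0 = f0, f1 = spec$grr_het * f0, f2 = spec$grr_hom * f0)
}

#' Expected case/control genotype and allele frequencies
#'
#' Bayes inversion of the penetrance model: `P(g|case) = f_g P(g) / K`,
#' `P(g|control) = (1-f_g) P(g) / (1-K)`, with `P(g)` the HWE genotype
#' frequencies; allele frequencies follow by allele counting.
#'
#' @param spec a [power_spec()].
#' @return list: `penetrance` (f0,f1,f2), `case_geno` / `control_geno`
#'   (hom_risk, het, hom_other triples summing to 1), `case_allele_freq`,
#'   `control_allele_freq` (risk allele).
#' @export
group_frequencies <- function(spec) {
  p <- spec$risk_allele_freq; q <- 1 - p
  f <- penetrances(spec)
  pg <- c(hom_risk = p^2, het = 2 * p * q, hom_other = q^2)
  fg <- c(f[["f2"]], f[["f1"]], f[["f0"]])
  k <- sum(fg * pg)  # equals spec$prevalence by construction
  case_g <- fg * pg / k
  ctrl_g <- (1 - fg) * pg / (1 - k)
  list(penetrance = f,
       case_geno = case_g, control_geno = ctrl_g,
       case_allele_freq = unname(case_g[1] + case_g[2] / 2),
       control_allele_freq = unname(ctrl_g[1] + ctrl_g[2] / 2))
}

#' Analytic power of the case-control association test
#'
#' Computes the non-centrality parameter of the chi-square association test
#' at the alternative defined by the spec and evaluates the power as the
#' non-central upper tail beyond the central critical value.
#'
#' For the 1-df allelic test (alleles treated as independent, `2N` per
#' group) the default unpooled-variance non-centrality is
#' \deqn{\lambda = (p_A - p_U)^2 / \left(\frac{p_A q_A}{2N_A} +
#'   \frac{p_U q_U}{2N_U}\right)}
#' with a pooled-variance variant selectable in the spec. For the 2-df
#' genotypic test, \eqn{\lambda} is the Pearson discrepancy of the expected
#' 2x3 genotype table from its pooled null expectation.
#'
#' @param spec a [power_spec()].
#' @return list of class `power_result`: `spec`, `penetrance`, group
#'   frequency triples and allele frequencies, `ncp`, `df`, `critical`,
#'   `power`.
#' @export
gpc_power <- function(spec) {
  gf <- group_frequencies(spec)
  na <- spec$n_cases; nu <- spec$n_controls
  pa <- gf$case_allele_freq; pu <- gf$control_allele_freq
  if (spec$test == "allelic_1df") {
    df <- 1
    if (spec$variance == "unpooled") {
      v <- pa * (1 - pa) / (2 * na) + pu * (1 - pu) / (2 * nu)
    } else {
      pbar <- (2 * na * pa + 2 * nu * pu) / (2 * na + 2 * nu)
      v <- pbar * (1 - pbar) * (1 / (2 * na) + 1 / (2 * nu))
    }
    ncp <- (pa - pu)^2 / v
  } else {
    df <- 2
    pbar <- (na * gf$case_geno + nu * gf$control_geno) / (na + nu)
    ncp <- sum(na * (gf$case_geno - pbar)^2 / pbar) +
      sum(nu * (gf$control_geno - pbar)^2 / pbar)
  }
  crit <- stats::qchisq(1 - spec$alpha, df)
  pow <- stats::pchisq(crit, df, ncp = ncp, lower.tail = FALSE)
  structure(list(spec = spec, penetrance = gf$penetrance,
                 case_geno = gf$case_geno, control_geno = gf$control_geno,
                 case_allele_freq = pa, control_allele_freq = pu,
                 ncp = ncp, df = df, critical = crit, power = pow),
            class = "power_result")
}

#' @export
print.power_result <- function(x, ...) {
  s <- x$spec
  cat(sprintf("Genetic power calculation (%s, %s variance)\n", s$test,
              s$variance))
  cat(sprintf("  p = %.3f, K = %.3f, GRR het/hom = %.2f/%.2f, N = %d/%d, alpha = %.3f\n",
              s$risk_allele_freq, s$prevalence, s$grr_het, s$grr_hom,
              s$n_cases, s$n_controls, s$alpha))
  cat(sprintf("  penetrances f0/f1/f2 = %.6f / %.6f / %.6f\n",
              x$penetrance[1], x$penetrance[2], x$penetrance[3]))
  cat(sprintf("  risk-allele freq cases %.6f, controls %.6f\n",
              x$case_allele_freq, x$control_allele_freq))
  cat(sprintf("  ncp = %.4f (df %d), power = %.4f\n", x$ncp, x$df, x$power))
  invisible(x)
}

#' Smallest case count reaching a target power
#'
#' Finds the minimal `n_cases` (controls scaled by `case_control_ratio`)
#' whose analytic power reaches `target_power`, by doubling then bisection,
#' finished with a local scan so that `power(n - 1) < target <= power(n)`.
#'
#' @param spec a [power_spec()] (its `n_cases`/`n_controls` are ignored).
#' @param target_power target in `(alpha, 1)`.
#' @param case_control_ratio controls per case (default 3, the study's
#'   design ratio).
#' @param n_max search cap on cases (default 1e7).
#' @return integer `n_cases`.
#' @export
required_n <- function(spec, target_power, case_control_ratio = 3,
                       n_max = 1e7) {
  if (target_power <= spec$alpha || target_power >= 1)
    stopf("target_power must be in (alpha, 1)")
  pow_at <- function(n) {
    s <- spec
    s$n_cases <- as.integer(n)
    s$n_controls <- as.integer(max(1, round(n * case_control_ratio)))
    gpc_power(s)$power
  }
  lo <- 1L
  if (pow_at(lo) >= target_power) return(lo)
  hi <- 2L
  while (pow_at(hi) < target_power) {
    lo <- hi
    hi <- hi * 2L
    if (hi > n_max) stopf("target power unattainable within n_max cases")
  }
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    if (pow_at(mid) >= target_power) hi <- mid else lo <- mid
  }
  hi
}
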