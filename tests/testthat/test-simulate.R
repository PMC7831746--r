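one_snp <- function(freq = 0.3, g1 = 1, g2 = 1) {
  data.frame(snp_id = "rs1801131", gene = "MTHFR", alleles = "A/C",
             risk_allele = "C", freq = freq, grr_het = g1, grr_hom = g2,
             stringsAsFactors = FALSE)
}

test_that("simulation is deterministic given the seed", {
  spec <- sim_spec(20, 60, 0.25, one_snp(0.3, 1.5, 2.25))
  a <- simulate_cohort(spec, seed = 5)
  b <- simulate_cohort(spec, seed = 5)
  expect_identical(a$cohort, b$cohort)
  fa <- withr::local_tempfile(fileext = ".csv")
  fb <- withr::local_tempfile(fileext = ".csv")
  write_cohort(a$cohort, fa)
  write_cohort(b$cohort, fb)
  expect_identical(readLines(fa), readLines(fb))
  expect_false(identical(simulate_cohort(spec, seed = 6)$cohort, a$cohort))
})

test_that("group sizes are exact and masking matches the requested rate", {
  spec <- sim_spec(400, 1200, 0.25, one_snp(), missing_rate = 0.065,
                   error_rate = 0)
  sim <- simulate_cohort(spec, seed = 8)
  expect_equal(sum(sim$cohort$status == "sarcopenic"), 400)
  expect_equal(sum(sim$cohort$status == "non_sarcopenic"), 1200)
  expect_lt(abs(mean(is.na(sim$cohort$rs1801131)) - 0.065), 0.01)
  expect_equal(sim$truth$n_masked, sum(is.na(sim$cohort$rs1801131)))
})

test_that("null SNPs show no case-control allele frequency difference", {
  spec <- sim_spec(2000, 2000, 0.25, one_snp(0.3, 1, 1))
  sim <- simulate_cohort(spec, seed = 12)
  panel <- two_snp_panel()[1, ]
  gc <- genotype_counts(sim$cohort, "rs1801131", panel, by_status = TRUE)
  freq_of <- function(u) (2 * u[1] + u[2]) / (2 * sum(u))
  diff <- abs(freq_of(gc$sarcopenic) - freq_of(gc$non_sarcopenic))
  # binomial sampling error on the difference of two frequencies
  sd2 <- sqrt(2 * 0.3 * 0.7 / 4000)
  expect_lt(diff, 2 * sd2)
})

test_that("an MTHFR-like effect SNP is recovered at the generating OR", {
  cal <- calibrate_snp(0.283, 3.3, 45 / 190)
  expect_equal(cal$achieved_control_freq, 0.283, tolerance = 1e-6)
  expect_equal(cal$achieved_or, 3.3, tolerance = 1e-6)
  spec <- sim_spec(4000, 4000, 45 / 190,
                   one_snp(cal$freq, cal$grr_het, cal$grr_hom))
  sim <- simulate_cohort(spec, seed = 31)
  panel <- two_snp_panel()[1, ]
  gc <- genotype_counts(sim$cohort, "rs1801131", panel, by_status = TRUE)
  or <- odds_ratio_woolf(allele_table(gc$sarcopenic, gc$non_sarcopenic))$or
  expect_lt(abs(or / 3.3 - 1), 0.10)
})

test_that("population and conditional samplers share one large-sample limit", {
  spec <- sim_spec(6000, 6000, 45 / 190, one_snp(0.35, 2.4, 5.8),
                   missing_rate = 0, error_rate = 0)
  pop <- simulate_cohort(spec, seed = 14, method = "population")
  cond <- simulate_cohort(spec, seed = 14, method = "conditional")
  panel <- two_snp_panel()[1, ]
  for (grp in c("sarcopenic", "non_sarcopenic")) {
    a <- genotype_counts(pop$cohort, "rs1801131", panel, TRUE)[[grp]]
    b <- genotype_counts(cond$cohort, "rs1801131", panel, TRUE)[[grp]]
    expect_equal(as.numeric(a) / sum(a), as.numeric(b) / sum(b),
                 tolerance = 0.05)
  }
  # and the analytic marginals sit between them
  igf <- implied_group_frequencies(spec)$snps
  a <- genotype_counts(pop$cohort, "rs1801131", panel, TRUE)$sarcopenic
  expect_equal(as.numeric(a) / sum(a),
               as.numeric(igf[1, c("case_hom_risk", "case_het",
                                   "case_hom_other")]),
               tolerance = 0.05)
})

test_that("implied marginals reduce to single-SNP penetrance algebra", {
  spec <- sim_spec(10, 10, 0.25, one_snp(0.3, 1.5, 2.25))
  igf <- implied_group_frequencies(spec)$snps
  gf <- group_frequencies(power_spec(0.3, 0.25, 1.5, 2.25, 10, 10))
  expect_equal(igf$case_allele_freq, gf$case_allele_freq, tolerance = 1e-9)
  expect_equal(igf$control_allele_freq, gf$control_allele_freq,
               tolerance = 1e-9)
})

test_that("the study-shaped default cohort mirrors the published structure", {
  spec <- study_default_spec()
  sim <- simulate_cohort(spec, seed = 2)
  co <- sim$cohort
  expect_equal(nrow(co), 190)
  expect_equal(sum(co$status == "sarcopenic"), 45)
  expect_equal(mean(co$age) > 70 && mean(co$age) < 87, TRUE)

  # analytic generator targets equal the published control frequencies/ORs
  igf <- implied_group_frequencies(spec)$snps
  eff <- match(c("rs1801131", "rs1815739", "rs12594956"), igf$snp_id)
  expect_equal(igf$control_allele_freq[eff], c(0.283, 0.424, 0.486),
               tolerance = 1e-6)
  expect_equal(igf$allelic_or[eff], c(3.317, 2.037, 1.915),
               tolerance = 1e-6)

  # realized control-group frequencies within binomial error of the targets
  panel <- study_panel()
  for (i in seq_along(eff)) {
    s <- igf$snp_id[eff[i]]
    gc <- genotype_counts(co, s, panel, by_status = TRUE)$non_sarcopenic
    freq <- (2 * gc[1] + gc[2]) / (2 * sum(gc))
    tgt <- c(0.283, 0.424, 0.486)[i]
    expect_lt(abs(freq - tgt), 3 * sqrt(tgt * (1 - tgt) / (2 * 145)))
  }
})

test_that("control genotypes stay in HWE across seeds", {
  spec <- study_default_spec()
  panel <- study_panel()
  ok <- 0L
  for (seed in 1:200) {
    sim <- simulate_cohort(spec, seed = seed, method = "conditional")
    controls_ok <- TRUE
    for (s in c("rs1801131", "rs1815739", "rs12594956")) {
      gc <- genotype_counts(sim$cohort, s, panel,
                            by_status = TRUE)$non_sarcopenic
      if (hwe_chisq(gc)$p < 0.01) controls_ok <- FALSE
    }
    ok <- ok + controls_ok
  }
  expect_gte(ok / 200, 0.95)
})

test_that("generator truth and estimator agree in the mean over seeds", {
  spec <- study_default_spec()
  spec$n_cases <- 450
  spec$n_controls <- 1450
  igf <- implied_group_frequencies(spec)$snps
  eff <- c("rs1801131", "rs1815739", "rs12594956")
  lors <- matrix(NA_real_, 300, 3, dimnames = list(NULL, eff))
  for (r in seq_len(300)) {
    sim <- simulate_cohort(spec, seed = 5000 + r, method = "conditional")
    for (s in eff) {
      tc <- sim$truth$genotype_counts[[s]]
      tab <- allele_table(tc$sarcopenic, tc$non_sarcopenic)
      lors[r, s] <- log((tab[1] * tab[4]) / (tab[2] * tab[3]))
    }
  }
  implied <- igf$allelic_or[match(eff, igf$snp_id)]
  est <- exp(colMeans(lors))
  expect_true(all(abs(est / implied - 1) < 0.05))
})

test_that("a built-in heterozygote deficit violates HWE in every group", {
  spec <- study_default_spec(include_hwe_violation = TRUE)
  expect_true("rs3732379" %in% spec$snps$snp_id)
  sim <- simulate_cohort(spec, seed = 9)
  panel <- study_panel()
  gc <- genotype_counts(sim$cohort, "rs3732379", panel,
                        by_status = TRUE)$non_sarcopenic
  expect_lt(hwe_chisq(gc)$p, 0.05)
})
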