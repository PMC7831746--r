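test_that("panel round-trips through the DCF config format", {
  p <- study_panel()
  expect_s3_class(p, "snp_panel")
  expect_equal(nrow(p), 7)
  expect_equal(p$risk_allele[p$gene == "MTHFR"], "C")

  f <- withr::local_tempfile(fileext = ".dcf")
  write_panel(p, f)
  p2 <- read_panel(f)
  expect_equal(as.data.frame(p2), as.data.frame(p))
})

test_that("panel validation rejects duplicates and foreign risk alleles", {
  expect_error(snp_panel(c("rs1", "rs1"), c("A", "B"), c("1p", "2q"),
                         c("A/C", "A/G")), "duplicate")
  expect_error(snp_panel("rs1", "A", "1p", "A/C", risk_allele = "G"),
               "risk_allele")
  f <- withr::local_tempfile(fileext = ".dcf")
  writeLines(character(0), f)
  expect_equal(nrow(read_panel(f)), 0)
})

test_that("cohort tables read, validate and round-trip cell for cell", {
  panel <- two_snp_panel()
  df <- make_cohort_df(3, rs1801131 = c("A/C", "C/A", "C/C"),
                       rs12594956 = c("A/A", "NA", "./."))
  f <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, f, row.names = FALSE, quote = FALSE)
  co <- read_cohort(f, panel)
  # heterozygotes canonicalized regardless of input allele order
  expect_equal(co$rs1801131, c("A/C", "A/C", "C/C"))
  # "", NA, ./., all read as missing
  expect_equal(is.na(co$rs12594956), c(FALSE, TRUE, TRUE))

  f2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, f2, panel)
  co2 <- read_cohort(f2, panel)
  expect_equal(as.data.frame(co2), as.data.frame(co),
               ignore_attr = TRUE)
})

test_that("cohort validation errors name the offending sample and column", {
  panel <- two_snp_panel()
  df <- make_cohort_df(2, rs1801131 = c("A/C", "A/G"),
                       rs12594956 = "A/A")
  expect_error(validate_cohort(df, panel), "P002.*rs1801131")
  df2 <- make_cohort_df(2, rs1801131 = "A/A", rs12594956 = "A/A")
  df2$grip_kg <- c("22", "strong")
  expect_error(validate_cohort(df2, panel), "P002.*grip_kg")
  df3 <- make_cohort_df(2, rs1801131 = "A/A", rs12594956 = "A/A")
  df3$age <- c(80, 40)
  expect_error(validate_cohort(df3, panel), "age below")
})

test_that("call rates reflect blanked genotype cells", {
  panel <- two_snp_panel()
  n <- 200
  df <- make_cohort_df(n, rs1801131 = "A/C", rs12594956 = "A/A")
  df$rs1801131[seq_len(13)] <- NA  # 6.5% of 200
  co <- validate_cohort(df, panel)
  cr <- attr(co, "call_rates")
  expect_equal(cr$call_rate[cr$snp_id == "rs1801131"], 0.935)
  expect_false(any(cr$flagged))
  cr2 <- call_rates(co, panel, threshold = 0.95)
  expect_true(cr2$flagged[cr2$snp_id == "rs1801131"])
})

test_that("dosage counts risk-allele copies and complements on flip", {
  expect_equal(genotype_dosage(c("C/C", "A/C", "A/A", NA), "C"),
               c(2L, 1L, 0L, NA))
  expect_error(genotype_dosage("A/C", NA_character_), "orient")
  calls <- c("A/A", "A/C", "C/C")
  expect_equal(genotype_dosage(calls, "C") + genotype_dosage(calls, "A"),
               rep(2L, 3))
})

test_that("genotype counts sum over groups to the ungrouped totals", {
  panel <- two_snp_panel()[1, ]
  co <- cohort_from_counts(panel, list(c(10, 5, 5)), list(c(4, 8, 12)))
  total <- genotype_counts(co, "rs1801131", panel)
  expect_equal(unclass(total), c(hom_risk = 14L, het = 13L, hom_other = 17L),
               ignore_attr = TRUE)
  by_grp <- genotype_counts(co, "rs1801131", panel, by_status = TRUE)
  expect_equal(as.integer(by_grp$sarcopenic + by_grp$non_sarcopenic),
               as.integer(total))
})

test_that("simulated cohorts tally exactly as the generator recorded", {
  spec <- sim_spec(30, 70, 0.25,
                   data.frame(snp_id = "rs1801131", gene = "MTHFR",
                              alleles = "A/C", risk_allele = "C",
                              freq = 0.3, grr_het = 1.5, grr_hom = 2.25,
                              stringsAsFactors = FALSE),
                   missing_rate = 0, error_rate = 0)
  sim <- simulate_cohort(spec, seed = 42)
  counts <- genotype_counts(sim$cohort, "rs1801131", two_snp_panel(),
                            by_status = TRUE)
  truth <- sim$truth$genotype_counts$rs1801131
  expect_equal(as.integer(counts$sarcopenic), as.integer(truth$sarcopenic))
  expect_equal(as.integer(counts$non_sarcopenic),
               as.integer(truth$non_sarcopenic))
})

test_that("VCF genotypes map onto panel alleles through REF/ALT", {
  skip_if_not_installed("vcfR")
  panel <- two_snp_panel()
  f <- withr::local_tempfile(fileext = ".vcf")
  write_vcf_fixture(f, c("S1", "S2", "S3"), list(
    list(id = "rs1801131", ref = "A", alt = "C",
         gt = c("0/1", "./.", "1|1"))))
  expect_warning(g <- import_vcf(f, panel), "rs12594956")
  expect_equal(g$rs1801131, c("A/C", NA, "C/C"))

  f2 <- withr::local_tempfile(fileext = ".vcf")
  write_vcf_fixture(f2, "S1", list(
    list(id = "rs1801131", ref = "A", alt = "C,G", gt = "0/1")))
  expect_error(suppressWarnings(import_vcf(f2, panel)), "multi-allelic")
})
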