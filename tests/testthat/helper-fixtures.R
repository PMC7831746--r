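# Fixtures built in code, and independent brute-force oracles used across
# the suite.

two_snp_panel <- function() {
  snp_panel(snp_id = c("rs1801131", "rs12594956"),
            gene = c("MTHFR", "NRF2"),
            locus = c("1p36.22", "15q21.2"),
            alleles = c("A/C", "A/C"),
            risk_allele = c("C", "C"))
}

# minimal valid cohort data frame; genotype columns appended from ...
make_cohort_df <- function(n = 3, status = "non_sarcopenic", sex = "female",
                           ...) {
  df <- data.frame(
    sample_id = sprintf("P%03d", seq_len(n)),
    sex = rep_len(sex, n), age = rep_len(80, n),
    height_cm = rep_len(160, n), mass_kg = rep_len(70, n),
    resistance_ohm = rep_len(520, n), grip_kg = rep_len(22, n),
    gait_m_s = rep_len(1.0, n), physical_activity = rep_len(0, n),
    status = rep_len(status, n), stringsAsFactors = FALSE)
  extra <- list(...)
  for (nm in names(extra)) df[[nm]] <- rep_len(extra[[nm]], n)
  df
}

# cohort whose genotype columns realize given case/control geno_counts
# triples (hom_risk, het, hom_other) for the panel's SNPs
cohort_from_counts <- function(panel, case_counts, control_counts) {
  build_calls <- function(counts, risk, other) {
    rep(c(canonical_geno(risk, risk), canonical_geno(risk, other),
          canonical_geno(other, other)), counts)
  }
  canonical_geno <- function(a, b) paste(min(a, b), max(a, b), sep = "/")
  stopifnot(nrow(panel) >= 1)
  n_case <- sum(case_counts[[1]])
  n_ctrl <- sum(control_counts[[1]])
  df <- make_cohort_df(n_case + n_ctrl,
                       status = rep(c("sarcopenic", "non_sarcopenic"),
                                    c(n_case, n_ctrl)))
  for (i in seq_len(nrow(panel))) {
    risk <- panel$risk_allele[i]
    other <- setdiff(c(panel$allele1[i], panel$allele2[i]), risk)
    df[[panel$snp_id[i]]] <- c(build_calls(case_counts[[i]], risk, other),
                               build_calls(control_counts[[i]], risk, other))
  }
  validate_cohort(df, panel)
}

write_vcf_fixture <- function(path, samples, records) {
  # records: list of list(id, ref, alt, gt = character vector per sample)
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  body <- vapply(records, function(r)
    paste(c("1", "1000", r$id, r$ref, r$alt, ".", "PASS", ".", "GT", r$gt),
          collapse = "\t"), "")
  writeLines(c(hdr, body), path)
  path
}

# --- independent oracles -------------------------------------------------

# generic goodness-of-fit statistic
chisq_gof_oracle <- function(obs, expected) sum((obs - expected)^2 / expected)

# Pearson chi-square on a 2x2 from margins, longhand
chisq_2x2_oracle <- function(tab) {
  m <- matrix(as.numeric(tab), 2, byrow = TRUE)
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  sum((m - e)^2 / e)
}

# exact HWE p by explicit enumeration of every genotype table with the
# observed allele counts
hwe_exact_oracle <- function(hom_risk, het, hom_other) {
  n <- hom_risk + het + hom_other
  na <- 2 * hom_risk + het
  tables <- list()
  for (h in 0:min(na, 2 * n - na)) {
    if ((na - h) %% 2 != 0) next
    hr <- (na - h) / 2
    ho <- n - hr - h
    if (ho < 0) next
    tables[[length(tables) + 1L]] <- c(hr, h, ho)
  }
  pr <- vapply(tables, function(t)
    exp(lfactorial(n) - sum(lfactorial(t)) + t[2] * log(2) +
          lfactorial(na) + lfactorial(2 * n - na) - lfactorial(2 * n)), 0)
  pr <- pr / sum(pr)
  obs <- vapply(tables, function(t) t[2] == het, TRUE)
  sum(pr[pr <= pr[obs] * (1 + 1e-12)])
}

# trapezoidal AUC from an ROC point set
auc_trapezoid_oracle <- function(roc) {
  o <- order(roc$fpr, roc$sensitivity)
  x <- roc$fpr[o]; y <- roc$sensitivity[o]
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

# exhaustive Youden search over the ROC's own thresholds
youden_oracle <- function(scores, labels, thresholds) {
  best <- NULL
  for (t in thresholds) {
    sens <- mean(scores[labels] >= t)
    spec <- mean(scores[!labels] < t)
    j <- sens + spec - 1
    if (is.null(best) || j > best$j + 1e-12 ||
        (abs(j - best$j) <= 1e-12 && sens > best$sens + 1e-12) ||
        (abs(j - best$j) <= 1e-12 && abs(sens - best$sens) <= 1e-12 &&
         t < best$t)) {
      best <- list(t = t, j = j, sens = sens)
    }
  }
  best
}
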