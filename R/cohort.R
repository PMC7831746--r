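# Cohort table IO and genotype bookkeeping.
#
# A cohort is a data.frame with one row per participant and columns
#   sample_id, sex, age, height_cm, mass_kg, resistance_ohm, grip_kg,
#   gait_m_s, physical_activity, status, <snp_id>...
# Genotype cells are "X/Y" strings; heterozygotes are stored with alleles in
# alphabetical order; missing calls are NA (accepted on read as "", "NA",
# "./.").

COHORT_BASE_COLS <- c("sample_id", "sex", "age", "height_cm", "mass_kg",
                      "resistance_ohm", "grip_kg", "gait_m_s",
                      "physical_activity", "status")

MISSING_GENO <- c("", "NA", "./.", ".")

canonical_genotype <- function(a1, a2) {
  paste(pmin(a1, a2), pmax(a1, a2), sep = "/")
}

# parse one genotype column; returns canonical "X/Y" strings with NA missing
parse_genotype_column <- function(x, snp_id, alleles, sample_ids) {
  x <- as.character(x)
  x[is.na(x) | trimws(x) %in% MISSING_GENO] <- NA
  out <- rep(NA_character_, length(x))
  idx <- which(!is.na(x))
  if (!length(idx)) return(out)
  parts <- strsplit(trimws(x[idx]), "/", fixed = TRUE)
  bad_shape <- vapply(parts, length, 0L) != 2L
  if (any(bad_shape))
    stopf("sample %s, SNP %s: genotype '%s' is not of the form X/Y",
          sample_ids[idx[bad_shape][1]], snp_id, x[idx[bad_shape][1]])
  a1 <- vapply(parts, `[`, "", 1L)
  a2 <- vapply(parts, `[`, "", 2L)
  unknown <- !(a1 %in% alleles) | !(a2 %in% alleles)
  if (any(unknown))
    stopf("sample %s, SNP %s: allele(s) in '%s' not in panel alleles %s",
          sample_ids[idx[unknown][1]], snp_id, x[idx[unknown][1]],
          paste(alleles, collapse = "/"))
  out[idx] <- canonical_genotype(a1, a2)
  out
}

#' Read a cohort table
#'
#' Reads a delimited cohort table (comma or tab separated, sniffed from the
#' header line), validates it against a SNP panel, canonicalizes genotype
#' cells and reports per-SNP call rates.
#'
#' @param path path to a CSV/TSV file with the cohort layout described in
#'   the package vignette (header mandatory).
#' @param panel a [snp_panel()]; every panel SNP must have a column.
#' @param min_age minimum allowed age in years (default 65, the study's
#'   inclusion criterion). Younger participants raise an error.
#' @param call_rate_threshold SNPs whose genotype call rate falls below this
#'   are flagged (not dropped) in the call-rate attribute.
#' @return A `data.frame` of class `sarco_cohort`. The attribute
#'   `"call_rates"` holds a per-SNP data frame (`snp_id`, `n_called`, `n`,
#'   `call_rate`, `flagged`).
#' @export
read_cohort <- function(path, panel, min_age = 65, call_rate_threshold = 0.90) {
  if (!file.exists(path)) stopf("cohort file not found: %s", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character", na.strings = NULL)
  validate_cohort(df, panel, min_age = min_age,
                  call_rate_threshold = call_rate_threshold)
}

#' Validate and canonicalize an in-memory cohort data frame
#'
#' @inheritParams read_cohort
#' @param df data frame with the cohort columns (character or typed).
#' @return a validated `sarco_cohort` data frame (see [read_cohort()]).
#' @export
validate_cohort <- function(df, panel, min_age = 65,
                            call_rate_threshold = 0.90) {
  miss <- setdiff(COHORT_BASE_COLS, names(df))
  if (length(miss))
    stopf("cohort table missing column(s): %s", paste(miss, collapse = ", "))
  miss_snp <- setdiff(panel$snp_id, names(df))
  if (length(miss_snp))
    stopf("cohort table missing genotype column(s): %s",
          paste(miss_snp, collapse = ", "))

  out <- df[, c(COHORT_BASE_COLS, panel$snp_id), drop = FALSE]
  out$sample_id <- as.character(out$sample_id)
  out$sex <- tolower(as.character(out$sex))
  bad_sex <- !(out$sex %in% c("male", "female"))
  if (any(bad_sex))
    stopf("sample %s: sex must be 'male' or 'female'",
          out$sample_id[bad_sex][1])

  num_cols <- c("age", "height_cm", "mass_kg", "resistance_ohm", "grip_kg",
                "gait_m_s", "physical_activity")
  for (cl in num_cols) {
    x <- as.character(out[[cl]])
    x[x %in% c("", "NA")] <- NA
    v <- suppressWarnings(as.numeric(x))
    bad <- !is.na(x) & is.na(v)
    if (any(bad))
      stopf("sample %s: non-numeric value '%s' in column %s",
            out$sample_id[bad][1], x[bad][1], cl)
    out[[cl]] <- v
  }
  if (any(!is.na(out$age) & out$age < min_age))
    stopf("sample %s: age below the configured minimum (%g)",
          out$sample_id[which(!is.na(out$age) & out$age < min_age)[1]],
          min_age)
  pos_cols <- setdiff(num_cols, c("age", "physical_activity"))
  for (cl in pos_cols) {
    bad <- !is.na(out[[cl]]) & out[[cl]] <= 0
    if (any(bad))
      stopf("sample %s: %s must be > 0", out$sample_id[bad][1], cl)
  }

  st <- as.character(out$status)
  st[is.na(st) | st == "" | st == "NA"] <- "unclassified"
  ok_status <- c("sarcopenic", "non_sarcopenic", "unclassified")
  if (any(!st %in% ok_status))
    stopf("sample %s: status '%s' not one of %s",
          out$sample_id[!st %in% ok_status][1], st[!st %in% ok_status][1],
          paste(ok_status, collapse = ", "))
  out$status <- st

  for (i in seq_len(nrow(panel))) {
    sid <- panel$snp_id[i]
    out[[sid]] <- parse_genotype_column(out[[sid]], sid,
                                        c(panel$allele1[i], panel$allele2[i]),
                                        out$sample_id)
  }

  cr <- call_rates(out, panel, threshold = call_rate_threshold)
  attr(out, "call_rates") <- cr
  class(out) <- c("sarco_cohort", "data.frame")
  out
}

#' Per-SNP genotype call rates
#'
#' @param cohort a cohort data frame.
#' @param panel a [snp_panel()].
#' @param threshold SNPs below this call rate are flagged.
#' @return data frame with `snp_id`, `n_called`, `n`, `call_rate`, `flagged`.
#' @export
call_rates <- function(cohort, panel, threshold = 0.90) {
  n <- nrow(cohort)
  called <- vapply(panel$snp_id, function(s) sum(!is.na(cohort[[s]])), 0L)
  data.frame(snp_id = panel$snp_id, n_called = called, n = n,
             call_rate = if (n > 0) called / n else NA_real_,
             flagged = if (n > 0) called / n < threshold else FALSE,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write a cohort table
#'
#' Writes the canonical cohort CSV: base columns then one column per panel
#' SNP, missing genotypes as `NA`. Reading the result back with
#' [read_cohort()] reproduces the table cell for cell.
#'
#' @param cohort a cohort data frame.
#' @param path output path.
#' @param panel optional [snp_panel()] fixing the genotype column order;
#'   defaults to the columns already present.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, panel = NULL) {
  snp_cols <- if (is.null(panel)) setdiff(names(cohort), COHORT_BASE_COLS)
              else panel$snp_id
  df <- as.data.frame(cohort)[, c(COHORT_BASE_COLS, snp_cols), drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Count copies of the risk allele in a genotype call
#'
#' Recodes a biallelic genotype to 0/1/2 dosage of the risk allele: the
#' risk-homozygous genotype scores 2, the heterozygote 1, the other
#' homozygote 0. Missing calls stay missing.
#'
#' @param call character vector of `"X/Y"` genotype strings (NA = missing).
#' @param risk_allele the allele whose copies are counted; must not be NA.
#' @return integer vector of 0, 1, 2 or NA.
#' @examples
#' genotype_dosage(c("C/C", "A/C", "A/A", NA), "C")
#' @export
genotype_dosage <- function(call, risk_allele) {
  if (length(risk_allele) != 1L || is.na(risk_allele))
    stopf(paste("risk allele undetermined; orient it first (see",
                "orient_risk_alleles) before computing dosages"))
  out <- rep(NA_integer_, length(call))
  idx <- which(!is.na(call))
  if (!length(idx)) return(out)
  parts <- strsplit(call[idx], "/", fixed = TRUE)
  out[idx] <- vapply(parts, function(p) sum(p == risk_allele), 0L)
  out
}

#' Genotype dosage matrix for a cohort
#'
#' @param cohort a cohort data frame.
#' @param panel a [snp_panel()] with risk alleles set for `snps`.
#' @param snps SNPs to include (default: all panel SNPs).
#' @return integer matrix, samples x SNPs, entries 0/1/2 or NA.
#' @export
dosage_matrix <- function(cohort, panel, snps = panel$snp_id) {
  m <- vapply(snps, function(s) {
    e <- panel_entry(panel, s)
    genotype_dosage(cohort[[s]], e$risk_allele)
  }, integer(nrow(cohort)))
  m <- matrix(m, nrow = nrow(cohort), dimnames = list(cohort$sample_id, snps))
  m
}

#' Genotype counts for one SNP
#'
#' Tallies risk-homozygote / heterozygote / other-homozygote counts among
#' non-missing calls, optionally split by case-control status.
#'
#' @param cohort a cohort data frame.
#' @param snp_id SNP to tally.
#' @param panel a [snp_panel()]. If the SNP's risk allele is undetermined the
#'   counts are oriented on `allele2` (the conventional alternate allele).
#' @param by_status if `TRUE`, return a list with elements `sarcopenic` and
#'   `non_sarcopenic` (unclassified samples are ignored).
#' @return a `geno_counts` vector (or a list of two, with `by_status`).
#' @export
genotype_counts <- function(cohort, snp_id, panel, by_status = FALSE) {
  e <- panel_entry(panel, snp_id)
  risk <- if (!is.na(e$risk_allele)) e$risk_allele else e$allele2
  tally <- function(calls) {
    d <- genotype_dosage(calls, risk)
    d <- d[!is.na(d)]
    if (!length(d)) stopf("SNP %s: no non-missing genotype calls", snp_id)
    geno_counts(sum(d == 2L), sum(d == 1L), sum(d == 0L), risk_allele = risk)
  }
  if (!by_status) return(tally(cohort[[snp_id]]))
  list(sarcopenic = tally(cohort[[snp_id]][cohort$status == "sarcopenic"]),
       non_sarcopenic =
         tally(cohort[[snp_id]][cohort$status == "non_sarcopenic"]))
}

#' Genotype count triple
#'
#' @param hom_risk,het,hom_other non-negative integer counts of
#'   risk-homozygotes, heterozygotes and other-homozygotes.
#' @param risk_allele optional allele symbol the orientation refers to.
#' @return named integer vector of class `geno_counts`.
#' @export
geno_counts <- function(hom_risk, het, hom_other, risk_allele = NA_character_) {
  x <- c(hom_risk = as.integer(hom_risk), het = as.integer(het),
         hom_other = as.integer(hom_other))
  if (any(is.na(x)) || any(x < 0)) stopf("genotype counts must be >= 0")
  structure(x, risk_allele = risk_allele, class = "geno_counts")
}

#' Genotype frequencies (percent, to 0.1)
#'
#' @param counts a [geno_counts()] triple.
#' @return named numeric vector of percentages rounded to one decimal.
#' @export
genotype_frequencies <- function(counts) {
  round(100 * counts / sum(counts), 1)
}
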