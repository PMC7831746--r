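# Full study workflow: classification -> HWE QC -> association -> logistic
# models -> risk-allele orientation -> genetic risk score / ROC -> report.

#' Run the full case-control association workflow
#'
#' Executes, in order: EWGSOP phenotype classification (only when `status`
#' is absent), per-group Hardy-Weinberg QC with exclusion of SNPs deviating
#' in controls, genotypic (2x3) / allelic / dominant / recessive association
#' statistics for every retained SNP, unadjusted and covariate-adjusted
#' logistic models, risk-allele orientation for SNPs the panel leaves
#' undetermined, the additive genetic risk score with ROC, AUC and
#' Youden-index cutoff, and a machine-readable summary. Each table is
#' written as TSV and the summary as JSON under `outdir`; a run log records
#' every exclusion and decision. A failure at any stage removes the partial
#' outputs before propagating the error.
#'
#' @param cohort a cohort data frame, or a path to a cohort CSV/TSV.
#' @param panel a [snp_panel()], or a path to a panel config.
#' @param outdir output directory (created if needed).
#' @param alpha significance threshold (default 0.05).
#' @param hwe_alpha threshold for the control-group HWE exclusion (default:
#'   `alpha`, matching small candidate-gene studies; large cohorts
#'   conventionally tighten this to 1e-4 or below, since at a strong-effect
#'   locus even the control group deviates slightly from HWE under
#'   case-control sampling).
#' @param covariates covariates for the adjusted models
#'   (default `c("age", "sex", "physical_activity")`).
#' @param grs_snps SNPs entering the risk score; default: retained SNPs
#'   whose allelic test is significant at `alpha` (the study's rule of
#'   scoring only the associated variants).
#' @param min_age passed to [validate_cohort()] when `cohort` is a path.
#' @return invisibly, a list with elements `hwe`, `association`, `logistic`
#'   (data frames), `grs` (scores, ROC, AUC, cutoff), `excluded_snps`,
#'   `panel` (risk-oriented) and `paths` of the written files.
#' @export
run_study_pipeline <- function(cohort, panel, outdir, alpha = 0.05,
                               hwe_alpha = alpha,
                               covariates = c("age", "sex",
                                              "physical_activity"),
                               grs_snps = NULL, min_age = 65) {
  if (alpha <= 0 || alpha >= 1) stopf("alpha must be in (0,1)")
  if (hwe_alpha <= 0 || hwe_alpha >= 1) stopf("hwe_alpha must be in (0,1)")
  if (is.character(panel)) panel <- read_panel(panel)
  if (is.character(cohort)) {
    # tolerate panels wider than the table: analyze the SNPs present
    header <- strsplit(readLines(cohort, n = 1L), "[,\t]")[[1]]
    panel_here <- panel[panel$snp_id %in% header, , drop = FALSE]
    cohort <- read_cohort(cohort, panel_here, min_age = min_age)
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  log_path <- file.path(outdir, "run.log")
  logf <- function(fmt, ...) cat(sprintf(paste0(fmt, "\n"), ...),
                                 file = log_path, append = TRUE)
  emit <- function(df, name) {
    p <- file.path(outdir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "NA")
    written <<- c(written, p)
    p
  }
  on_fail <- function(stage, e) {
    unlink(c(written, log_path))
    stopf("pipeline stage '%s' failed: %s", stage, conditionMessage(e))
  }
  cat(sprintf("sarcoscore pipeline run %s\n", format(Sys.time(), "%Y-%m-%d")),
      file = log_path)
  written <- c(written, log_path)

  # panel SNPs without a genotype column cannot be analyzed
  absent <- setdiff(panel$snp_id, names(cohort))
  if (length(absent)) {
    logf("panel SNP(s) without genotype columns, skipped: %s",
         paste(absent, collapse = ", "))
    panel <- panel[!panel$snp_id %in% absent, , drop = FALSE]
  }

  # --- phenotype classification ------------------------------------------
  tryCatch({
    if (all(cohort$status == "unclassified")) {
      cohort <- classify_sarcopenia(cohort)
      logf("classified cohort: %d sarcopenic / %d non-sarcopenic / %d unclassified",
           sum(cohort$status == "sarcopenic"),
           sum(cohort$status == "non_sarcopenic"),
           sum(cohort$status == "unclassified"))
    } else logf("status column present; classification skipped")
  }, error = function(e) on_fail("phenotype", e))

  # --- HWE QC -------------------------------------------------------------
  hwe_tab <- NULL
  excluded <- character(0)
  tryCatch({
    rows <- list()
    for (s in panel$snp_id) {
      gc <- genotype_counts(cohort, s, panel, by_status = TRUE)
      for (grp in names(gc)) {
        h <- hwe_chisq(gc[[grp]])
        flag <- grp == "non_sarcopenic" && h$p < hwe_alpha
        rows[[length(rows) + 1L]] <- data.frame(
          snp_id = s, group = grp,
          hom_risk = gc[[grp]][1], het = gc[[grp]][2],
          hom_other = gc[[grp]][3],
          chi2 = h$chi2, p = h$p, excluded = flag,
          stringsAsFactors = FALSE)
        if (flag) {
          excluded <- c(excluded, s)
          logf("SNP %s excluded: control-group HWE deviation (chi2 = %.3f, p = %s)",
               s, h$chi2, format_pvalue(h$p))
        } else if (grp == "sarcopenic" && h$p < hwe_alpha) {
          logf("SNP %s deviates from HWE in cases (chi2 = %.3f, p = %s); retained",
               s, h$chi2, format_pvalue(h$p))
        }
      }
    }
    hwe_tab <- do.call(rbind, rows)
    emit(hwe_tab, "hwe.tsv")
  }, error = function(e) on_fail("hwe", e))
  retained <- setdiff(panel$snp_id, excluded)
  if (!length(retained))
    on_fail("hwe", simpleError("all SNPs excluded by HWE QC"))

  # --- risk-allele orientation -------------------------------------------
  tryCatch({
    undet <- intersect(retained, panel$snp_id[is.na(panel$risk_allele)])
    if (length(undet)) {
      panel <- orient_risk_alleles(cohort, panel, snps = undet)
      for (s in undet)
        logf("SNP %s risk allele oriented to %s (allelic OR %.3f)", s,
             panel$risk_allele[match(s, panel$snp_id)],
             attr(panel, "orientation_or")[s])
    }
  }, error = function(e) on_fail("orientation", e))

  # --- contingency association -------------------------------------------
  assoc_tab <- NULL
  tryCatch({
    rows <- list()
    for (s in retained) {
      gc <- genotype_counts(cohort, s, panel, by_status = TRUE)
      cc <- gc$sarcopenic; uu <- gc$non_sarcopenic
      g23 <- rbind(cases = as.numeric(cc), controls = as.numeric(uu))
      gt <- suppressWarnings(chisq_assoc(g23))
      rows[[length(rows) + 1L]] <- data.frame(
        snp_id = s, model = "genotypic", a = NA, b = NA, c = NA, d = NA,
        or_ = NA, ci_low = NA, ci_high = NA, chi2 = gt$chi2, df = gt$df,
        p = gt$p, stringsAsFactors = FALSE)
      tabs <- list(allelic = allele_table(cc, uu),
                   dominant = model_table(cc, uu, "dominant"),
                   recessive = model_table(cc, uu, "recessive"))
      for (m in names(tabs)) {
        r <- suppressWarnings(odds_ratio_woolf(tabs[[m]], model = m))
        rows[[length(rows) + 1L]] <- data.frame(
          snp_id = s, model = m, a = tabs[[m]][1], b = tabs[[m]][2],
          c = tabs[[m]][3], d = tabs[[m]][4], or_ = r$or,
          ci_low = r$ci_low, ci_high = r$ci_high, chi2 = r$chi2,
          df = r$df, p = r$p, stringsAsFactors = FALSE)
      }
    }
    assoc_tab <- do.call(rbind, rows)
    out <- assoc_tab
    for (cl in c("or_", "ci_low", "ci_high", "chi2"))
      out[[cl]] <- round(out[[cl]], 3)
    out$p <- ifelse(out$p < 0.001, formatC(out$p, format = "e", digits = 2),
                    formatC(out$p, format = "f", digits = 3))
    emit(out, "association.tsv")
  }, error = function(e) on_fail("association", e))

  # --- logistic models ----------------------------------------------------
  logit_tab <- NULL
  tryCatch({
    rows <- list()
    for (s in retained) for (coding in c("dominant", "recessive")) {
      for (adj in c(FALSE, TRUE)) {
        fit <- fit_model(cohort, panel, s, coding,
                         covariates = if (adj) covariates else character())
        i <- match(s, fit$terms)
        rows[[length(rows) + 1L]] <- data.frame(
          snp_id = s, model = coding, adjusted = adj, or_ = fit$or[i],
          ci_low = fit$ci_low[i], ci_high = fit$ci_high[i], p = fit$p[i],
          nagelkerke_r2 = fit$nagelkerke_r2, n_used = fit$n_used,
          stringsAsFactors = FALSE)
      }
    }
    logit_tab <- do.call(rbind, rows)
    emit(logit_tab, "logistic.tsv")
  }, error = function(e) on_fail("logistic", e))

  # --- genetic risk score -------------------------------------------------
  grs_out <- NULL
  tryCatch({
    if (is.null(grs_snps)) {
      al <- assoc_tab[assoc_tab$model == "allelic", ]
      grs_snps <- al$snp_id[al$p < alpha]
      logf("risk-score SNPs (allelic p < %.3g): %s", alpha,
           if (length(grs_snps)) paste(grs_snps, collapse = ", ") else "none")
    }
    if (length(grs_snps) == 0) {
      logf("no SNPs qualify for the risk score; GRS stage skipped")
    } else {
      scores <- sgs_cohort(cohort, panel, snps = grs_snps)
      emit(scores, "grs_scores.tsv")
      lab <- cohort$status == "sarcopenic"
      use <- cohort$status %in% c("sarcopenic", "non_sarcopenic") &
        !is.na(scores$scaled)
      roc <- roc_curve(scores$scaled[use], lab[use])
      emit(as.data.frame(roc), "grs_roc.tsv")
      auc <- roc_auc(scores$scaled[use], lab[use])
      cut <- youden_cutoff(roc)
      sgs_fit <- fit_model(cohort, panel, coding = "grs_continuous",
                           grs_snps = grs_snps)
      i <- match("sgs", sgs_fit$terms)
      grs_out <- list(
        snps = grs_snps, scores = scores, roc = roc,
        auc = auc, cutoff = cut,
        or_per_unit = sgs_fit$or[i],
        or_ci = c(sgs_fit$ci_low[i], sgs_fit$ci_high[i]),
        or_p = sgs_fit$p[i],
        nagelkerke_r2 = sgs_fit$nagelkerke_r2,
        prop_above_cutoff = c(
          cases = mean(scores$scaled[use][lab[use]] >= cut$threshold),
          controls = mean(scores$scaled[use][!lab[use]] >= cut$threshold)))
      logf("GRS: AUC %.3f (%.3f-%.3f), Youden cutoff %.4g", auc$auc,
           auc$ci_low, auc$ci_high, cut$threshold)
    }
  }, error = function(e) on_fail("grs", e))

  # --- summary ------------------------------------------------------------
  tryCatch({
    summary <- list(
      n = nrow(cohort),
      n_cases = sum(cohort$status == "sarcopenic"),
      n_controls = sum(cohort$status == "non_sarcopenic"),
      alpha = alpha,
      excluded_snps = excluded,
      risk_alleles = stats::setNames(panel$risk_allele, panel$snp_id),
      association = assoc_tab,
      logistic = logit_tab,
      grs = if (!is.null(grs_out)) list(
        snps = grs_out$snps, auc = grs_out$auc$auc,
        auc_ci = c(grs_out$auc$ci_low, grs_out$auc$ci_high),
        cutoff = grs_out$cutoff$threshold,
        youden_j = grs_out$cutoff$youden_j,
        sensitivity = grs_out$cutoff$sensitivity,
        specificity = grs_out$cutoff$specificity,
        or_per_unit = grs_out$or_per_unit, or_ci = grs_out$or_ci,
        or_p = grs_out$or_p, nagelkerke_r2 = grs_out$nagelkerke_r2,
        prop_above_cutoff = as.list(grs_out$prop_above_cutoff)))
    p <- file.path(outdir, "summary.json")
    jsonlite::write_json(summary, p, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
    written <- c(written, p)
  }, error = function(e) on_fail("summary", e))

  invisible(list(hwe = hwe_tab, association = assoc_tab,
                 logistic = logit_tab, grs = grs_out,
                 excluded_snps = excluded, panel = panel,
                 cohort = cohort, paths = written))
}
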