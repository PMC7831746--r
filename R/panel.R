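#' Construct a SNP panel
#'
#' A panel describes the biallelic markers an analysis operates on: rsID,
#' gene symbol, cytogenetic locus, the two nucleotide alleles, optionally the
#' risk allele, and an optional display label per nucleotide (e.g. the
#' R/X protein-level labels commonly used for ACTN3 R577X, which is C/T at
#' the nucleotide level).
#'
#' @param snp_id character vector of rsIDs (must be unique).
#' @param gene gene symbols.
#' @param locus cytoband strings.
#' @param alleles character vector like `"A/C"`: the two alleles, slash
#'   separated.
#' @param risk_allele one of the two alleles, or `NA` when the risk
#'   orientation has not been determined yet (see [orient_risk_alleles()]).
#' @param label_map optional character vector like `"C=R,T=X"` mapping
#'   nucleotides to display labels; `NA` for identity.
#' @return A data frame of class `snp_panel` with columns `snp_id`, `gene`,
#'   `locus`, `allele1`, `allele2`, `risk_allele`, `label_map`.
#' @examples
#' snp_panel("rs1801131", "MTHFR", "1p36.22", "A/C", risk_allele = "C")
#' @export
snp_panel <- function(snp_id, gene, locus, alleles, risk_allele = NA_character_,
                      label_map = NA_character_) {
  n <- length(snp_id)
  stopifnot(length(gene) == n, length(locus) == n, length(alleles) == n)
  risk_allele <- rep_len(as.character(risk_allele), n)
  label_map <- rep_len(as.character(label_map), n)
  if (anyDuplicated(snp_id))
    stopf("duplicate snp_id in panel: %s",
          paste(unique(snp_id[duplicated(snp_id)]), collapse = ", "))
  parts <- strsplit(alleles, "/", fixed = TRUE)
  bad <- vapply(parts, function(p) length(p) != 2L || p[1] == p[2], logical(1))
  if (any(bad))
    stopf("alleles must be two distinct symbols 'X/Y' (offending: %s)",
          paste(snp_id[bad], collapse = ", "))
  a1 <- vapply(parts, `[`, "", 1L)
  a2 <- vapply(parts, `[`, "", 2L)
  ok <- is.na(risk_allele) | risk_allele == a1 | risk_allele == a2
  if (!all(ok))
    stopf("risk_allele not among the declared alleles for %s",
          paste(snp_id[!ok], collapse = ", "))
  structure(
    data.frame(snp_id = snp_id, gene = gene, locus = locus,
               allele1 = a1, allele2 = a2, risk_allele = risk_allele,
               label_map = label_map, stringsAsFactors = FALSE),
    class = c("snp_panel", "data.frame"))
}

#' Read a SNP panel from a structured text config
#'
#' The file holds one block per SNP in Debian-control (DCF) layout: blank-line
#' separated blocks of `key: value` lines with keys `id`, `gene`, `locus`,
#' `alleles`, and optionally `risk_allele` and `label_map`.
#'
#' @param path path to the panel config file.
#' @return a [snp_panel()].
#' @seealso [write_panel()], [study_panel()]
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) stopf("panel file not found: %s", path)
  m <- tryCatch(read.dcf(path), error = function(e)
    stopf("malformed panel file %s: %s", path, conditionMessage(e)))
  if (nrow(m) == 0L)
    return(snp_panel(character(), character(), character(), character()))
  need <- c("id", "gene", "locus", "alleles")
  miss <- setdiff(need, colnames(m))
  if (length(miss))
    stopf("panel file %s: missing required key(s) %s", path,
          paste(miss, collapse = ", "))
  get <- function(key) if (key %in% colnames(m)) as.character(m[, key]) else
    rep(NA_character_, nrow(m))
  snp_panel(snp_id = get("id"), gene = get("gene"), locus = get("locus"),
            alleles = get("alleles"), risk_allele = get("risk_allele"),
            label_map = get("label_map"))
}

#' Write a SNP panel config
#'
#' @param panel a [snp_panel()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  m <- cbind(id = panel$snp_id, gene = panel$gene, locus = panel$locus,
             alleles = paste(panel$allele1, panel$allele2, sep = "/"),
             risk_allele = panel$risk_allele, label_map = panel$label_map)
  write.dcf(m, path)
  invisible(path)
}

#' The seven-SNP candidate panel for sarcopenia
#'
#' The candidate markers genotyped in the motivating study: MTHFR rs1801131
#' (A/C, risk C), ACTN3 rs1815739 (C/T at the nucleotide level, displayed
#' R/X, risk T = X), NRF2 rs12594956 (A/C, risk C), VDR FokI rs2228570,
#' ADRB2 rs1042713, CX3CR1 rs3732379 and NPAS4 rs7947391. Risk alleles are
#' set only for the three markers the study found associated with sarcopenia;
#' the rest are left undetermined.
#'
#' @return a [snp_panel()] with seven rows.
#' @export
study_panel <- function() {
  snp_panel(
    snp_id = c("rs1801131", "rs1815739", "rs12594956", "rs2228570",
               "rs1042713", "rs3732379", "rs7947391"),
    gene  = c("MTHFR", "ACTN3", "NRF2", "VDR", "ADRB2", "CX3CR1", "NPAS4"),
    locus = c("1p36.22", "11q13.2", "15q21.2", "12q13.1", "5q32", "3p22",
              "11q13.2"),
    alleles = c("A/C", "C/T", "A/C", "C/T", "A/G", "C/T", "A/G"),
    risk_allele = c("C", "T", "C", NA, NA, NA, NA),
    label_map = c(NA, "C=R,T=X", NA, NA, NA, NA, NA))
}

panel_entry <- function(panel, snp_id) {
  i <- match(snp_id, panel$snp_id)
  if (is.na(i)) stopf("SNP %s is not in the panel", snp_id)
  panel[i, , drop = FALSE]
}

panel_alleles <- function(panel, snp_id) {
  e <- panel_entry(panel, snp_id)
  c(e$allele1, e$allele2)
}
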