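#' Import panel genotypes from a VCF file
#'
#' Reads genotype calls for the panel's SNPs (matched by the VCF `ID` column)
#' from a VCF 4.x file and returns them in the cohort genotype dialect:
#' canonical `"X/Y"` strings per sample. Diploid GT fields `0/0`, `0/1`,
#' `1/1` are mapped onto REF/ALT alleles; phased separators (`|`) are
#' accepted and phase is discarded; `./.` becomes a missing call.
#'
#' @param path path to a VCF file (uncompressed or bgzipped).
#' @param panel a [snp_panel()].
#' @return a data frame with `sample_id` and one genotype column per panel
#'   SNP found in the file; panel SNPs absent from the VCF yield a warning
#'   and all-missing columns.
#' @export
import_vcf <- function(path, panel) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stopf("import_vcf requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1,
                                     dimnames = list(NULL, names(gt)))
  samples <- colnames(gt)
  out <- data.frame(sample_id = samples, stringsAsFactors = FALSE)

  for (i in seq_len(nrow(panel))) {
    sid <- panel$snp_id[i]
    j <- which(fix[, "ID"] == sid)
    if (length(j) == 0L) {
      warnf("panel SNP %s not found in VCF %s; calls set to missing",
            sid, path)
      out[[sid]] <- rep(NA_character_, length(samples))
      next
    }
    if (length(j) > 1L)
      stopf("SNP %s appears %d times in VCF %s", sid, length(j), path)
    ref <- fix[j, "REF"]
    alt <- fix[j, "ALT"]
    if (grepl(",", alt, fixed = TRUE))
      stopf("SNP %s is multi-allelic in VCF %s (ALT = %s)", sid, path, alt)
    alleles <- c(ref, alt)
    pair <- panel_alleles(panel, sid)
    if (!all(alleles %in% pair))
      stopf("SNP %s: VCF alleles %s/%s do not match panel alleles %s",
            sid, ref, alt, paste(pair, collapse = "/"))
    g <- gt[j, ]
    out[[sid]] <- vapply(g, function(cell) {
      if (is.na(cell)) return(NA_character_)
      idx <- strsplit(cell, "[/|]")[[1]]
      if (length(idx) != 2L || any(idx == "."))  return(NA_character_)
      ai <- suppressWarnings(as.integer(idx))
      if (any(is.na(ai)) || any(ai > 1L))
        stopf("SNP %s: unsupported GT '%s'", sid, cell)
      canonical_genotype(alleles[ai[1] + 1L], alleles[ai[2] + 1L])
    }, "", USE.NAMES = FALSE)
  }
  out
}
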