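# shared internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Format a p-value the way association tables report it
#'
#' Three decimals, with values below 0.001 collapsed to `"<0.001"`.
#'
#' @param p numeric vector of p-values.
#' @return character vector.
#' @export
format_pvalue <- function(p) {
  ifelse(p < 0.001, "<0.001", formatC(p, format = "f", digits = 3))
}

# round half away from zero (base round() rounds half to even)
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# z quantile used for all 95% Wald-type intervals
Z975 <- 1.959964
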