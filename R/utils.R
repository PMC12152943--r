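`%||%` <- function(a, b) if (is.null(a)) b else a

# one deterministic stream of sub-seeds per parent seed; keeps all derived
# seeds within 32-bit integer range
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max, n)
}

# zero denominators surface as NA, never as a silent 0
safe_div <- function(num, den) {
  if (!is.finite(den) || den == 0) return(NA_real_)
  num / den
}

#' Format a negative:positive ratio as "R:1"
#'
#' @param ratio numeric ratio (negatives per positive), or `NA` when undefined.
#' @param digits decimal places, default 2 (the reporting convention).
#' @return character scalar such as `"3.26:1"`, or `"undefined"`.
#' @export
format_ratio <- function(ratio, digits = 2) {
  if (is.na(ratio)) return("undefined")
  sprintf(paste0("%.", digits, "f:1"), ratio)
}

#' Format a fraction as a percentage
#'
#' Coverage and similar fractions are held as values in \[0,1\] internally;
#' percent formatting happens only at the reporting layer.
#'
#' @param x fraction in \[0,1\].
#' @param digits decimal places, default 2.
#' @return character scalar such as `"0.89%"`.
#' @export
format_percent <- function(x, digits = 2) {
  sprintf(paste0("%.", digits, "f%%"), 100 * x)
}

stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("cholecon_config_error", "error")))
}

stop_schema <- function(...) {
  stop(errorCondition(paste0(...), class = c("cholecon_schema_error", "error")))
}
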