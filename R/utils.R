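#' Round half-up to a number of significant figures
#'
#' Report-style rounding used for printed endpoint values (e.g. 64.86 -> 65,
#' 19.17 -> 19, 0.2295 -> 0.23): round-half-away-from-zero at a fixed number
#' of significant figures, unlike [signif()] which rounds half-to-even.
#'
#' @param x Numeric vector.
#' @param digits Significant figures to keep (default 2).
#' @return Numeric vector rounded half-up at `digits` significant figures.
#' @export
#' @examples
#' signif_half_up(c(19.17, 64.86, 0.2295))
signif_half_up <- function(x, digits = 2) {
  stopifnot(is.numeric(x), digits >= 1)
  out <- x
  nz <- is.finite(x) & x != 0
  e <- floor(log10(abs(x[nz])))
  f <- 10^(digits - 1 - e)
  # tiny eps guards against binary representation of decimal halves
  out[nz] <- sign(x[nz]) * floor(abs(x[nz]) * f + 0.5 + 1e-9) / f
  out
}

# internal: stop with a consistent message when a scalar is not a positive number
check_positive <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    stop(sprintf("`%s` must be a positive finite number", name), call. = FALSE)
  }
  invisible(x)
}

check_nonnegative <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0)) {
    stop(sprintf("`%s` must be a non-negative finite number", name), call. = FALSE)
  }
  invisible(x)
}
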