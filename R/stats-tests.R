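#' One-tailed F test for equality of two standard deviations
#'
#' Fisher-Snedecor variance-ratio test from summary statistics. The
#' statistic is the larger over the smaller variance, so F >= 1 and the
#' test is symmetric in its two groups. The decision compares F against a
#' supplied critical value (default 19.00, the alpha = 0.05 one-tailed
#' value at df = (2, 2), i.e. triplicate groups); the distribution-based
#' p-value is reported alongside.
#'
#' @param sd1,sd2 Group standard deviations (>= 0, not both 0).
#' @param n1,n2 Group sizes (>= 2).
#' @param f_crit Critical value (default 19.00).
#' @return A `comparison_result` list: `statistic`, `critical_value`,
#'   `pass` (F < F_crit), `df` (numerator, denominator), `p_value`.
#' @export
#' @examples
#' f_test(3, 3, 1, 3) # F = 9, pass vs 19.00
f_test <- function(sd1, n1, sd2, n2, f_crit = 19.00) {
  check_nonnegative(sd1, "sd1"); check_nonnegative(sd2, "sd2")
  stopifnot(n1 >= 2, n2 >= 2)
  if (sd1 == 0 && sd2 == 0) stop("undefined F: both SDs are zero", call. = FALSE)
  v <- c(sd1^2, sd2^2)
  n <- c(n1, n2)
  hi <- which.max(v); lo <- 3 - hi
  f_calc <- if (v[lo] == 0) Inf else v[hi] / v[lo]
  df <- c(n[hi] - 1, n[lo] - 1)
  p <- if (is.finite(f_calc)) stats::pf(f_calc, df[1], df[2], lower.tail = FALSE) else 0
  structure(list(statistic = f_calc, critical_value = f_crit,
                 pass = f_calc < f_crit, df = df, p_value = p),
            class = "comparison_result")
}

#' Two-sample pooled-variance Student t-test from summary statistics
#'
#' \eqn{t = (\bar{x}_1 - \bar{x}_2) / (s_p \sqrt{1/n_1 + 1/n_2})} with the
#' pooled SD \eqn{s_p}, df = n1 + n2 - 2. The two-sided decision compares
#' |t| against a supplied critical value (default 2.776, alpha = 0.05 at
#' df = 4, i.e. two triplicate groups). Zero pooled variance with unequal
#' means yields an infinite t and fails; with equal means, t = 0 passes.
#'
#' @param mean1,mean2 Group means.
#' @param sd1,sd2 Group standard deviations (>= 0).
#' @param n1,n2 Group sizes (>= 2).
#' @param t_crit Critical value (default 2.776).
#' @return A `comparison_result` list: `statistic`, `critical_value`,
#'   `pass` (|t| < t_crit), `df`, `p_value`.
#' @export
two_sample_t <- function(mean1, sd1, n1, mean2, sd2, n2, t_crit = 2.776) {
  check_nonnegative(sd1, "sd1"); check_nonnegative(sd2, "sd2")
  stopifnot(n1 >= 2, n2 >= 2)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  delta <- mean1 - mean2
  t_calc <- if (sp2 == 0) {
    if (delta == 0) 0 else Inf * sign(delta)
  } else {
    delta / sqrt(sp2 * (1 / n1 + 1 / n2))
  }
  p <- if (is.finite(t_calc)) 2 * stats::pt(-abs(t_calc), df) else 0
  structure(list(statistic = t_calc, critical_value = t_crit,
                 pass = abs(t_calc) < t_crit, df = df, p_value = p),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("statistic = %.4g vs critical %.4g (df %s): %s\n",
              x$statistic, x$critical_value,
              paste(x$df, collapse = ", "),
              if (x$pass) "no significant difference" else "significant difference"))
  invisible(x)
}

#' Pearson correlation with direction label
#'
#' Product-moment correlation between two paired series (e.g. total
#' phenolic content vs total element content across herb forms).
#'
#' @param x,y Numeric vectors of equal length >= 3 with nonzero variance.
#' @param label Optional label for the pair being correlated.
#' @return A `correlation_result` list: `r`, `direction`
#'   (`"positive"`/`"negative"`), `n`, `label`.
#' @export
pearson_r <- function(x, y, label = NULL) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: zero variance", call. = FALSE)
  }
  r <- stats::cor(x, y)
  structure(list(r = r,
                 direction = if (r >= 0) "positive" else "negative",
                 n = length(x), label = label),
            class = "correlation_result")
}

#' Overlap of expanded-uncertainty ranges
#'
#' Two results `v (1 ± U/100)` agree when their closed uncertainty
#' intervals intersect; boundary touching counts as overlap.
#'
#' @param value1,value2 Result values.
#' @param U1_percent,U2_percent Expanded uncertainties in percent (>= 0).
#' @return TRUE when the intervals overlap.
#' @export
#' @examples
#' uncertainty_overlap(10, 10, 10.5, 10) # TRUE
uncertainty_overlap <- function(value1, U1_percent, value2, U2_percent) {
  check_nonnegative(U1_percent, "U1_percent")
  check_nonnegative(U2_percent, "U2_percent")
  lo1 <- value1 * (1 - U1_percent / 100); hi1 <- value1 * (1 + U1_percent / 100)
  lo2 <- value2 * (1 - U2_percent / 100); hi2 <- value2 * (1 + U2_percent / 100)
  max(lo1, lo2) <= min(hi1, hi2)
}
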