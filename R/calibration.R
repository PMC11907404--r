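#' Fit an internal-standard-ratio calibration curve
#'
#' Ordinary least-squares fit of the linear calibration model
#' \eqn{y = b x + a}, where `y` is the analyte / internal-standard signal
#' ratio and `x` the standard concentration in ng/mL. The fit quality is
#' summarised by the Pearson correlation coefficient `r` of (x, y), the
#' figure of merit conventionally reported for ICP-MS calibrations.
#'
#' @param conc Numeric vector of standard concentrations (ng/mL), one per
#'   calibration level (>= 3 distinct non-negative values).
#' @param signal Numeric vector of mean signal ratios, same length as `conc`.
#' @return An object of class `calibration_curve`: a list with elements
#'   `slope`, `intercept`, `r`, `n_levels`, `range` (c(low, high) in ng/mL)
#'   and `quantitative` (FALSE for a flat or negative-slope response).
#' @export
#' @examples
#' fit_calibration(c(1, 2, 3), c(2, 4, 6))
fit_calibration <- function(conc, signal) {
  stopifnot(is.numeric(conc), is.numeric(signal), length(conc) == length(signal))
  if (any(!is.finite(conc)) || any(!is.finite(signal))) {
    stop("calibration levels must be finite", call. = FALSE)
  }
  if (any(conc < 0)) stop("concentrations must be >= 0", call. = FALSE)
  if (length(unique(conc)) < 3) {
    stop("degenerate calibration design: need >= 3 distinct concentration levels",
         call. = FALSE)
  }
  fit <- stats::lm(signal ~ conc)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  if (stats::sd(signal) == 0) { # flat response: exactly zero, not fp residue
    slope <- 0
    intercept <- signal[1]
  }
  r <- if (stats::sd(signal) == 0) NA_real_ else stats::cor(conc, signal)
  quantitative <- is.finite(r) && slope > 0
  if (!quantitative) {
    warning("non-quantitative calibration: flat or non-positive response",
            call. = FALSE)
  }
  structure(
    list(slope = slope, intercept = intercept, r = r,
         n_levels = length(conc), range = range(conc),
         quantitative = quantitative),
    class = "calibration_curve"
  )
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("Calibration curve: y = %.6g x + %.6g (r = %s, %d levels, %g-%g ng/mL)\n",
              x$slope, x$intercept,
              ifelse(is.na(x$r), "NA", sprintf("%.4f", x$r)),
              x$n_levels, x$range[1], x$range[2]))
  if (!x$quantitative) cat("  flagged non-quantitative\n")
  invisible(x)
}

#' Blank signal statistics
#'
#' @param signals Numeric vector of blank signal ratios (>= 2 values), or
#'   pass `mean` and `sd` directly with `n`.
#' @param mean,sd,n Alternative summary-statistics entry.
#' @return A `blank_stats` list with `mean`, `sd`, `n`.
#' @export
blank_stats <- function(signals = NULL, mean = NULL, sd = NULL, n = NULL) {
  if (!is.null(signals)) {
    stopifnot(is.numeric(signals), length(signals) >= 2)
    out <- list(mean = base::mean(signals), sd = stats::sd(signals),
                n = length(signals))
  } else {
    stopifnot(is.numeric(mean), is.numeric(sd), sd >= 0, n >= 2)
    out <- list(mean = mean, sd = sd, n = as.integer(n))
  }
  structure(out, class = "blank_stats")
}

#' Predict concentration from a signal ratio
#'
#' Inverts the calibration line: \eqn{c = (y - a) / b}. The returned value
#' may be negative for sub-blank signals; censoring is the caller's decision
#' (see [censor_below_loq()]).
#'
#' @param curve A [fit_calibration()] result.
#' @param signal Numeric vector of signal ratios.
#' @return Concentration(s) in ng/mL.
#' @export
predict_concentration <- function(curve, signal) {
  stopifnot(inherits(curve, "calibration_curve"), is.numeric(signal))
  if (curve$slope == 0) stop("non-quantitative curve: zero slope", call. = FALSE)
  (signal - curve$intercept) / curve$slope
}

#' Detection and quantification limits from blank statistics
#'
#' LOD is the concentration read from the calibration line at the blank
#' mean signal plus 3 blank SD; LOQ uses 10 blank SD. Both are floored at
#' zero (a blank mean below the intercept cannot yield a negative limit).
#'
#' @param curve A [fit_calibration()] result with positive slope.
#' @param blank A [blank_stats()] object.
#' @return Named numeric `c(lod = , loq = )` in ng/mL.
#' @export
#' @examples
#' cv <- fit_calibration(c(1, 5, 10), c(1, 5, 10))
#' detection_limits(cv, blank_stats(mean = 0, sd = 1, n = 10))
detection_limits <- function(curve, blank) {
  stopifnot(inherits(curve, "calibration_curve"), inherits(blank, "blank_stats"))
  if (curve$slope <= 0) stop("detection limits require a positive slope", call. = FALSE)
  lod <- (blank$mean + 3 * blank$sd - curve$intercept) / curve$slope
  loq <- (blank$mean + 10 * blank$sd - curve$intercept) / curve$slope
  c(lod = max(0, lod), loq = max(0, loq))
}

#' Censor concentrations below the limit of quantification
#'
#' Marks values below `loq` as censored while retaining the numeric value,
#' mirroring report tables that print "<LOQ" but exclude the cell from sums.
#'
#' @param x Numeric concentrations.
#' @param loq Limit of quantification (same units as `x`).
#' @return A tibble with columns `value`, `censored`, `label`.
#' @export
censor_below_loq <- function(x, loq) {
  check_nonnegative(loq, "loq")
  tibble::tibble(
    value = x,
    censored = x < loq,
    label = ifelse(x < loq, "<LOQ", formatC(x, format = "g"))
  )
}

#' Precision as the per-level CV range
#'
#' Per-level coefficient of variation (100 * sample SD / mean) of replicate
#' signal intensities of standard solutions; returns the (min, max) range
#' over levels, the way precision is reported for a multi-level calibration.
#'
#' @param replicates_per_level List of numeric vectors, one per concentration
#'   level, each with >= 2 replicates.
#' @return Named numeric `c(min = , max = )` in percent.
#' @export
precision_cv <- function(replicates_per_level) {
  stopifnot(is.list(replicates_per_level), length(replicates_per_level) >= 1)
  cvs <- vapply(replicates_per_level, function(v) {
    stopifnot(is.numeric(v), length(v) >= 2)
    m <- mean(v)
    if (m == 0) stop("undefined CV: level with zero mean signal", call. = FALSE)
    100 * stats::sd(v) / m
  }, numeric(1))
  c(min = min(cvs), max = max(cvs))
}

#' Repeatability CV over a multi-day determination series
#'
#' CV of repeated determinations of the same material (e.g. a CRM measured
#' in triplicate on several days). The default pools all day-by-replicate
#' values into one sample SD / mean; `method = "day_means"` computes the CV
#' of the per-day mean values instead.
#'
#' @param determinations Numeric vector of content values (>= 2).
#' @param day Optional grouping vector (required for `"day_means"`).
#' @param method `"pooled"` (default) or `"day_means"`.
#' @return Repeatability CV in percent.
#' @export
repeatability_cv <- function(determinations, day = NULL,
                             method = c("pooled", "day_means")) {
  method <- match.arg(method)
  stopifnot(is.numeric(determinations), length(determinations) >= 2)
  vals <- determinations
  if (method == "day_means") {
    if (is.null(day)) stop("`day` is required for method = \"day_means\"", call. = FALSE)
    vals <- tapply(determinations, day, mean)
    if (length(vals) < 2) stop("need >= 2 days for day-mean repeatability", call. = FALSE)
  }
  m <- mean(vals)
  if (m == 0) stop("undefined CV: zero mean", call. = FALSE)
  100 * stats::sd(vals) / m
}

#' Certified reference material entry
#'
#' @param element Element symbol.
#' @param certified_value Certified content (positive; μg/g or ng/g).
#' @param expanded_uncertainty Expanded uncertainty (same units, k = 2).
#' @return A `crm_reference` list.
#' @export
crm_reference <- function(element, certified_value, expanded_uncertainty = NA_real_) {
  check_positive(certified_value, "certified_value")
  structure(list(element = element, certified_value = certified_value,
                 expanded_uncertainty = expanded_uncertainty),
            class = "crm_reference")
}

#' Recovery against a certified reference material
#'
#' @param found Determined content (same units as the certified value).
#' @param crm A [crm_reference()] object.
#' @return Recovery in percent (100 * found / certified).
#' @export
#' @examples
#' recovery(1.521, crm_reference("Cr", 1.69, 0.13))
recovery <- function(found, crm) {
  stopifnot(inherits(crm, "crm_reference"), is.numeric(found))
  100 * found / crm$certified_value
}

#' Trueness one-sample t-test on recoveries
#'
#' Tests whether mean recovery differs from the reference (100 %):
#' \eqn{t = (\bar{x} - \mu_0) / (s / \sqrt{n})}. The method passes when
#' |t_calc| < t_crit. A zero-SD sample with mean off the reference yields
#' an infinite t and fails.
#'
#' @param recoveries Numeric vector of recoveries in percent (>= 2 values).
#' @param reference Reference recovery (default 100).
#' @param t_crit Critical value (default 2.776; the df convention is the
#'   caller's, supply `t_crit = qt(0.975, df)` to change it).
#' @return List with `t_calc`, `df`, `pass`, `p_value`.
#' @export
trueness_t_test <- function(recoveries, reference = 100, t_crit = 2.776) {
  stopifnot(is.numeric(recoveries), length(recoveries) >= 2)
  n <- length(recoveries)
  s <- stats::sd(recoveries)
  delta <- mean(recoveries) - reference
  t_calc <- if (s == 0) {
    if (delta == 0) 0 else Inf * sign(delta)
  } else {
    delta / (s / sqrt(n))
  }
  df <- n - 1
  p <- if (is.finite(t_calc)) 2 * stats::pt(-abs(t_calc), df) else 0
  list(t_calc = t_calc, df = df, pass = abs(t_calc) < t_crit, p_value = p)
}

#' Expanded uncertainty from repeatability and recovery components
#'
#' Combined standard uncertainty as the root-sum-of-squares of the relative
#' repeatability and recovery standard uncertainties, expanded by the
#' coverage factor k (k = 2 for ~95 % coverage).
#'
#' @param u_repeat Relative standard uncertainty of repeatability (%).
#' @param u_recovery Relative standard uncertainty of recovery (%).
#' @param k Coverage factor (default 2).
#' @return Expanded uncertainty U in percent.
#' @export
#' @examples
#' uncertainty_budget(3, 4) # 2 * sqrt(9 + 16) = 10
uncertainty_budget <- function(u_repeat, u_recovery, k = 2) {
  check_nonnegative(u_repeat, "u_repeat")
  check_nonnegative(u_recovery, "u_recovery")
  check_positive(k, "k")
  k * sqrt(u_repeat^2 + u_recovery^2)
}

#' Method-validation report for a panel of analytes
#'
#' Assembles the per-element validation table (correlation coefficient,
#' LOD/LOQ, precision CV range, repeatability CV, mean recovery with SD,
#' trueness t, expanded uncertainty) from replicate-level calibration
#' signals, blank replicates and CRM determinations.
#'
#' @param signals Tibble with columns `element`, `conc`, `replicate`,
#'   `signal` (calibration standards, replicate signal ratios per level).
#' @param blanks Tibble with columns `element`, `signal` (blank replicates).
#' @param crm_found Tibble with columns `element`, `content` (CRM
#'   determinations) plus optionally `day` for repeatability grouping.
#' @param crm_values Named numeric vector of certified values per element.
#' @param t_crit Critical t for the trueness test.
#' @param k Coverage factor for the uncertainty budget.
#' @return Tibble, one row per element, validation-table shaped.
#' @export
validation_report <- function(signals, blanks, crm_found, crm_values,
                              t_crit = 2.776, k = 2) {
  stopifnot(all(c("element", "conc", "signal") %in% names(signals)),
            all(c("element", "signal") %in% names(blanks)),
            all(c("element", "content") %in% names(crm_found)))
  elements <- unique(signals$element)
  rows <- lapply(elements, function(el) {
    sig <- signals[signals$element == el, ]
    lvl <- dplyr::summarise(dplyr::group_by(sig, .data$conc),
                            mean_signal = mean(.data$signal), .groups = "drop")
    curve <- fit_calibration(lvl$conc, lvl$mean_signal)
    blk <- blank_stats(blanks$signal[blanks$element == el])
    lims <- detection_limits(curve, blk)
    prec <- precision_cv(split(sig$signal, sig$conc))
    found <- crm_found$content[crm_found$element == el]
    rep_cv <- repeatability_cv(found)
    recs <- recovery(found, crm_reference(el, crm_values[[el]]))
    tt <- trueness_t_test(recs, t_crit = t_crit)
    u_rec <- stats::sd(recs) / sqrt(length(recs))
    tibble::tibble(
      element = el, r = curve$r,
      lod_ng_mL = lims[["lod"]], loq_ng_mL = lims[["loq"]],
      precision_cv_min = prec[["min"]], precision_cv_max = prec[["max"]],
      repeatability_cv = rep_cv,
      recovery_mean = mean(recs), recovery_sd = stats::sd(recs),
      t_calc = tt$t_calc, trueness_pass = tt$pass,
      expanded_U = uncertainty_budget(rep_cv, u_rec, k = k)
    )
  })
  dplyr::bind_rows(rows)
}
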