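#' Sample specification for a digested herb sample
#'
#' Default sample masses follow the digestion protocol: 2.5 g for fresh,
#' dried and supplement forms, 0.5 g for lyophilizates (a lyophilizate
#' portion equivalent to 2.5 g of fresh plant). Default water fractions are
#' the gravimetric values for the fresh herbs: basil 89.6 %, peppermint
#' 85.1 %, rosemary 74.4 %.
#'
#' @param herb One of `"basil"`, `"peppermint"`, `"rosemary"`.
#' @param form One of `"fresh"`, `"lyophilizate"`, `"dried"`, `"supplement"`.
#' @param mass_g Sample mass in grams (defaults by form, see above).
#' @param water_fraction Water mass fraction in `[0, 1]` (defaults by herb
#'   for fresh forms, 0 otherwise).
#' @return A `sample_spec` list.
#' @export
sample_spec <- function(herb = c("basil", "peppermint", "rosemary"),
                        form = c("fresh", "lyophilizate", "dried", "supplement"),
                        mass_g = NULL, water_fraction = NULL) {
  herb <- match.arg(herb)
  form <- match.arg(form)
  if (is.null(mass_g)) mass_g <- if (form == "lyophilizate") 0.5 else 2.5
  check_positive(mass_g, "mass_g")
  if (is.null(water_fraction)) {
    water_fraction <- if (form == "fresh") {
      c(basil = 0.896, peppermint = 0.851, rosemary = 0.744)[[herb]]
    } else 0
  }
  stopifnot(water_fraction >= 0, water_fraction < 1)
  structure(list(herb = herb, form = form, mass_g = mass_g,
                 water_fraction = water_fraction),
            class = "sample_spec")
}

#' Digestion vessel and dialysis volumes
#'
#' Default volumes follow the two-stage protocol: 15 mL pepsin solution
#' (gastric stage), 5 mL pancreatin/bile solution (intestinal stage),
#' 60 mL dialysate water outside the membrane. The in-tube volume `v_tube`
#' defaults to the sum of the two added enzyme solutions (20 mL); the
#' bicarbonate titrant and sample moisture are not counted, and the value
#' is fully configurable.
#'
#' @param v_pepsin_mL,v_pancreatin_mL,v_dialysate_mL,v_tube_mL Volumes (mL).
#' @return A `digestion_setup` list.
#' @export
digestion_setup <- function(v_pepsin_mL = 15, v_pancreatin_mL = 5,
                            v_dialysate_mL = 60,
                            v_tube_mL = v_pepsin_mL + v_pancreatin_mL) {
  for (v in c(v_pepsin_mL, v_pancreatin_mL, v_dialysate_mL, v_tube_mL)) {
    check_positive(v, "volume")
  }
  structure(list(v_pepsin_mL = v_pepsin_mL, v_pancreatin_mL = v_pancreatin_mL,
                 v_dialysate_mL = v_dialysate_mL, v_tube_mL = v_tube_mL),
            class = "digestion_setup")
}

#' Convert a measured solution concentration to content per gram of sample
#'
#' \eqn{content = c \cdot V \cdot f / (m \cdot 1000)} with `c` in ng/mL,
#' `V` the final solution volume in mL, `f` the dilution factor and `m`
#' the sample mass in g, giving μg per g of sample.
#'
#' @param c_solution Solution concentration (ng/mL), non-negative.
#' @param v_final_mL Final solution volume (mL).
#' @param dilution_factor Dilution factor applied before measurement.
#' @param mass_g Sample mass (g).
#' @return Content in μg/g.
#' @export
#' @examples
#' content_per_gram(100, 10, 1, 0.1) # 10 ug/g
content_per_gram <- function(c_solution, v_final_mL, dilution_factor, mass_g) {
  check_nonnegative(c_solution, "c_solution")
  check_positive(v_final_mL, "v_final_mL")
  check_positive(dilution_factor, "dilution_factor")
  check_positive(mass_g, "mass_g")
  c_solution * v_final_mL * dilution_factor / (mass_g * 1000)
}

#' Amount of an element in a fraction of the digested sample
#'
#' @param content Content in μg per g of sample.
#' @param sample A [sample_spec()] (or a bare mass in grams).
#' @return Amount in μg in the digestion vessel.
#' @export
amount_in_fraction <- function(content, sample) {
  check_nonnegative(content, "content")
  mass <- if (inherits(sample, "sample_spec")) sample$mass_g else sample
  check_positive(mass, "mass_g")
  content * mass
}

#' Convert an as-received (wet-basis) content to dry basis
#'
#' @param content Content in μg/g as received.
#' @param water_fraction Water mass fraction in `[0, 1)`.
#' @return Content in μg per g of dry matter.
#' @export
dry_basis <- function(content, water_fraction) {
  stopifnot(water_fraction >= 0, water_fraction < 1)
  content / (1 - water_fraction)
}

#' Mass-balance agreement between fractions and total content
#'
#' Compares the sum of the dialyzable and nondialyzable fraction contents
#' with the independently determined total content:
#' agreement (%) = 100 * (dialyzable + nondialyzable) / total. SDs are
#' propagated in quadrature for the sum and in relative quadrature for the
#' ratio. An agreement within \[80, 120\] % is flagged quantitative. A
#' censored (NA) fraction makes the balance unavailable, mirroring report
#' tables that leave such cells blank.
#'
#' @param dialyzable,nondialyzable,total Contents in μg/g (NA = censored
#'   fraction; `total` must be positive).
#' @param sd_dialyzable,sd_nondialyzable,sd_total Optional SDs (μg/g).
#' @return A `mass_balance` list: `sum`, `sum_sd`, `agreement`,
#'   `agreement_sd`, `quantitative`, `available`.
#' @export
#' @examples
#' mass_balance(12.8, 34.7, 46.7) # agreement ~ 101.7 %
mass_balance <- function(dialyzable, nondialyzable, total,
                         sd_dialyzable = 0, sd_nondialyzable = 0, sd_total = 0) {
  check_positive(total, "total")
  if (is.na(dialyzable) || is.na(nondialyzable)) {
    return(structure(list(sum = NA_real_, sum_sd = NA_real_,
                          agreement = NA_real_, agreement_sd = NA_real_,
                          quantitative = NA, available = FALSE),
                     class = "mass_balance"))
  }
  check_nonnegative(dialyzable, "dialyzable")
  check_nonnegative(nondialyzable, "nondialyzable")
  s <- dialyzable + nondialyzable
  s_sd <- sqrt(sd_dialyzable^2 + sd_nondialyzable^2)
  agreement <- 100 * s / total
  agreement_sd <- if (s > 0) {
    agreement * sqrt((s_sd / s)^2 + (sd_total / total)^2)
  } else 0
  structure(list(sum = s, sum_sd = s_sd,
                 agreement = agreement, agreement_sd = agreement_sd,
                 quantitative = agreement >= 80 && agreement <= 120,
                 available = TRUE),
            class = "mass_balance")
}

#' Percentage of the dialyzable fraction in the recovered element
#'
#' Share of the element found in the dialyzable fraction relative to the
#' sum present in both fractions: 100 * D / (D + T). Amount or content
#' basis give the same share for a single sample.
#'
#' @param D Dialyzable amount (μg) or content (μg/g), >= 0.
#' @param T_ Nondialyzable amount or content (same basis), >= 0.
#' @return Share in percent, in `[0, 100]`.
#' @export
dialyzable_share <- function(D, T_) {
  check_nonnegative(D, "D")
  check_nonnegative(T_, "T_")
  if (any(D + T_ == 0)) stop("undefined share: D + T = 0", call. = FALSE)
  100 * D / (D + T_)
}
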