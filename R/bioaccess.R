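#' Equilibrium correction for the dialyzable amount
#'
#' Amount of dialyzable element still inside the dialysis tube at
#' concentration equilibrium across the membrane. If the dialyzable amount
#' `D` equilibrated into the dialysate volume `V_d`, the same concentration
#' occupies the tube volume `V_t`, so \eqn{D_r = D \cdot V_t / V_d}.
#'
#' @param D Dialyzable amount (μg), >= 0.
#' @param setup A [digestion_setup()] object.
#' @return D_r in μg.
#' @export
#' @examples
#' equilibrium_correction(0.9, digestion_setup()) # 0.9 * 20/60 = 0.3
equilibrium_correction <- function(D, setup = digestion_setup()) {
  check_nonnegative(D, "D")
  stopifnot(inherits(setup, "digestion_setup"))
  D * setup$v_tube_mL / setup$v_dialysate_mL
}

#' Bioaccessibility percentage of an element
#'
#' The dialysis-equilibrium-corrected bioaccessibility statistic. Three
#' algebraic variants are provided, because the three quantities D, D_r, T
#' admit more than one defensible combination and every result records
#' which one produced it:
#'
#' * `"corrected_share"` (default): \eqn{B = 100 (D + D_r) / (D + T)} —
#'   D_r is physically part of the in-tube residue T but sits at dialyzable
#'   equilibrium concentration, so it counts as bioaccessible.
#' * `"literal"`: \eqn{B = 100 D / (D_r + T)}.
#' * `"uncorrected"`: \eqn{B = 100 D / (D + T)} — the plain dialyzable share.
#'
#' When `D_r <= T` the corrected share cannot exceed 100; a value above 100
#' indicates a mass-balance inconsistency and raises a warning (never a
#' silent clamp).
#'
#' @param D Dialyzable amount (μg).
#' @param D_r Equilibrium-corrected in-tube amount (μg), from
#'   [equilibrium_correction()].
#' @param T_ Nondialyzable amount (μg).
#' @param variant One of `"corrected_share"`, `"literal"`, `"uncorrected"`.
#' @return B in percent, with the variant attached as attribute `"variant"`.
#' @export
#' @examples
#' D <- 0.8; T_ <- 0.95
#' bioaccessibility(D, equilibrium_correction(D), T_) # ~ 61.0
bioaccessibility <- function(D, D_r, T_,
                             variant = c("corrected_share", "literal", "uncorrected")) {
  variant <- match.arg(variant)
  check_nonnegative(D, "D")
  check_nonnegative(D_r, "D_r")
  check_nonnegative(T_, "T_")
  denom <- switch(variant,
    corrected_share = D + T_,
    literal = D_r + T_,
    uncorrected = D + T_
  )
  if (any(denom == 0)) stop("undefined bioaccessibility: zero denominator", call. = FALSE)
  B <- switch(variant,
    corrected_share = 100 * (D + D_r) / (D + T_),
    literal = 100 * D / (D_r + T_),
    uncorrected = 100 * D / (D + T_)
  )
  if (variant == "corrected_share" && any(B > 100)) {
    warning("bioaccessibility above 100 %: D_r exceeds T, mass-balance inconsistency",
            call. = FALSE)
  }
  structure(B, variant = variant)
}

#' Bioaccessibility table for a full study
#'
#' Computes B% for every (herb, form, element) cell from per-gram fraction
#' contents, converting to amounts with the per-form sample masses and
#' applying the equilibrium correction. SD on B is propagated by relative
#' quadrature from the fraction-content SDs (volume uncertainty ignored).
#' Cells with a censored (NA) dialyzable or nondialyzable content yield
#' `B = NA` and `censored = TRUE`.
#'
#' @param records Tibble with columns `herb`, `form`, `element`,
#'   `dialyzable`, `nondialyzable` (μg/g; NA = censored) and optionally
#'   `sd_dialyzable`, `sd_nondialyzable`.
#' @param setup A [digestion_setup()].
#' @param variant Bioaccessibility variant, see [bioaccessibility()].
#' @param mass_g Optional named override of the per-form default masses.
#' @return Long tibble: herb, form, element, D, D_r, T (μg), B, sd_B,
#'   censored, variant.
#' @export
bioaccess_table <- function(records, setup = digestion_setup(),
                            variant = c("corrected_share", "literal", "uncorrected"),
                            mass_g = NULL) {
  variant <- match.arg(variant)
  req <- c("herb", "form", "element", "dialyzable", "nondialyzable")
  missing_cols <- setdiff(req, names(records))
  if (length(missing_cols) > 0) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"sd_dialyzable" %in% names(records)) records$sd_dialyzable <- 0
  if (!"sd_nondialyzable" %in% names(records)) records$sd_nondialyzable <- 0

  kr <- setup$v_tube_mL / setup$v_dialysate_mL
  rows <- lapply(seq_len(nrow(records)), function(i) {
    rec <- records[i, ]
    mass <- if (!is.null(mass_g)) {
      mass_g[[rec$form]]
    } else {
      sample_spec(rec$herb, rec$form)$mass_g
    }
    censored <- is.na(rec$dialyzable) || is.na(rec$nondialyzable)
    if (censored) {
      return(tibble::tibble(herb = rec$herb, form = rec$form, element = rec$element,
                            D = NA_real_, D_r = NA_real_, T_amount = NA_real_,
                            B = NA_real_, sd_B = NA_real_, censored = TRUE))
    }
    D <- amount_in_fraction(rec$dialyzable, mass)
    T_ <- amount_in_fraction(rec$nondialyzable, mass)
    D_r <- D * kr
    B <- as.numeric(suppressWarnings(bioaccessibility(D, D_r, T_, variant)))
    sd_D <- rec$sd_dialyzable * mass
    sd_T <- rec$sd_nondialyzable * mass
    num <- switch(variant, corrected_share = D + D_r, literal = D, uncorrected = D)
    sd_num <- switch(variant, corrected_share = (1 + kr) * sd_D,
                     literal = sd_D, uncorrected = sd_D)
    den <- switch(variant, corrected_share = D + T_, literal = D_r + T_,
                  uncorrected = D + T_)
    sd_den <- switch(variant,
                     corrected_share = sqrt(sd_D^2 + sd_T^2),
                     literal = sqrt((kr * sd_D)^2 + sd_T^2),
                     uncorrected = sqrt(sd_D^2 + sd_T^2))
    sd_B <- if (num > 0) B * sqrt((sd_num / num)^2 + (sd_den / den)^2) else 0
    tibble::tibble(herb = rec$herb, form = rec$form, element = rec$element,
                   D = D, D_r = D_r, T_amount = T_, B = B, sd_B = sd_B,
                   censored = FALSE)
  })
  out <- dplyr::bind_rows(rows)
  out$variant <- variant
  out
}

#' Wide bioaccessibility matrix for heatmap rendering
#'
#' Pivots a [bioaccess_table()] result into a dense (herb, form) x element
#' matrix of B%, with censored cells as NA. Row names are `herb:form`.
#'
#' @param records,setup,variant,mass_g Passed to [bioaccess_table()], or
#'   pass a precomputed long table as `records` with `long = TRUE`.
#' @param long Set TRUE when `records` is already a [bioaccess_table()]
#'   output.
#' @return Numeric matrix of B% with attribute `"variant"`.
#' @export
bioaccess_matrix <- function(records, setup = digestion_setup(),
                             variant = c("corrected_share", "literal", "uncorrected"),
                             mass_g = NULL, long = FALSE) {
  tab <- if (long) records else bioaccess_table(records, setup, variant, mass_g)
  variant <- tab$variant[1]
  wide <- tidyr::pivot_wider(
    dplyr::mutate(tab, row = paste(.data$herb, .data$form, sep = ":")),
    id_cols = "row", names_from = "element", values_from = "B"
  )
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$row
  attr(m, "variant") <- variant
  m
}
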