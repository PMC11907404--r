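#' Total phenolic content assay definition
#'
#' A Folin-Ciocalteu assay: a gallic-acid standard curve (absorbance at
#' 752 nm vs μg/mL gallic acid, standards spanning 20–300 μg/mL), the
#' sample absorbance, and the extraction bookkeeping. Defaults follow the
#' extraction protocol: 50 mg of plant material in 5 mL of acidified 50 %
#' methanol; extracts of lyophilized/dried/supplement material are diluted
#' 10-fold before the colour reaction, fresh-herb extracts are not.
#'
#' @param standard_curve A [fit_calibration()] result (absorbance vs μg/mL
#'   gallic acid).
#' @param sample_absorbance Measured absorbance (>= 0).
#' @param dilution_factor Extract dilution before the reaction (10 for
#'   lyophilized/dried/supplement, 1 for fresh).
#' @param extract_volume_mL Extraction solution volume (mL, default 5).
#' @param sample_mass_g Extracted sample mass (g, default 0.05).
#' @return A `tpc_assay` list.
#' @export
tpc_assay <- function(standard_curve, sample_absorbance, dilution_factor = 1,
                      extract_volume_mL = 5, sample_mass_g = 0.05) {
  stopifnot(inherits(standard_curve, "calibration_curve"))
  check_nonnegative(sample_absorbance, "sample_absorbance")
  check_positive(dilution_factor, "dilution_factor")
  check_positive(extract_volume_mL, "extract_volume_mL")
  check_positive(sample_mass_g, "sample_mass_g")
  structure(list(standard_curve = standard_curve,
                 sample_absorbance = sample_absorbance,
                 dilution_factor = dilution_factor,
                 extract_volume_mL = extract_volume_mL,
                 sample_mass_g = sample_mass_g),
            class = "tpc_assay")
}

#' Total phenolic content in mg gallic acid per g of herb
#'
#' Reads the extract concentration off the gallic-acid curve,
#' \eqn{c = (A - a)/b} in μg/mL, and accounts for dilution and extraction:
#' \eqn{TPC = c \cdot f \cdot V / (m \cdot 1000)} mg GAE per g. A predicted
#' concentration outside the standard-curve range is returned with
#' attribute `extrapolated = TRUE`.
#'
#' @param assay A [tpc_assay()].
#' @return TPC in mg gallic-acid equivalents per g of sample, with
#'   attributes `conc_ug_mL` and `extrapolated`.
#' @export
#' @examples
#' curve <- fit_calibration(c(20, 100, 300), 0.005 * c(20, 100, 300))
#' tpc_mg_per_g(tpc_assay(curve, 0.5)) # 10 mg/g
tpc_mg_per_g <- function(assay) {
  stopifnot(inherits(assay, "tpc_assay"))
  curve <- assay$standard_curve
  if (curve$slope <= 0) stop("non-quantitative gallic-acid curve", call. = FALSE)
  conc <- predict_concentration(curve, assay$sample_absorbance)
  extrapolated <- conc < curve$range[1] || conc > curve$range[2]
  tpc <- conc * assay$dilution_factor * assay$extract_volume_mL /
    (assay$sample_mass_g * 1000)
  structure(tpc, conc_ug_mL = conc, extrapolated = extrapolated)
}
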