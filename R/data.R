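#' Printed study fraction table for basil, peppermint and rosemary
#'
#' Loads the shipped per-gram element contents (total, dialyzable and
#' nondialyzable fractions, with replicate SDs, n = 3) for three herbs in
#' four forms and five elements (Cr, Mn, Fe, Cu, Zn), together with the
#' published sum and mass-balance agreement columns for cross-checking.
#' The one below-LOQ cell (Cr, dried rosemary, dialyzable fraction) is NA.
#' All contents are μg per g of sample as received (wet basis for fresh).
#'
#' @param path Optional alternative CSV in the same layout.
#' @return Tibble with columns herb, form, element, total, sd_total,
#'   dialyzable, sd_dialyzable, nondialyzable, sd_nondialyzable,
#'   sum_printed, sd_sum_printed, agreement_printed, sd_agreement_printed.
#' @export
herb_panel <- function(path = system.file("extdata", "herb_panel.csv",
                                          package = "herbdial")) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Published content extremes of toxic elements in the tested herbs
#'
#' Minimum and maximum total contents (ng/g) of Cd, As, Pb and Ni over all
#' tested herb/form combinations, used as inputs to the exposure indices.
#'
#' @param path Optional alternative CSV in the same layout.
#' @return Tibble with columns element, unit, min_ng_g, max_ng_g.
#' @export
toxic_content_extremes <- function(path = system.file("extdata",
                                                      "toxic_content_extremes.csv",
                                                      package = "herbdial")) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Certified reference material values (mixed Polish herbs CRM)
#'
#' Certified contents used for trueness/recovery quality control.
#' Values are μg/g except As, Cd, Hg and Co which are ng/g; the unit
#' column records which.
#'
#' @return Tibble with columns element, certified, expanded_uncertainty,
#'   unit.
#' @export
crm_certified_values <- function() {
  tibble::tribble(
    ~element, ~certified, ~expanded_uncertainty, ~unit,
    "Cr",   1.69, 0.13, "ug/g",
    "Mn",  191,  12,   "ug/g",
    "Fe",  460,  NA,   "ug/g",
    "Co",  210,  25,   "ng/g",
    "Ni",   1.57, 0.16, "ug/g",
    "Cu",   7.77, 0.53, "ug/g",
    "Zn",  33.5,  2.1, "ug/g",
    "As", 191,   23,   "ng/g",
    "Cd", 199,   15,   "ng/g",
    "Hg",  17.6,  1.6, "ng/g",
    "Pb",   2.16, 0.23, "ug/g"
  )
}
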