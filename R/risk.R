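#' Reference-dose registry
#'
#' Loads the PTMI / BMDL / RDA / EU-limit registry from a YAML file. The
#' file shipped with the package carries the values used throughout:
#' PTMI Cd 25 μg/kg b.w. per month; BMDL As (skin cancer) 0.06, Pb (kidney)
#' 0.63 and Pb (cardiovascular) 1.50 μg/kg b.w. per day; Polish RDA for
#' adults 31–50 (Mn 1.8/2.3, Fe 18/10, Cu 0.9/0.9, Zn 8/11 mg/day for
#' women/men); EU maximum levels Cd 0.1 μg/g in herbs, Cd 1 and Pb 3 μg/g
#' in dietary supplements.
#'
#' @param path Path to a registry YAML (default: the shipped registry).
#' @return A `reference_doses` list of tibbles: `ptmi`, `bmdl`, `rda`,
#'   `eu_limits`.
#' @export
reference_doses <- function(path = system.file("extdata", "reference_doses.yaml",
                                               package = "herbdial")) {
  raw <- yaml::read_yaml(path)
  as_tbl <- function(x) dplyr::bind_rows(lapply(x, tibble::as_tibble))
  doses <- structure(list(
    ptmi = tibble::tibble(element = names(raw$ptmi),
                          value = as.numeric(unlist(raw$ptmi))),
    bmdl = as_tbl(raw$bmdl),
    rda = as_tbl(raw$rda),
    eu_limits = as_tbl(raw$eu_limits)
  ), class = "reference_doses")
  stopifnot(all(doses$ptmi$value > 0), all(doses$bmdl$value > 0),
            all(doses$rda$value > 0), all(doses$eu_limits$value > 0))
  doses
}

#' Dietary exposure scenario
#'
#' Defaults describe the assessment scenario used throughout: an adult of
#' 60 kg consuming 1 g of herb per day, a 30-day month for monthly intake,
#' and a 25 g fresh-leaf portion (a pesto serving) for serving-based RDA
#' coverage.
#'
#' @param intake_g_per_day Daily herb intake (g).
#' @param body_weight_kg Body weight (kg).
#' @param days_per_month Days per month for PTMI time base.
#' @param portion_g Serving size (g) for serving-based coverage.
#' @return An `exposure_scenario` list.
#' @export
exposure_scenario <- function(intake_g_per_day = 1, body_weight_kg = 60,
                              days_per_month = 30, portion_g = 25) {
  for (v in c(intake_g_per_day, body_weight_kg, days_per_month, portion_g)) {
    check_positive(v, "scenario value")
  }
  structure(list(intake_g_per_day = intake_g_per_day,
                 body_weight_kg = body_weight_kg,
                 days_per_month = days_per_month,
                 portion_g = portion_g),
            class = "exposure_scenario")
}

lookup_dose <- function(tbl, what, ...) {
  keys <- list(...)
  idx <- rep(TRUE, nrow(tbl))
  for (k in names(keys)) idx <- idx & tbl[[k]] == keys[[k]]
  if (sum(idx) != 1) {
    stop(sprintf("no unique %s entry for %s", what,
                 paste(unlist(keys), collapse = "/")), call. = FALSE)
  }
  tbl$value[idx]
}

#' Percent of the provisional tolerable monthly intake (PTMI)
#'
#' Monthly contaminant dose from daily herb consumption, relative to the
#' PTMI: 100 * (content/1000 * intake * days_per_month / bw) / PTMI, with
#' content in ng/g.
#'
#' @param content_ng_g Element content in ng per g of herb.
#' @param element Element symbol with a PTMI entry (e.g. `"Cd"`).
#' @param scenario An [exposure_scenario()].
#' @param doses A [reference_doses()] registry.
#' @return Percent of PTMI.
#' @export
#' @examples
#' ptmi_percent(115, "Cd") # 0.23 %
ptmi_percent <- function(content_ng_g, element = "Cd",
                         scenario = exposure_scenario(),
                         doses = reference_doses()) {
  check_nonnegative(content_ng_g, "content_ng_g")
  ptmi <- lookup_dose(doses$ptmi, "PTMI", element = element)
  monthly <- content_ng_g / 1000 * scenario$intake_g_per_day *
    scenario$days_per_month / scenario$body_weight_kg
  100 * monthly / ptmi
}

#' Percent of the benchmark dose lower confidence limit (BMDL)
#'
#' Daily dose from herb consumption relative to the BMDL:
#' 100 * (content/1000 * intake / bw) / BMDL, with content in ng/g.
#'
#' @param content_ng_g Element content in ng per g of herb.
#' @param element Element symbol.
#' @param endpoint Toxicological endpoint keying the BMDL (required where
#'   several exist, e.g. `"kidney"` vs `"cardiovascular"` for Pb).
#' @param scenario An [exposure_scenario()].
#' @param doses A [reference_doses()] registry.
#' @return Percent of BMDL.
#' @export
#' @examples
#' bmdl_percent(1148, "As", "skin_cancer") # ~ 31.9 %
bmdl_percent <- function(content_ng_g, element, endpoint,
                         scenario = exposure_scenario(),
                         doses = reference_doses()) {
  check_nonnegative(content_ng_g, "content_ng_g")
  bmdl <- lookup_dose(doses$bmdl, "BMDL", element = element, endpoint = endpoint)
  daily <- content_ng_g / 1000 * scenario$intake_g_per_day /
    scenario$body_weight_kg
  100 * daily / bmdl
}

#' Percent of the recommended dietary allowance (RDA) covered
#'
#' Coverage of the daily allowance by one portion:
#' 100 * content * portion / RDA, with content in μg/g and RDA in μg/day.
#'
#' @param content_ug_g Element content in μg per g of herb.
#' @param element Element symbol.
#' @param sex `"women"` or `"men"`.
#' @param portion_g Portion size in g (default 1 g daily intake).
#' @param doses A [reference_doses()] registry.
#' @return Percent of RDA.
#' @export
#' @examples
#' rda_percent(46.7, "Mn", "women", portion_g = 25) # ~ 64.9 %
rda_percent <- function(content_ug_g, element, sex = c("women", "men"),
                        portion_g = 1, doses = reference_doses()) {
  sex <- match.arg(sex)
  check_nonnegative(content_ug_g, "content_ug_g")
  check_positive(portion_g, "portion_g")
  rda <- lookup_dose(doses$rda, "RDA", element = element, sex = sex)
  100 * content_ug_g * portion_g / rda
}

#' EU regulatory-limit check
#'
#' @param content_ug_g Element content in μg/g.
#' @param element Element symbol.
#' @param category Food category of the limit (`"herbs"` or `"supplements"`).
#' @param doses A [reference_doses()] registry.
#' @return List with `pass` (content <= limit), `limit` and `margin`
#'   (limit - content, μg/g).
#' @export
eu_limit_check <- function(content_ug_g, element, category,
                           doses = reference_doses()) {
  check_nonnegative(content_ug_g, "content_ug_g")
  limit <- lookup_dose(doses$eu_limits, "EU limit",
                       element = element, category = category)
  list(pass = content_ug_g <= limit, limit = limit,
       margin = limit - content_ug_g)
}

#' Endpoint range of a set of index values
#'
#' Min/max endpoints of a vector of percentages, rounded half-up to 2
#' significant figures for reporting; the unrounded endpoints are kept as
#' attribute `"raw"`.
#'
#' @param values Non-empty numeric vector of percentages.
#' @return Named numeric `c(min = , max = )` (rounded), with `attr(, "raw")`.
#' @export
range_summary <- function(values) {
  stopifnot(is.numeric(values), length(values) >= 1, all(is.finite(values)))
  raw <- c(min = min(values), max = max(values))
  structure(signif_half_up(raw, 2), raw = raw, names = names(raw))
}
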