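#' Default per-element measurement CVs
#'
#' Relative measurement SDs (percent) per element, taken from the method's
#' repeatability figures (3.7–9.9 % depending on element).
#'
#' @return Named numeric vector of CVs in percent.
#' @export
default_measurement_cv <- function() {
  c(Cr = 3.7, Mn = 5.1, Fe = 6.6, Co = 8.5, Ni = 7.9,
    Cu = 7.8, Zn = 7.4, As = 7.3, Cd = 8.5, Pb = 9.9)
}

#' Default instrument truth per element for the generator
#'
#' Latent calibration line (slope, intercept in signal-ratio units), blank
#' signal distribution and calibration range per element. Ranges are
#' 1–500 ng/mL for Mn and Fe and 0.25–100 ng/mL for the others.
#'
#' @return Tibble with columns element, slope, intercept, blank_mean,
#'   blank_sd, cal_low, cal_high.
#' @export
default_instrument_truth <- function() {
  el <- names(default_measurement_cv())
  tibble::tibble(
    element = el,
    slope = 0.01, intercept = 0.001,
    blank_mean = 0.002, blank_sd = 0.0004,
    cal_low = ifelse(el %in% c("Mn", "Fe"), 1, 0.25),
    cal_high = ifelse(el %in% c("Mn", "Fe"), 500, 100)
  )
}

#' Generator configuration for a synthetic bioaccessibility study
#'
#' Ground-truth parameters for [generate_study()]. The default panel is
#' derived from the shipped study table: true total contents are the
#' printed totals and the true dialyzable fraction p of each cell is the
#' printed dialyzable share D/(D+T); the one censored cell is dropped.
#' Defaults therefore reproduce the study conditions (triplicates,
#' element-specific CVs, certified CRM values).
#'
#' @param panel Tibble with columns herb, form, element, total (μg/g),
#'   p (true dialyzable fraction in `[0, 1]`).
#' @param cv_by_element Named vector of measurement CVs in percent.
#' @param n_replicates Replicates per measurement (default 3).
#' @param instrument Tibble as [default_instrument_truth()].
#' @param crm CRM table as [crm_certified_values()] (certified values are
#'   the latent truth for CRM replicates).
#' @param tpc_truth Named vector of true TPC (mg GAE/g) by form.
#' @param seed Mandatory integer seed.
#' @return A `generator_config` list.
#' @export
generator_config <- function(panel = NULL,
                             cv_by_element = default_measurement_cv(),
                             n_replicates = 3,
                             instrument = default_instrument_truth(),
                             crm = crm_certified_values(),
                             tpc_truth = c(fresh = 5, lyophilizate = 30,
                                           dried = 50, supplement = 30),
                             seed) {
  if (missing(seed) || !is.numeric(seed)) {
    stop("`seed` is mandatory for a reproducible study", call. = FALSE)
  }
  if (is.null(panel)) {
    hp <- herb_panel()
    hp <- hp[!is.na(hp$dialyzable) & !is.na(hp$nondialyzable), ]
    panel <- tibble::tibble(
      herb = hp$herb, form = hp$form, element = hp$element,
      total = hp$total,
      p = hp$dialyzable / (hp$dialyzable + hp$nondialyzable)
    )
  }
  stopifnot(all(c("herb", "form", "element", "total", "p") %in% names(panel)),
            all(panel$total > 0))
  if (any(panel$p < 0 | panel$p > 1)) {
    stop("true dialyzable fraction p must lie in [0, 1]", call. = FALSE)
  }
  if (any(cv_by_element < 0)) stop("CVs must be >= 0", call. = FALSE)
  missing_cv <- setdiff(unique(panel$element), names(cv_by_element))
  if (length(missing_cv) > 0) {
    stop("no CV configured for element(s): ", paste(missing_cv, collapse = ", "),
         call. = FALSE)
  }
  stopifnot(n_replicates >= 1)
  # instrument/CRM blocks only for elements with a configured CV
  instrument <- instrument[instrument$element %in% names(cv_by_element), ]
  crm <- crm[crm$element %in% names(cv_by_element), ]
  structure(list(panel = panel, cv_by_element = cv_by_element,
                 n_replicates = as.integer(n_replicates),
                 instrument = instrument, crm = crm,
                 tpc_truth = tpc_truth, seed = as.integer(seed)),
            class = "generator_config")
}

# mean-preserving multiplicative log-normal noise at relative SD cv (fraction)
rlnorm_mean <- function(n, mu, cv) {
  if (mu == 0 || cv == 0) return(rep(mu, n))
  sdlog <- sqrt(log(1 + cv^2))
  mu * stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Generate a complete synthetic study
#'
#' Draws the observed blocks of a full study from the configured ground
#' truth: replicate per-gram contents for the total, dialyzable and
#' nondialyzable fractions of every panel cell (with D_true = p * total
#' and T_true = (1 - p) * total, so conservation holds by construction);
#' replicate calibration signals at seven levels through the latent line;
#' blank signal replicates; CRM determinations around the certified
#' values; and TPC absorbances through the inverse assay chain. Content
#' noise is mean-preserving multiplicative log-normal at the per-element
#' CV; blank noise is additive Gaussian. The output is deterministic for
#' a fixed config (the seed is part of the config).
#'
#' @param config A [generator_config()].
#' @return A `synthetic_study` list: `config`, `truth` (panel with
#'   D_true/T_true), and `observed` with tibbles `fractions`,
#'   `calibration`, `blanks`, `crm`, `tpc`.
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  n <- config$n_replicates
  panel <- config$panel
  truth <- dplyr::mutate(panel,
                         D_true = .data$p * .data$total,
                         T_true = (1 - .data$p) * .data$total)

  frac_rows <- lapply(seq_len(nrow(truth)), function(i) {
    row <- truth[i, ]
    cv <- config$cv_by_element[[row$element]] / 100
    tibble::tibble(
      herb = row$herb, form = row$form, element = row$element,
      fraction = rep(c("total", "dialyzable", "nondialyzable"), each = n),
      replicate = rep(seq_len(n), times = 3),
      content = c(rlnorm_mean(n, row$total, cv),
                  rlnorm_mean(n, row$D_true, cv),
                  rlnorm_mean(n, row$T_true, cv))
    )
  })
  fractions <- dplyr::bind_rows(frac_rows)

  cal_rows <- lapply(seq_len(nrow(config$instrument)), function(i) {
    ins <- config$instrument[i, ]
    cv <- config$cv_by_element[[ins$element]] / 100
    levels <- exp(seq(log(ins$cal_low), log(ins$cal_high), length.out = 7))
    true_signal <- rep(ins$slope * levels + ins$intercept, each = n)
    tibble::tibble(
      element = ins$element,
      conc = rep(levels, each = n),
      replicate = rep(seq_len(n), times = 7),
      signal = rlnorm_mean(7 * n, 1, cv) * true_signal
    )
  })
  calibration <- dplyr::bind_rows(cal_rows)

  blank_rows <- lapply(seq_len(nrow(config$instrument)), function(i) {
    ins <- config$instrument[i, ]
    tibble::tibble(element = ins$element,
                   replicate = 1:10,
                   signal = stats::rnorm(10, ins$blank_mean, ins$blank_sd))
  })
  blanks <- dplyr::bind_rows(blank_rows)

  crm_tbl <- config$crm[config$crm$element %in% names(config$cv_by_element), ]
  crm_rows <- lapply(seq_len(nrow(crm_tbl)), function(i) {
    ref <- crm_tbl[i, ]
    cv <- config$cv_by_element[[ref$element]] / 100
    tibble::tibble(element = ref$element,
                   day = rep(1:5, each = 3), replicate = rep(1:3, times = 5),
                   content = rlnorm_mean(15, ref$certified, cv),
                   unit = ref$unit)
  })
  crm <- dplyr::bind_rows(crm_rows)

  gallic <- fit_calibration(c(20, 100, 300), 0.005 * c(20, 100, 300))
  cells <- unique(panel[, c("herb", "form")])
  tpc_rows <- lapply(seq_len(nrow(cells)), function(i) {
    cell <- cells[i, ]
    df <- if (cell$form == "fresh") 1 else 10
    tpc_true <- config$tpc_truth[[cell$form]]
    conc_true <- tpc_true * 0.05 * 1000 / (df * 5)
    absorb <- gallic$intercept + gallic$slope *
      rlnorm_mean(n, conc_true, 0.03)
    tibble::tibble(herb = cell$herb, form = cell$form,
                   replicate = seq_len(n), absorbance = absorb,
                   dilution_factor = df, tpc_true = tpc_true)
  })
  tpc <- dplyr::bind_rows(tpc_rows)

  structure(list(config = config, truth = truth,
                 observed = list(fractions = fractions,
                                 calibration = calibration,
                                 blanks = blanks, crm = crm, tpc = tpc)),
            class = "synthetic_study")
}

#' Parameter-recovery report for a synthetic study
#'
#' Runs the estimation chain on the observed block of a study and compares
#' the estimates with the generator's ground truth, per cell: estimated
#' total content vs true total, and the uncorrected bioaccessibility (the
#' plain dialyzable share, whose truth is 100 p) vs 100 p.
#'
#' @param study A [generate_study()] result.
#' @return Tibble with per-cell truth, estimates and errors: columns
#'   herb, form, element, true_total, est_total, rel_err_total, true_B,
#'   est_B, abs_err_B (percentage points).
#' @export
parameter_recovery <- function(study) {
  stopifnot(inherits(study, "synthetic_study"))
  obs <- study$observed$fractions
  est <- tidyr::pivot_wider(
    dplyr::summarise(
      dplyr::group_by(obs, .data$herb, .data$form, .data$element, .data$fraction),
      mean = mean(.data$content), .groups = "drop"),
    names_from = "fraction", values_from = "mean")
  names(est)[names(est) == "total"] <- "total_obs"
  out <- dplyr::inner_join(study$truth, est,
                           by = c("herb", "form", "element"))
  est_B <- 100 * out$dialyzable / (out$dialyzable + out$nondialyzable)
  tibble::tibble(
    herb = out$herb, form = out$form, element = out$element,
    true_total = out$total, est_total = out$total_obs,
    rel_err_total = (out$total_obs - out$total) / out$total,
    true_B = 100 * out$p,
    est_B = est_B,
    abs_err_B = abs(est_B - 100 * out$p)
  )
}
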