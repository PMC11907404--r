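#' Run the full bioaccessibility analysis pipeline
#'
#' Orchestrates the analysis from replicate-level fraction contents to the
#' mass-balance, bioaccessibility and (optionally) risk reports:
#' summarise replicates to per-cell mean ± SD, check the mass balance of
#' every cell, compute B% with the chosen variant, and collect warnings
#' (censored cells, agreement outside the 80–120 % quantitative window,
#' B above 100 %) with their cell identity.
#'
#' @param fractions Tibble with columns `herb`, `form`, `element`,
#'   `fraction` (one of `"total"`, `"dialyzable"`, `"nondialyzable"`),
#'   `replicate`, `content` (μg/g; NA = censored determination). Summary
#'   input (columns `mean`, `sd` instead of `replicate`/`content`) is
#'   also accepted.
#' @param setup A [digestion_setup()].
#' @param variant Bioaccessibility variant, see [bioaccessibility()].
#' @param doses Optional [reference_doses()] registry; when supplied and
#'   the panel contains elements with RDA entries, a per-cell RDA coverage
#'   report is added.
#' @param scenario An [exposure_scenario()] for the risk report.
#' @return A `pipeline_result` list: `summary` (per-cell mean/SD wide
#'   table), `balance` (mass-balance report), `bioaccess` (long B table),
#'   `matrix` (wide B matrix), `risk` (RDA coverage, or NULL), `warnings`
#'   (character vector).
#' @export
run_pipeline <- function(fractions, setup = digestion_setup(),
                         variant = c("corrected_share", "literal", "uncorrected"),
                         doses = NULL, scenario = exposure_scenario()) {
  variant <- match.arg(variant)
  req <- c("herb", "form", "element", "fraction")
  missing_cols <- setdiff(req, names(fractions))
  if (length(missing_cols) > 0) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(unique(fractions$fraction),
                 c("total", "dialyzable", "nondialyzable"))
  if (length(bad) > 0) {
    stop("unknown fraction label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }

  if ("content" %in% names(fractions)) {
    cell <- dplyr::summarise(
      dplyr::group_by(fractions, .data$herb, .data$form, .data$element,
                      .data$fraction),
      mean = if (any(is.na(.data$content))) NA_real_ else mean(.data$content),
      sd = if (any(is.na(.data$content))) NA_real_ else stats::sd(.data$content),
      .groups = "drop")
  } else if (all(c("mean", "sd") %in% names(fractions))) {
    cell <- fractions[, c("herb", "form", "element", "fraction", "mean", "sd")]
  } else {
    stop("missing column(s): content (or mean + sd)", call. = FALSE)
  }
  cell$sd[is.na(cell$sd) & !is.na(cell$mean)] <- 0

  wide <- tidyr::pivot_wider(cell,
                             names_from = "fraction",
                             values_from = c("mean", "sd"))
  names(wide) <- sub("^mean_", "", names(wide))

  warnings_out <- character(0)
  note <- function(msg) warnings_out <<- c(warnings_out, msg)

  bal_rows <- lapply(seq_len(nrow(wide)), function(i) {
    w <- wide[i, ]
    id <- paste(w$herb, w$form, w$element, sep = "/")
    mb <- mass_balance(w$dialyzable, w$nondialyzable, w$total,
                       sd_dialyzable = w$sd_dialyzable %||% 0,
                       sd_nondialyzable = w$sd_nondialyzable %||% 0,
                       sd_total = w$sd_total %||% 0)
    if (!mb$available) {
      note(sprintf("%s: censored fraction, mass balance unavailable", id))
    } else if (!mb$quantitative) {
      note(sprintf("%s: agreement %.1f%% outside the 80-120%% window",
                   id, mb$agreement))
    }
    tibble::tibble(herb = w$herb, form = w$form, element = w$element,
                   total = w$total, sd_total = w$sd_total,
                   dialyzable = w$dialyzable, sd_dialyzable = w$sd_dialyzable,
                   nondialyzable = w$nondialyzable,
                   sd_nondialyzable = w$sd_nondialyzable,
                   sum = mb$sum, sd_sum = mb$sum_sd,
                   agreement = mb$agreement, sd_agreement = mb$agreement_sd,
                   quantitative = mb$quantitative, available = mb$available)
  })
  balance <- dplyr::bind_rows(bal_rows)

  btab <- bioaccess_table(balance, setup = setup, variant = variant)
  for (i in seq_len(nrow(btab))) {
    if (isTRUE(btab$B[i] > 100)) {
      note(sprintf("%s/%s/%s: B = %.1f%% above 100, mass-balance inconsistency",
                   btab$herb[i], btab$form[i], btab$element[i], btab$B[i]))
    }
  }
  bmat <- bioaccess_matrix(btab, long = TRUE)

  risk <- NULL
  if (!is.null(doses)) {
    has_rda <- balance$element %in% unique(doses$rda$element)
    if (any(has_rda)) {
      rk <- balance[has_rda, c("herb", "form", "element", "total")]
      rk <- tidyr::expand_grid(rk, sex = c("women", "men"))
      rk$rda_percent <- vapply(seq_len(nrow(rk)), function(i) {
        rda_percent(rk$total[i], rk$element[i], rk$sex[i],
                    portion_g = scenario$intake_g_per_day, doses = doses)
      }, numeric(1))
      risk <- rk
    }
  }

  structure(list(summary = wide, balance = balance, bioaccess = btab,
                 matrix = bmat, risk = risk, warnings = warnings_out),
            class = "pipeline_result")
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a)) b else a

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("Bioaccessibility pipeline result: %d cells, variant '%s'\n",
              nrow(x$balance), x$bioaccess$variant[1]))
  cat(sprintf("  quantitative mass balance: %d of %d available cells\n",
              sum(x$balance$quantitative, na.rm = TRUE),
              sum(x$balance$available)))
  if (length(x$warnings) > 0) {
    cat(sprintf("  %d warning(s); first: %s\n", length(x$warnings),
                x$warnings[1]))
  } else {
    cat("  no warnings\n")
  }
  invisible(x)
}

#' Write the pipeline reports as delimited text
#'
#' Writes the balance, bioaccessibility (long and wide) and, when present,
#' risk tables as comma-separated UTF-8 files with a header row and period
#' decimal separator. Core values are written unrounded.
#'
#' @param result A [run_pipeline()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_reports <- function(result, dir) {
  stopifnot(inherits(result, "pipeline_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    balance = file.path(dir, "mass_balance.csv"),
    bioaccess = file.path(dir, "bioaccessibility.csv"),
    matrix = file.path(dir, "bioaccessibility_matrix.csv")
  )
  utils::write.csv(result$balance, paths["balance"], row.names = FALSE)
  utils::write.csv(result$bioaccess, paths["bioaccess"], row.names = FALSE)
  m <- as.data.frame(result$matrix)
  m <- cbind(cell = rownames(result$matrix), m)
  utils::write.csv(m, paths["matrix"], row.names = FALSE)
  if (!is.null(result$risk)) {
    paths <- c(paths, risk = file.path(dir, "risk.csv"))
    utils::write.csv(result$risk, paths["risk"], row.names = FALSE)
  }
  invisible(paths)
}
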