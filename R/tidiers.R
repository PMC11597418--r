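#' Tidy a fitted calibration
#'
#' @param x A `paddy_calibration` object.
#' @param ... Unused.
#' @return A tibble with one row per fitted parameter: `parameter, estimate,
#'   lower, upper`.
#' @export
tidy.paddy_calibration <- function(x, ...) {
  tibble::tibble(
    parameter = names(x$estimate),
    estimate = unname(x$estimate),
    lower = x$spec$parameters$lower[match(names(x$estimate),
                                          x$spec$parameters$name)],
    upper = x$spec$parameters$upper[match(names(x$estimate),
                                          x$spec$parameters$name)]
  )
}

#' One-row summary of a fitted calibration
#'
#' @param x A `paddy_calibration` object.
#' @param ... Unused.
#' @return A tibble: `objective, n_eval, n_series, seed`.
#' @export
glance.paddy_calibration <- function(x, ...) {
  tibble::tibble(objective = x$objective, n_eval = x$n_eval,
                 n_series = nrow(x$metrics), seed = x$seed)
}

#' Tidy a simulated season
#'
#' Joins the daily water and nitrogen tables of a season into one long-form
#' friendly daily tibble.
#'
#' @param x A `paddy_season` object.
#' @param ... Unused.
#' @return A daily tibble combining fluxes, depth, masses and concentrations.
#' @export
tidy.paddy_season <- function(x, ...) {
  dplyr::left_join(
    x$water,
    dplyr::select(x$nitrogen, -"pd"),
    by = c("date", "day")
  ) |>
    dplyr::mutate(treatment = x$treatment, .before = 1)
}

#' One-row summary of a simulated season
#'
#' @param x A `paddy_season` object.
#' @param ... Unused.
#' @return A tibble with the seasonal water and N budget headline numbers.
#' @export
glance.paddy_season <- function(x, ...) {
  tibble::tibble(
    treatment = x$treatment,
    n_days = nrow(x$water),
    rain = sum(x$water$prem),
    irrigation = sum(x$water$irri),
    runoff = sum(x$water$rf),
    n_events = x$totals$n_events,
    tn_loss = x$totals$tn,
    din_loss = x$totals$din,
    water_residual = x$balance$water_residual,
    n_residual = x$balance$n_residual
  )
}

#' Tidy a scenario summary
#'
#' @param x A `scenario_summary` object.
#' @param ... Unused.
#' @return The reductions table (per treatment x year type).
#' @export
tidy.scenario_summary <- function(x, ...) {
  x$reductions
}

#' One-row summary of a scenario summary
#'
#' @param x A `scenario_summary` object.
#' @param ... Unused.
#' @return A tibble: baseline, year counts per type, procedure.
#' @export
glance.scenario_summary <- function(x, ...) {
  counts <- x$by_group |>
    dplyr::distinct(.data$label, .data$n_years) |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(n = max(.data$n_years), .groups = "drop")
  tibble::tibble(
    baseline = x$baseline,
    n_dry = counts$n[counts$label == "dry"],
    n_normal = counts$n[counts$label == "normal"],
    n_wet = counts$n[counts$label == "wet"],
    procedure = x$procedure
  )
}
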