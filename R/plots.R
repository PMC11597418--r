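#' Plot the daily water balance of a season
#'
#' Ponding depth line with precipitation bars and runoff events marked;
#' drainage windows shaded.
#'
#' @param season A `paddy_season` or `paddy_water` object.
#' @return A ggplot object.
#' @export
plot_season_water <- function(season) {
  w <- if (inherits(season, "paddy_season")) season$water else season
  ggplot2::ggplot(w, ggplot2::aes(x = .data$day)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$prem), fill = "steelblue",
                      alpha = 0.5, width = 1) +
    ggplot2::geom_line(ggplot2::aes(y = .data$pd), linewidth = 0.6) +
    ggplot2::geom_point(data = w[w$rf > 0, ], ggplot2::aes(y = .data$pd),
                        colour = "red", size = 1) +
    ggplot2::labs(x = "days after transplanting",
                  y = "mm (ponding depth line, rain bars)",
                  title = "Ponding-water balance") +
    ggplot2::theme_minimal()
}

#' Plot surface-water nitrogen concentration dynamics
#'
#' @param season A `paddy_season` object.
#' @param forms Concentration columns to draw.
#' @return A ggplot object.
#' @export
plot_season_nitrogen <- function(season,
                                 forms = c("c_tn", "c_din", "c_nh4")) {
  stopifnot(inherits(season, "paddy_season"))
  long <- season$nitrogen |>
    dplyr::select("day", dplyr::all_of(forms)) |>
    tidyr::pivot_longer(-"day", names_to = "form", values_to = "conc")
  fert_days <- season$schedule$fertilization$day
  ggplot2::ggplot(long, ggplot2::aes(.data$day, .data$conc,
                                     colour = .data$form)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_vline(xintercept = fert_days, linetype = 3) +
    ggplot2::labs(x = "days after transplanting",
                  y = "concentration (mg N/L)",
                  title = paste0("Surface-water N dynamics (",
                                 season$treatment, ")"),
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.paddy_season <- function(object, ...) {
  plot_season_nitrogen(object)
}

#' @export
autoplot.paddy_calibration <- function(object, ...) {
  ggplot2::ggplot(object$trace,
                  ggplot2::aes(.data$eval, .data$objective)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "objective evaluation", y = "best objective",
                  title = "Calibration descent trace") +
    ggplot2::theme_minimal()
}

#' Grouped bar chart of scenario losses by year type
#'
#' Mean seasonal TN and DIN losses per treatment within each rainfall year
#' type, with +/- one standard deviation bars.
#'
#' @param object A `scenario_summary` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.scenario_summary <- function(object, ...) {
  long <- object$by_group |>
    tidyr::pivot_longer(c("mean_tn", "mean_din"), names_to = "form",
                        values_to = "mean") |>
    dplyr::mutate(
      sd = ifelse(.data$form == "mean_tn", .data$sd_tn, .data$sd_din),
      form = ifelse(.data$form == "mean_tn", "TN", "DIN")
    )
  ggplot2::ggplot(long, ggplot2::aes(.data$label, .data$mean,
                                     fill = .data$treatment)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = pmax(0, .data$mean - .data$sd),
                   ymax = .data$mean + .data$sd),
      position = ggplot2::position_dodge(width = 0.8), width = 0.2
    ) +
    ggplot2::facet_wrap(~form, scales = "free_y") +
    ggplot2::labs(x = "rainfall year type",
                  y = "seasonal runoff N loss (kg N/ha)",
                  fill = "treatment") +
    ggplot2::theme_minimal()
}
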