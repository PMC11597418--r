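#' Classify years by the drought index
#'
#' The drought index of year *i* is the standardized rainfall anomaly
#' `DI = (P - A) / sigma`, where `P` is the year's rainfall over the
#' classification window, and `A` and `sigma` are the mean and standard
#' deviation of `P` over all supplied years (the classified set is its own
#' climatology). A year is *wet* when `DI > 0.35`, *dry* when `DI < -0.35`,
#' and *normal* otherwise (boundaries inclusive in "normal").
#'
#' @param yearly_p Either a numeric vector of yearly rainfall (mm) or a data
#'   frame with columns `year` and `P`.
#' @param threshold Classification threshold on `DI` (default 0.35).
#' @return A tibble with columns `year, P, A, sigma, DI, label` where `label`
#'   is a factor with levels `dry, normal, wet`.
#' @examples
#' drought_index(c(480, 520, 610, 700, 455, 530))
#' @export
drought_index <- function(yearly_p, threshold = 0.35) {
  if (is.data.frame(yearly_p)) {
    if (!all(c("year", "P") %in% names(yearly_p))) {
      abort("data-frame input needs columns `year` and `P`.")
    }
    year <- yearly_p$year
    P <- yearly_p$P
  } else {
    P <- as.numeric(yearly_p)
    year <- seq_along(P)
  }
  if (length(P) < 3L) abort("at least 3 years are required (sigma undefined).")
  if (anyNA(P)) abort("yearly rainfall contains missing values.")
  A <- mean(P)
  sigma <- sd(P)
  if (sigma == 0) abort("sigma = 0: all years identical, classification undefined.")
  DI <- (P - A) / sigma
  label <- factor(
    ifelse(DI > threshold, "wet", ifelse(DI < -threshold, "dry", "normal")),
    levels = c("dry", "normal", "wet")
  )
  tibble::tibble(year = year, P = P, A = A, sigma = sigma, DI = DI, label = label)
}

#' Seasonal rainfall totals per year
#'
#' Sums precipitation over the rice-season window (transplant to harvest
#' month-day, inclusive) for every calendar year in a weather series. This is
#' the default classification window for [drought_index()]; pass
#' `window = "year"` for calendar-year totals instead.
#'
#' @param weather A daily weather tibble.
#' @param transplant,harvest Window bounds as `"MM-DD"` strings (or dates,
#'   whose month-day is used).
#' @param window `"season"` (default) or `"year"`.
#' @return A tibble with columns `year` and `P` (mm), one row per year whose
#'   window is fully covered by the series.
#' @examples
#' params <- markov_gamma_params(0.3, 0.7, 0.8, 12)
#' w <- generate_weather(params, n_years = 3, seed = 1)
#' season_rainfall(w, "06-11", "10-01")
#' @export
season_rainfall <- function(weather, transplant, harvest, window = c("season", "year")) {
  window <- match.arg(window)
  weather <- validate_weather(weather)
  yr <- as.integer(format(weather$date, "%Y"))
  if (window == "year") {
    return(
      tibble::tibble(year = yr, prcp = weather$prcp) |>
        dplyr::group_by(year = .data$year) |>
        dplyr::summarise(P = sum(.data$prcp), .groups = "drop")
    )
  }
  md <- function(x) {
    if (inherits(x, "Date")) format(x, "%m-%d") else as.character(x)
  }
  t_md <- md(transplant); h_md <- md(harvest)
  if (t_md >= h_md) abort("season window must lie within one calendar year.")
  out <- purrr::map(sort(unique(yr)), function(y) {
    lo <- as.Date(sprintf("%d-%s", y, t_md))
    hi <- as.Date(sprintf("%d-%s", y, h_md))
    idx <- weather$date >= lo & weather$date <= hi
    if (sum(idx) < as.numeric(hi - lo) + 1) return(NULL)  # incomplete window
    tibble::tibble(year = y, P = sum(weather$prcp[idx]))
  })
  dplyr::bind_rows(out)
}
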