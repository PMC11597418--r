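#' Construct monthly Markov-Gamma precipitation parameters
#'
#' A precipitation generator is parameterized per calendar month by the
#' two-state first-order Markov chain transition probabilities `p_wd`
#' (P(wet | previous day dry)) and `p_ww` (P(wet | previous day wet)) and by a
#' two-parameter Gamma distribution (`shape`, `scale`) for the wet-day amount
#' in excess of the wet-day threshold.
#'
#' @param p_wd,p_ww Transition probabilities, scalars or length-12 vectors.
#' @param shape,scale Gamma shape (dimensionless) and scale (mm), scalars or
#'   length-12 vectors.
#' @param wet_threshold Precipitation at or above this depth (mm) counts as a
#'   wet day; generated wet-day amounts are `wet_threshold` + Gamma draw.
#' @param temperature Optional tibble of monthly temperature normals with
#'   columns `month, tmax_mean, tmax_sd, tmin_mean, tmin_sd` (degrees C).
#' @return A 12-row tibble of class `markov_gamma_params` with columns
#'   `month, p_wd, p_ww, shape, scale, n_wet, pooled`.
#' @examples
#' markov_gamma_params(p_wd = 0.3, p_ww = 0.7, shape = 0.8, scale = 12)
#' @export
markov_gamma_params <- function(p_wd, p_ww, shape, scale,
                                wet_threshold = 0.1,
                                temperature = NULL) {
  rep12 <- function(x, nm) {
    if (length(x) == 1L) x <- rep(x, 12L)
    if (length(x) != 12L) abort(paste0("`", nm, "` must have length 1 or 12."))
    x
  }
  out <- tibble::tibble(
    month = 1:12,
    p_wd = rep12(p_wd, "p_wd"), p_ww = rep12(p_ww, "p_ww"),
    shape = rep12(shape, "shape"), scale = rep12(scale, "scale"),
    n_wet = NA_integer_, pooled = FALSE
  )
  validate_markov_gamma(
    structure(out, class = c("markov_gamma_params", class(out)),
              wet_threshold = wet_threshold, temperature = temperature)
  )
}

validate_markov_gamma <- function(params) {
  if (!all(c("month", "p_wd", "p_ww", "shape", "scale") %in% names(params))) {
    abort("Markov-Gamma parameters need columns month, p_wd, p_ww, shape, scale.")
  }
  if (nrow(params) != 12L || !identical(as.integer(params$month), 1:12)) {
    abort("Markov-Gamma parameters must have one row per calendar month 1..12.")
  }
  p <- c(params$p_wd, params$p_ww)
  if (anyNA(p) || any(p < 0 | p > 1)) {
    abort("transition probabilities must lie in [0, 1].")
  }
  if (anyNA(params$shape) || anyNA(params$scale) ||
      any(params$shape <= 0) || any(params$scale <= 0)) {
    abort("Gamma shape and scale must be positive.")
  }
  wt <- attr(params, "wet_threshold") %||% 0.1
  if (wt < 0) abort("`wet_threshold` must be >= 0 mm.")
  params
}

#' Fit the monthly Markov-Gamma precipitation model
#'
#' Estimates, for each calendar month, the wet/dry transition probabilities of
#' a two-state first-order Markov chain as empirical conditional frequencies,
#' and a two-parameter Gamma distribution for wet-day amounts in excess of the
#' wet-day threshold (method of moments by default, maximum likelihood
#' optionally). Months with fewer than 5 wet days, or with an undefined
#' transition frequency, fall back to the pooled all-month fit and are flagged
#' `pooled = TRUE`. Monthly temperature normals (mean/sd of tmax and tmin) are
#' fitted alongside and attached for use by [generate_weather()].
#'
#' @param weather A daily weather tibble (see [validate_weather()]) spanning
#'   at least two full years.
#' @param wet_threshold Wet-day threshold, mm (default 0.1).
#' @param method Gamma estimator: `"moments"` (default) or `"mle"`
#'   (via `MASS::fitdistr()`, falling back to moments on failure).
#' @return A `markov_gamma_params` tibble (with an extra `mean_wet` column,
#'   the observed monthly mean wet-day amount including the threshold);
#'   attributes `wet_threshold` and `temperature` carry the threshold and the
#'   monthly temperature normals.
#' @examples
#' params <- markov_gamma_params(0.3, 0.7, 0.8, 12)
#' w <- generate_weather(params, n_years = 3, seed = 1)
#' fit_markov_gamma(w)
#' @export
fit_markov_gamma <- function(weather, wet_threshold = 0.1,
                             method = c("moments", "mle")) {
  method <- match.arg(method)
  weather <- validate_weather(weather)
  if (wet_threshold < 0) abort("`wet_threshold` must be >= 0 mm.")
  if (nrow(weather) < 730L) {
    abort("weather series must span at least 2 full years (>= 730 days).")
  }
  month <- as.integer(format(weather$date, "%m"))
  wet <- weather$prcp >= wet_threshold
  if (!any(wet)) {
    abort(paste0("all-dry record: no wet days in any month (months ",
                 paste(sort(unique(month)), collapse = ", "),
                 "); Gamma fit undefined."))
  }

  # transitions between consecutive calendar days only
  consec <- c(FALSE, diff(as.numeric(weather$date)) == 1)
  prev_wet <- dplyr::lag(wet)
  tr <- tibble::tibble(month = month, wet = wet, prev_wet = prev_wet)[consec, ]

  excess <- pmax(weather$prcp[wet] - wet_threshold, 0)
  mo_wet <- month[wet]

  gamma_fit <- function(x) {
    # method-of-moments on threshold excesses; MLE optionally.  A record with
    # (near-)constant amounts has no variance to fit: represent it as a
    # near-degenerate Gamma that preserves the mean.
    x <- x[!is.na(x)]
    if (length(x) < 2L) return(NULL)
    m <- max(mean(x), 1e-6); v <- var(x)
    if (!is.finite(v)) return(NULL)
    if (v <= 1e-12) return(c(shape = 100, scale = m / 100))
    mom <- c(shape = m^2 / v, scale = v / m)
    if (method == "moments") return(mom)
    xp <- pmax(x, 1e-3)  # clamp exact-threshold days for the likelihood
    fit <- tryCatch(
      MASS::fitdistr(xp, "gamma",
                     start = list(shape = mom[["shape"]],
                                  rate = 1 / mom[["scale"]]),
                     lower = c(1e-6, 1e-6)),
      error = function(e) NULL
    )
    if (is.null(fit)) return(mom)
    c(shape = unname(fit$estimate["shape"]),
      scale = 1 / unname(fit$estimate["rate"]))
  }

  pooled_gamma <- gamma_fit(excess)
  if (is.null(pooled_gamma)) {
    abort("degenerate precipitation record: pooled Gamma fit undefined.")
  }
  pooled_p_wd <- {
    den <- sum(!tr$prev_wet); if (den > 0) sum(tr$wet & !tr$prev_wet) / den else 0
  }
  pooled_p_ww <- {
    den <- sum(tr$prev_wet); if (den > 0) sum(tr$wet & tr$prev_wet) / den else 0
  }

  rows <- purrr::map(1:12, function(m) {
    trm <- tr[tr$month == m, ]
    n_dry <- sum(!trm$prev_wet); n_wetp <- sum(trm$prev_wet)
    p_wd <- if (n_dry > 0) sum(trm$wet & !trm$prev_wet) / n_dry else NA_real_
    p_ww <- if (n_wetp > 0) sum(trm$wet & trm$prev_wet) / n_wetp else NA_real_
    ex <- excess[mo_wet == m]
    g <- if (length(ex) >= 5L) gamma_fit(ex) else NULL
    pooled <- is.null(g) || is.na(p_wd) || is.na(p_ww)
    if (is.null(g)) g <- pooled_gamma
    tibble::tibble(
      month = m,
      p_wd = if (is.na(p_wd)) pooled_p_wd else p_wd,
      p_ww = if (is.na(p_ww)) pooled_p_ww else p_ww,
      shape = g[["shape"]], scale = g[["scale"]],
      mean_wet = wet_threshold +
        if (length(ex)) mean(ex) else mean(excess),
      n_wet = length(ex), pooled = pooled
    )
  })
  out <- dplyr::bind_rows(rows)

  temp <- tibble::tibble(month = month,
                         tmax = weather$tmax, tmin = weather$tmin) |>
    dplyr::group_by(.data$month) |>
    dplyr::summarise(
      tmax_mean = mean(.data$tmax, na.rm = TRUE),
      tmax_sd = sd(.data$tmax, na.rm = TRUE),
      tmin_mean = mean(.data$tmin, na.rm = TRUE),
      tmin_sd = sd(.data$tmin, na.rm = TRUE),
      .groups = "drop"
    )

  validate_markov_gamma(
    structure(out, class = c("markov_gamma_params", class(out)),
              wet_threshold = wet_threshold, temperature = temp)
  )
}

#' Generate synthetic daily weather
#'
#' Samples a daily weather series from monthly Markov-Gamma precipitation
#' parameters. The wet/dry sequence follows the two-state first-order chain
#' (initialized from the stationary probability of the starting month); wet
#' days receive `wet_threshold` plus a Gamma-distributed amount; dry days have
#' zero precipitation. Temperatures are drawn from the attached monthly
#' normals (minimal plumbing, used only for evapotranspiration) with
#' `tmin <= tmax - 0.1` enforced. Output is bit-reproducible for a given seed.
#'
#' @param params A `markov_gamma_params` object.
#' @param n_years Number of calendar years to generate (>= 1).
#' @param seed Integer RNG seed.
#' @param start_year First calendar year of the generated series.
#' @return A weather tibble (`date, prcp, tmax, tmin`).
#' @examples
#' params <- markov_gamma_params(0.3, 0.7, 0.8, 12)
#' generate_weather(params, n_years = 1, seed = 42)
#' @export
generate_weather <- function(params, n_years, seed, start_year = 2001L) {
  params <- validate_markov_gamma(params)
  if (n_years < 1) abort("`n_years` must be >= 1.")
  wt <- attr(params, "wet_threshold") %||% 0.1
  temp <- attr(params, "temperature")
  if (is.null(temp)) {
    temp <- default_temperature_normals()
  }
  dates <- seq(as.Date(sprintf("%d-01-01", start_year)),
               as.Date(sprintf("%d-12-31", start_year + n_years - 1L)),
               by = "day")
  n <- length(dates)
  mo <- as.integer(format(dates, "%m"))
  p_wd <- params$p_wd[mo]; p_ww <- params$p_ww[mo]

  withr::with_seed(seed, {
    u <- runif(n + 1L)
    amt <- rgamma(n, shape = params$shape[mo], scale = params$scale[mo])
    tmax <- rnorm(n, temp$tmax_mean[mo], temp$tmax_sd[mo])
    tmin <- rnorm(n, temp$tmin_mean[mo], temp$tmin_sd[mo])
  })

  # stationary wet probability of the first month seeds the chain
  pi1 <- params$p_wd[mo[1]] / (1 + params$p_wd[mo[1]] - params$p_ww[mo[1]])
  if (!is.finite(pi1)) pi1 <- 0
  wet <- logical(n)
  prev <- u[1] < pi1
  for (i in seq_len(n)) {
    p <- if (prev) p_ww[i] else p_wd[i]
    wet[i] <- u[i + 1L] < p
    prev <- wet[i]
  }

  tibble::tibble(
    date = dates,
    prcp = ifelse(wet, wt + amt, 0),
    tmax = tmax,
    tmin = pmin(tmin, tmax - 0.1)
  )
}

# Humid subtropical monthly temperature normals used when a parameter set
# carries no fitted temperature model.
default_temperature_normals <- function() {
  tibble::tibble(
    month = 1:12,
    tmax_mean = c(8, 10, 15, 21, 26, 29, 33, 32, 28, 22, 16, 10),
    tmax_sd = 2.5,
    tmin_mean = c(0, 2, 6, 11, 16, 20, 24, 23, 19, 13, 7, 2),
    tmin_sd = 2.5
  )
}
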