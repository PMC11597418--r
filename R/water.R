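#' One day of the ponding-water balance
#'
#' Advances the ponding depth by one day according to the daily balance
#' `pd = pd_prev + prem + irri - et - inf - rf`, with fluxes applied in a
#' fixed order so that management reacts to same-day rain:
#' precipitation is added; the irrigation decision is taken (topping up to
#' `pd_target` when the depth is below `pd_lower`, suppressed during drainage
#' windows); crop evapotranspiration (`kc * et0`) and percolation are
#' subtracted, each capped at the available water so the depth never goes
#' negative; finally runoff spills any excess above `pd_max`, and in a
#' drainage window the pond is additionally force-drained to zero (the
#' drained volume is reported as runoff).
#'
#' @param pd_prev Ponding depth at the end of the previous day, mm (>= 0).
#' @param prcp Precipitation, mm.
#' @param et0 Reference evapotranspiration, mm.
#' @param soil A [soil_params()] object.
#' @param policy An [irrigation_policy()] object.
#' @param kc Crop coefficient for the day (dimensionless).
#' @param drained `TRUE` when the day lies inside a forced-drainage window.
#' @return A one-row tibble `pd, prem, irri, et, inf, rf, drained`.
#' @examples
#' step_water_balance(50, prcp = 30, et0 = 5,
#'                    soil = soil_params(perc_rate = 10, pd_max = 100),
#'                    policy = irrigation_policy(20, 60), kc = 1)
#' @export
step_water_balance <- function(pd_prev, prcp, et0, soil, policy,
                               kc = 1, drained = FALSE) {
  if (pd_prev < 0 || prcp < 0 || et0 < 0 || kc < 0) {
    abort("`pd_prev`, `prcp`, `et0` and `kc` must be non-negative.")
  }
  stopifnot(inherits(soil, "soil_params"), inherits(policy, "irrigation_policy"))
  r <- .water_step(pd_prev, prcp, kc * et0, soil, policy, drained)
  tibble::as_tibble(r)
}

# scalar daily water step; pet = kc * et0 (potential crop ET)
.water_step <- function(pd_prev, prcp, pet, soil, policy, drained) {
  pd <- pd_prev + prcp
  irri <- 0
  if (!drained && pd < policy$pd_lower) {
    irri <- policy$pd_target - pd
    pd <- policy$pd_target
  }
  et <- min(pet, pd)
  pd <- pd - et
  inf <- min(soil$perc_rate, pd)
  pd <- pd - inf
  if (drained) {
    rf <- pd           # forced drainage empties the pond
    pd <- 0
  } else {
    rf <- max(0, pd - soil$pd_max)
    pd <- pd - rf
  }
  list(pd = pd, prem = prcp, irri = irri, et = et, inf = inf, rf = rf,
       drained = drained)
}

# crop coefficient by growth phase for DAT 0..n_days
kc_schedule <- function(soil, n_days) {
  day <- 0:n_days
  kc <- rep(soil$kc[["mid"]], n_days + 1L)
  kc[day < soil$kc_initial_days] <- soil$kc[["initial"]]
  kc[day > n_days - soil$kc_late_days] <- soil$kc[["late"]]
  kc
}

# default mid-season + pre-harvest drying windows (DAT, inclusive)
default_drainage_windows <- function(n_days) {
  win <- tibble::tibble(start = n_days - 9L, end = n_days)
  if (n_days >= 52L) {
    win <- dplyr::bind_rows(tibble::tibble(start = 27L, end = 33L), win)
  }
  win
}

#' Simulate the ponding-water balance over a season
#'
#' Runs [step_water_balance()] from transplanting to harvest under the given
#' soil, irrigation policy and weather, producing one record per day. The
#' seasonal budget closes exactly:
#' `sum(prem) + sum(irri) - sum(et) - sum(inf) - sum(rf) = pd_end - pd_init`.
#'
#' @param weather Daily weather covering the whole season (gaps are an error
#'   naming the first missing date).
#' @param soil A [soil_params()] object.
#' @param policy An [irrigation_policy()] object; `NULL` drainage windows get
#'   the defaults from the policy's documentation.
#' @param transplant,harvest Season bounds (`Date` or `"YYYY-MM-DD"`).
#' @param latitude Latitude in decimal degrees (for Hargreaves ET when the
#'   weather has no `et0` column).
#' @param pd_init Initial ponding depth at transplanting, mm (default
#'   `policy$pd_target`).
#' @return A tibble with one row per day: `date, day` (DAT), the fluxes
#'   `prem, irri, et, inf, rf` (mm), the end-of-day depth `pd` (mm) and the
#'   `drained` flag.
#' @export
simulate_water_season <- function(weather, soil, policy, transplant, harvest,
                                  latitude = 30, pd_init = policy$pd_target) {
  stopifnot(inherits(soil, "soil_params"), inherits(policy, "irrigation_policy"))
  transplant <- as.Date(transplant); harvest <- as.Date(harvest)
  if (policy$pd_target > soil$pd_max) {
    abort("`pd_target` must not exceed `pd_max`.")
  }
  if (pd_init < 0) abort("`pd_init` must be >= 0 mm.")
  days <- seq(transplant, harvest, by = "day")
  weather <- validate_weather(weather)
  idx <- match(days, weather$date)
  if (anyNA(idx)) {
    abort(paste0("weather gap: no record for ", format(days[which(is.na(idx))[1]]), "."))
  }
  season <- reference_et(weather[idx, ], latitude)
  n_days <- length(days) - 1L
  kc <- kc_schedule(soil, n_days)
  windows <- policy$drainage_windows %||% default_drainage_windows(n_days)
  dat <- 0:n_days
  drained <- purrr::map_lgl(dat, function(d) any(d >= windows$start & d <= windows$end))

  pd <- pd_init
  rows <- vector("list", n_days + 1L)
  for (i in seq_along(dat)) {
    r <- .water_step(pd, season$prcp[i], kc[i] * season$et0[i], soil, policy,
                     drained[i])
    pd <- r$pd
    rows[[i]] <- r
  }
  out <- dplyr::bind_rows(rows)
  out <- dplyr::bind_cols(tibble::tibble(date = days, day = dat), out)
  attr(out, "pd_init") <- pd_init
  class(out) <- c("paddy_water", class(out))
  out
}
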