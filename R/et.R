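#' Reference evapotranspiration
#'
#' Adds (or passes through) a reference evapotranspiration column `et0`
#' (mm day^-1). When the weather table already carries `et0`, those values are
#' returned verbatim. Otherwise a Hargreaves-Samani estimate is computed from
#' the daily temperature range, latitude and day of year:
#' `et0 = 0.0023 * (Tmean + 17.8) * sqrt(Tmax - Tmin) * Ra`, with the
#' extraterrestrial radiation `Ra` (converted to mm day^-1) from the standard
#' astronomical formulas. Actual crop evapotranspiration is `kc * et0` and is
#' applied inside the water balance.
#'
#' @param weather A daily weather tibble.
#' @param latitude Site latitude, decimal degrees (positive north).
#' @return `weather` with an `et0` column (mm day^-1).
#' @examples
#' w <- tibble::tibble(date = as.Date("2023-06-29"), prcp = 0,
#'                     tmax = 30, tmin = 20)
#' reference_et(w, latitude = 30)
#' @export
reference_et <- function(weather, latitude) {
  weather <- tibble::as_tibble(weather)
  if ("et0" %in% names(weather) && !anyNA(weather$et0)) {
    if (any(weather$et0 < 0)) abort("`et0` must be non-negative.")
    return(weather)
  }
  if (!all(c("tmax", "tmin") %in% names(weather)) ||
      anyNA(weather$tmax) || anyNA(weather$tmin)) {
    abort("missing temperatures and no `et0` column: cannot estimate ET.")
  }
  if (any(weather$tmax < weather$tmin)) abort("tmax < tmin in weather input.")
  doy <- as.integer(format(weather$date, "%j"))
  weather$et0 <- hargreaves_et0(weather$tmax, weather$tmin, latitude, doy)
  weather
}

# Hargreaves-Samani reference ET (mm/day); Ra per FAO-56 astronomy.
hargreaves_et0 <- function(tmax, tmin, latitude, doy) {
  phi <- latitude * pi / 180
  dr <- 1 + 0.033 * cos(2 * pi * doy / 365)
  dec <- 0.409 * sin(2 * pi * doy / 365 - 1.39)
  ws <- acos(pmin(1, pmax(-1, -tan(phi) * tan(dec))))
  ra <- (24 * 60 / pi) * 0.0820 * dr *
    (ws * sin(phi) * sin(dec) + cos(phi) * cos(dec) * sin(ws))  # MJ m-2 d-1
  ra_mm <- ra / 2.45  # latent heat of vaporization
  pmax(0, 0.0023 * ((tmax + tmin) / 2 + 17.8) * sqrt(pmax(tmax - tmin, 0)) * ra_mm)
}
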