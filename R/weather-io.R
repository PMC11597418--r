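#' Read a daily weather table
#'
#' Reads a comma-separated daily weather file with unit-suffixed headers
#' (`date, prcp_mm, tmax_c, tmin_c[, sunshine_h][, et0_mm]`) into the internal
#' column names (`date, prcp, tmax, tmin, sunshine, et0`) and validates it.
#' Lines starting with `#` are treated as comments.
#'
#' @param path Path to a CSV file.
#' @return A validated weather tibble.
#' @seealso [write_weather()], [validate_weather()]
#' @export
read_weather <- function(path) {
  if (!file.exists(path)) abort(paste0("weather file not found: ", path))
  raw <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  map <- c(prcp_mm = "prcp", tmax_c = "tmax", tmin_c = "tmin",
           sunshine_h = "sunshine", et0_mm = "et0")
  hit <- intersect(names(map), names(raw))
  names(raw)[match(hit, names(raw))] <- map[hit]
  required <- c("date", "prcp", "tmax", "tmin")
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    abort(paste0("weather file is missing required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  raw$date <- as.Date(raw$date)
  validate_weather(raw)
}

#' Write a daily weather table
#'
#' Writes the on-disk representation read by [read_weather()], with units
#' embedded in the column headers so files are self-describing.
#'
#' @param weather A weather tibble (`date, prcp, tmax, tmin, ...`).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_weather <- function(weather, path) {
  weather <- validate_weather(weather)
  out <- weather
  map <- c(prcp = "prcp_mm", tmax = "tmax_c", tmin = "tmin_c",
           sunshine = "sunshine_h", et0 = "et0_mm")
  hit <- intersect(names(map), names(out))
  names(out)[match(hit, names(out))] <- map[hit]
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Validate a daily weather series
#'
#' Checks the structural invariants of a weather series: strictly increasing
#' dates, non-negative precipitation and `tmax >= tmin` wherever both are
#' present. Violations raise an error naming the offending row/date.
#'
#' @param weather A data frame with columns `date`, `prcp`, `tmax`, `tmin`.
#' @return The validated weather tibble.
#' @export
validate_weather <- function(weather) {
  weather <- tibble::as_tibble(weather)
  required <- c("date", "prcp", "tmax", "tmin")
  missing <- setdiff(required, names(weather))
  if (length(missing)) {
    abort(paste0("weather is missing column(s): ", paste(missing, collapse = ", ")))
  }
  if (!inherits(weather$date, "Date")) weather$date <- as.Date(weather$date)
  if (nrow(weather) == 0) abort("weather series is empty.")
  if (anyNA(weather$date)) abort("weather contains unparseable dates.")
  dd <- diff(as.numeric(weather$date))
  if (any(dd <= 0)) {
    i <- which(dd <= 0)[1] + 1L
    abort(paste0("weather dates must be strictly increasing; violation at row ",
                 i, " (", format(weather$date[i]), ")."))
  }
  bad <- which(is.na(weather$prcp) | weather$prcp < 0)
  if (length(bad)) {
    abort(paste0("negative or missing precipitation at row ", bad[1],
                 " (", format(weather$date[bad[1]]), ")."))
  }
  both <- !is.na(weather$tmax) & !is.na(weather$tmin)
  bad <- which(both & weather$tmax < weather$tmin)
  if (length(bad)) {
    abort(paste0("tmax < tmin at row ", bad[1],
                 " (", format(weather$date[bad[1]]), ")."))
  }
  weather
}
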