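# shared fixtures: all synthetic, built in code at test time

# constant dry weather with a fixed reference ET column
const_weather <- function(n_days, prcp = 0, et0 = 5,
                          start = as.Date("2023-06-11")) {
  tibble::tibble(
    date = seq(start, by = "day", length.out = n_days),
    prcp = rep_len(prcp, n_days),
    tmax = 30, tmin = 22,
    et0 = rep_len(et0, n_days)
  )
}

# a small fast site-season configuration (no organics, no background fluxes)
clean_rates <- function(...) {
  n_rate_params(base_min = 0, rain_conc = 0, ...)
}

quiet_season <- function(...) suppressWarnings(simulate_season(...))

# deterministic alternating wet/dry record, all wet amounts equal
alternating_weather <- function(n_days = 740, amount = 10) {
  tibble::tibble(
    date = seq(as.Date("2001-01-01"), by = "day", length.out = n_days),
    prcp = rep_len(c(amount, 0), n_days),
    tmax = 25, tmin = 15
  )
}
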