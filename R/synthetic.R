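#' Synthetic experimental site
#'
#' Builds a fully specified synthetic paddy site: crop calendar and
#' conventional fertilizer rate/split of one of the four network stations
#' (Gaoan 150 kg N ha^-1 at 6:4; Jingzhou 165 at 7:2:1; Nanjing 200 at 6:4;
#' Chizhou 192 at 11:7:2; the `default` profile mirrors Nanjing), together
#' with hydraulic parameters, N transformation rates, green-manure/straw
#' input definitions, monthly weather-generator parameters and observation
#' noise levels. The site object is the "truth" that
#' [generate_observations()] perturbs and that calibration tries to recover.
#'
#' The `default` profile uses fixed canonical parameters
#' (`perc_rate = 8` mm/day, `k_nh4 = 0.35`/day, `f_surf = 0.3`, bund height
#' `pd_max = 100` mm); named station profiles draw their hydraulic and rate
#' parameters from documented plausible ranges using `seed`. For Gaoan only
#' the early-rice season is represented.
#'
#' @param profile One of `"default"`, `"gaoan"`, `"jingzhou"`, `"nanjing"`,
#'   `"chizhou"`.
#' @param seed Integer seed for the station-profile parameter draws
#'   (ignored by `"default"`).
#' @return A list of class `paddy_site`.
#' @examples
#' site <- make_site("nanjing", seed = 1)
#' site$fert
#' @export
make_site <- function(profile = c("default", "gaoan", "jingzhou", "nanjing",
                                  "chizhou"),
                      seed = 1L) {
  valid <- c("default", "gaoan", "jingzhou", "nanjing", "chizhou")
  if (!is.character(profile) || !profile[1] %in% valid) {
    abort(paste0("unknown profile '", profile[1], "'; valid profiles: ",
                 paste(valid, collapse = ", "), "."))
  }
  profile <- match.arg(profile)

  defs <- list(
    default = list(lat = 31.00, transplant = "06-11", harvest = "10-01",
                   n_rate = 200, splits = c(basal = 0.6, tillering = 0.4),
                   fert_days = c(0, 20), rain_factor = 1.0),
    gaoan = list(lat = 28.42, transplant = "04-26", harvest = "07-17",
                 n_rate = 150, splits = c(basal = 0.6, tillering = 0.4),
                 fert_days = c(0, 20), rain_factor = 1.1),
    jingzhou = list(lat = 30.33, transplant = "05-20", harvest = "09-06",
                    n_rate = 165,
                    splits = c(basal = 0.7, tillering = 0.2, booting = 0.1),
                    fert_days = c(0, 20, 50), rain_factor = 0.85),
    nanjing = list(lat = 31.65, transplant = "06-11", harvest = "10-01",
                   n_rate = 200, splits = c(basal = 0.6, tillering = 0.4),
                   fert_days = c(0, 20), rain_factor = 0.85),
    chizhou = list(lat = 30.65, transplant = "06-06", harvest = "09-26",
                   n_rate = 192,
                   splits = c(basal = 0.55, tillering = 0.35, booting = 0.10),
                   fert_days = c(0, 20, 50), rain_factor = 1.1)
  )
  # Chizhou's 11:7:2 split expressed as fractions of 20
  defs$chizhou$splits <- c(basal = 11, tillering = 7, booting = 2) / 20
  d <- defs[[profile]]

  if (profile == "default") {
    perc_rate <- 8; k_nh4 <- 0.35; f_surf <- 0.30
    k_don <- 0.08; k_pn <- 0.2
  } else {
    draws <- withr::with_seed(seed, runif(5))
    perc_rate <- 5 + 6 * draws[1]
    k_nh4 <- 0.28 + 0.14 * draws[2]
    f_surf <- 0.22 + 0.16 * draws[3]
    k_don <- 0.06 + 0.04 * draws[4]
    k_pn <- 0.15 + 0.10 * draws[5]
  }

  weather_params <- markov_gamma_params(
    p_wd = c(.30, .32, .38, .40, .35, .40, .36, .35, .30, .30, .28, .28),
    p_ww = c(.55, .58, .60, .62, .58, .62, .62, .60, .55, .55, .52, .52),
    shape = c(.70, .70, .70, .70, .68, .65, .65, .65, .68, .70, .70, .70),
    scale = c(8, 9, 11, 14, 18, 24, 26, 24, 17, 12, 9, 8) * d$rain_factor,
    wet_threshold = 0.1,
    temperature = default_temperature_normals()
  )

  structure(
    list(
      profile = profile,
      latitude = d$lat,
      transplant = d$transplant,
      harvest = d$harvest,
      soil = soil_params(perc_rate = perc_rate, pd_max = 100),
      policy = irrigation_policy(pd_lower = 50, pd_target = 70),
      rates = n_rate_params(k_nh4 = k_nh4, k_no3 = 1.2, k_don = k_don,
                            k_pn = k_pn, nitrif_frac = 0.08),
      fert = fert_events(d$n_rate, d$splits, d$fert_days, f_surf = f_surf),
      gm = organic_input("green_manure"),
      straw = organic_input("straw"),
      init_conc = c(nh4 = 0.5, no3 = 0.2, don = 1.0, pn = 0.5),
      weather_params = weather_params,
      noise = c(ponding_depth = 0.05, conc = 0.10, runoff = 0.10),
      seed = seed
    ),
    class = "paddy_site"
  )
}

#' Truth parameters of a synthetic site
#'
#' The named parameter vector a calibration run tries to recover.
#'
#' @param site A [make_site()] object.
#' @return Named numeric vector.
#' @export
truth_params <- function(site) {
  c(perc_rate = site$soil$perc_rate, pd_max = site$soil$pd_max,
    k_nh4 = site$rates$k_nh4, k_no3 = site$rates$k_no3,
    k_don = site$rates$k_don, k_pn = site$rates$k_pn,
    nitrif_frac = site$rates$nitrif_frac,
    f_surf = site$fert$f_surf[1])
}

#' The four fertilization treatments
#'
#' FR: conventional fertilization (the winter-fallow baseline); FRS:
#' conventional plus straw return; MR: green manure with a 40% fertilizer N
#' reduction; MRS: green manure plus straw with a 40% reduction.
#'
#' @return A tibble with columns `name, fert_fraction, straw, green_manure`.
#' @examples
#' paddy_treatments()
#' @export
paddy_treatments <- function() {
  tibble::tibble(
    name = c("FR", "FRS", "MR", "MRS"),
    fert_fraction = c(1, 1, 0.6, 0.6),
    straw = c(FALSE, TRUE, FALSE, TRUE),
    green_manure = c(FALSE, FALSE, TRUE, TRUE)
  )
}

#' Management schedule of a treatment at a site
#'
#' Builds a [management_schedule()] for one treatment-year: the site's
#' fertilizer events scaled by the treatment's fertilizer fraction, plus the
#' green-manure and/or straw organic inputs the treatment prescribes.
#'
#' @param site A [make_site()] object.
#' @param treatment A treatment name (`"FR"`, `"FRS"`, `"MR"`, `"MRS"`) or a
#'   one-row slice of [paddy_treatments()].
#' @param year Calendar year used to anchor the crop dates.
#' @return A `management_schedule`.
#' @export
treatment_schedule <- function(site, treatment = "FR", year = 2023L) {
  if (is.character(treatment)) {
    tr <- paddy_treatments()
    treatment <- tr[tr$name == treatment, ]
    if (nrow(treatment) != 1L) {
      abort("`treatment` must be one of FR, FRS, MR, MRS.")
    }
  }
  fert <- site$fert
  fert$n_amount <- fert$n_amount * treatment$fert_fraction
  organics <- dplyr::bind_rows(
    if (treatment$green_manure) site$gm,
    if (treatment$straw) site$straw
  )
  if (is.null(organics)) organics <- site$gm[0, ]
  management_schedule(
    transplant = as.Date(sprintf("%d-%s", year, site$transplant)),
    harvest = as.Date(sprintf("%d-%s", year, site$harvest)),
    fertilization = fert,
    organics = organics,
    name = treatment$name,
    init_conc = site$init_conc
  )
}

#' Generate noisy synthetic field observations
#'
#' Runs the simulator under the site's true parameters for one season and
#' emits observation tables with the structure of a field campaign: daily
#' ponding depth, per-event runoff, and surface-water N concentrations (TN,
#' DIN, NH4) sampled on the fertilization day (pre-fertilization, "day 0")
#' and on days 1, 3, 5, 7 and 10 after each fertilization. Observations are
#' perturbed by multiplicative lognormal noise with the stated relative
#' standard deviations (mean-one parameterization, so zero noise reproduces
#' the simulation exactly); lognormal noise cannot produce negative values.
#'
#' @param site A [make_site()] object.
#' @param seed Integer seed driving both the season's weather and the noise.
#' @param noise Named relative standard deviations
#'   (`ponding_depth`, `conc`, `runoff`); defaults to `site$noise`.
#' @param treatment Treatment to observe (calibration uses `"FR"`).
#' @param year Calendar year of the season.
#' @return A list of class `paddy_observations`: `observations` (tibble
#'   `series, day, value, unit`), `weather` (the season's weather),
#'   `truth` (the site), `treatment`, `seed`.
#' @export
generate_observations <- function(site, seed = 1L, noise = site$noise,
                                  treatment = "FR", year = 2023L) {
  stopifnot(inherits(site, "paddy_site"))
  if (any(noise < 0)) abort("noise relative sds must be >= 0.")
  weather <- generate_weather(site$weather_params, n_years = 1L, seed = seed,
                              start_year = year)
  schedule <- treatment_schedule(site, treatment, year)
  season <- suppressWarnings(
    simulate_season(weather, schedule, site$soil, site$policy, site$rates,
                    site$latitude)
  )
  nd <- max(season$water$day)

  conc_at <- function(series, day) {
    season$nitrogen[[series]][match(day, season$nitrogen$day)]
  }
  # the "day 0, before fertilization" sample of a daily-step model is the
  # previous end-of-day state; the transplant-day event has no simulated
  # predecessor and contributes post-application samples only
  conc_obs <- purrr::map(c("c_tn", "c_din", "c_nh4"), function(s) {
    purrr::map(schedule$fertilization$day, function(d) {
      days <- c(if (d > 0) d - 1L, d + c(1L, 3L, 5L, 7L, 10L))
      days <- days[days >= 0 & days <= nd]
      tibble::tibble(series = s, day = days, value = conc_at(s, days),
                     unit = "mg N/L")
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows() |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::distinct(.data$series, .data$day, .keep_all = TRUE)

  pond_obs <- tibble::tibble(series = "ponding_depth", day = season$water$day,
                             value = season$water$pd, unit = "mm")
  rf_days <- season$water$day[season$water$rf > 0]
  runoff_obs <- tibble::tibble(series = "runoff", day = rf_days,
                               value = season$water$rf[match(rf_days, season$water$day)],
                               unit = "mm")
  obs <- dplyr::bind_rows(pond_obs, runoff_obs, conc_obs)

  # one composite water sample per day is analyzed for all N forms, so the
  # (dominant) sampling error is shared across concentration series of the
  # same day; depth and runoff readings err independently
  rel_sd <- dplyr::case_when(
    obs$series == "ponding_depth" ~ noise[["ponding_depth"]],
    obs$series == "runoff" ~ noise[["runoff"]],
    .default = noise[["conc"]]
  )
  conc_rows <- !obs$series %in% c("ponding_depth", "runoff")
  obs$value <- withr::with_seed(seed + 1L, {
    mult <- rlnorm(nrow(obs), meanlog = -rel_sd^2 / 2, sdlog = rel_sd)
    conc_days <- sort(unique(obs$day[conc_rows]))
    shared <- rlnorm(length(conc_days),
                     meanlog = -noise[["conc"]]^2 / 2, sdlog = noise[["conc"]])
    mult[conc_rows] <- shared[match(obs$day[conc_rows], conc_days)]
    obs$value * mult
  })

  structure(
    list(observations = obs, weather = weather, truth = site,
         treatment = if (is.character(treatment)) treatment else treatment$name,
         season = season, seed = seed),
    class = "paddy_observations"
  )
}
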