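#' Soil and field hydraulic parameters
#'
#' Bundle the hydraulic properties of a paddy field that control the daily
#' water balance: the steady percolation rate under ponding, the maximum
#' ponding depth before surface runoff spills over the bund, and the crop
#' coefficient schedule used to scale reference evapotranspiration.
#'
#' Percolation is represented as a constant daily rate under ponded
#' conditions (unit-gradient saturated flow); it is a calibration parameter,
#' not a measured soil property.
#'
#' @param perc_rate Steady percolation/infiltration under ponding, mm day^-1.
#' @param pd_max Maximum ponding depth before runoff (bund height), mm.
#' @param kc Named numeric vector of crop coefficients by growth phase,
#'   `c(initial, mid, late)`, dimensionless.
#' @param kc_initial_days Length of the initial crop phase, days after
#'   transplanting.
#' @param kc_late_days Length of the late-season phase before harvest, days.
#' @return A list of class `soil_params`.
#' @examples
#' soil_params(perc_rate = 8, pd_max = 100)
#' @export
soil_params <- function(perc_rate = 6,
                        pd_max = 250,
                        kc = c(initial = 1.05, mid = 1.2, late = 0.9),
                        kc_initial_days = 25,
                        kc_late_days = 20) {
  if (!is.numeric(perc_rate) || length(perc_rate) != 1L || is.na(perc_rate) || perc_rate < 0) {
    abort("`perc_rate` must be a single non-negative number (mm/day).")
  }
  if (!is.numeric(pd_max) || length(pd_max) != 1L || is.na(pd_max) || pd_max <= 0) {
    abort("`pd_max` must be a single positive number (mm).")
  }
  kc <- kc[c("initial", "mid", "late")]
  if (anyNA(kc) || any(kc <= 0)) {
    abort("`kc` must supply positive values named 'initial', 'mid' and 'late'.")
  }
  structure(
    list(perc_rate = perc_rate, pd_max = pd_max, kc = kc,
         kc_initial_days = kc_initial_days, kc_late_days = kc_late_days),
    class = "soil_params"
  )
}

#' Irrigation and drainage management policy
#'
#' Describes how the pond is managed: irrigation is triggered whenever the
#' ponding depth falls below `pd_lower` and refills to `pd_target`; during
#' drainage windows (mid-season drying at late tillering and pre-harvest
#' drying) irrigation is suppressed and the pond is drained.
#'
#' @param pd_lower Irrigation trigger depth, mm.
#' @param pd_target Post-irrigation depth, mm.
#' @param drainage_windows Optional tibble with integer columns `start` and
#'   `end` (days after transplanting, inclusive) during which the field is
#'   force-drained. When `NULL`, [simulate_water_season()] applies a default
#'   7-day late-tillering window (DAT 27-33) and a 10-day pre-harvest window.
#' @return A list of class `irrigation_policy`.
#' @examples
#' irrigation_policy(pd_lower = 20, pd_target = 60)
#' @export
irrigation_policy <- function(pd_lower = 20,
                              pd_target = 60,
                              drainage_windows = NULL) {
  if (!is.numeric(pd_lower) || pd_lower < 0) abort("`pd_lower` must be >= 0 mm.")
  if (!is.numeric(pd_target) || pd_target <= pd_lower) {
    abort("`pd_target` must exceed `pd_lower`.")
  }
  if (!is.null(drainage_windows)) {
    drainage_windows <- tibble::as_tibble(drainage_windows)
    if (!all(c("start", "end") %in% names(drainage_windows))) {
      abort("`drainage_windows` needs columns `start` and `end` (DAT).")
    }
    if (any(drainage_windows$end < drainage_windows$start)) {
      abort("each drainage window must have `end` >= `start`.")
    }
  }
  structure(
    list(pd_lower = pd_lower, pd_target = pd_target,
         drainage_windows = drainage_windows),
    class = "irrigation_policy"
  )
}

#' First-order surface-water nitrogen transformation rates
#'
#' The surface-water N pools (NH4+-N, NO3--N, dissolved organic N, particulate
#' N) each decay with a lumped first-order rate representing every removal
#' process the pool is subject to. NH4 removal lumps ammonia volatilization,
#' nitrification, crop uptake and adsorption; a fraction `nitrif_frac` of the
#' base NH4 removal is credited to the NO3 pool as nitrification. NO3 removal
#' lumps denitrification, uptake and leaching to soil; DON decays by microbial
#' decomposition; PN settles.
#'
#' In addition to the pool rates, a constant background flux `base_min`
#' (soil organic matter mineralization reaching the flood water, identical
#' across treatments) feeds the NH4 and DON pools on every ponded day, split
#' by `base_nh4_frac`. It sustains the low background concentrations observed
#' between fertilization events.
#'
#' @param k_nh4,k_no3,k_don,k_pn First-order removal rates, day^-1.
#' @param nitrif_frac Fraction of NH4 removal routed to the NO3 pool,
#'   dimensionless in \[0, 1\].
#' @param base_min Background mineralization flux into surface water,
#'   kg N ha^-1 day^-1 (while ponded).
#' @param base_nh4_frac NH4 share of the background flux (rest DON).
#' @param rain_conc Nitrogen concentration of rainfall (atmospheric wet
#'   deposition), mg N L^-1; each mm of rain adds `rain_conc * 1e-2`
#'   kg N ha^-1 split 60/20/20 between NH4, NO3 and DON.
#' @return A list of class `n_rate_params`.
#' @examples
#' n_rate_params()
#' @export
n_rate_params <- function(k_nh4 = 0.35,
                          k_no3 = 1.2,
                          k_don = 0.08,
                          k_pn = 0.2,
                          nitrif_frac = 0.08,
                          base_min = 0.15,
                          base_nh4_frac = 0.6,
                          rain_conc = 2.5) {
  rates <- c(k_nh4 = k_nh4, k_no3 = k_no3, k_don = k_don, k_pn = k_pn)
  if (anyNA(rates) || any(rates < 0)) {
    abort("all first-order rates must be non-negative (day^-1).")
  }
  if (is.na(nitrif_frac) || nitrif_frac < 0 || nitrif_frac > 1) {
    abort("`nitrif_frac` must lie in [0, 1].")
  }
  if (base_min < 0 || base_nh4_frac < 0 || base_nh4_frac > 1 || rain_conc < 0) {
    abort("`base_min` and `rain_conc` must be >= 0 and `base_nh4_frac` in [0, 1].")
  }
  structure(
    list(k_nh4 = k_nh4, k_no3 = k_no3, k_don = k_don, k_pn = k_pn,
         nitrif_frac = nitrif_frac, base_min = base_min,
         base_nh4_frac = base_nh4_frac, rain_conc = rain_conc),
    class = "n_rate_params"
  )
}

#' Mineral fertilizer application events
#'
#' Build the fertilization table of a management schedule from a seasonal
#' total and a named split, e.g. the common basal:tillering 6:4 split or the
#' three-way basal:tillering:booting splits.
#'
#' @param total_n Seasonal mineral fertilizer N, kg N ha^-1.
#' @param splits Named numeric vector of split fractions summing to 1; names
#'   from `c("basal", "tillering", "booting")`.
#' @param days Application days (DAT), same length and order as `splits`.
#' @param f_surf Fraction of applied N entering the surface-water dissolved
#'   pool on the application day (broadcast urea; calibration parameter).
#' @param f_pn Fraction of applied N entering the particulate N pool on the
#'   application day (application disturbance/algal uptake), dimensionless.
#' @return A tibble with columns `day`, `n_amount`, `kind`, `f_surf`, `f_pn`.
#' @examples
#' fert_events(200, c(basal = 0.6, tillering = 0.4), days = c(0, 20))
#' @export
fert_events <- function(total_n,
                        splits = c(basal = 0.6, tillering = 0.4),
                        days = c(0, 20),
                        f_surf = 0.3,
                        f_pn = 0.02) {
  if (total_n < 0) abort("`total_n` must be >= 0 kg N/ha.")
  if (length(splits) != length(days)) abort("`splits` and `days` lengths differ.")
  if (abs(sum(splits) - 1) > 1e-8) abort("`splits` must sum to 1.")
  if (f_surf < 0 || f_surf > 1) abort("`f_surf` must lie in [0, 1].")
  if (f_pn < 0 || f_surf + f_pn > 1) abort("`f_surf + f_pn` must not exceed 1.")
  tibble::tibble(
    day = as.integer(days),
    n_amount = total_n * as.numeric(splits),
    kind = names(splits) %||% rep("basal", length(splits)),
    f_surf = f_surf,
    f_pn = f_pn
  )
}

#' Organic matter inputs (green manure, straw)
#'
#' An organic input mineralizes from its incorporation day with first-order
#' rate `k_min`; the daily release is split `nh4_frac` / (1 - `nh4_frac`)
#' between the NH4 and DON surface pools, of which only the fraction `f_surf`
#' enters the surface water while the field is ponded (the remainder feeds the
#' soil store). Incorporation adds a small particulate-N pulse (`f_pn` of the
#' total organic N). High C:N residues such as rice straw additionally
#' immobilize surface NH4 while decomposing: an extra first-order NH4 removal
#' `k_immob * exp(-k_min * t)` proportional to the remaining residue mass.
#'
#' Defaults: green manure (Chinese milk vetch, low C:N) mineralizes fast
#' (`k_min` = 0.05/day) and does not immobilize; straw mineralizes slowly
#' (`k_min` = 0.01/day) and immobilizes (`k_immob` = 0.1/day at incorporation).
#'
#' @param kind `"green_manure"` or `"straw"`.
#' @param day Incorporation day (DAT); values <= 0 mean pre-transplant
#'   incorporation.
#' @param n_content Organic N incorporated, kg N ha^-1.
#' @param k_min First-order mineralization rate, day^-1.
#' @param nh4_frac Fraction of mineralized N released as NH4 (rest DON);\n#'   higher for the low C:N legume residue.
#' @param f_surf Fraction of in-season release entering surface water (the
#'   rest mineralizes within the soil matrix).
#' @param f_pn Fraction of `n_content` entering the PN pool at incorporation.
#' @param k_immob Extra first-order NH4 immobilization rate at full residue
#'   mass, day^-1 (decays with the residue).
#' @return A one-row tibble describing the input.
#' @examples
#' organic_input("green_manure", n_content = 60)
#' organic_input("straw")
#' @export
organic_input <- function(kind = c("green_manure", "straw"),
                          day = if (kind == "green_manure") -30L else -5L,
                          n_content = if (kind == "green_manure") 60 else 25,
                          k_min = if (kind == "green_manure") 0.05 else 0.01,
                          nh4_frac = if (kind == "green_manure") 0.8 else 0.6,
                          f_surf = 0.10,
                          f_pn = if (kind == "green_manure") 0.03 else 0.02,
                          k_immob = if (kind == "green_manure") 0 else 0.04) {
  kind <- match.arg(kind)
  if (n_content < 0) abort("`n_content` must be >= 0 kg N/ha.")
  if (k_min < 0 || k_immob < 0) abort("rates must be >= 0 day^-1.")
  if (nh4_frac < 0 || nh4_frac > 1 || f_surf < 0 || f_surf > 1 || f_pn < 0 || f_pn > 1) {
    abort("fractions must lie in [0, 1].")
  }
  tibble::tibble(
    day = as.integer(day), n_content = n_content, k_min = k_min, kind = kind,
    nh4_frac = nh4_frac, f_surf = f_surf, f_pn = f_pn, k_immob = k_immob
  )
}

#' Management schedule for one rice season
#'
#' Combines crop dates, mineral fertilization events and organic inputs into
#' the treatment definition consumed by [simulate_season()].
#'
#' @param transplant,harvest Transplanting and harvest dates (`Date` or
#'   `"YYYY-MM-DD"`).
#' @param fertilization Tibble from [fert_events()].
#' @param organics Tibble of [organic_input()] rows (zero rows for none).
#' @param name Treatment label (e.g. `"FR"`).
#' @param init_conc Named vector of initial surface-water concentrations
#'   `c(nh4, no3, don, pn)` in mg N L^-1 at transplanting.
#' @return A list of class `management_schedule`.
#' @examples
#' management_schedule("2023-06-11", "2023-10-01",
#'                     fert_events(200, days = c(0, 18)))
#' @export
management_schedule <- function(transplant,
                                harvest,
                                fertilization = fert_events(0, c(basal = 1), days = 0),
                                organics = organic_input("green_manure")[0, ],
                                name = "FR",
                                init_conc = c(nh4 = 0.5, no3 = 0.2, don = 1.0, pn = 0.5)) {
  transplant <- as.Date(transplant)
  harvest <- as.Date(harvest)
  if (is.na(transplant) || is.na(harvest) || harvest <= transplant) {
    abort("`harvest` must fall after `transplant`.")
  }
  fertilization <- tibble::as_tibble(fertilization)
  needed <- c("day", "n_amount", "kind", "f_surf", "f_pn")
  if (!all(needed %in% names(fertilization))) {
    abort(paste0("`fertilization` needs columns: ", paste(needed, collapse = ", ")))
  }
  if (any(fertilization$n_amount < 0)) abort("fertilizer amounts must be >= 0.")
  organics <- tibble::as_tibble(organics)
  if (anyNA(init_conc[c("nh4", "no3", "don", "pn")]) ||
      any(init_conc[c("nh4", "no3", "don", "pn")] < 0)) {
    abort("`init_conc` must supply non-negative nh4, no3, don, pn (mg/L).")
  }
  structure(
    list(transplant = transplant, harvest = harvest,
         fertilization = fertilization, organics = organics,
         name = name, init_conc = init_conc),
    class = "management_schedule"
  )
}

#' @export
print.management_schedule <- function(x, ...) {
  cat("<management_schedule> ", x$name, ": ",
      format(x$transplant), " -> ", format(x$harvest), "\n", sep = "")
  cat("  fertilizer N: ", sum(x$fertilization$n_amount), " kg N/ha in ",
      nrow(x$fertilization), " split(s)\n", sep = "")
  if (nrow(x$organics)) {
    cat("  organics: ", paste(x$organics$kind, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}
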