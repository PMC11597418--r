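#' Difference-method nitrogen form partitioning
#'
#' Assembles the composite nitrogen forms from the four measured/simulated
#' pools: `DIN = NH4 + NO3`, `DTN = DIN + DON`, `TN = DTN + PN`.
#'
#' @param c_nh4,c_no3,c_don,c_pn Concentrations by form, mg N L^-1
#'   (vectorized).
#' @return A tibble with columns `c_din, c_dtn, c_tn`.
#' @examples
#' partition_forms(5, 0.5, 2, 1.5)  # din 5.5, dtn 7.5, tn 9
#' @export
partition_forms <- function(c_nh4, c_no3, c_don, c_pn) {
  x <- c(c_nh4, c_no3, c_don, c_pn)
  if (any(!is.na(x) & x < 0)) abort("concentrations must be non-negative.")
  c_din <- c_nh4 + c_no3
  c_dtn <- c_din + c_don
  tibble::tibble(c_din = c_din, c_dtn = c_dtn, c_tn = c_dtn + c_pn)
}

# kg N / ha in a pond of depth pd mm  ->  mg N / L
# (1 kg/ha = 0.1 g/m2; 1 mm ponding = 1 L/m2; hence 100 * mass / pd)
conc_from_mass <- function(mass, pd) {
  out <- 100 * mass / pd
  out[rep_len(!(pd > 0), length(out))] <- NA_real_
  out
}

#' Surface-water nitrogen state
#'
#' Builds the per-area mass state of the four surface-water N pools together
#' with the concentrations they imply at the current ponding depth
#' (`conc = 100 * mass / pd` for mass in kg N ha^-1 and pd in mm).
#'
#' @param m_nh4,m_no3,m_don,m_pn Pool masses, kg N ha^-1.
#' @param pd Ponding depth, mm.
#' @return A one-row tibble with masses, `pd`, and concentrations
#'   `c_nh4, c_no3, c_don, c_pn, c_din, c_dtn, c_tn` (mg N L^-1; `NA` when
#'   the pond is empty).
#' @export
surface_n_state <- function(m_nh4 = 0, m_no3 = 0, m_don = 0, m_pn = 0, pd = 0) {
  m <- c(m_nh4, m_no3, m_don, m_pn)
  if (anyNA(m) || any(m < 0)) abort("pool masses must be non-negative.")
  if (pd < 0) abort("`pd` must be >= 0 mm.")
  conc <- conc_from_mass(m, pd)
  out <- tibble::tibble(
    m_nh4 = m_nh4, m_no3 = m_no3, m_don = m_don, m_pn = m_pn, pd = pd,
    c_nh4 = conc[1], c_no3 = conc[2], c_don = conc[3], c_pn = conc[4]
  )
  dplyr::bind_cols(out, partition_forms(conc[1], conc[2], conc[3], conc[4]))
}

#' Apply a fertilization event to the surface-water state
#'
#' On the application day a fraction `f_surf` of the applied N enters the
#' surface-water NH4 pool (urea is assumed hydrolyzed within the daily step)
#' and a fraction `f_pn` enters the particulate pool; the remainder goes to
#' the soil N store outside the surface system. If the pond is empty the
#' event cannot mix into surface water: the state is returned unchanged with
#' attribute `deferred = TRUE` and a warning (the season simulator re-applies
#' the event on the first ponded day).
#'
#' @param state A one-row state tibble from [surface_n_state()].
#' @param event A list or one-row tibble with `n_amount` (kg N ha^-1),
#'   `f_surf` and `f_pn`.
#' @param pd Ponding depth at application, mm.
#' @return The updated state (concentrations re-derived at `pd`).
#' @examples
#' st <- surface_n_state(pd = 50)
#' apply_fertilization(st, list(n_amount = 60, f_surf = 0.3, f_pn = 0), pd = 50)
#' @export
apply_fertilization <- function(state, event, pd) {
  n <- event$n_amount
  f_surf <- event$f_surf
  f_pn <- event$f_pn %||% 0
  if (n < 0 || f_surf < 0 || f_surf > 1 || f_pn < 0 || f_surf + f_pn > 1) {
    abort("invalid fertilization event: need n_amount >= 0 and fractions in [0, 1].")
  }
  if (pd <= 0) {
    warn("fertilization on a dry field: event deferred to the first ponded day.")
    out <- surface_n_state(state$m_nh4, state$m_no3, state$m_don, state$m_pn, pd)
    attr(out, "deferred") <- TRUE
    return(out)
  }
  surface_n_state(state$m_nh4 + f_surf * n, state$m_no3,
                  state$m_don, state$m_pn + f_pn * n, pd)
}

# one day of pool decay: exact exponential steps, nitrification credit from
# the base NH4 rate only (residue immobilization removes mineral N without
# producing NO3)
.n_decay <- function(m, rates, k_imm = 0) {
  k4 <- rates$k_nh4 + k_imm
  rem4 <- m[["nh4"]] * (1 - exp(-k4))
  credit <- if (k4 > 0) rates$nitrif_frac * rem4 * (rates$k_nh4 / k4) else 0
  rem3 <- m[["no3"]] * (1 - exp(-rates$k_no3))
  remD <- m[["don"]] * (1 - exp(-rates$k_don))
  remP <- m[["pn"]] * (1 - exp(-rates$k_pn))
  m_new <- c(
    nh4 = m[["nh4"]] - rem4,
    no3 = m[["no3"]] - rem3 + credit,
    don = m[["don"]] - remD,
    pn = m[["pn"]] - remP
  )
  list(m = m_new, removed = rem4 - credit + rem3 + remD + remP)
}

#' One day of surface-water nitrogen dynamics
#'
#' Advances the four N pools by one day against a simulated water-balance
#' record: (1) any mineralization release from active organic inputs is added
#' (split NH4/DON, surface fraction only); (2) each pool decays by its exact
#' exponential step, with the nitrification share of NH4 removal credited to
#' NO3; (3) if the day carries runoff, the runoff export (fully mixed,
#' pre-runoff concentration) is deducted. Concentrations are always re-derived
#' from masses and the day's depth, so dilution and evapo-concentration are
#' exact.
#'
#' @param state A one-row state tibble from [surface_n_state()].
#' @param rates An [n_rate_params()] object.
#' @param water_day A one-row water record (columns `pd`, `rf`, `day`), e.g.
#'   one row of [simulate_water_season()].
#' @param organics Optional tibble of [organic_input()] rows still active.
#' @return The updated state at the end-of-day depth.
#' @export
step_nitrogen <- function(state, rates, water_day, organics = NULL) {
  stopifnot(inherits(rates, "n_rate_params"))
  m <- c(nh4 = state$m_nh4, no3 = state$m_no3, don = state$m_don, pn = state$m_pn)
  pd_pre <- water_day$pd + water_day$rf
  if (pd_pre > 0 && rates$base_min > 0) {
    m[["nh4"]] <- m[["nh4"]] + rates$base_min * rates$base_nh4_frac
    m[["don"]] <- m[["don"]] + rates$base_min * (1 - rates$base_nh4_frac)
  }
  if (pd_pre > 0 && water_day$prem > 0 && rates$rain_conc > 0) {
    dep <- rates$rain_conc * water_day$prem * 1e-2
    m[["nh4"]] <- m[["nh4"]] + 0.6 * dep
    m[["no3"]] <- m[["no3"]] + 0.2 * dep
    m[["don"]] <- m[["don"]] + 0.2 * dep
  }
  k_imm <- 0
  if (!is.null(organics) && nrow(organics)) {
    t_rel <- water_day$day - organics$day
    act <- t_rel >= 0
    if (any(act)) {
      rel <- organics$n_content[act] *
        (exp(-organics$k_min[act] * t_rel[act]) -
           exp(-organics$k_min[act] * (t_rel[act] + 1)))
      if (pd_pre > 0) {
        surf <- rel * organics$f_surf[act]
        m[["nh4"]] <- m[["nh4"]] + sum(surf * organics$nh4_frac[act])
        m[["don"]] <- m[["don"]] + sum(surf * (1 - organics$nh4_frac[act]))
      }
      k_imm <- sum(organics$k_immob[act] * exp(-organics$k_min[act] * t_rel[act]))
    }
  }
  dec <- .n_decay(m, rates, k_imm)
  m <- dec$m
  if (water_day$rf > 0 && pd_pre > 0) {
    m <- m - m * min(1, water_day$rf / pd_pre)
  }
  surface_n_state(m[["nh4"]], m[["no3"]], m[["don"]], m[["pn"]], water_day$pd)
}

#' Runoff nitrogen loss for one or more events
#'
#' Per-form runoff loss of an event is `loss = conc * rf * 1e-2` with `conc`
#' in mg N L^-1, `rf` in mm and `loss` in kg N ha^-1. Composite-form losses
#' (`din`, `dtn`, `tn`) are derived by the difference-method sums.
#'
#' @param events A tibble with columns `rf` (mm) and concentrations
#'   `c_nh4, c_no3, c_don, c_pn` (mg N L^-1); any other columns (e.g. `day`)
#'   are carried through.
#' @return `events` with per-form loss columns
#'   `loss_nh4, loss_no3, loss_don, loss_pn, loss_din, loss_dtn, loss_tn`
#'   (kg N ha^-1).
#' @examples
#' runoff_n_loss(tibble::tibble(rf = 50, c_nh4 = 8, c_no3 = 1,
#'                              c_don = 0.5, c_pn = 0.5))
#' @export
runoff_n_loss <- function(events) {
  events <- tibble::as_tibble(events)
  need <- c("rf", "c_nh4", "c_no3", "c_don", "c_pn")
  missing <- setdiff(need, names(events))
  if (length(missing)) {
    abort(paste0("`events` is missing column(s): ", paste(missing, collapse = ", ")))
  }
  if (any(events$rf < 0)) abort("runoff must be non-negative.")
  out <- events
  for (f in c("nh4", "no3", "don", "pn")) {
    out[[paste0("loss_", f)]] <- out[[paste0("c_", f)]] * out$rf * 1e-2
  }
  out$loss_din <- out$loss_nh4 + out$loss_no3
  out$loss_dtn <- out$loss_din + out$loss_don
  out$loss_tn <- out$loss_dtn + out$loss_pn
  out
}

#' Seasonal nitrogen loss totals
#'
#' Sums the per-event runoff losses of a season by nitrogen form.
#'
#' @param events An event tibble from [runoff_n_loss()].
#' @return A one-row tibble of totals (kg N ha^-1): `tn, dtn, din, don, nh4,
#'   no3, pn` and the number of events `n_events`.
#' @export
season_n_loss <- function(events) {
  cols <- c("loss_tn", "loss_dtn", "loss_din", "loss_don",
            "loss_nh4", "loss_no3", "loss_pn")
  if (!all(cols %in% names(events))) {
    events <- runoff_n_loss(events)
  }
  tibble::tibble(
    tn = sum(events$loss_tn), dtn = sum(events$loss_dtn),
    din = sum(events$loss_din), don = sum(events$loss_don),
    nh4 = sum(events$loss_nh4), no3 = sum(events$loss_no3),
    pn = sum(events$loss_pn), n_events = nrow(events)
  )
}
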