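test_that("difference-method partitioning sums and inverts exactly", {
  p <- partition_forms(5, 0.5, 2, 1.5)
  expect_equal(p$c_din, 5.5)
  expect_equal(p$c_dtn, 7.5)
  expect_equal(p$c_tn, 9.0)
  expect_equal(unlist(partition_forms(0, 0, 0, 0)), c(c_din = 0, c_dtn = 0, c_tn = 0))

  withr::with_seed(99, {
    for (i in 1:50) {
      x <- runif(4, 0, 20)
      p <- partition_forms(x[1], x[2], x[3], x[4])
      # algebraic inverse: recover the pools by differences
      expect_equal(p$c_tn - p$c_dtn, x[4])
      expect_equal(p$c_dtn - p$c_din, x[3])
      expect_equal(p$c_din - x[1], x[2])
    }
  })
  expect_error(partition_forms(-1, 0, 0, 0), "non-negative")
})

test_that("fertilization raises NH4 concentration by the unit-oracle amount", {
  # 1 kg/ha dissolved in 1 mm of ponded water is 100 mg/L, so
  # 0.3 * 60 kg/ha in 50 mm adds 36 mg/L
  st <- surface_n_state(pd = 50)
  out <- apply_fertilization(st, list(n_amount = 60, f_surf = 0.3, f_pn = 0), 50)
  expect_equal(out$c_nh4 - st$c_nh4, 36)

  expect_equal(apply_fertilization(st, list(n_amount = 0, f_surf = 0.3), 50),
               st)
  # linearity: two equal applications double the added mass
  once <- apply_fertilization(st, list(n_amount = 30, f_surf = 0.3), 50)
  twice <- apply_fertilization(once, list(n_amount = 30, f_surf = 0.3), 50)
  expect_equal(twice$m_nh4 - st$m_nh4, 2 * (once$m_nh4 - st$m_nh4))

  expect_warning(apply_fertilization(st, list(n_amount = 10, f_surf = 0.3), 0),
                 "deferred")
})

test_that("pools decay by the analytic exponential", {
  rates <- clean_rates(k_nh4 = 0.3, k_no3 = 0, k_don = 0, k_pn = 0,
                       nitrif_frac = 0)
  st <- surface_n_state(m_nh4 = 10, m_no3 = 2, m_don = 3, m_pn = 1, pd = 60)
  day <- list(pd = 60, rf = 0, day = 1L, prem = 0)
  out <- step_nitrogen(st, rates, day)
  expect_equal(out$m_nh4, 10 * exp(-0.3))
  expect_equal(out$m_no3, 2)
  expect_equal(out$m_don, 3)
})

test_that("with all rates zero mass is conserved and dilution is exact", {
  rates <- clean_rates(k_nh4 = 0, k_no3 = 0, k_don = 0, k_pn = 0,
                       nitrif_frac = 0)
  st <- surface_n_state(4, 1, 2, 1, pd = 50)
  deep <- step_nitrogen(st, rates, list(pd = 100, rf = 0, day = 1L, prem = 0))
  expect_equal(deep$m_nh4, st$m_nh4)
  # depth doubled with no N fluxes: every concentration exactly halves
  expect_equal(deep$c_tn, st$c_tn / 2)
  expect_equal(deep$c_din, st$c_din / 2)
})

test_that("runoff loss follows conc x depth with the 1e-2 unit factor", {
  ev <- runoff_n_loss(tibble::tibble(rf = 50, c_nh4 = 8, c_no3 = 1,
                                     c_don = 0.5, c_pn = 0.5))
  expect_equal(ev$loss_tn, 10 * 50 * 1e-2)   # TN 10 mg/L, 50 mm -> 5 kg/ha
  expect_equal(ev$loss_din, 9 * 50 * 1e-2)

  ev0 <- runoff_n_loss(tibble::tibble(rf = 0, c_nh4 = 8, c_no3 = 1,
                                      c_don = 0.5, c_pn = 0.5))
  expect_true(all(unlist(ev0[grep("loss_", names(ev0))]) == 0))

  # seasonal totals equal an independent brute-force accumulation
  withr::with_seed(5, {
    events <- tibble::tibble(rf = runif(20, 0, 60),
                             c_nh4 = runif(20, 0, 30), c_no3 = runif(20, 0, 3),
                             c_don = runif(20, 0, 5), c_pn = runif(20, 0, 4))
  })
  totals <- season_n_loss(events)
  brute <- 0
  for (i in 1:20) {
    brute <- brute + (events$c_nh4[i] + events$c_no3[i] + events$c_don[i] +
                        events$c_pn[i]) * events$rf[i] * 1e-2
  }
  expect_equal(totals$tn, brute)
  expect_true(totals$tn >= totals$dtn && totals$dtn >= totals$din)
})

test_that("a season without any N input loses no nitrogen", {
  w <- const_weather(60, prcp = 0, et0 = 3)
  sch <- management_schedule(w$date[1], w$date[60],
                             fert_events(0, c(basal = 1), days = 0),
                             init_conc = c(nh4 = 0, no3 = 0, don = 0, pn = 0))
  out <- quiet_season(w, sch, soil_params(perc_rate = 5, pd_max = 100),
                      irrigation_policy(20, 60),
                      clean_rates(), latitude = 30)
  expect_equal(out$totals$tn, 0)
})

test_that("nitrogen mass balance closes over full seasons", {
  site <- make_site("default")
  for (sdd in c(2, 8)) {
    w <- generate_weather(site$weather_params, 1, seed = sdd, start_year = 2023)
    for (trt in c("FR", "MRS")) {
      out <- quiet_season(w, treatment_schedule(site, trt), site$soil,
                          site$policy, site$rates, site$latitude)
      expect_lt(abs(out$balance$n_residual), 1e-9)
      expect_lt(abs(out$balance$water_residual), 1e-9)
    }
  }
})

test_that("the concentration identity chain holds on every simulated day", {
  site <- make_site("default")
  w <- generate_weather(site$weather_params, 1, seed = 4, start_year = 2023)
  out <- quiet_season(w, treatment_schedule(site, "FRS"), site$soil,
                      site$policy, site$rates, site$latitude)
  n <- out$nitrogen[!is.na(out$nitrogen$c_tn), ]
  expect_true(all(n$c_tn >= n$c_dtn - 1e-12))
  expect_true(all(n$c_dtn >= n$c_din - 1e-12))
  expect_true(all(n$c_din >= n$c_nh4 - 1e-12))
})

test_that("seasonal TN loss grows with fertilizer rate and with f_surf", {
  site <- make_site("default")
  w <- generate_weather(site$weather_params, 1, seed = 6, start_year = 2023)
  run_with <- function(total_n, f_surf = 0.3) {
    sch <- management_schedule("2023-06-11", "2023-10-01",
                               fert_events(total_n, days = c(0, 20),
                                           f_surf = f_surf),
                               init_conc = site$init_conc)
    quiet_season(w, sch, site$soil, site$policy, site$rates,
                 site$latitude)$totals$tn
  }
  by_rate <- vapply(c(0, 100, 200, 300), run_with, numeric(1))
  expect_true(all(diff(by_rate) >= 0))
  by_fsurf <- vapply(c(0.1, 0.3, 0.5), function(f) run_with(200, f), numeric(1))
  expect_true(all(diff(by_fsurf) >= 0))
})

test_that("reduced fertilizer with green manure loses strictly less DIN", {
  site <- make_site("default")
  w <- generate_weather(site$weather_params, 1, seed = 10, start_year = 2023)
  fr <- quiet_season(w, treatment_schedule(site, "FR"), site$soil,
                     site$policy, site$rates, site$latitude)
  mr <- quiet_season(w, treatment_schedule(site, "MR"), site$soil,
                     site$policy, site$rates, site$latitude)
  expect_lt(mr$totals$din, fr$totals$din)
})

test_that("concentration declines monotonically after a pulse on dry weather", {
  w <- const_weather(40, prcp = 0, et0 = 5)
  sch <- management_schedule(w$date[1], w$date[40],
                             fert_events(200, c(basal = 1), days = 0, f_pn = 0),
                             init_conc = c(nh4 = 0, no3 = 0, don = 0, pn = 0))
  policy <- irrigation_policy(50, 70,
                              drainage_windows = tibble::tibble(start = integer(),
                                                                end = integer()))
  out <- quiet_season(w, sch, soil_params(perc_rate = 8, pd_max = 100), policy,
                      clean_rates(nitrif_frac = 0), latitude = 30)
  tn <- out$nitrogen$c_tn
  expect_equal(which.max(tn), 1L)            # peak on the application day
  expect_true(all(diff(tn) <= 1e-12))
})

test_that("fertilization on a drained day defers to the next ponded day", {
  w <- const_weather(30, prcp = 0, et0 = 5)
  policy <- irrigation_policy(20, 60,
                              drainage_windows = tibble::tibble(start = 0L, end = 2L))
  sch <- management_schedule(w$date[1], w$date[30],
                             fert_events(100, c(basal = 1), days = 0),
                             init_conc = c(nh4 = 0, no3 = 0, don = 0, pn = 0))
  expect_warning(
    out <- simulate_season(w, sch, soil_params(perc_rate = 5, pd_max = 100),
                           policy, clean_rates(), latitude = 30),
    "deferred"
  )
  n <- out$nitrogen
  expect_equal(n$m_nh4[n$day <= 2], rep(0, 3))        # nothing while drained
  expect_gt(n$m_nh4[n$day == 3], 0)                   # applied when ponded
})
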