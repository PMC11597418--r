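test_that("reference ET passes through supplied et0 and estimates otherwise", {
  w <- const_weather(3, et0 = 4.2)
  expect_equal(reference_et(w, 30)$et0, rep(4.2, 3))

  w2 <- tibble::tibble(date = as.Date("2023-06-29"), prcp = 0,
                       tmax = 30, tmin = 20)
  # frozen value from an independent hand evaluation of the Hargreaves form
  # (tmax 30, tmin 20, lat 30 N, DOY 180)
  expect_equal(reference_et(w2, 30)$et0, 5.21855322078, tolerance = 1e-9)

  # zero diurnal range forces et0 = 0 through the sqrt(Tmax - Tmin) factor
  w3 <- tibble::tibble(date = as.Date("2023-06-29"), prcp = 0,
                       tmax = 25, tmin = 25)
  expect_equal(reference_et(w3, 30)$et0, 0)

  w4 <- tibble::tibble(date = as.Date("2023-06-29"), prcp = 0,
                       tmax = NA_real_, tmin = NA_real_)
  expect_error(reference_et(w4, 30), "missing temperatures")
})

test_that("single-day balance follows the flux order and runoff threshold", {
  soil <- soil_params(perc_rate = 10, pd_max = 100)
  policy <- irrigation_policy(20, 60)
  r <- step_water_balance(50, prcp = 30, et0 = 5, soil = soil,
                          policy = policy, kc = 1)
  expect_equal(r$pd, 65)      # 50 + 30 - 5 - 10
  expect_equal(r$rf, 0)

  r2 <- step_water_balance(90, prcp = 80, et0 = 5, soil = soil,
                           policy = policy, kc = 1)
  expect_equal(r2$rf, 55)     # intermediate 155 spills above the 100 mm bund
  expect_equal(r2$pd, 100)

  expect_error(step_water_balance(-1, 0, 0, soil, policy), "non-negative")
})

test_that("irrigation triggers only below pd_lower and refills to pd_target", {
  soil <- soil_params(perc_rate = 10, pd_max = 200)
  policy <- irrigation_policy(pd_lower = 20, pd_target = 60)
  # hand-iterated dry spell from pd = 100 with et 5 + inf 10 per day:
  # 85, 70, 55, 40, 25, 10 -> refill day: irrigation tops up to 60 - wait,
  # the trigger fires when the post-rain depth is below 20, i.e. at 10.
  pd <- 100; irri_days <- integer(0)
  for (d in 1:7) {
    r <- step_water_balance(pd, 0, 5, soil, policy, kc = 1)
    if (r$irri > 0) irri_days <- c(irri_days, d)
    pd <- r$pd
  }
  expect_equal(irri_days, 7)            # first trigger after six 15 mm days
  expect_equal(pd, 60 - 15)             # refilled to target, then day fluxes
})

test_that("runoff is non-decreasing in depth and zero below the bund", {
  soil <- soil_params(perc_rate = 0, pd_max = 120)
  policy <- irrigation_policy(0.001, 60)
  pds <- seq(0, 300, by = 10)
  rf <- vapply(pds, function(p) {
    step_water_balance(p, 0, 0, soil, policy, kc = 1)$rf
  }, numeric(1))
  expect_true(all(diff(rf) >= 0))
  expect_true(all(rf[pds <= 120] == 0))
  expect_equal(rf[pds > 120], pds[pds > 120] - 120)
})

test_that("seasonal water budget closes exactly and respects the bund", {
  site <- make_site("default")
  w <- generate_weather(site$weather_params, 1, seed = 13, start_year = 2023)
  out <- simulate_water_season(w, site$soil, site$policy,
                               "2023-06-11", "2023-10-01", site$latitude)
  residual <- sum(out$prem) + sum(out$irri) - sum(out$et) - sum(out$inf) -
    sum(out$rf) - (out$pd[nrow(out)] - attr(out, "pd_init"))
  expect_lt(abs(residual), 1e-9)
  expect_true(all(out$pd >= 0))
  expect_true(all(out$pd[!out$drained] <= site$soil$pd_max + 1e-12))
  expect_true(all(out$pd[out$drained] == 0))
})

test_that("a 300 mm storm on a full pond must run off almost entirely", {
  soil <- soil_params(perc_rate = 8, pd_max = 250)
  policy <- irrigation_policy(20, 60)
  r <- step_water_balance(250, prcp = 300, et0 = 5, soil = soil,
                          policy = policy, kc = 1)
  expect_gte(r$rf, 300 - (r$et + r$inf))
})

test_that("zero-flux season keeps the pond constant with no runoff", {
  w <- const_weather(60, prcp = 0, et0 = 0)
  soil <- soil_params(perc_rate = 0, pd_max = 100,
                      kc_initial_days = 0, kc_late_days = 0)
  policy <- irrigation_policy(20, 60,
                              drainage_windows = tibble::tibble(start = integer(),
                                                                end = integer()))
  out <- simulate_water_season(w, soil, policy, w$date[1], w$date[60])
  expect_true(all(out$pd == 60))
  expect_true(all(out$rf == 0))
})

test_that("more percolation never produces more seasonal runoff", {
  site <- make_site("default")
  w <- generate_weather(site$weather_params, 1, seed = 17, start_year = 2023)
  totals <- vapply(c(2, 6, 10, 14), function(p) {
    soil <- soil_params(perc_rate = p, pd_max = 100)
    sum(simulate_water_season(w, soil, site$policy, "2023-06-11", "2023-10-01",
                              site$latitude)$rf)
  }, numeric(1))
  expect_true(all(diff(totals) <= 1e-9))
})

test_that("weather gaps are reported with the missing date", {
  w <- const_weather(50)
  w <- w[-25, ]
  expect_error(
    simulate_water_season(w, soil_params(), irrigation_policy(),
                          w$date[1], w$date[1] + 48),
    format(as.Date("2023-06-11") + 24)
  )
})
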