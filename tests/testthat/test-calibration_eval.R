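test_that("metric identities hold at a perfect fit", {
  o <- c(1.2, 3.4, 2.2, 5.1)
  expect_equal(rmse(o, o), 0)
  expect_equal(nse(o, o), 1)
  expect_equal(agreement_index(o, o), 1)
  # simulating the observed mean scores zero efficiency
  expect_equal(nse(o, rep(mean(o), 4)), 0)
})

test_that("hand-computed oracle values are reproduced", {
  expect_equal(rmse(c(0, 0), c(3, 4)), sqrt(25 / 2))
  # O = (1,3), P = (3,1): numerator 8, denominator (1+1)^2 + (1+1)^2 = 8
  expect_equal(agreement_index(c(1, 3), c(3, 1)), 0)
  # scaling both series scales rmse by |c|
  o <- c(1, 2, 8); p <- c(2, 1, 6)
  expect_equal(rmse(3 * o, 3 * p), 3 * rmse(o, p))
})

test_that("metrics match direct formula evaluation on random vectors", {
  withr::with_seed(31, {
    for (i in 1:100) {
      n <- sample(3:12, 1)
      o <- rnorm(n, 10, 4)
      p <- o + rnorm(n, 0, 2)
      expect_equal(rmse(o, p), sqrt(sum((o - p)^2) / n))
      expect_equal(nse(o, p), 1 - sum((o - p)^2) / sum((o - mean(o))^2))
      d <- 1 - sum((o - p)^2) /
        sum((abs(p - mean(o)) + abs(o - mean(o)))^2)
      expect_equal(agreement_index(o, p), d)
      expect_gte(agreement_index(o, p), 0)
      expect_lte(agreement_index(o, p), 1)
    }
  })
})

test_that("undefined metrics raise instead of returning sentinels", {
  expect_error(rmse(1:3, 1:4), "length mismatch")
  expect_error(nse(c(2, 2, 2), c(1, 2, 3)), "constant")
  expect_error(agreement_index(c(2, 2), c(2, 2)), "zero potential error")
})

test_that("zero-noise observations with truth at the start give a perfect fit", {
  site <- make_site("default")
  obs <- suppressWarnings(generate_observations(
    site, seed = 3, noise = c(ponding_depth = 0, conc = 0, runoff = 0)))
  # bounds whose midpoints sit exactly on the generating truth
  spec <- calib_spec(parameters = tibble::tibble(
    name = c("perc_rate", "k_nh4", "f_surf"),
    lower = c(1, 0.1, 0.1), upper = c(15, 0.6, 0.5)),
    n_grid = 5, n_refine = 1)
  fit <- calibrate(obs$observations, obs$weather,
                   treatment_schedule(site, "FR"), site$soil, site$policy,
                   site$rates, site$latitude, spec = spec)
  expect_equal(fit$objective, 0)
  expect_equal(unname(fit$estimate["perc_rate"]), 8)
  expect_equal(unname(fit$estimate["k_nh4"]), 0.35)
  expect_equal(unname(fit$estimate["f_surf"]), 0.3)
  expect_true(all(fit$metrics$d == 1))
  expect_true(all(fit$metrics$e == 1))
  expect_true(all(fit$metrics$rmse == 0))
})

test_that("the descent trace is monotone and the fit reproducible", {
  site <- make_site("default")
  obs <- suppressWarnings(generate_observations(site, seed = 12))
  spec <- calib_spec(n_grid = 5, n_refine = 2, max_sweeps = 2)
  fit1 <- calibrate(obs$observations, obs$weather,
                    treatment_schedule(site, "FR"), site$soil, site$policy,
                    site$rates, site$latitude, spec = spec, seed = 12)
  expect_true(all(diff(fit1$trace$objective) <= 0))
  fit2 <- calibrate(obs$observations, obs$weather,
                    treatment_schedule(site, "FR"), site$soil, site$policy,
                    site$rates, site$latitude, spec = spec, seed = 12)
  expect_identical(fit1$estimate, fit2$estimate)
  expect_identical(fit1$objective, fit2$objective)
})

test_that("parameters fitted on FR transfer to other treatments for validation", {
  site <- make_site("default")
  obs_fr <- suppressWarnings(generate_observations(site, seed = 3))
  obs_mr <- suppressWarnings(generate_observations(site, seed = 3,
                                                   treatment = "MR"))
  params <- c(perc_rate = 8, k_nh4 = 0.35, f_surf = 0.3)
  val <- simulation_metrics(obs_mr$observations, obs_mr$weather,
                            treatment_schedule(site, "MR"), site$soil,
                            site$policy, site$rates, site$latitude,
                            params = params)
  expect_setequal(val$series,
                  c("ponding_depth", "runoff", "c_tn", "c_din", "c_nh4"))
  expect_true(all(val$rmse >= 0))
  # true parameters applied to the held-out treatment still fit well
  expect_true(all(val$d[val$series %in% c("c_tn", "c_din")] > 0.8))
})

test_that("invalid calibration specifications are rejected", {
  expect_error(calib_spec(parameters = tibble::tibble(
    name = "mystery", lower = 0, upper = 1)), "unknown calibration parameter")
  expect_error(calib_spec(parameters = tibble::tibble(
    name = "k_nh4", lower = 1, upper = 0.5)), "lower < upper")
  site <- make_site("default")
  obs <- suppressWarnings(generate_observations(site, seed = 3))
  const_obs <- obs$observations
  const_obs$value[const_obs$series == "c_tn"] <- 5
  expect_error(
    calibrate(const_obs, obs$weather, treatment_schedule(site, "FR"),
              site$soil, site$policy, site$rates, site$latitude),
    "constant"
  )
})

test_that("tidy and glance summarize a fit", {
  site <- make_site("default")
  obs <- suppressWarnings(generate_observations(site, seed = 3))
  spec <- calib_spec(n_grid = 3, n_refine = 1, max_sweeps = 1)
  fit <- calibrate(obs$observations, obs$weather,
                   treatment_schedule(site, "FR"), site$soil, site$policy,
                   site$rates, site$latitude, spec = spec)
  td <- tidy(fit)
  expect_equal(td$parameter, c("perc_rate", "k_nh4", "f_surf"))
  expect_true(all(td$estimate >= td$lower & td$estimate <= td$upper))
  gl <- glance(fit)
  expect_equal(gl$n_eval, fit$n_eval)
})
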