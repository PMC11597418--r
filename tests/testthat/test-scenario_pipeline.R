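make_toy_losses <- function() {
  # 6 years, 2 known wet / 2 normal / 2 dry, fixed losses
  tibble::tibble(
    year = rep(1:6, each = 2),
    treatment = rep(c("FR", "MR"), 6),
    P = rep(c(900, 880, 700, 690, 500, 480), each = 2),
    runoff = 100,
    tn = c(10, 8, 12, 9, 6, 5, 7, 5, 4, 3.5, 3, 2.5),
    dtn = 1, din = c(5, 4, 6, 4.5, 3, 2.5, 3.5, 2.5, 2, 1.75, 1.5, 1.25),
    don = 1, nh4 = 1, no3 = 0.1, pn = 0.5
  )
}

toy_classes <- function() {
  drought_index(tibble::tibble(year = 1:6, P = c(900, 880, 700, 690, 500, 480)))
}

test_that("group means equal a spreadsheet-style brute-force average", {
  summ <- summarize_by_year_type(make_toy_losses(), toy_classes(),
                                 baseline = "FR", n_boot = 200, seed = 1)
  bg <- summ$by_group
  # wet years are 1 and 2 (P = 900, 880): FR mean = (10 + 12) / 2
  expect_equal(bg$mean_tn[bg$treatment == "FR" & bg$label == "wet"], 11)
  expect_equal(bg$mean_tn[bg$treatment == "MR" & bg$label == "wet"], 8.5)
  expect_equal(bg$mean_tn[bg$treatment == "FR" & bg$label == "dry"], 3.5)
  expect_equal(bg$n_years[bg$treatment == "FR" & bg$label == "normal"], 2)
})

test_that("percent reductions are the documented arithmetic", {
  summ <- summarize_by_year_type(make_toy_losses(), toy_classes(),
                                 n_boot = 200, seed = 1)
  red <- summ$reductions
  wet <- red[red$label == "wet", ]
  expect_equal(wet$abs_reduction_tn, 11 - 8.5)
  expect_equal(wet$pct_reduction_tn, 100 * (11 - 8.5) / 11)
  # reductions recomputed from the stored group means match exactly
  bg <- summ$by_group
  for (lb in c("dry", "normal", "wet")) {
    base_mean <- bg$mean_tn[bg$treatment == "FR" & bg$label == lb]
    trt_mean <- bg$mean_tn[bg$treatment == "MR" & bg$label == lb]
    expect_equal(red$abs_reduction_tn[red$label == lb], base_mean - trt_mean)
  }
})

test_that("a treatment identical to baseline shows zero, insignificant reduction", {
  losses <- make_toy_losses()
  losses$tn[losses$treatment == "MR"] <- losses$tn[losses$treatment == "FR"]
  losses$din[losses$treatment == "MR"] <- losses$din[losses$treatment == "FR"]
  summ <- summarize_by_year_type(losses, toy_classes(), n_boot = 200, seed = 2)
  expect_true(all(summ$reductions$pct_reduction_tn == 0))
  expect_true(all(!summ$reductions$sig_tn))
})

test_that("summaries are invariant to row order", {
  losses <- make_toy_losses()
  summ1 <- summarize_by_year_type(losses, toy_classes(), n_boot = 500, seed = 3)
  shuffled <- losses[rev(seq_len(nrow(losses))), ]
  summ2 <- summarize_by_year_type(shuffled, toy_classes(), n_boot = 500, seed = 3)
  expect_equal(summ1$by_group, summ2$by_group)
  expect_equal(summ1$reductions$pct_reduction_tn,
               summ2$reductions$pct_reduction_tn)
})

test_that("an empty year type yields an n = 0 row without comparisons", {
  losses <- make_toy_losses()[1:8, ]            # drop the dry years
  classes <- toy_classes()[1:4, ]
  summ <- summarize_by_year_type(losses, classes, n_boot = 200, seed = 1)
  dry <- summ$reductions[summ$reductions$label == "dry", ]
  expect_equal(dry$n_years, 0L)
  expect_true(is.na(dry$pct_reduction_tn))
})

test_that("unclassified years and absent baselines are rejected", {
  expect_error(summarize_by_year_type(make_toy_losses(), toy_classes()[1:3, ]),
               "classified")
  expect_error(summarize_by_year_type(make_toy_losses(), toy_classes(),
                                      baseline = "XX"), "baseline")
})

test_that("scenario runs are pure: duplicate treatments give identical losses", {
  site <- make_site("default")
  w <- generate_weather(site$weather_params, 2, seed = 23)
  tr <- paddy_treatments()[c(1, 1), ]
  out <- run_scenarios(site, w, treatments = tr)
  a <- out[seq(1, nrow(out) / 2), ]
  b <- out[seq(nrow(out) / 2 + 1, nrow(out)), ]
  expect_equal(a$tn, b$tn)
  expect_equal(a$runoff, b$runoff)
})

test_that("MR never exceeds FR DIN loss in any paired year", {
  site <- make_site("default")
  w <- generate_weather(site$weather_params, 5, seed = 29)
  out <- run_scenarios(site, w, treatments = paddy_treatments()[c(1, 3), ])
  wide <- tidyr::pivot_wider(out[, c("year", "treatment", "din")],
                             names_from = "treatment", values_from = "din")
  expect_true(all(wide$MR <= wide$FR))
})
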