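single_region_series <- function(temp_c, deaths, start = "2015-06-01") {
  dates <- as.Date(start) + seq_along(temp_c) - 1
  list(
    temps = tibble::tibble(region_id = "A", date = dates, temp_c = temp_c),
    deaths = tibble::tibble(region_id = "A", date = dates, deaths = deaths)
  )
}

test_that("yearly baseline rate averages deaths in the OT window", {
  # deaths are missing on the two hottest days; of the remaining days,
  # 26.5, 27 and 29 lie within +/-2 of OT = 28 -> mean(3, 5, 4) = 4
  s <- single_region_series(c(26.5, 27, 29, 30, 31), c(3L, 5L, 4L, NA, NA))
  out <- estimate_mmtd_year(s$deaths, s$temps, ot = 28, year = 2015)
  expect_equal(out$mmtd, 4)
  expect_equal(out$qualifying_days, 3L)

  # every day inside the window with constant deaths
  s <- single_region_series(rep(28, 10), rep(7L, 10))
  out <- estimate_mmtd_year(s$deaths, s$temps, ot = 28, year = 2015)
  expect_equal(out$mmtd, 7)
  expect_equal(out$qualifying_days, 10L)

  # all days outside the window: missing with a warning
  s <- single_region_series(c(35, 36, 37), c(1L, 2L, 3L))
  expect_warning(out <- estimate_mmtd_year(s$deaths, s$temps, 28, 2015),
                 "missing")
  expect_true(is.na(out$mmtd))
  expect_equal(out$qualifying_days, 0L)
})

test_that("sparse region-years fall back to a widened then pooled window", {
  clim <- tibble::tibble(region_id = "A", ot = 28, smt = 28, p95 = 32)
  cfg <- run_config(mmtd_fit_years = c(2013, 2014))
  # 2013: 6 days within +/-2 (observed); 2014: 3 within +/-2 but 6 within +/-3
  t13 <- rep(c(27, 29), 3)
  t14 <- c(27, 28, 29, 30.5, 30.5, 30.5)
  s <- single_region_series(c(t13, rep(40, 359), t14), # pad year boundary
                            c(rep(4L, 6), rep(0L, 359), rep(6L, 6)),
                            start = "2013-01-01")
  out <- estimate_mmtd(s$deaths, s$temps, clim, cfg)
  o13 <- out[out$year == 2013, ]
  expect_equal(o13$source, "observed")
  expect_equal(o13$mmtd, 4)
  o14 <- out[out$year == 2014, ]
  expect_equal(o14$source, "widened")
  expect_equal(o14$qualifying_days, 6L)
  expect_equal(o14$mmtd, 6)
})

test_that("persistently sparse years use the pooled multi-year mean", {
  clim <- tibble::tibble(region_id = "A", ot = 28, smt = 28, p95 = 32)
  cfg <- run_config(mmtd_fit_years = c(2013, 2014))
  # 2013 has 6 qualifying days of 4 deaths; 2014 only 2 days of 10 deaths
  days13 <- rep(28, 6)
  days14 <- c(28, 28)
  s <- single_region_series(c(days13, rep(40, 359), days14),
                            c(rep(4L, 6), rep(0L, 359), rep(10L, 2)),
                            start = "2013-01-01")
  out <- estimate_mmtd(s$deaths, s$temps, clim, cfg)
  o14 <- out[out$year == 2014, ]
  expect_equal(o14$source, "pooled")
  # pooled over all 8 qualifying days: (6*4 + 2*10) / 8
  expect_equal(o14$mmtd, (6 * 4 + 2 * 10) / 8)
  expect_equal(o14$qualifying_days, 8L)
})

test_that("the MMTD trend line reproduces exact and degenerate fits", {
  obs <- tibble::tibble(region_id = "A", year = 2013:2019, mmtd = 10:16)
  model <- fit_mmtd_model(obs)
  expect_equal(model$fits$slope, 1)
  expect_equal(model$fits$intercept + model$fits$slope * 2013, 10)

  flat <- tibble::tibble(region_id = "A", year = 2013:2019, mmtd = rep(5, 7))
  model <- fit_mmtd_model(flat)
  expect_equal(model$fits$slope, 0)
  expect_equal(predict_mmtd(model, 2010:2023)$mmtd, rep(5, 14))
})

test_that("the trend fit matches the normal-equations solution", {
  set.seed(7)
  for (i in 1:20) {
    obs <- tibble::tibble(region_id = "A", year = 2013:2019,
                          mmtd = 8 + 0.4 * (0:6) + rnorm(7))
    model <- fit_mmtd_model(obs)
    oracle <- ols_oracle(obs$year, obs$mmtd)
    expect_equal(model$fits$intercept, unname(oracle["intercept"]),
                 tolerance = 1e-8)
    expect_equal(model$fits$slope, unname(oracle["slope"]), tolerance = 1e-8)
  }
})

test_that("prediction uses observed values inside and the line outside", {
  obs <- tibble::tibble(region_id = "A", year = 2013:2019, mmtd = 10:16)
  obs$mmtd[3] <- 13.7  # 2015 deviates from the line
  model <- fit_mmtd_model(obs, fit_window = c(2013, 2019))
  pred <- predict_mmtd(model, c(2010, 2015, 2023))
  expect_equal(pred$source, c("extrapolated", "observed", "extrapolated"))
  expect_equal(pred$mmtd[pred$year == 2015], 13.7)  # observed, not fitted
  # the exact 10..16 line (2015 barely perturbs it); check against the
  # model's own coefficients
  line <- model$fits$intercept + model$fits$slope * c(2010, 2023)
  expect_equal(pred$mmtd[pred$year %in% c(2010, 2023)], line)

  exact <- fit_mmtd_model(tibble::tibble(region_id = "A", year = 2013:2019,
                                         mmtd = 10:16))
  pred <- predict_mmtd(exact, c(2010, 2023))
  expect_equal(pred$mmtd, c(7, 20))
})

test_that("negative extrapolations are floored at zero with a warning", {
  obs <- tibble::tibble(region_id = "A", year = 2013:2019,
                        mmtd = seq(30, 0, length.out = 7))
  model <- fit_mmtd_model(obs)
  expect_warning(pred <- predict_mmtd(model, 2023), "floored")
  expect_equal(pred$mmtd, 0)
})

test_that("regions with fewer than two observations are named in the error", {
  obs <- tibble::tibble(region_id = c("A", "A", "B"), year = c(2013, 2014, 2013),
                        mmtd = c(5, 6, 7))
  expect_error(fit_mmtd_model(obs), "B")
})

test_that("the estimator recovers a constant true baseline within 3 SE", {
  cfg <- scenario_config(n_regions = 2, years = 2013:2019, mmtd_level = 12,
                         mmtd_drift = 0, warming_per_decade = 0, seed = 31)
  temps <- generate_temperature(cfg)
  deaths <- generate_mortality(temps, cfg)
  clim <- build_climatology(temps, run_config(climatology_window = c(2013, 2019)))
  out <- estimate_mmtd(deaths, temps, clim, run_config(climatology_window = c(2013, 2019)))
  expect_true(all(out$qualifying_days >= 30))
  se <- sqrt(12 / out$qualifying_days)
  expect_true(all(abs(out$mmtd - 12) <= 3 * se))
})

test_that("extrapolation recovers a drifting true baseline within 3 SE", {
  cfg <- scenario_config(n_regions = 2, years = 2010:2023, mmtd_level = 10,
                         mmtd_drift = 0.3, warming_per_decade = 0, seed = 32)
  temps <- generate_temperature(cfg)
  deaths <- generate_mortality(temps, cfg)
  rc <- run_config()
  clim <- build_climatology(temps, rc)
  model <- fit_mmtd_model(estimate_mmtd(deaths, temps, clim, rc),
                          fit_window = rc$mmtd_fit_years)
  pred <- predict_mmtd(model, c(2010, 2023))
  true_vals <- 10 + 0.3 * (pred$year - 2010)
  # extrapolated line SE: generous bound from per-year estimate SEs (~0.2)
  expect_true(all(abs(pred$mmtd - true_vals) < 3 * 0.6))
})
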