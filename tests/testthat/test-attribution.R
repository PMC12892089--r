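toy_climatology <- function(ot = 28, smt = 28, p95 = 32, regions = "A") {
  tibble::tibble(region_id = regions, ot = ot, smt = smt, p95 = p95)
}

toy_temps <- function(temp_c, regions = "A", start = "2020-07-01") {
  tibble::tibble(
    region_id = rep(regions, each = length(temp_c)),
    date = rep(as.Date(start) + seq_along(temp_c) - 1, length(regions)),
    temp_c = rep(temp_c, length(regions))
  )
}

toy_mmtd <- function(mmtd, regions = "A", years = 2020) {
  tidyr::expand_grid(region_id = regions, year = years, mmtd = mmtd)
}

test_that("daily attribution follows (RR - 1) times the baseline rate", {
  clim <- toy_climatology()
  cfg <- run_config()

  # T = OT: no excess risk, no attributable deaths
  out <- daily_hrd(toy_temps(28), clim, toy_mmtd(50), cfg)
  expect_equal(out$hrd, 0)
  expect_equal(out$rr, 1)

  # rr = 1.2, baseline 50/day -> 10 deaths
  cf <- flat_coeffs(0, 0.04)  # RR(OT+5) = 1.2
  out <- daily_hrd(toy_temps(33), clim, toy_mmtd(50), cfg, coeffs = cf)
  expect_equal(out$hrd, 10)

  # chained hand computation: RR = 1 + 0.002*16 + 0.01*4 = 1.072, mmtd 100
  cf <- flat_coeffs(0.002, 0.01)
  out <- daily_hrd(toy_temps(32), toy_climatology(p95 = 33), toy_mmtd(100),
                   cfg, coeffs = cf)
  expect_equal(out$hrd, 7.2)
  expect_true(out$exceeds_ot)
  expect_true(out$is_summer)
  expect_false(out$exceeds_p95)
  # the extreme-day flag is inclusive at the threshold
  at95 <- daily_hrd(toy_temps(32), clim, toy_mmtd(100), cfg, coeffs = cf)
  expect_true(at95$exceeds_p95)
})

test_that("attribution is zero outside summer and below OT", {
  clim <- toy_climatology()
  cf <- flat_coeffs(0.002, 0.01)
  # hot January day: risk is evaluated but no summertime attribution
  out <- daily_hrd(toy_temps(33, start = "2020-01-10"), clim,
                   toy_mmtd(100), run_config(), coeffs = cf)
  expect_false(out$is_summer)
  expect_equal(out$hrd, 0)
  expect_gt(out$rr, 1)
  # summer day below OT
  out <- daily_hrd(toy_temps(25), clim, toy_mmtd(100), run_config(), coeffs = cf)
  expect_equal(out$hrd, 0)
  expect_error(daily_hrd(toy_temps(25), clim, toy_mmtd(-1), run_config()),
               "negative MMTD")
})

test_that("annual aggregation sums attributable deaths over threshold days", {
  clim <- toy_climatology()
  cfg <- run_config()
  cf <- flat_coeffs(0, 0.04)

  # nothing exceeds OT
  daily <- daily_hrd(toy_temps(c(26, 27, 28)), clim, toy_mmtd(50), cfg, cf)
  otm <- aggregate_otm(daily)
  expect_equal(otm$otm, c(0, 0))

  # ten summer days, each contributing hrd = 2 (RR(OT+1) = 1.04, mmtd 50)
  daily <- daily_hrd(toy_temps(rep(29, 10)), clim, toy_mmtd(50), cfg, cf)
  otm <- aggregate_otm(daily)
  expect_equal(otm$otm[otm$scope == "A"], 20)
  # below the extreme threshold: XHM sees none of it
  expect_equal(aggregate_xhm(daily)$xhm, c(0, 0))

  # days at or above the 95th-percentile threshold count for XHM
  daily <- daily_hrd(toy_temps(c(32, 33)), clim, toy_mmtd(50), cfg, cf)
  xhm <- aggregate_xhm(daily)
  expect_equal(xhm$xhm[xhm$scope == "A"], sum(daily$hrd))
})

test_that("statewide attribution is the sum over regions", {
  clim <- toy_climatology(regions = c("A", "B"))
  cf <- flat_coeffs(0, 0.04)
  temps <- dplyr::bind_rows(
    toy_temps(rep(29, 5), "A"),   # 5 days * 2 deaths
    toy_temps(rep(29.5, 7), "B")  # 7 days * 3 deaths
  )
  daily <- daily_hrd(temps, clim, toy_mmtd(50, c("A", "B")), run_config(), cf)
  otm <- aggregate_otm(daily)
  expect_equal(otm$otm[otm$scope == "A"], 10)
  expect_equal(otm$otm[otm$scope == "B"], 21)
  expect_equal(otm$otm[otm$scope == "statewide"], 31)
})

test_that("extreme-heat attribution never exceeds the optimal-temperature total", {
  for (seed in 1:5) {
    cfg <- scenario_config(n_regions = 3, years = 2012:2015, seed = seed)
    temps <- generate_temperature(cfg)
    deaths <- generate_mortality(temps, cfg)
    rc <- run_config(climatology_window = c(2012, 2015),
                     mmtd_fit_years = c(2012, 2015))
    res <- run_attribution_pipeline(temps, deaths, rc)
    expect_true(all(res$table$xhm <= res$table$otm + 1e-9))
    expect_true(all(res$table$otm >= 0))
    expect_true(all(res$daily$hrd >= 0, na.rm = TRUE))
  }
})

test_that("the baseline constant is the mean annual attribution", {
  clim <- toy_climatology()
  cf <- flat_coeffs(0, 0.04)
  cfg <- run_config()
  # two baseline years: annual OTM 100 and 140 -> constant 120
  temps <- dplyr::bind_rows(
    toy_temps(rep(29, 50), start = "1950-07-01"),   # 50 * 2 = 100
    toy_temps(rep(29, 70), start = "1951-07-01")    # 70 * 2 = 140
  )
  ref <- tibble::tibble(region_id = "A", mmtd = 50)
  otm_b <- compute_baseline_otm(temps, clim, ref, cfg, cf)
  expect_equal(otm_b$otm_b[otm_b$scope == "A"], 120)

  # baseline never exceeding OT contributes nothing
  cold <- toy_temps(rep(25, 30), start = "1950-07-01")
  otm_b <- compute_baseline_otm(cold, clim, ref, cfg, cf)
  expect_equal(otm_b$otm_b, c(0, 0))

  expect_error(compute_baseline_otm(temps[0, ], clim, ref, cfg, cf), "no temperature")
})

test_that("excess deaths subtract the baseline constant, sign preserved", {
  otm <- tibble::tibble(scope = "statewide", year = 2010:2011,
                        otm = c(915, 2854))
  otm_b <- tibble::tibble(scope = "statewide", otm_b = 239.5)
  edm <- compute_edm(otm, otm_b)
  expect_equal(edm$edm, c(675.5, 2614.5))

  # zero baseline: excess equals the attribution itself
  edm <- compute_edm(otm, tibble::tibble(scope = "statewide", otm_b = 0))
  expect_equal(edm$edm, c(915, 2854))

  # cool years below the baseline stay negative
  edm <- compute_edm(tibble::tibble(scope = "s", year = 1, otm = 100),
                     tibble::tibble(scope = "s", otm_b = 150))
  expect_equal(edm$edm, -50)
})

test_that("a self-baseline with a constant baseline rate gives zero mean excess", {
  cfg <- scenario_config(n_regions = 2, years = 2010:2023, mmtd_drift = 0,
                         warming_per_decade = 0, seed = 23)
  temps <- generate_temperature(cfg)
  deaths <- generate_mortality(temps, cfg)
  res <- run_attribution_pipeline(temps, deaths, run_config(),
                                  baseline_temps = temps)
  # constant true MMTD: predictions are noisy but the reference MMTD is their
  # mean, and the baseline climate is the study climate, so mean EDM is the
  # deviation of yearly OTM from its own mean weighted by MMTD noise
  state <- res$table[res$table$scope == "statewide", ]
  expect_lt(abs(mean(state$edm)), 0.05 * mean(state$otm))
})

test_that("uniform warming of above-threshold days increases the attribution", {
  cfg <- scenario_config(n_regions = 2, years = 2018:2020, seed = 14)
  temps <- generate_temperature(cfg)
  rc <- run_config(climatology_window = c(2018, 2020))
  clim <- build_climatology(temps, rc)
  mmtd <- toy_mmtd(10, c("R01", "R02"), 2018:2020)
  daily0 <- daily_hrd(temps, clim, mmtd, rc)
  warmed <- temps
  hot <- warmed$temp_c > clim$ot[match(warmed$region_id, clim$region_id)]
  warmed$temp_c[hot] <- warmed$temp_c[hot] + 1
  daily1 <- daily_hrd(warmed, clim, mmtd, rc)
  otm0 <- aggregate_otm(daily0)
  otm1 <- aggregate_otm(daily1)
  expect_true(all(otm1$otm > otm0$otm))
})
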