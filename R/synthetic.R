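#' Synthetic scenario configuration
#'
#' Defines a multi-region synthetic study with known ground truth: each
#' region's daily mean temperature follows a seasonal sinusoid plus AR(1)
#' noise and an optional linear warming trend, and daily deaths are drawn
#' from a count distribution whose mean is
#' \eqn{MMTD_{true}(y) \times RR_{true}(T)}, with \eqn{RR_{true}} equal to 1
#' at and below the true optimal temperature. Because the truth is known in
#' closed form, every downstream estimator can be validated against its
#' analytic expectation (see [analytic_expected_hrd()]).
#'
#' Region climates are spread evenly over `region_spread` deg C around
#' `climate_mean`, so optimal temperatures and summer mean temperatures vary
#' across regions as they do across real counties.
#'
#' True OT, SMT and the true extreme threshold default to the closed-form
#' marginal climate distribution of the generator (a mixture of normals over
#' the seasonal cycle), not to any realized sample percentile; supplying
#' them explicitly decouples the generator's truth from the estimator's
#' percentile convention so that OT estimation error is itself testable.
#'
#' @param n_regions Number of regions.
#' @param years Integer vector of simulated calendar years (contiguous).
#' @param climate_mean Mean annual temperature of the central region, deg C.
#' @param region_spread Total span of region mean offsets, deg C (regions
#'   are evenly spaced over `climate_mean` +/- `region_spread`/2).
#' @param seasonal_amplitude Amplitude of the seasonal cycle, deg C.
#' @param peak_doy Day of year of the seasonal peak (default 213, early
#'   August, so the hottest days fall inside summertime).
#' @param noise_sd Marginal standard deviation of the AR(1) temperature
#'   noise, deg C (>= 0).
#' @param noise_autocorr Lag-1 autocorrelation of the noise, in [0, 1).
#' @param warming_per_decade Linear trend, deg C per decade (0 at the first
#'   simulated day).
#' @param mmtd_level True baseline (minimum-mortality-temperature) death
#'   rate in the first simulated year, deaths/day, > 0.
#' @param mmtd_drift Linear drift of the true baseline, deaths/day per year.
#' @param reporting_fraction Fraction of true heat deaths captured by the
#'   official-counts emulator, in [0, 1].
#' @param coefficients True [risk_coefficients()] of the generator.
#' @param true_ot,true_smt,true_p95 Optional per-region overrides (scalar or
#'   length `n_regions`), deg C. `NULL` derives them from the climate: OT and
#'   the extreme threshold as the 0.84 / 0.95 quantiles of the marginal
#'   temperature distribution, SMT as the mean June--September temperature.
#' @param dispersion `NULL` for Poisson daily death counts (default), or a
#'   positive size parameter for an overdispersed negative-binomial
#'   alternative.
#' @param seed Integer seed controlling all randomness of the scenario.
#'
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(n_regions = 10L,
                            years = 2010:2023,
                            climate_mean = 21,
                            region_spread = 4,
                            seasonal_amplitude = 8.5,
                            peak_doy = 213L,
                            noise_sd = 2.5,
                            noise_autocorr = 0.7,
                            warming_per_decade = 0.3,
                            mmtd_level = 12,
                            mmtd_drift = 0.1,
                            reporting_fraction = 0.3,
                            coefficients = default_risk_coefficients(),
                            true_ot = NULL,
                            true_smt = NULL,
                            true_p95 = NULL,
                            dispersion = NULL,
                            seed = 1L) {
  num_ok <- function(x) is.numeric(x) && all(is.finite(x))
  stopifnot(
    num_ok(n_regions), n_regions >= 1,
    num_ok(years), length(years) >= 1,
    num_ok(climate_mean), num_ok(region_spread), region_spread >= 0,
    num_ok(seasonal_amplitude), seasonal_amplitude >= 0,
    num_ok(peak_doy),
    num_ok(noise_sd), noise_sd >= 0,
    num_ok(noise_autocorr), noise_autocorr >= 0, noise_autocorr < 1,
    num_ok(warming_per_decade),
    num_ok(mmtd_level), num_ok(mmtd_drift),
    num_ok(reporting_fraction),
    reporting_fraction >= 0, reporting_fraction <= 1,
    num_ok(seed)
  )
  if (!inherits(coefficients, "risk_coefficients")) {
    stop("`coefficients` must be a risk_coefficients object", call. = FALSE)
  }
  years <- as.integer(sort(years))
  if (!all(diff(years) == 1) && length(years) > 1) {
    stop("`years` must be contiguous", call. = FALSE)
  }
  mmtd_end <- mmtd_level + mmtd_drift * (length(years) - 1)
  if (mmtd_level <= 0 || mmtd_end <= 0) {
    stop("true MMTD must stay positive over the simulated years", call. = FALSE)
  }
  for (ov in list(true_ot, true_smt, true_p95)) {
    if (!is.null(ov) && !(num_ok(ov) && length(ov) %in% c(1L, n_regions))) {
      stop("truth overrides must be finite scalars or length n_regions", call. = FALSE)
    }
  }
  if (!is.null(dispersion) && !(num_ok(dispersion) && dispersion > 0)) {
    stop("`dispersion` must be NULL or a positive number", call. = FALSE)
  }
  structure(
    list(
      n_regions = as.integer(n_regions), years = years,
      climate_mean = climate_mean, region_spread = region_spread,
      seasonal_amplitude = seasonal_amplitude, peak_doy = as.integer(peak_doy),
      noise_sd = noise_sd, noise_autocorr = noise_autocorr,
      warming_per_decade = warming_per_decade,
      mmtd_level = mmtd_level, mmtd_drift = mmtd_drift,
      reporting_fraction = reporting_fraction,
      coefficients = coefficients,
      true_ot = true_ot, true_smt = true_smt, true_p95 = true_p95,
      dispersion = dispersion,
      seed = as.integer(seed)
    ),
    class = "scenario_config"
  )
}

scenario_region_ids <- function(config) sprintf("R%02d", seq_len(config$n_regions))

scenario_region_offsets <- function(config) {
  n <- config$n_regions
  if (n == 1) return(0)
  seq(-config$region_spread / 2, config$region_spread / 2, length.out = n)
}

scenario_dates <- function(config) {
  seq(as.Date(sprintf("%d-01-01", min(config$years))),
      as.Date(sprintf("%d-12-31", max(config$years))), by = "day")
}

# deterministic day-mean surface: seasonal cycle + warming trend, per region
scenario_day_means <- function(config) {
  dates <- scenario_dates(config)
  doy <- as.POSIXlt(dates)$yday + 1
  elapsed_yr <- as.numeric(dates - dates[1]) / 365.25
  seasonal <- config$seasonal_amplitude *
    cos(2 * pi * (doy - config$peak_doy) / 365.25)
  trend <- config$warming_per_decade / 10 * elapsed_yr
  offsets <- scenario_region_offsets(config)
  ids <- scenario_region_ids(config)
  dplyr::bind_rows(lapply(seq_along(ids), function(r) {
    tibble::tibble(
      region_id = ids[r],
      date = dates,
      mu = config$climate_mean + offsets[r] + seasonal + trend
    )
  }))
}

#' Quantile of the generator's marginal temperature distribution
#'
#' The marginal distribution of daily mean temperature over the whole
#' simulated period is an equal-weight mixture of normals, one per calendar
#' day, each centred on that day's deterministic mean with standard
#' deviation `noise_sd`. This closed form is inverted numerically, giving
#' the true percentile thresholds of a scenario without reference to any
#' realized sample.
#'
#' @param config A [scenario_config()].
#' @param q Quantile fraction in (0, 1).
#' @param region_id Region whose climate to use (default first region).
#' @return The quantile, deg C.
#' @export
climate_quantile <- function(config, q, region_id = scenario_region_ids(config)[1]) {
  stopifnot(inherits(config, "scenario_config"), q > 0, q < 1)
  mu <- scenario_day_means(config)
  mu <- mu$mu[mu$region_id == region_id]
  if (length(mu) == 0) stop("unknown region_id", call. = FALSE)
  if (config$noise_sd == 0) return(empirical_quantile(mu, q))
  cdf <- function(x) mean(stats::pnorm(x, mean = mu, sd = config$noise_sd)) - q
  lo <- min(mu) - 8 * config$noise_sd
  hi <- max(mu) + 8 * config$noise_sd
  stats::uniroot(cdf, c(lo, hi), tol = 1e-10)$root
}

#' Ground truth of a synthetic scenario
#'
#' Per-region true optimal temperature, true summer mean temperature and
#' true extreme-heat threshold (defaults derived from the climate, see
#' [scenario_config()]), plus the true baseline death rate per year.
#'
#' @param config A [scenario_config()].
#' @param summer_months Months defining summertime for the true SMT.
#' @return A list with `regions` (tibble: `region_id`, `true_ot`,
#'   `true_smt`, `true_p95`) and `mmtd` (tibble: `year`, `mmtd_true`).
#' @export
scenario_truth <- function(config, summer_months = 6:9) {
  ids <- scenario_region_ids(config)
  n <- config$n_regions
  expand1 <- function(x) if (length(x) == 1) rep(x, n) else x

  if (is.null(config$true_smt)) {
    mu <- scenario_day_means(config)
    mu$month <- as.integer(format(mu$date, "%m"))
    smt <- mu |>
      dplyr::filter(month %in% summer_months) |>
      dplyr::group_by(region_id) |>
      dplyr::summarise(true_smt = mean(mu), .groups = "drop")
    true_smt <- smt$true_smt[match(ids, smt$region_id)]
  } else {
    true_smt <- expand1(config$true_smt)
  }
  true_ot <- if (is.null(config$true_ot)) {
    vapply(ids, function(r) climate_quantile(config, 0.84, r), numeric(1))
  } else expand1(config$true_ot)
  true_p95 <- if (is.null(config$true_p95)) {
    vapply(ids, function(r) climate_quantile(config, 0.95, r), numeric(1))
  } else expand1(config$true_p95)
  if (any(true_p95 < true_ot)) {
    stop("true extreme threshold must not fall below true OT", call. = FALSE)
  }
  list(
    regions = tibble::tibble(
      region_id = ids, true_ot = true_ot,
      true_smt = true_smt, true_p95 = true_p95
    ),
    mmtd = tibble::tibble(
      year = config$years,
      mmtd_true = config$mmtd_level +
        config$mmtd_drift * (config$years - min(config$years))
    )
  )
}

#' Generate synthetic daily mean temperatures
#'
#' One record per region per calendar day:
#' seasonal sinusoid + linear warming trend + stationary AR(1) noise with
#' the configured marginal standard deviation and lag-1 autocorrelation.
#' Bit-identical under a fixed seed and config.
#'
#' @param config A [scenario_config()].
#' @return A tibble with columns `region_id`, `date`, `temp_c`.
#' @export
generate_temperature <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  mu <- scenario_day_means(config)
  set.seed(config$seed)
  n_days <- length(scenario_dates(config))
  phi <- config$noise_autocorr
  noise <- unlist(lapply(seq_len(config$n_regions), function(r) {
    if (config$noise_sd == 0) {
      rep(0, n_days)
    } else if (phi == 0) {
      stats::rnorm(n_days, sd = config$noise_sd)
    } else {
      # innovation sd chosen so the stationary marginal sd is noise_sd
      as.numeric(stats::arima.sim(
        model = list(ar = phi), n = n_days,
        sd = config$noise_sd * sqrt(1 - phi^2)
      ))
    }
  }), use.names = FALSE)
  tibble::tibble(
    region_id = mu$region_id,
    date = mu$date,
    temp_c = mu$mu + noise
  )
}

#' Generate synthetic daily death counts
#'
#' Daily deaths are drawn independently from a Poisson distribution (or a
#' negative-binomial when `dispersion` is set) with mean
#' \eqn{MMTD_{true}(year) \times RR_{true}(T)}, where the true relative
#' risk uses the scenario's true OT, SMT and coefficients and equals 1 at
#' and below the true OT.
#'
#' @param temps Temperature series from [generate_temperature()] (must
#'   cover every region-day).
#' @param config The same [scenario_config()].
#' @return A tibble with columns `region_id`, `date`, `deaths`.
#' @export
generate_mortality <- function(temps, config) {
  stopifnot(inherits(config, "scenario_config"),
            all(c("region_id", "date", "temp_c") %in% names(temps)))
  truth <- scenario_truth(config)
  if (any(truth$mmtd$mmtd_true <= 0)) {
    stop("true MMTD must be positive for every simulated year", call. = FALSE)
  }
  df <- temps
  df$year <- as.integer(format(df$date, "%Y"))
  df <- df |>
    dplyr::left_join(truth$regions, by = "region_id") |>
    dplyr::left_join(truth$mmtd, by = "year")
  if (any(is.na(df$true_ot)) || any(is.na(df$mmtd_true))) {
    stop("temperature series contains regions or years outside the scenario", call. = FALSE)
  }
  rr <- relative_risk(df$temp_c, df$true_ot, df$true_smt, config$coefficients)
  lambda <- df$mmtd_true * rr
  set.seed(config$seed + 1L)
  deaths <- if (is.null(config$dispersion)) {
    stats::rpois(length(lambda), lambda)
  } else {
    stats::rnbinom(length(lambda), mu = lambda, size = config$dispersion)
  }
  tibble::tibble(region_id = df$region_id, date = df$date,
                 deaths = as.integer(deaths))
}

#' Emulate official annual heat-death counts
#'
#' Official death-certificate tallies capture only a fraction of true
#' heat-related deaths. This emulator applies a configurable reporting
#' fraction to the true annual totals, optionally adding Poisson count
#' noise.
#'
#' @param true_hrd_by_year Tibble with columns `year` and `hrd` (true
#'   annual heat-related deaths), or a plain numeric vector of totals.
#' @param reporting_fraction Fraction in [0, 1].
#' @param noise If `TRUE`, draw Poisson counts with mean
#'   `reporting_fraction * hrd` instead of rounding.
#' @param seed Seed used when `noise = TRUE`.
#' @return A tibble with columns `year` (if supplied) and `count`.
#' @export
generate_official_counts <- function(true_hrd_by_year, reporting_fraction,
                                     noise = FALSE, seed = 1L) {
  if (!(is.numeric(reporting_fraction) && length(reporting_fraction) == 1 &&
        is.finite(reporting_fraction) &&
        reporting_fraction >= 0 && reporting_fraction <= 1)) {
    stop("reporting_fraction must be in [0, 1]", call. = FALSE)
  }
  if (is.data.frame(true_hrd_by_year)) {
    stopifnot(all(c("year", "hrd") %in% names(true_hrd_by_year)))
    years <- true_hrd_by_year$year
    hrd <- true_hrd_by_year$hrd
  } else {
    years <- seq_along(true_hrd_by_year)
    hrd <- as.numeric(true_hrd_by_year)
  }
  stopifnot(all(is.finite(hrd)), all(hrd >= 0))
  mean_counts <- reporting_fraction * hrd
  counts <- if (noise) {
    set.seed(seed)
    stats::rpois(length(mean_counts), mean_counts)
  } else {
    round(mean_counts)
  }
  tibble::tibble(year = as.integer(years), count = as.integer(counts))
}

#' Analytic expected attribution under the generator's truth
#'
#' For each region-year, the expected Optimal Temperature Method estimate is
#' \deqn{E[OTM] = \sum_{\text{summer days},\ T > OT_{true}}
#'   (RR_{true}(T) - 1)\, MMTD_{true}(y)}
#' and the expected Extreme Heat Method estimate restricts the sum to days
#' with \eqn{T \ge} the true extreme threshold. These expectations are
#' deterministic functions of a generated temperature series and serve as
#' the oracle for parameter-recovery tests of the full estimation pipeline.
#'
#' @param temps A generated temperature series.
#' @param config The [scenario_config()] that generated it.
#' @param summer_months Months defining summertime (default June--September).
#' @return A tibble with columns `region_id`, `year`, `expected_otm`,
#'   `expected_xhm`, with the scenario truth attached as attribute
#'   `"truth"`.
#' @export
analytic_expected_hrd <- function(temps, config, summer_months = 6:9) {
  stopifnot(inherits(config, "scenario_config"))
  truth <- scenario_truth(config, summer_months = summer_months)
  df <- temps
  df$year <- as.integer(format(df$date, "%Y"))
  df$month <- as.integer(format(df$date, "%m"))
  df <- df |>
    dplyr::left_join(truth$regions, by = "region_id") |>
    dplyr::left_join(truth$mmtd, by = "year")
  rr <- relative_risk(df$temp_c, df$true_ot, df$true_smt, config$coefficients)
  is_summer <- df$month %in% summer_months
  hrd <- pmax(rr - 1, 0) * df$mmtd_true
  out <- df |>
    dplyr::mutate(
      .otm = ifelse(is_summer & temp_c > true_ot, hrd, 0),
      .xhm = ifelse(is_summer & temp_c >= true_p95, hrd, 0)
    ) |>
    dplyr::group_by(region_id, year) |>
    dplyr::summarise(
      expected_otm = sum(.otm),
      expected_xhm = sum(.xhm),
      .groups = "drop"
    )
  attr(out, "truth") <- truth
  out
}
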