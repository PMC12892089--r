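#' Baseline death rate for one region-year
#'
#' The minimum-mortality-temperature death rate (MMTD) for a year is the
#' mean daily death count over days whose temperature lies within
#' `halfwidth` deg C of the optimal temperature. With no qualifying days the
#' value is missing (with a warning); callers normally rely on the
#' sparse-data fallback in [estimate_mmtd()] instead.
#'
#' @param deaths Single-region daily deaths tibble (`region_id`, `date`,
#'   `deaths`).
#' @param temps Single-region daily temperature tibble aligned on the same
#'   dates.
#' @param ot Optimal temperature, deg C.
#' @param year Calendar year to estimate.
#' @param halfwidth Window half-width, deg C (default 2).
#' @return A list with `mmtd` (deaths/day, or `NA`) and `qualifying_days`.
#' @export
estimate_mmtd_year <- function(deaths, temps, ot, year, halfwidth = 2) {
  df <- dplyr::inner_join(deaths, temps, by = c("region_id", "date"))
  df$year <- as.integer(format(df$date, "%Y"))
  df <- df[df$year == year & !is.na(df$deaths) & !is.na(df$temp_c), , drop = FALSE]
  inside <- abs(df$temp_c - ot) <= halfwidth
  n <- sum(inside)
  if (n == 0) {
    warning(sprintf("no days within +/-%g degC of OT in %d; MMTD is missing",
                    halfwidth, year), call. = FALSE)
    return(list(mmtd = NA_real_, qualifying_days = 0L))
  }
  list(mmtd = mean(df$deaths[inside]), qualifying_days = as.integer(n))
}

#' Estimate the MMTD for every region and fit-window year
#'
#' For each region and each year of the fit window, averages daily death
#' counts over days with temperature within `mmtd_window_halfwidth` deg C of
#' the region's OT (all calendar days by default; `mmtd_window_days =
#' "summer"` restricts to summertime). Sparse region-years are stabilized in
#' two steps: fewer than `mmtd_min_days` qualifying days widens the window
#' by 1 deg C; if still sparse, the pooled mean over all the region's
#' qualifying days across the fit window is used. The `source` column
#' records which rule produced each value.
#'
#' @param deaths Daily deaths tibble (`region_id`, `date`, `deaths`).
#' @param temps Daily temperature tibble (`region_id`, `date`, `temp_c`).
#' @param climatology Output of [build_climatology()].
#' @param config A [run_config()].
#' @return A tibble with `region_id`, `year`, `mmtd`, `qualifying_days`,
#'   `source` (`"observed"`, `"widened"` or `"pooled"`).
#' @export
estimate_mmtd <- function(deaths, temps, climatology, config = run_config()) {
  h <- config$mmtd_window_halfwidth
  fit_years <- seq(config$mmtd_fit_years[1], config$mmtd_fit_years[2])
  df <- dplyr::inner_join(deaths, temps, by = c("region_id", "date")) |>
    dplyr::inner_join(climatology[c("region_id", "ot")], by = "region_id")
  df$year <- as.integer(format(df$date, "%Y"))
  df <- df[df$year %in% fit_years & !is.na(df$deaths) & !is.na(df$temp_c), , drop = FALSE]
  if (config$mmtd_window_days == "summer") {
    df <- df[as.integer(format(df$date, "%m")) %in% config$summer_months, , drop = FALSE]
  }
  if (nrow(df) == 0) stop("no aligned death/temperature data in the MMTD fit window", call. = FALSE)

  df$in2 <- abs(df$temp_c - df$ot) <= h
  df$in3 <- abs(df$temp_c - df$ot) <= h + 1

  per_year <- df |>
    dplyr::group_by(region_id, year) |>
    dplyr::summarise(
      n2 = sum(in2), m2 = ifelse(sum(in2) > 0, mean(deaths[in2]), NA_real_),
      n3 = sum(in3), m3 = ifelse(sum(in3) > 0, mean(deaths[in3]), NA_real_),
      .groups = "drop"
    )
  pooled <- df |>
    dplyr::group_by(region_id) |>
    dplyr::summarise(
      pooled_n = sum(in2),
      pooled_m = ifelse(sum(in2) > 0, mean(deaths[in2]), NA_real_),
      .groups = "drop"
    )
  out <- per_year |>
    dplyr::left_join(pooled, by = "region_id") |>
    dplyr::mutate(
      source = dplyr::case_when(
        n2 >= config$mmtd_min_days ~ "observed",
        n3 >= config$mmtd_min_days ~ "widened",
        TRUE ~ "pooled"
      ),
      mmtd = dplyr::case_when(
        source == "observed" ~ m2,
        source == "widened" ~ m3,
        TRUE ~ pooled_m
      ),
      qualifying_days = dplyr::case_when(
        source == "observed" ~ n2,
        source == "widened" ~ n3,
        TRUE ~ pooled_n
      )
    )
  if (any(is.na(out$mmtd))) {
    warning("region-years with no qualifying days even after fallback: ",
            paste(sprintf("%s/%d", out$region_id[is.na(out$mmtd)],
                          out$year[is.na(out$mmtd)]), collapse = ", "),
            call. = FALSE)
  }
  out[c("region_id", "year", "mmtd", "qualifying_days", "source")]
}

#' Fit the MMTD trend line per region
#'
#' Ordinary least squares of observed MMTD on calendar year, one line per
#' region, used to extrapolate the baseline death rate outside the fit
#' window (avoiding, in particular, pandemic-era mortality anomalies).
#'
#' @param observed Tibble with `region_id`, `year`, `mmtd` (missing values
#'   are dropped); at least two points per region are required.
#' @param fit_window Inclusive year range the observations come from.
#' @return An object of class `mmtd_model`: list with `observed`, `fits`
#'   (tibble `region_id`, `intercept`, `slope`) and `fit_window`.
#' @export
fit_mmtd_model <- function(observed, fit_window = range(observed$year)) {
  stopifnot(all(c("region_id", "year", "mmtd") %in% names(observed)))
  obs <- observed[!is.na(observed$mmtd), , drop = FALSE]
  counts <- table(obs$region_id)
  too_few <- names(counts)[counts < 2]
  too_few <- union(too_few, setdiff(unique(observed$region_id), obs$region_id))
  if (length(too_few) > 0) {
    stop("fewer than 2 MMTD observations for region(s): ",
         paste(too_few, collapse = ", "), call. = FALSE)
  }
  fits <- obs |>
    dplyr::group_by(region_id) |>
    dplyr::summarise(
      intercept = stats::coef(stats::lm(mmtd ~ year))[[1]],
      slope = stats::coef(stats::lm(mmtd ~ year))[[2]],
      .groups = "drop"
    )
  structure(
    list(observed = obs, fits = fits, fit_window = as.integer(fit_window)),
    class = "mmtd_model"
  )
}

#' @export
print.mmtd_model <- function(x, ...) {
  cat(sprintf("MMTD model: %d region(s), fit window %d-%d\n",
              nrow(x$fits), x$fit_window[1], x$fit_window[2]))
  print(x$fits, ...)
  invisible(x)
}

#' Predict the MMTD for arbitrary years
#'
#' Years inside the fit window with an observed value return that value;
#' all other years use the region's fitted line, floored at zero (a warning
#' flags any floored prediction).
#'
#' @param model An [fit_mmtd_model()] object.
#' @param years Integer vector of years to predict.
#' @return A tibble with `region_id`, `year`, `mmtd`, `source`
#'   (`"observed"` or `"extrapolated"`).
#' @export
predict_mmtd <- function(model, years) {
  stopifnot(inherits(model, "mmtd_model"))
  years <- as.integer(years)
  grid <- tidyr::expand_grid(region_id = model$fits$region_id, year = years)
  out <- grid |>
    dplyr::left_join(model$observed[c("region_id", "year", "mmtd")],
                     by = c("region_id", "year")) |>
    dplyr::left_join(model$fits, by = "region_id") |>
    dplyr::mutate(
      in_window = year >= model$fit_window[1] & year <= model$fit_window[2],
      use_observed = in_window & !is.na(mmtd),
      line = intercept + slope * year,
      source = ifelse(use_observed, "observed", "extrapolated"),
      mmtd = ifelse(use_observed, mmtd, line)
    )
  floored <- out$mmtd < 0
  if (any(floored)) {
    warning("extrapolated MMTD below zero floored at 0 for ",
            sum(floored), " region-year(s)", call. = FALSE)
    out$mmtd[floored] <- 0
  }
  out[c("region_id", "year", "mmtd", "source")]
}
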