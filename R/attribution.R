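#' Daily heat-related deaths
#'
#' Evaluates the attribution model day by day:
#' \deqn{HRD = (RR(T) - 1)\, MMTD(y)}
#' with the relative risk from [relative_risk()] (1 at and below OT) and the
#' baseline death rate from [predict_mmtd()]. HRD is computed for summer
#' days only; other days carry `hrd = 0` with `is_summer = FALSE`.
#'
#' @param temps Daily temperature tibble (`region_id`, `date`, `temp_c`).
#' @param climatology Output of [build_climatology()].
#' @param mmtd Tibble with `region_id`, `year`, `mmtd` (e.g. from
#'   [predict_mmtd()]); must be non-negative.
#' @param config A [run_config()]; supplies summer months and, unless
#'   `coeffs` is given, the risk coefficients.
#' @param coeffs Optional [risk_coefficients()] override.
#' @return A tibble with `region_id`, `date`, `year`, `temp_c`, `rr`,
#'   `mmtd`, `hrd` and the flags `is_summer`, `exceeds_ot`, `exceeds_p95`.
#' @export
daily_hrd <- function(temps, climatology, mmtd, config = run_config(),
                      coeffs = config$coefficients) {
  stopifnot(all(c("region_id", "date", "temp_c") %in% names(temps)),
            all(c("region_id", "year", "mmtd") %in% names(mmtd)))
  if (any(mmtd$mmtd < 0, na.rm = TRUE)) {
    stop("negative MMTD supplied to daily_hrd", call. = FALSE)
  }
  df <- temps
  df$year <- as.integer(format(df$date, "%Y"))
  df$month <- as.integer(format(df$date, "%m"))
  df <- df |>
    dplyr::inner_join(climatology[c("region_id", "ot", "smt", "p95")],
                      by = "region_id") |>
    dplyr::left_join(mmtd[c("region_id", "year", "mmtd")],
                     by = c("region_id", "year"))
  if (any(is.na(df$mmtd))) {
    miss <- unique(df[is.na(df$mmtd), c("region_id", "year")])
    stop("no MMTD for region-year(s): ",
         paste(sprintf("%s/%d", miss$region_id, miss$year), collapse = ", "),
         call. = FALSE)
  }
  ok <- !is.na(df$temp_c)
  rr <- rep(NA_real_, nrow(df))
  rr[ok] <- relative_risk(df$temp_c[ok], df$ot[ok], df$smt[ok], coeffs)
  is_summer <- df$month %in% config$summer_months
  hrd <- ifelse(is_summer & ok, pmax(rr - 1, 0) * df$mmtd, 0)
  tibble::tibble(
    region_id = df$region_id, date = df$date, year = df$year,
    temp_c = df$temp_c, rr = rr, mmtd = df$mmtd, hrd = hrd,
    is_summer = is_summer,
    exceeds_ot = !is.na(df$temp_c) & df$temp_c > df$ot,
    exceeds_p95 = !is.na(df$temp_c) & df$temp_c >= df$p95
  )
}

# shared aggregator: sum daily hrd under a day filter, add statewide rows
aggregate_daily <- function(daily, keep, col) {
  region <- daily |>
    dplyr::mutate(..keep = keep) |>
    dplyr::group_by(region_id, year) |>
    dplyr::summarise(value = sum(hrd[..keep], na.rm = TRUE), .groups = "drop") |>
    dplyr::rename(scope = region_id)
  state <- region |>
    dplyr::group_by(year) |>
    dplyr::summarise(value = sum(value), .groups = "drop") |>
    dplyr::mutate(scope = "statewide", .before = 1)
  out <- dplyr::bind_rows(region, state)
  names(out)[names(out) == "value"] <- col
  out
}

#' Annual attribution by the Optimal Temperature Method
#'
#' Sums daily HRD over all summer days warmer than the optimal temperature,
#' per region-year, and appends statewide rows (the sum over regions).
#'
#' @param daily Output of [daily_hrd()].
#' @return A tibble with `scope` (region id or `"statewide"`), `year`,
#'   `otm`.
#' @export
aggregate_otm <- function(daily) {
  aggregate_daily(daily, daily$is_summer & daily$exceeds_ot, "otm")
}

#' Annual attribution by the Extreme Heat Method
#'
#' Restricts the OTM sum to summer days at or above the extreme-heat
#' threshold (the 95th percentile by default), per region-year, with
#' statewide rows appended.
#'
#' @param daily Output of [daily_hrd()].
#' @return A tibble with `scope`, `year`, `xhm`.
#' @export
aggregate_xhm <- function(daily) {
  aggregate_daily(daily, daily$is_summer & daily$exceeds_p95, "xhm")
}

#' Counterfactual baseline attribution constant
#'
#' Computes the mean annual summertime OTM under the climate of a historical
#' baseline period, holding everything but the climate at study-period
#' values: the current OT, SMT, extreme threshold and risk curve, and a
#' fixed reference MMTD per region (conventionally the study-period mean of
#' the predicted MMTD). The result is a single constant per scope, the
#' \eqn{OTM_B} term of the excess-death method.
#'
#' @param baseline_temps Daily temperatures over the baseline window.
#' @param climatology Study-period [build_climatology()] output.
#' @param reference_mmtd Tibble with `region_id`, `mmtd`: fixed reference
#'   baseline death rate per region.
#' @param config A [run_config()].
#' @param coeffs Optional [risk_coefficients()] override.
#' @return A tibble with `scope`, `otm_b`.
#' @export
compute_baseline_otm <- function(baseline_temps, climatology, reference_mmtd,
                                 config = run_config(),
                                 coeffs = config$coefficients) {
  if (nrow(baseline_temps) == 0) {
    stop("baseline window contains no temperature data", call. = FALSE)
  }
  stopifnot(all(c("region_id", "mmtd") %in% names(reference_mmtd)))
  years <- sort(unique(as.integer(format(baseline_temps$date, "%Y"))))
  mmtd <- tidyr::expand_grid(
    region_id = reference_mmtd$region_id, year = years
  ) |>
    dplyr::left_join(reference_mmtd[c("region_id", "mmtd")], by = "region_id")
  daily <- daily_hrd(baseline_temps, climatology, mmtd, config, coeffs)
  aggregate_otm(daily) |>
    dplyr::group_by(scope) |>
    dplyr::summarise(otm_b = mean(otm), .groups = "drop")
}

#' Excess deaths relative to the baseline climate
#'
#' The Excess Death Method: \eqn{EDM_y = OTM_y - OTM_B}, the study-period
#' attribution minus the constant baseline-climate attribution. Negative
#' values (years cooler than the baseline average) are preserved.
#'
#' @param otm_annual Tibble with `scope`, `year`, `otm` from
#'   [aggregate_otm()].
#' @param otm_baseline Tibble with `scope`, `otm_b` from
#'   [compute_baseline_otm()].
#' @return A tibble with `scope`, `year`, `edm`.
#' @export
compute_edm <- function(otm_annual, otm_baseline) {
  stopifnot(all(c("scope", "year", "otm") %in% names(otm_annual)),
            all(c("scope", "otm_b") %in% names(otm_baseline)))
  out <- dplyr::inner_join(otm_annual, otm_baseline, by = "scope")
  out$edm <- out$otm - out$otm_b
  out[c("scope", "year", "edm")]
}

#' Assemble the attribution results table
#'
#' Joins the three estimators (and official counts where available) into
#' one table of per-scope, per-year results.
#'
#' @param otm,xhm Tibbles from [aggregate_otm()] / [aggregate_xhm()].
#' @param edm Optional tibble from [compute_edm()].
#' @param official Optional tibble with `region_id` (or `scope`), `year`,
#'   `count`.
#' @return A tibble with `scope`, `year`, `otm`, `xhm`, and where supplied
#'   `edm` and `official`.
#' @export
build_hrd_table <- function(otm, xhm, edm = NULL, official = NULL) {
  out <- dplyr::full_join(otm, xhm, by = c("scope", "year"))
  if (!is.null(edm)) out <- dplyr::left_join(out, edm, by = c("scope", "year"))
  if (!is.null(official)) {
    off <- official
    if ("region_id" %in% names(off) && !("scope" %in% names(off))) {
      off <- dplyr::rename(off, scope = region_id)
    }
    off <- dplyr::rename(off, official = count)
    out <- dplyr::left_join(out, off[c("scope", "year", "official")],
                            by = c("scope", "year"))
  }
  dplyr::arrange(out, scope, year)
}
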