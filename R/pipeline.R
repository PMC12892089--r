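#' Run the full attribution pipeline
#'
#' Chains the estimation stages end to end: climatology (OT, SMT, extreme
#' threshold) from the study-period temperatures, MMTD estimation over the
#' fit window with a fitted trend line for the remaining years, daily HRD,
#' and the annual OTM and XHM aggregates. When baseline-period temperatures
#' are supplied the excess-death method is computed as well, using as the
#' fixed reference MMTD each region's study-period mean predicted MMTD.
#'
#' @param temps Study-period daily temperatures (`region_id`, `date`,
#'   `temp_c`).
#' @param deaths Study-period daily deaths (`region_id`, `date`, `deaths`).
#' @param config A [run_config()].
#' @param official Optional official annual counts (tibble with `region_id`
#'   or `scope`, `year`, `count`).
#' @param baseline_temps Optional daily temperatures over the excess-death
#'   baseline window.
#' @return A list with `climatology`, `mmtd_model`, `mmtd` (per-year
#'   predictions), `daily`, `otm_baseline` (or `NULL`), and `table`, the
#'   assembled per-scope annual attribution table.
#' @export
run_attribution_pipeline <- function(temps, deaths, config = run_config(),
                                     official = NULL, baseline_temps = NULL) {
  clim <- build_climatology(temps, config)
  observed <- estimate_mmtd(deaths, temps, clim, config)
  model <- fit_mmtd_model(observed, fit_window = config$mmtd_fit_years)
  years <- sort(unique(as.integer(format(temps$date, "%Y"))))
  mmtd <- predict_mmtd(model, years)
  daily <- daily_hrd(temps, clim, mmtd, config)
  otm <- aggregate_otm(daily)
  xhm <- aggregate_xhm(daily)
  edm <- NULL
  otm_b <- NULL
  if (!is.null(baseline_temps)) {
    reference_mmtd <- mmtd |>
      dplyr::group_by(region_id) |>
      dplyr::summarise(mmtd = mean(mmtd), .groups = "drop")
    otm_b <- compute_baseline_otm(baseline_temps, clim, reference_mmtd, config)
    edm <- compute_edm(otm, otm_b)
  }
  list(
    climatology = clim,
    mmtd_model = model,
    mmtd = mmtd,
    daily = daily,
    otm_baseline = otm_b,
    table = build_hrd_table(otm, xhm, edm, official)
  )
}
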