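#' Analysis run configuration
#'
#' Collects the tunable parameters of the attribution pipeline into a single
#' validated list. Defaults follow the Texas analysis conventions: summertime
#' is June through September, the optimal temperature (OT) is the 84th
#' percentile of daily mean temperature over 2010--2023, extreme heat is at or
#' above the 95th percentile, the minimum-mortality-temperature death rate
#' (MMTD) is fit on 2013--2019 and linearly extrapolated outside that window,
#' and the excess-death baseline climate is 1950--1963.
#'
#' @param summer_months Integer months defining summertime (default `6:9`).
#' @param ot_quantile Quantile of daily mean temperature defining the optimal
#'   temperature (default 0.84).
#' @param extreme_quantile Quantile defining the extreme-heat threshold
#'   (default 0.95). Must exceed `ot_quantile`.
#' @param climatology_window Inclusive year range `c(first, last)` over which
#'   OT, SMT and the extreme threshold are computed (default 2010--2023).
#' @param mmtd_fit_years Inclusive year range for direct MMTD estimation
#'   (default 2013--2019); other years use the fitted line.
#' @param mmtd_window_halfwidth Half-width in deg C of the temperature window
#'   around OT used to estimate MMTD (default 2).
#' @param mmtd_min_days Minimum qualifying days before the sparse-data
#'   fallback widens the window (default 5).
#' @param edm_baseline_window Inclusive year range of the counterfactual
#'   baseline climate for the excess-death method (default 1950--1963; the
#'   1990--2003 window is the usual sensitivity alternative).
#' @param quantile_days Which days enter the OT / extreme-threshold
#'   distribution: `"all"` calendar days (default) or `"summer"` only.
#' @param mmtd_window_days Which days may qualify for the MMTD window:
#'   `"all"` (default) or `"summer"`.
#' @param coefficients A [risk_coefficients()] object parameterizing the
#'   relative-risk curve.
#'
#' @return A list of class `run_config`.
#' @export
run_config <- function(summer_months = 6:9,
                       ot_quantile = 0.84,
                       extreme_quantile = 0.95,
                       climatology_window = c(2010L, 2023L),
                       mmtd_fit_years = c(2013L, 2019L),
                       mmtd_window_halfwidth = 2,
                       mmtd_min_days = 5L,
                       edm_baseline_window = c(1950L, 1963L),
                       quantile_days = c("all", "summer"),
                       mmtd_window_days = c("all", "summer"),
                       coefficients = default_risk_coefficients()) {
  quantile_days <- match.arg(quantile_days)
  mmtd_window_days <- match.arg(mmtd_window_days)
  stopifnot(
    is.numeric(summer_months), length(summer_months) >= 1,
    all(summer_months %in% 1:12),
    is.numeric(ot_quantile), length(ot_quantile) == 1,
    is.numeric(extreme_quantile), length(extreme_quantile) == 1,
    is.numeric(mmtd_window_halfwidth), mmtd_window_halfwidth > 0,
    is.numeric(mmtd_min_days), mmtd_min_days >= 1
  )
  if (!(ot_quantile > 0 && ot_quantile < extreme_quantile && extreme_quantile < 1)) {
    stop("require 0 < ot_quantile < extreme_quantile < 1", call. = FALSE)
  }
  for (w in list(climatology_window, mmtd_fit_years, edm_baseline_window)) {
    if (!(is.numeric(w) && length(w) == 2 && is.finite(w[1]) && is.finite(w[2]) && w[1] <= w[2])) {
      stop("year windows must be c(first, last) with first <= last", call. = FALSE)
    }
  }
  if (!inherits(coefficients, "risk_coefficients")) {
    stop("`coefficients` must be a risk_coefficients object", call. = FALSE)
  }
  structure(
    list(
      summer_months = as.integer(sort(unique(summer_months))),
      ot_quantile = ot_quantile,
      extreme_quantile = extreme_quantile,
      climatology_window = as.integer(climatology_window),
      mmtd_fit_years = as.integer(mmtd_fit_years),
      mmtd_window_halfwidth = mmtd_window_halfwidth,
      mmtd_min_days = as.integer(mmtd_min_days),
      edm_baseline_window = as.integer(edm_baseline_window),
      quantile_days = quantile_days,
      mmtd_window_days = mmtd_window_days,
      coefficients = coefficients
    ),
    class = "run_config"
  )
}

#' Read a run configuration from a YAML file
#'
#' Keys mirror the arguments of [run_config()]; absent keys keep their
#' defaults. Risk coefficients may be given inline under a `coefficients`
#' mapping (keys `a_s`, `a_i`, `b_s`, `b_i`, optional `provenance`) or as a
#' `coefficients_file` path to a CSV readable by [read_risk_coefficients()].
#'
#' @param path Path to a YAML file.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  stopifnot(file.exists(path))
  raw <- yaml::read_yaml(path)
  args <- list()
  scalar_keys <- c(
    "summer_months", "ot_quantile", "extreme_quantile", "climatology_window",
    "mmtd_fit_years", "mmtd_window_halfwidth", "mmtd_min_days",
    "edm_baseline_window", "quantile_days", "mmtd_window_days"
  )
  for (key in intersect(names(raw), scalar_keys)) args[[key]] <- unlist(raw[[key]])
  if (!is.null(raw$coefficients_file)) {
    args$coefficients <- read_risk_coefficients(raw$coefficients_file)
  } else if (!is.null(raw$coefficients)) {
    cf <- raw$coefficients
    args$coefficients <- risk_coefficients(
      a_s = cf$a_s, a_i = cf$a_i, b_s = cf$b_s, b_i = cf$b_i,
      provenance = cf$provenance %||% paste0("yaml:", path)
    )
  }
  do.call(run_config, args)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
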