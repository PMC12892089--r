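#' Relative-risk curve coefficients
#'
#' The heat relative-risk curve is a second-order polynomial in the
#' temperature excess above a region's optimal temperature (OT), whose
#' quadratic and linear terms vary with the region's summer mean temperature
#' (SMT):
#' \deqn{RR(T) = 1 + A(SMT) (T - OT)^2 + B(SMT) (T - OT), \quad T > OT}
#' with \eqn{A(SMT) = a_s SMT + a_i} and \eqn{B(SMT) = b_s SMT + b_i}.
#' Negative SMT slopes encode the common finding that cooler regions have
#' steeper mortality responses to heat. The composite terms A and B are
#' treated as the ground truth; no sign re-derivation happens downstream.
#'
#' @param a_s,a_i Slope (per deg C) and intercept of the quadratic term A,
#'   in RR units per deg C squared.
#' @param b_s,b_i Slope and intercept of the linear term B, in RR units per
#'   deg C.
#' @param provenance Free-text note on where the values came from.
#'
#' @return An object of class `risk_coefficients`.
#' @export
risk_coefficients <- function(a_s, a_i, b_s, b_i, provenance = "user-supplied") {
  vals <- c(a_s = a_s, a_i = a_i, b_s = b_s, b_i = b_i)
  if (!is.numeric(vals) || length(vals) != 4 || any(!is.finite(vals))) {
    stop("risk coefficients must be four finite numbers", call. = FALSE)
  }
  structure(
    list(a_s = a_s, a_i = a_i, b_s = b_s, b_i = b_i,
         provenance = as.character(provenance)[1]),
    class = "risk_coefficients"
  )
}

#' @export
print.risk_coefficients <- function(x, ...) {
  cat("Relative-risk coefficients (A = a_s*SMT + a_i, B = b_s*SMT + b_i)\n")
  cat(sprintf("  a_s = %g  a_i = %g  (quadratic, RR / degC^2)\n", x$a_s, x$a_i))
  cat(sprintf("  b_s = %g  b_i = %g  (linear,    RR / degC)\n", x$b_s, x$b_i))
  cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' Default relative-risk coefficients
#'
#' A representative coefficient set for warm-climate U.S. regions. The curve
#' is quadratic-dominant (risk accelerates as heat becomes extreme, with a
#' shallow slope just above OT) and steeper for cooler regions, and yields
#' relative risks of roughly 1.10--1.25 at the 95th temperature percentile
#' for summer mean temperatures in the Texas range (about 26--31 deg C).
#' Published fits can be substituted via [risk_coefficients()] or
#' [read_risk_coefficients()].
#'
#' @return A `risk_coefficients` object.
#' @export
default_risk_coefficients <- function() {
  risk_coefficients(
    a_s = -0.0010, a_i = 0.0400,
    b_s = -0.0003, b_i = 0.0135,
    provenance = "heatmort package defaults (representative warm-climate fit)"
  )
}

#' Read risk coefficients from a CSV file
#'
#' Expects a single-row CSV with columns `a_s`, `a_i`, `b_s`, `b_i` and an
#' optional `provenance` column.
#'
#' @param path Path to the CSV file.
#' @return A `risk_coefficients` object.
#' @export
read_risk_coefficients <- function(path) {
  stopifnot(file.exists(path))
  df <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("a_s", "a_i", "b_s", "b_i")
  if (!all(need %in% names(df)) || nrow(df) != 1) {
    stop("coefficient file needs one row with columns a_s, a_i, b_s, b_i", call. = FALSE)
  }
  risk_coefficients(df$a_s, df$a_i, df$b_s, df$b_i,
                    provenance = if ("provenance" %in% names(df)) df$provenance else paste0("file:", path))
}

#' Empirical quantile by linear interpolation of closest ranks
#'
#' With sorted values \eqn{x_{(1)} \le \dots \le x_{(n)}} and
#' \eqn{h = (n - 1)q + 1}, returns
#' \eqn{x_{(\lfloor h \rfloor)} + (h - \lfloor h \rfloor)(x_{(\lfloor h \rfloor + 1)} - x_{(\lfloor h \rfloor)})}.
#' This is the standard interpolation convention (`stats::quantile` type 7).
#'
#' @param x Non-empty numeric vector of finite values.
#' @param q Quantile fraction in (0, 1).
#' @return The interpolated quantile, a length-1 numeric.
#' @export
empirical_quantile <- function(x, q) {
  if (length(x) == 0) stop("empirical_quantile: empty input", call. = FALSE)
  if (any(!is.finite(x))) stop("empirical_quantile: non-finite values", call. = FALSE)
  if (!is.numeric(q) || length(q) != 1 || !(q > 0 && q < 1)) {
    stop("empirical_quantile: q must be a single fraction in (0, 1)", call. = FALSE)
  }
  stats::quantile(x, probs = q, type = 7, names = FALSE)
}

#' Per-region temperature climatology: OT, SMT and extreme threshold
#'
#' Computes, for each region over the climatology window, the optimal
#' temperature OT (the `ot_quantile` percentile of daily mean temperature),
#' the extreme-heat threshold (the `extreme_quantile` percentile of the same
#' distribution) and the summer mean temperature SMT (mean over summer-month
#' days). By default the percentile distribution uses all calendar days;
#' set `quantile_days = "summer"` in the configuration for a summer-only
#' distribution.
#'
#' Regions with no data inside the window are excluded with a warning, as is
#' any region whose OT fails to fall below its extreme threshold (degenerate,
#' e.g. constant, series — kept in the output but flagged).
#'
#' @param temps Daily temperature series: a data frame with columns
#'   `region_id`, `date`, `temp_c`.
#' @param config A [run_config()].
#' @return A tibble with columns `region_id`, `ot`, `smt`, `p95` (the
#'   extreme threshold), `n_days`, plus the window bounds and quantile
#'   conventions as attributes.
#' @export
build_climatology <- function(temps, config = run_config()) {
  stopifnot(all(c("region_id", "date", "temp_c") %in% names(temps)))
  win <- config$climatology_window
  yrs <- as.integer(format(temps$date, "%Y"))
  inside <- temps[yrs >= win[1] & yrs <= win[2] & is.finite(temps$temp_c), , drop = FALSE]
  missing_regions <- setdiff(unique(temps$region_id), unique(inside$region_id))
  if (length(missing_regions) > 0) {
    warning("regions with no data in the climatology window excluded: ",
            paste(missing_regions, collapse = ", "), call. = FALSE)
  }
  if (nrow(inside) == 0) stop("no temperature data inside the climatology window", call. = FALSE)

  months <- as.integer(format(inside$date, "%m"))
  is_summer <- months %in% config$summer_months
  qdays <- if (config$quantile_days == "summer") is_summer else rep(TRUE, nrow(inside))

  clim <- inside |>
    dplyr::mutate(.is_summer = is_summer, .qday = qdays) |>
    dplyr::group_by(region_id) |>
    dplyr::summarise(
      ot = empirical_quantile(temp_c[.qday], config$ot_quantile),
      p95 = empirical_quantile(temp_c[.qday], config$extreme_quantile),
      smt = mean(temp_c[.is_summer]),
      n_days = dplyr::n(),
      .groups = "drop"
    )
  bad <- clim$region_id[!(clim$ot < clim$p95)]
  if (length(bad) > 0) {
    warning("OT is not below the extreme threshold (degenerate temperature ",
            "distribution) for: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  attr(clim, "window") <- win
  attr(clim, "ot_quantile") <- config$ot_quantile
  attr(clim, "extreme_quantile") <- config$extreme_quantile
  attr(clim, "quantile_days") <- config$quantile_days
  clim
}

#' Evaluate the relative-risk curve
#'
#' RR is 1 at and below the optimal temperature (only the heat branch is
#' modelled) and \eqn{1 + A (T-OT)^2 + B (T-OT)} above it, floored at 1 so
#' that coefficient sets whose polynomial dips below 1 never produce negative
#' attributable mortality.
#'
#' @param temp_c Daily mean temperature(s), deg C; vectorized.
#' @param ot Optimal temperature, deg C (scalar or same length as `temp_c`).
#' @param smt Summer mean temperature, deg C (scalar or same length).
#' @param coeffs A [risk_coefficients()] object.
#' @return Numeric vector of relative risks, all >= 1.
#' @export
relative_risk <- function(temp_c, ot, smt, coeffs = default_risk_coefficients()) {
  if (!inherits(coeffs, "risk_coefficients")) {
    stop("`coeffs` must be a risk_coefficients object", call. = FALSE)
  }
  if (any(!is.finite(temp_c))) stop("relative_risk: non-finite temperature", call. = FALSE)
  a <- coeffs$a_s * smt + coeffs$a_i
  b <- coeffs$b_s * smt + coeffs$b_i
  excess <- pmax(temp_c - ot, 0)
  pmax(1 + a * excess^2 + b * excess, 1)
}
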