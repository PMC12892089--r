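#' Period totals and annual averages per estimator
#'
#' Column sums and per-year averages of the attribution table over a span
#' of years, for each method present (`otm`, `xhm`, `edm`, `official`).
#'
#' @param table An attribution table ([build_hrd_table()] output or any
#'   tibble with `scope`, `year` and method columns).
#' @param years Years to include (default: all present).
#' @param scope Scope to summarise (default `"statewide"`).
#' @return A tibble with `method`, `total`, `annual_average` (unrounded;
#'   round for display).
#' @export
period_totals <- function(table, years = NULL, scope = "statewide") {
  df <- table[table$scope == scope, , drop = FALSE]
  if (!is.null(years)) df <- df[df$year %in% years, , drop = FALSE]
  if (nrow(df) == 0) stop("no rows for the requested scope/years", call. = FALSE)
  methods <- intersect(c("otm", "xhm", "edm", "official"), names(df))
  tibble::tibble(
    method = methods,
    total = unname(vapply(methods, function(m) sum(df[[m]]), numeric(1))),
    annual_average = unname(vapply(methods, function(m) sum(df[[m]]) / nrow(df),
                                   numeric(1)))
  )
}

#' Ratio of a method's total to the official total
#'
#' Computed as the ratio of period sums (not the mean of yearly ratios):
#' total attributed deaths over the span divided by total official deaths.
#' A zero or absent official total yields `NA` with a warning.
#'
#' @param table Attribution table including an `official` column.
#' @param method One of `"otm"`, `"xhm"`, `"edm"`.
#' @param years Years to include (default: all present).
#' @param scope Scope to summarise (default `"statewide"`).
#' @return A single numeric ratio (unitless).
#' @export
ratio_to_official <- function(table, method = c("otm", "xhm", "edm"),
                              years = NULL, scope = "statewide") {
  method <- match.arg(method)
  if (!("official" %in% names(table))) {
    stop("attribution table has no official counts", call. = FALSE)
  }
  df <- table[table$scope == scope, , drop = FALSE]
  if (!is.null(years)) df <- df[df$year %in% years, , drop = FALSE]
  official <- sum(df$official)
  if (!is.finite(official) || official == 0) {
    warning("official total is zero or missing; ratio undefined", call. = FALSE)
    return(NA_real_)
  }
  sum(df[[method]]) / official
}

#' Share of attribution due to moderate (non-extreme) heat
#'
#' The fraction of optimal-temperature-method deaths occurring on days
#' below the extreme threshold: \eqn{(OTM - XHM) / OTM} over the period.
#'
#' @inheritParams ratio_to_official
#' @return A fraction in [0, 1], or `NA` when the OTM total is zero.
#' @export
moderate_heat_split <- function(table, years = NULL, scope = "statewide") {
  df <- table[table$scope == scope, , drop = FALSE]
  if (!is.null(years)) df <- df[df$year %in% years, , drop = FALSE]
  otm <- sum(df$otm)
  if (!is.finite(otm) || otm == 0) {
    warning("OTM total is zero; moderate-heat share undefined", call. = FALSE)
    return(NA_real_)
  }
  (otm - sum(df$xhm)) / otm
}

#' Full method-versus-official comparison report
#'
#' Assembles the summary quantities of the analysis into one long table:
#' period totals and annual averages per method, full-period and
#' sub-period ratios of each method to official counts, and the
#' moderate-heat share. Deterministic given the attribution table.
#'
#' @param table Attribution table with `otm`, `xhm`, and optionally `edm`
#'   and `official` columns.
#' @param years Years of the full period (default: all present for the
#'   scope).
#' @param subperiods Named list of year vectors for sub-period ratios
#'   (default: the first and last four years of the period).
#' @param scope Scope to report on (default `"statewide"`).
#' @return A tibble with `quantity` and `value`; totals/averages in deaths,
#'   ratios unitless, shares as fractions.
#' @export
comparison_report <- function(table, years = NULL, subperiods = NULL,
                              scope = "statewide") {
  df <- table[table$scope == scope, , drop = FALSE]
  if (is.null(years)) years <- sort(unique(df$year))
  if (is.null(subperiods)) {
    yrs <- sort(years)
    subperiods <- list(utils::head(yrs, 4), utils::tail(yrs, 4))
    names(subperiods) <- vapply(subperiods, function(y) {
      sprintf("%d_%d", min(y), max(y))
    }, character(1))
  }
  totals <- period_totals(table, years, scope)
  rows <- list(tibble::tibble(
    quantity = c(paste0(totals$method, "_total"),
                 paste0(totals$method, "_annual_average")),
    value = c(totals$total, totals$annual_average)
  ))
  has_official <- "official" %in% names(table)
  methods <- intersect(c("otm", "xhm", "edm"), names(table))
  if (has_official) {
    for (m in methods) {
      vals <- unname(c(ratio_to_official(table, m, years, scope),
                       vapply(subperiods, function(y) {
                         ratio_to_official(table, m, y, scope)
                       }, numeric(1))))
      rows <- c(rows, list(tibble::tibble(
        quantity = c(paste0(m, "_official_ratio"),
                     paste0(m, "_official_ratio_", names(subperiods))),
        value = vals
      )))
    }
  }
  if (all(c("otm", "xhm") %in% names(table))) {
    rows <- c(rows, list(tibble::tibble(
      quantity = "moderate_heat_share",
      value = moderate_heat_split(table, years, scope)
    )))
  }
  dplyr::bind_rows(rows)
}

#' Reference statewide attribution table for Texas, 2010--2023
#'
#' Published statewide annual heat-related-death estimates for Texas under
#' the three estimators (EDM relative to a 1950--1963 baseline climate),
#' alongside official death-certificate counts, shipped as a plain-text
#' fixture. Used as a regression target for the reporting layer and for
#' structural checks of the excess-death definition.
#'
#' @return A tibble with `scope` (`"statewide"`), `year`, `otm`, `xhm`,
#'   `edm`, `official`.
#' @export
texas_reference_table <- function() {
  path <- system.file("extdata", "texas_hrd_statewide_2010_2023.csv",
                      package = "heatmort", mustWork = TRUE)
  df <- readr::read_csv(path, col_types = "iiiii", show_col_types = FALSE)
  dplyr::mutate(df, scope = "statewide", .before = 1)
}

#' Write an attribution table to CSV
#'
#' Mirrors the conventional presentation: one row per scope-year with the
#' three estimators and official counts, values rounded to whole deaths.
#'
#' @param table Attribution table.
#' @param path Output CSV path.
#' @param digits Decimal places for the estimator columns (default 0,
#'   matching how such tables are normally printed).
#' @return `path`, invisibly.
#' @export
write_hrd_table <- function(table, path, digits = 0) {
  out <- table
  for (m in intersect(c("otm", "xhm", "edm"), names(out))) {
    out[[m]] <- round(out[[m]], digits)
  }
  readr::write_csv(out, path)
  invisible(path)
}
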