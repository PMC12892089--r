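#' Read and validate a long-format daily series
#'
#' Reads a CSV with columns `region_id`, `date` (ISO-8601), `value` and
#' returns a validated series. Duplicate (region, date) pairs and, for the
#' deaths flavor, negative or non-integer counts are rejected. After
#' validation the series is made contiguous per region: any calendar day
#' missing between a region's first and last date becomes an explicit row
#' with a missing value, so downstream code never has to distinguish absent
#' rows from missing data.
#'
#' @param path Path to the CSV file.
#' @param flavor `"temperature"` (values in deg C, column `temp_c` on
#'   output) or `"deaths"` (non-negative integers, column `deaths`).
#' @return A tibble with columns `region_id`, `date`, and `temp_c` or
#'   `deaths`.
#' @export
read_daily_series <- function(path, flavor = c("temperature", "deaths")) {
  flavor <- match.arg(flavor)
  stopifnot(file.exists(path))
  df <- readr::read_csv(
    path,
    col_types = readr::cols(
      region_id = readr::col_character(),
      date = readr::col_character(),
      value = readr::col_double()
    ),
    show_col_types = FALSE
  )
  if (!all(c("region_id", "date", "value") %in% names(df))) {
    stop("daily series file must have columns region_id, date, value", call. = FALSE)
  }
  parsed <- as.Date(df$date, format = "%Y-%m-%d")
  bad <- which(is.na(parsed) & !is.na(df$date))
  if (length(bad) > 0) {
    stop(sprintf("malformed date %s at row %d of %s",
                 df$date[bad[1]], bad[1], path), call. = FALSE)
  }
  df$date <- parsed
  dup <- duplicated(df[c("region_id", "date")])
  if (any(dup)) {
    first <- df[which(dup)[1], ]
    stop(sprintf("duplicate (region, date) pair: (%s, %s)",
                 first$region_id, format(first$date)), call. = FALSE)
  }
  if (flavor == "deaths") {
    v <- df$value[!is.na(df$value)]
    if (any(v < 0)) stop("death counts must be non-negative", call. = FALSE)
    if (any(v != round(v))) stop("death counts must be integers", call. = FALSE)
  }
  value_col <- if (flavor == "temperature") "temp_c" else "deaths"
  out <- tibble::tibble(
    region_id = df$region_id,
    date = df$date,
    value = if (flavor == "deaths") as.integer(df$value) else df$value
  )
  names(out)[names(out) == "value"] <- value_col
  # make per-region date coverage contiguous (explicit NA rows for gaps)
  out <- out |>
    dplyr::group_by(region_id) |>
    tidyr::complete(date = seq(min(date), max(date), by = "day")) |>
    dplyr::ungroup() |>
    dplyr::arrange(region_id, date)
  out
}

#' Write a daily series to CSV
#'
#' Inverse of [read_daily_series()]: writes `region_id`, `date`, `value`
#' columns with ISO-8601 dates, so that reading the file back reproduces the
#' validated series.
#'
#' @param series A daily-series tibble (`temp_c` or `deaths` value column).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_daily_series <- function(series, path) {
  value_col <- intersect(c("temp_c", "deaths"), names(series))
  if (length(value_col) != 1) {
    stop("series must have exactly one of temp_c or deaths", call. = FALSE)
  }
  out <- tibble::tibble(
    region_id = series$region_id,
    date = format(series$date, "%Y-%m-%d"),
    value = series[[value_col]]
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' Read and validate annual official heat-death counts
#'
#' Expects columns `year`, `count`, and optionally `region_id` (absent or
#' `"statewide"` for state-level totals). Counts must be non-negative
#' integers and each (scope, year) may appear once.
#'
#' @param path Path to the CSV file.
#' @return A tibble with columns `region_id`, `year`, `count`.
#' @export
read_official_counts <- function(path) {
  stopifnot(file.exists(path))
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("year", "count") %in% names(df))) {
    stop("official counts file must have columns year, count", call. = FALSE)
  }
  if (nrow(df) == 0) {
    warning("official counts file is empty", call. = FALSE)
    return(tibble::tibble(region_id = character(), year = integer(), count = integer()))
  }
  if (!("region_id" %in% names(df))) df$region_id <- "statewide"
  if (any(!is.finite(df$count)) || any(df$count < 0) || any(df$count != round(df$count))) {
    stop("official counts must be non-negative integers", call. = FALSE)
  }
  if (any(!is.finite(df$year)) || any(df$year != round(df$year))) {
    stop("years must be integers", call. = FALSE)
  }
  dup <- duplicated(df[c("region_id", "year")])
  if (any(dup)) {
    stop(sprintf("repeated year %d for scope %s",
                 df$year[which(dup)[1]], df$region_id[which(dup)[1]]), call. = FALSE)
  }
  tibble::tibble(
    region_id = as.character(df$region_id),
    year = as.integer(df$year),
    count = as.integer(df$count)
  )
}

#' Assign each region to its nearest grid point
#'
#' Maps every region centroid to the lattice point minimizing great-circle
#' (haversine) distance on a spherical Earth, the standard way of attaching
#' a gridded reanalysis temperature to an administrative region. Ties are
#' broken by the lexicographically smallest (lat, lon) pair.
#'
#' @param centroids Data frame with columns `region_id`, `lat`, `lon`
#'   (degrees).
#' @param lattice Data frame with columns `lat`, `lon`: the grid points.
#' @return A tibble with `region_id`, `grid_index` (row of `lattice`),
#'   `grid_lat`, `grid_lon`, `distance_m`.
#' @export
assign_nearest_gridpoint <- function(centroids, lattice) {
  stopifnot(
    all(c("region_id", "lat", "lon") %in% names(centroids)),
    all(c("lat", "lon") %in% names(lattice)),
    nrow(lattice) > 0
  )
  if (any(abs(centroids$lat) > 90) || any(abs(centroids$lon) > 360)) {
    stop("centroid coordinates outside plausible bounds", call. = FALSE)
  }
  # distm: rows = centroids, cols = lattice points
  d <- geosphere::distm(
    cbind(centroids$lon, centroids$lat),
    cbind(lattice$lon, lattice$lat),
    fun = geosphere::distHaversine
  )
  pick <- vapply(seq_len(nrow(centroids)), function(i) {
    di <- d[i, ]
    tied <- which(di <= min(di) * (1 + 1e-12))
    # lexicographic tie-break on (lat, lon)
    tied[order(lattice$lat[tied], lattice$lon[tied])][1]
  }, integer(1))
  tibble::tibble(
    region_id = centroids$region_id,
    grid_index = pick,
    grid_lat = lattice$lat[pick],
    grid_lon = lattice$lon[pick],
    distance_m = d[cbind(seq_len(nrow(centroids)), pick)]
  )
}
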