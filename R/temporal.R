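# Temporal aggregation and classical additive decomposition of monthly
# sighting counts.

#' Monthly sighting counts
#'
#' Counts records per calendar month across a period, with zero-count months
#' present as 0 so the series is contiguous.
#'
#' @param records Cleaned record tibble with valid `date`.
#' @param period Length-2 integer vector `c(first_year, last_year)`;
#'   defaults to the data's span.
#' @return A `monthly_series` tibble with columns `year`, `month`, `count`.
#' @export
monthly_counts <- function(records, period = NULL) {
  yrs <- as.integer(format(records$date, "%Y"))
  if (is.null(period)) {
    if (nrow(records) == 0) abort("Empty records and no `period` supplied.")
    period <- range(yrs)
  }
  if (nrow(records) > 0 && (period[1] > max(yrs) || period[2] < min(yrs))) {
    warn("`period` lies outside the data span; series will be zero-filled.")
  }
  grid <- tidyr::expand_grid(year = seq(period[1], period[2]), month = 1:12)
  mo <- as.integer(format(records$date, "%m"))
  counts <- tibble(year = yrs, month = mo) |>
    dplyr::filter(.data$year >= period[1], .data$year <= period[2]) |>
    dplyr::count(.data$year, .data$month, name = "count")
  out <- grid |>
    dplyr::left_join(counts, by = c("year", "month")) |>
    dplyr::mutate(count = tidyr::replace_na(.data$count, 0L)) |>
    dplyr::arrange(.data$year, .data$month)
  structure(out, class = c("monthly_series", class(out)))
}

#' Per-period month-of-year sighting totals
#'
#' Aggregates counts to (period, calendar month) cells, the multi-panel
#' seasonal view. Default periods are the study's four blocks 1997–2000,
#' 2001–2004, 2005–2008 and 2009–2013.
#'
#' @param records Cleaned record tibble.
#' @param period_breaks Ascending integer years; period k is
#'   `[breaks[k], breaks[k+1] - 1]`.
#' @return Tibble with `period`, `month`, `count`; records outside every
#'   period are totalled under period `"outside"`.
#' @export
period_aggregate <- function(records, period_breaks = c(1997, 2001, 2005, 2009, 2014)) {
  if (is.unsorted(period_breaks, strictly = TRUE)) {
    abort("`period_breaks` must be strictly ascending.")
  }
  k <- length(period_breaks) - 1
  labels <- sprintf("%d-%d", period_breaks[-(k + 1)], period_breaks[-1] - 1)
  yrs <- as.integer(format(records$date, "%Y"))
  idx <- findInterval(yrs, period_breaks)
  period <- ifelse(idx >= 1 & idx <= k, labels[pmax(idx, 1)], "outside")
  tibble(
    period = factor(period, levels = c(labels, "outside")),
    month = as.integer(format(records$date, "%m"))
  ) |>
    dplyr::count(.data$period, .data$month, name = "count", .drop = FALSE)
}

#' Classical additive decomposition of a monthly series
#'
#' Splits a monthly count series into trend, seasonal and random components:
#' trend by a centred moving average of order 12 (half weights at the window
#' ends), seasonal effects as month-of-year means of the detrended series
#' re-centred to sum to zero, random as the remainder. At interior months
#' trend + seasonal + random reproduces the observed series exactly; the
#' first and last six months of trend are undefined, not extrapolated.
#'
#' @param series A [monthly_counts()] tibble (or any tibble with `year`,
#'   `month`, `count` over contiguous months).
#' @return A `sighting_decomposition` tibble with columns `year`, `month`,
#'   `observed`, `trend`, `seasonal`, `random`.
#' @export
decompose_additive <- function(series) {
  if (nrow(series) < 24) {
    abort("Need at least 24 contiguous months to estimate seasonal effects.")
  }
  x <- stats::ts(series$count,
    start = c(series$year[1], series$month[1]), frequency = 12
  )
  dec <- stats::decompose(x, type = "additive")
  out <- tibble(
    year = series$year,
    month = series$month,
    observed = as.double(series$count),
    trend = as.double(dec$trend),
    seasonal = as.double(dec$seasonal),
    random = as.double(dec$random)
  )
  structure(out, class = c("sighting_decomposition", class(out)))
}

#' @export
tidy.sighting_decomposition <- function(x, ...) {
  as_tibble(unclass(x)[c("year", "month", "observed", "trend", "seasonal", "random")])
}

#' Export a decomposition as tidy CSV
#' @param x A `sighting_decomposition`.
#' @param path Output path.
#' @export
write_decomposition <- function(x, path) {
  readr::write_csv(as_tibble(x), path)
  invisible(path)
}
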