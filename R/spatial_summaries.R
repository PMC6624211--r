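# Banded and categorical spatial tabulations: distance-to-coast bands,
# elevation classes, point-in-polygon counts by attribute.

band_labels <- function(breaks, unit) {
  k <- length(breaks)
  c(
    sprintf("[%g,%g) %s", breaks[-k], breaks[-1], unit),
    sprintf(">=%g %s", breaks[k], unit)
  )
}

#' Tabulate points by distance-to-coast band
#'
#' Euclidean point-to-segment distance to the nearest coastline feature,
#' binned into half-open bands `[b_k, b_{k+1})` with a final open band above
#' the last break (default 0–20 km in 5 km increments plus `>= 20 km`).
#'
#' @param points Tibble with `x`, `y` (km).
#' @param coastline Segment tibble (columns `x0`, `y0`, `x1`, `y1`).
#' @param breaks Ascending band cutpoints in km, starting at 0.
#' @return A `band_tabulation` tibble: `band`, `lower`, `n`, `prop`.
#' @export
coast_distance_bands <- function(points, coastline, breaks = c(0, 5, 10, 15, 20)) {
  if (is.null(coastline) || nrow(coastline) == 0) abort("`coastline` is empty.")
  if (is.unsorted(breaks, strictly = TRUE)) abort("`breaks` must be ascending.")
  d <- dist_to_segments(points$x, points$y, coastline)
  idx <- findInterval(d, breaks)
  lab <- band_labels(breaks, "km")
  tab <- tibble(band = factor(lab[pmax(idx, 1)], levels = lab)) |>
    dplyr::count(.data$band, name = "n", .drop = FALSE) |>
    dplyr::mutate(
      lower = breaks[seq_along(lab)],
      prop = if (nrow(points) > 0) .data$n / nrow(points) else NA_real_
    ) |>
    dplyr::relocate("band", "lower")
  structure(tab, class = c("band_tabulation", class(tab)))
}

#' Tabulate points by elevation class
#'
#' Samples the elevation raster at each point (nearest cell — classification,
#' not interpolation) and bins into classes below/between/above the breaks
#' (default < 100 m, 100–200 m, > 200 m).
#'
#' @param points Tibble with `x`, `y` (km).
#' @param dem Elevation `spatial_raster` (m).
#' @param breaks Ascending class cutpoints (m).
#' @return A `band_tabulation` tibble: `class`, `n`, `prop`, with points
#'   outside the raster extent counted under `"unassigned"`.
#' @export
elevation_classes <- function(points, dem, breaks = c(100, 200)) {
  k <- length(breaks)
  lab <- c(
    sprintf("<%g m", breaks[1]),
    sprintf(">%g-%g m", breaks[-k], breaks[-1]),
    sprintf(">%g m", breaks[k])
  )
  nx <- nrow(dem$values)
  ny <- ncol(dem$values)
  inside <- points$x >= dem$origin[1] &
    points$x <= dem$origin[1] + nx * dem$cellsize &
    points$y >= dem$origin[2] &
    points$y <= dem$origin[2] + ny * dem$cellsize
  cls <- rep("unassigned", nrow(points))
  if (any(inside)) {
    z <- covariate_at_points(dem, points[inside, ], mode = "nearest")
    cls[inside] <- lab[findInterval(z, breaks) + 1L]
  }
  tab <- tibble(class = factor(cls, levels = c(lab, "unassigned"))) |>
    dplyr::count(.data$class, name = "n", .drop = FALSE) |>
    dplyr::mutate(prop = if (nrow(points) > 0) .data$n / nrow(points) else NA_real_)
  structure(tab, class = c("band_tabulation", class(tab)))
}

#' Tabulate points by polygon attribute
#'
#' Point-in-polygon assignment (boundaries count as inside) and counts per
#' attribute level — used for land types, habitat suitability classes and
#' administrative regions. A point covered by several polygons is assigned
#' to the first matching row of `polygons`; points in none are
#' `"unassigned"`.
#'
#' @param points Tibble with `x`, `y` (km); optionally a `period` column for
#'   per-period tabulation via `by_period = TRUE`.
#' @param polygons Tibble with list-column `geometry` and the attribute
#'   column named by `attribute`.
#' @param attribute Name of the attribute column (e.g. `"suitability"`).
#' @param by_period Also split counts by `points$period`.
#' @return Tibble of `level`, `n`, `prop` (plus `period` when requested).
#' @export
polygon_tabulate <- function(points, polygons, attribute, by_period = FALSE) {
  if (!attribute %in% names(polygons)) {
    abort(sprintf("`polygons` has no attribute column `%s`.", attribute))
  }
  lev <- unique(as.character(polygons[[attribute]]))
  assigned <- rep("unassigned", nrow(points))
  if (nrow(points) > 0) {
    for (k in rev(seq_len(nrow(polygons)))) {
      hit <- points_in_ring(points$x, points$y, polygons$geometry[[k]])
      assigned[hit] <- as.character(polygons[[attribute]][k])
    }
  }
  base <- tibble(level = factor(assigned, levels = c(lev, "unassigned")))
  if (by_period) {
    if (!"period" %in% names(points)) abort("`by_period` needs a `period` column.")
    base$period <- points$period
    out <- base |>
      dplyr::count(.data$period, .data$level, name = "n", .drop = FALSE)
  } else {
    out <- base |> dplyr::count(.data$level, name = "n", .drop = FALSE)
  }
  out |>
    dplyr::mutate(prop = if (nrow(points) > 0) .data$n / nrow(points) else NA_real_)
}
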