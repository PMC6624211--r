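# Fixed-bandwidth Gaussian kernel density mapping of sighting locations and
# Table-1-style classification of the study grid into density categories.

#' Scott's rule bandwidth for planar point data
#'
#' Per-axis plug-in bandwidth for bivariate (d = 2) kernel smoothing:
#' `sigma_i = n^(-1/6) * sd(coordinate_i)` (exponent `-1/(d + 4)`).
#'
#' @param points Tibble with `x`, `y` (km), `n >= 2`, non-degenerate spread.
#' @return Named numeric `c(sigma_x, sigma_y)` in km.
#' @export
#' @examples
#' pts <- tibble::tibble(x = rnorm(4096), y = rnorm(4096))
#' scott_bandwidth(pts) # ~ 4096^(-1/6) * sd = ~0.25 per axis
scott_bandwidth <- function(points) {
  n <- nrow(points)
  if (n < 2) abort("Scott bandwidth needs at least 2 points.")
  s <- c(sigma_x = stats::sd(points$x), sigma_y = stats::sd(points$y))
  if (any(!is.finite(s)) || any(s <= 0)) {
    abort("Degenerate point pattern: zero spread on an axis.")
  }
  n^(-1 / 6) * s
}

#' Gaussian kernel density surface of a point pattern
#'
#' Raw (uncorrected) fixed-bandwidth Gaussian kernel intensity estimate,
#' evaluated at the centres of the window's analysis grid:
#' `value(u) = sum_i (2 pi sx sy)^(-1) exp(-(ux - xi)^2 / (2 sx^2)
#' - (uy - yi)^2 / (2 sy^2))`, in events per km^2. No edge correction is
#' applied, so kernel mass extending beyond the window is lost; with
#' interior points and bandwidths small against the window the grid mass
#' `sum(value) * cellsize^2` recovers the point count.
#'
#' @param points Tibble with `x`, `y` (km).
#' @param window A [make_window()] object.
#' @param bandwidth Length-2 `c(sigma_x, sigma_y)` in km (e.g.
#'   [scott_bandwidth()]), or a single number used for both axes.
#' @param cellsize Evaluation grid resolution (km, default 1).
#' @return A `density_grid`: a `spatial_raster` of intensities with the
#'   bandwidth stored in `$bandwidth`.
#' @export
kde_gaussian <- function(points, window, bandwidth, cellsize = 1) {
  check_window(window)
  if (length(bandwidth) == 1) bandwidth <- rep(bandwidth, 2)
  if (any(!is.finite(bandwidth)) || any(bandwidth <= 0)) {
    abort("`bandwidth` must be positive.")
  }
  nx <- ceiling(window$width / cellsize - 1e-12)
  ny <- ceiling(window$height / cellsize - 1e-12)
  cx <- (seq_len(nx) - 0.5) * cellsize
  cy <- (seq_len(ny) - 0.5) * cellsize
  n <- nrow(points)
  if (n == 0) {
    v <- matrix(0, nx, ny)
  } else {
    # separable kernel: sum_i outer(ex_i, ey_i) as one matrix product
    ex <- exp(-outer(cx, points$x, "-")^2 / (2 * bandwidth[1]^2))
    ey <- exp(-outer(points$y, cy, "-")^2 / (2 * bandwidth[2]^2))
    v <- (ex %*% ey) / (2 * pi * bandwidth[1] * bandwidth[2])
  }
  out <- spatial_raster(v, origin = c(0, 0), cellsize = cellsize,
    feature_class = "sighting_density")
  out$bandwidth <- c(sigma_x = bandwidth[1], sigma_y = bandwidth[2])
  out$window <- window
  class(out) <- c("density_grid", class(out))
  out
}

#' Classify a density surface into sighting-density categories
#'
#' Assigns every study cell to a density category (default 0, >0–1, >1–2,
#' >2–3, > 3 koalas per km^2) and reports the percentage of study cells per
#' category, cell counts, and the density range. A kernel estimate is never
#' exactly zero away from all mass, so the zero category uses a numerical
#' floor.
#'
#' @param grid A [kde_gaussian()] result (or any `spatial_raster` of
#'   densities).
#' @param breaks Category upper bounds above zero (default `c(1, 2, 3)`).
#' @param zero_tol Values below this count as zero density (default 1e-9).
#' @param period_label Optional label carried into the output.
#' @return A `density_classification` tibble: `period`, `category`,
#'   `cell_count`, `area_share_pct`, with the density range in attributes
#'   `density_min` / `density_max`.
#' @export
classify_density <- function(grid, breaks = c(1, 2, 3), zero_tol = 1e-9,
                             period_label = NA_character_) {
  v <- as.vector(grid$values)
  v <- v[is.finite(v)]
  k <- length(breaks)
  labels <- c(
    "0",
    sprintf(">%g-%g", c(0, breaks[-k]), breaks),
    sprintf(">%g", breaks[k])
  )
  idx <- ifelse(v < zero_tol, 1L, findInterval(v, breaks, left.open = TRUE) + 2L)
  counts <- tabulate(idx, nbins = k + 2L)
  out <- tibble(
    period = period_label,
    category = factor(labels, levels = labels),
    cell_count = counts,
    area_share_pct = 100 * counts / length(v)
  )
  attr(out, "density_min") <- min(v)
  attr(out, "density_max") <- max(v)
  structure(out, class = c("density_classification", class(out)))
}
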