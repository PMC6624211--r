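#' Create a rectangular study window
#'
#' The observation window for all spatial operations: a `width_km` by
#' `height_km` rectangle with its lower-left corner at the origin, carrying a
#' 1 km^2 analysis grid whose cell edges lie on integer-kilometre lines.
#' Coordinates throughout the package are planar kilometres; longitude /
#' latitude data must be projected before entry.
#'
#' @param width_km,height_km Window dimensions in kilometres; both must be
#'   strictly positive.
#' @return A `study_window` object: a list with `width`, `height`, `xrange`,
#'   `yrange` and `area` (km^2).
#' @export
#' @examples
#' w <- make_window(10, 10)
#' w$area
make_window <- function(width_km, height_km) {
  stop_if_not_scalar_pos(width_km, "width_km")
  stop_if_not_scalar_pos(height_km, "height_km")
  structure(
    list(
      width = as.double(width_km),
      height = as.double(height_km),
      xrange = c(0, as.double(width_km)),
      yrange = c(0, as.double(height_km)),
      area = as.double(width_km) * as.double(height_km)
    ),
    class = "study_window"
  )
}

#' @export
print.study_window <- function(x, ...) {
  cat(sprintf(
    "<study_window> %.6g x %.6g km (area %.6g km^2)\n",
    x$width, x$height, x$area
  ))
  invisible(x)
}

is_window <- function(x) inherits(x, "study_window")

check_window <- function(window) {
  if (!is_window(window)) abort("`window` must be a `study_window` object.")
  invisible(window)
}

#' Analysis-grid cells of a study window
#'
#' Enumerates the cells of the window's analysis grid. Cell edges are anchored
#' at the origin on multiples of `cellsize`; the grid ceil-covers the window,
#' so boundary cells of a non-integer window are partial and carry their
#' clipped area as `weight`. Area-weighted statistics over the window
#' (Berman-test moments, covariate distributions) use these weights.
#'
#' @param window A [make_window()] object.
#' @param cellsize Cell edge length in km (default 1).
#' @return A tibble with cell-centre coordinates `x`, `y` and clipped cell
#'   area `weight` (km^2).
#' @export
window_cells <- function(window, cellsize = 1) {
  check_window(window)
  stop_if_not_scalar_pos(cellsize, "cellsize")
  nx <- ceiling(window$width / cellsize - 1e-12)
  ny <- ceiling(window$height / cellsize - 1e-12)
  cx <- (seq_len(nx) - 0.5) * cellsize
  cy <- (seq_len(ny) - 0.5) * cellsize
  wx <- pmin(cellsize, window$width - (seq_len(nx) - 1) * cellsize)
  wy <- pmin(cellsize, window$height - (seq_len(ny) - 1) * cellsize)
  tibble(
    x = rep(cx, times = ny),
    y = rep(cy, each = nx),
    weight = rep(wx, times = ny) * rep(wy, each = nx)
  )
}

# TRUE for points inside or on the boundary of the window rectangle.
in_window <- function(window, x, y) {
  x >= window$xrange[1] & x <= window$xrange[2] &
    y >= window$yrange[1] & y <= window$yrange[2]
}
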