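# Planar geometry primitives: point-to-segment distance, polygon containment
# and boundary distance. Everything is vectorised over points; feature counts
# are modest (tens to hundreds), so loops run over features.

# Distance from points (px, py) to the segment (x0,y0)-(x1,y1).
dist_point_segment <- function(px, py, x0, y0, x1, y1) {
  dx <- x1 - x0
  dy <- y1 - y0
  l2 <- dx * dx + dy * dy
  if (l2 == 0) {
    return(sqrt((px - x0)^2 + (py - y0)^2))
  }
  t <- ((px - x0) * dx + (py - y0) * dy) / l2
  t <- pmin(1, pmax(0, t))
  sqrt((px - x0 - t * dx)^2 + (py - y0 - t * dy)^2)
}

# Minimum distance from points to a set of segments given as a data frame
# with columns x0, y0, x1, y1. Returns Inf when `segments` has no rows.
dist_to_segments <- function(px, py, segments) {
  d <- rep(Inf, length(px))
  if (is.null(segments) || nrow(segments) == 0) {
    return(d)
  }
  for (k in seq_len(nrow(segments))) {
    d <- pmin(d, dist_point_segment(
      px, py,
      segments$x0[k], segments$y0[k], segments$x1[k], segments$y1[k]
    ))
  }
  d
}

# Edges of a polygon ring (two-column matrix of vertices, open or closed)
# as a segment data frame.
ring_edges <- function(ring) {
  ring <- as.matrix(ring)
  n <- nrow(ring)
  if (n >= 2 &&
    isTRUE(all.equal(ring[1, ], ring[n, ], check.attributes = FALSE))) {
    ring <- ring[-n, , drop = FALSE]
    n <- n - 1
  }
  if (n < 3) abort("A polygon ring needs at least 3 distinct vertices.")
  j <- c(seq_len(n)[-1], 1L)
  data.frame(
    x0 = ring[, 1], y0 = ring[, 2],
    x1 = ring[j, 1], y1 = ring[j, 2]
  )
}

# Distance from points to the boundary of a polygon ring.
dist_to_ring <- function(px, py, ring) {
  dist_to_segments(px, py, ring_edges(ring))
}

# Point-in-polygon with boundary included. mgcv::in.out decides strict
# interior membership; points within `eps` of the boundary are forced TRUE so
# the boundary counts as inside ("covers" semantics).
points_in_ring <- function(px, py, ring, eps = 1e-9) {
  ring <- as.matrix(ring)
  n <- nrow(ring)
  if (!isTRUE(all.equal(ring[1, ], ring[n, ], check.attributes = FALSE))) {
    ring <- rbind(ring, ring[1, ])
  }
  inside <- mgcv::in.out(ring, cbind(px, py))
  on_edge <- dist_to_ring(px, py, ring) <= eps
  inside | on_edge
}

# Regular-polygon approximation of a circle, used for synthetic habitat blobs.
circle_ring <- function(cx, cy, r, n_vertices = 24L) {
  th <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  cbind(x = cx + r * cos(th), y = cy + r * sin(th))
}

# Clip a polygon ring to a rectangle [0,w] x [0,h] (Sutherland-Hodgman).
clip_ring_to_window <- function(ring, window) {
  ring <- as.matrix(ring)
  clip_half <- function(pts, inside, intersect) {
    n <- nrow(pts)
    if (n == 0) {
      return(pts)
    }
    out <- matrix(numeric(0), ncol = 2)
    for (i in seq_len(n)) {
      a <- pts[i, ]
      b <- pts[if (i == n) 1L else i + 1L, ]
      ain <- inside(a)
      bin <- inside(b)
      if (ain && bin) {
        out <- rbind(out, b)
      } else if (ain && !bin) {
        out <- rbind(out, intersect(a, b))
      } else if (!ain && bin) {
        out <- rbind(out, intersect(a, b), b)
      }
    }
    out
  }
  ix <- function(a, b, bound, axis) {
    t <- (bound - a[axis]) / (b[axis] - a[axis])
    a + t * (b - a)
  }
  w <- window$width
  h <- window$height
  ring <- clip_half(ring, function(p) p[1] >= 0, function(a, b) ix(a, b, 0, 1))
  ring <- clip_half(ring, function(p) p[1] <= w, function(a, b) ix(a, b, w, 1))
  ring <- clip_half(ring, function(p) p[2] >= 0, function(a, b) ix(a, b, 0, 2))
  ring <- clip_half(ring, function(p) p[2] <= h, function(a, b) ix(a, b, h, 2))
  if (nrow(ring) >= 3) ring else NULL
}
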