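# Point-process inference against spatial covariates: nonparametric
# intensity-vs-covariate estimation (rho-hat), the Berman Z1 dependence
# test, point-process ROC/AUC, and log-linear Poisson models fitted by the
# Berman-Turner quadrature device.

# Weighted 1-D Gaussian KDE on a fixed grid with reflection at the support
# ends [a, b]. Reflection keeps the integral over [a, b] at ~1 for bounded
# covariates (distance covariates pile mass at z = 0). Blockwise over
# samples to bound memory.
kde1d_reflect <- function(x, grid, bw, weights = NULL, support = range(grid)) {
  n <- length(x)
  w <- if (is.null(weights)) rep(1 / n, n) else weights / sum(weights)
  a <- support[1]
  b <- support[2]
  f <- numeric(length(grid))
  block <- 4000L
  for (s in seq(1, n, by = block)) {
    e <- min(n, s + block - 1L)
    xs <- x[s:e]
    ws <- w[s:e]
    for (xx in list(xs, 2 * a - xs, 2 * b - xs)) {
      f <- f + as.vector(exp(-outer(grid, xx, "-")^2 / (2 * bw^2)) %*% ws)
    }
  }
  f / (bw * sqrt(2 * pi))
}

# Covariate values and area weights over the window cells of a raster.
raster_window_values <- function(raster, window) {
  cells <- window_cells(window, raster$cellsize)
  list(z = as.vector(raster$values), w = cells$weight)
}

#' Nonparametric intensity as a function of a covariate (rho-hat)
#'
#' Estimates `rho(z)` in the intensity model `lambda(u) = rho(Z(u))` by the
#' ratio method: a kernel density `f(z)` of covariate values at the event
#' points over a kernel density `g(z)` of covariate values across the whole
#' window (area-weighted), scaled by the average intensity `n / |W|`.
#' Both densities use a common fixed Gaussian bandwidth (Scott's 1-D rule on
#' the event covariate values) with reflection at the covariate range ends.
#' Pointwise 95\% confidence bands come from the Poisson delta method: the
#' event-side kernel intensity has variance `tau(z) / (2 sqrt(pi) h)`, and
#' `g` is treated as fixed (it is estimated from every window cell and is
#' effectively noiseless by comparison).
#'
#' @param points Event locations (`x`, `y`), at least 20.
#' @param covariate_raster A `spatial_raster` covariate Z(u).
#' @param window A [make_window()] object.
#' @param n_grid Number of evaluation points across the covariate's window
#'   range (default 512).
#' @param conf Confidence level for the bands (default 0.95).
#' @param mode Point sampling mode, see [covariate_at_points()].
#' @return A `rho_estimate` tibble: `z`, `rho`, `lo`, `hi`, with `baseline`,
#'   `bandwidth`, `n` and `area` attributes.
#' @export
rhohat <- function(points, covariate_raster, window, n_grid = 512,
                   conf = 0.95, mode = "bilinear") {
  check_window(window)
  n <- nrow(points)
  if (n < 20) abort("rhohat needs at least 20 points for a meaningful band.")
  # window-side covariate distribution: sample the same interpolated field
  # the points see, on a 4x-per-axis oversampled grid, so g-hat reflects the
  # continuous field rather than the raster's discrete cell values
  sub <- window_cells(window, covariate_raster$cellsize / 4)
  wv <- list(
    z = covariate_at_points(covariate_raster, sub, mode = mode),
    w = sub$weight
  )
  if (stats::sd(wv$z) == 0) abort("Covariate is constant over the window.")
  zp <- covariate_at_points(covariate_raster, points, mode = mode)
  zr <- range(wv$z)
  grid <- seq(zr[1], zr[2], length.out = n_grid)
  h <- stats::sd(zp) * n^(-1 / 5)
  h <- max(h, diff(zr) / n_grid) # degenerate patterns: floor at grid scale
  f <- kde1d_reflect(zp, grid, h, support = zr)
  g <- kde1d_reflect(wv$z, grid, h, weights = wv$w, support = zr)
  area <- sum(wv$w)
  baseline <- n / area
  g_floor <- pmax(g, 1e-12)
  rho <- baseline * f / g_floor
  se <- sqrt(n * f / (2 * sqrt(pi) * h)) / (area * g_floor)
  zq <- stats::qnorm(1 - (1 - conf) / 2)
  out <- tibble(
    z = grid,
    rho = rho,
    lo = pmax(0, rho - zq * se),
    hi = rho + zq * se
  )
  attr(out, "baseline") <- baseline
  attr(out, "bandwidth") <- h
  attr(out, "n") <- n
  attr(out, "area") <- area
  attr(out, "feature_class") <- covariate_raster$feature_class
  structure(out, class = c("rho_estimate", class(out)))
}

#' @export
tidy.rho_estimate <- function(x, ...) {
  as_tibble(unclass(x)[c("z", "rho", "lo", "hi")])
}

#' Berman Z1 test of covariate dependence
#'
#' Tests whether event locations depend on a spatial covariate. Under the
#' null (homogeneous Poisson), the sum `S = sum_i Z(x_i)` of covariate
#' values at the `n` events has mean `n mu` and variance `n sigma^2`, where
#' `mu` and `sigma^2` are the area-weighted moments of Z over the window;
#' `Z1 = (S - n mu) / sqrt(n sigma^2)` is referred to the standard normal
#' (two-sided). A negative statistic means events sit at lower covariate
#' values than the window average.
#'
#' @inheritParams rhohat
#' @return A `berman_test` object with `statistic_Z1`, `p_value`, `n`,
#'   `covariate_mean`, `covariate_var`.
#' @export
berman_test <- function(points, covariate_raster, window, mode = "bilinear") {
  check_window(window)
  n <- nrow(points)
  if (n < 1) abort("Berman test needs at least one point.")
  wv <- raster_window_values(covariate_raster, window)
  W <- sum(wv$w)
  mu <- sum(wv$w * wv$z) / W
  sig2 <- sum(wv$w * (wv$z - mu)^2) / W
  if (sig2 <= 0) abort("Covariate variance over the window is zero.")
  S <- sum(covariate_at_points(covariate_raster, points, mode = mode))
  z1 <- (S - n * mu) / sqrt(n * sig2)
  structure(
    list(
      statistic_Z1 = z1,
      p_value = 2 * stats::pnorm(-abs(z1)),
      n = n,
      covariate_mean = mu,
      covariate_var = sig2,
      feature_class = covariate_raster$feature_class
    ),
    class = "berman_test"
  )
}

#' @export
print.berman_test <- function(x, ...) {
  cat(sprintf(
    "Berman Z1 test%s\n  Z1 = %.4f, p = %.4g (n = %d)\n  window covariate: mean %.4g, var %.4g\n",
    if (is.null(x$feature_class)) "" else paste0(" [", x$feature_class, "]"),
    x$statistic_Z1, x$p_value, x$n, x$covariate_mean, x$covariate_var
  ))
  invisible(x)
}

#' @export
tidy.berman_test <- function(x, ...) {
  tibble(
    statistic = x$statistic_Z1, p.value = x$p_value, n = x$n,
    covariate_mean = x$covariate_mean, covariate_var = x$covariate_var
  )
}

#' ROC curve and AUC of a covariate for a point pattern
#'
#' Ranks the window's area by the covariate — in the direction that puts
#' predicted-high-intensity area first (ascending distance for distance
#' covariates, `high_intensity_at = "low"`) — and plots the cumulative
#' fraction of events captured against the cumulative fraction of area.
#' Events are assigned to their containing grid cell and cells with tied
#' covariate values are grouped, so reversing the orientation maps the
#' curve through the point (1/2, 1/2) and AUC to 1 - AUC exactly. AUC 0.5
#' means the covariate has no discriminatory power; 1 means complete
#' concentration of events in the best-ranked area.
#'
#' @inheritParams rhohat
#' @param high_intensity_at `"low"` (default; events expected at low
#'   covariate values) or `"high"`.
#' @return A `roc_curve` tibble: `area_fraction`, `point_fraction`, with an
#'   `auc` attribute.
#' @export
roc_auc <- function(points, covariate_raster, window,
                    high_intensity_at = c("low", "high")) {
  check_window(window)
  high_intensity_at <- match.arg(high_intensity_at)
  wv <- raster_window_values(covariate_raster, window)
  n <- nrow(points)
  # containing-cell assignment
  nx <- nrow(covariate_raster$values)
  i <- pmin(nx, pmax(1L, ceiling((points$x - covariate_raster$origin[1]) /
    covariate_raster$cellsize)))
  j <- pmin(
    ncol(covariate_raster$values),
    pmax(1L, ceiling((points$y - covariate_raster$origin[2]) /
      covariate_raster$cellsize))
  )
  cell <- (j - 1L) * nx + i
  npts <- tabulate(cell, nbins = length(wv$z))
  df <- tibble(z = wv$z, w = wv$w, np = npts) |>
    dplyr::group_by(.data$z) |>
    dplyr::summarise(w = sum(.data$w), np = sum(.data$np)) |>
    dplyr::arrange(if (high_intensity_at == "low") .data$z else dplyr::desc(.data$z))
  x <- c(0, cumsum(df$w) / sum(df$w))
  y <- c(0, if (n > 0) cumsum(df$np) / n else rep(0, nrow(df)))
  auc <- sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  out <- tibble(area_fraction = x, point_fraction = y)
  attr(out, "auc") <- auc
  attr(out, "direction") <- high_intensity_at
  attr(out, "feature_class") <- covariate_raster$feature_class
  structure(out, class = c("roc_curve", class(out)))
}

#' Area under a ROC curve
#' @param roc A [roc_auc()] result.
#' @return The AUC as a single number.
#' @export
auc <- function(roc) attr(roc, "auc")

# Berman-Turner quadrature scheme: data + dummy-grid points, counting
# weights cell_area / points-in-cell over the dummy tessellation.
bt_quadrature <- function(points, window, n_dummy) {
  dx <- window$width / n_dummy
  dy <- window$height / n_dummy
  gx <- (seq_len(n_dummy) - 0.5) * dx
  gy <- (seq_len(n_dummy) - 0.5) * dy
  dummy <- tibble(
    x = rep(gx, times = n_dummy),
    y = rep(gy, each = n_dummy)
  )
  quad <- dplyr::bind_rows(points[, c("x", "y")], dummy)
  is_data <- c(rep(TRUE, nrow(points)), rep(FALSE, nrow(dummy)))
  ti <- pmin(n_dummy, pmax(1L, ceiling(quad$x / dx)))
  tj <- pmin(n_dummy, pmax(1L, ceiling(quad$y / dy)))
  tile <- (tj - 1L) * n_dummy + ti
  counts <- tabulate(tile, nbins = n_dummy^2)
  w <- (dx * dy) / counts[tile]
  list(quad = quad, is_data = is_data, w = w)
}

#' Fit a log-linear inhomogeneous Poisson point-process model
#'
#' Maximises the inhomogeneous-Poisson log-likelihood
#' `sum_i log lambda(x_i) - integral_W lambda(u) du` for
#' `lambda(u) = exp(alpha + sum_k beta_k Z_k(u))` via the Berman-Turner
#' device: the integral is approximated on a quadrature scheme of data plus
#' an `n_dummy` x `n_dummy` dummy grid with counting weights from the dummy
#' tessellation, which reduces the likelihood to a weighted Poisson
#' regression with log link (response `1/w` at data points, 0 at dummies).
#'
#' @inheritParams rhohat
#' @param covariates A single `spatial_raster` or a named list of them.
#' @param n_dummy Dummy points per axis (default 80).
#' @return A `ppm_fit` with coefficients, standard errors, per-km intensity
#'   multiplier, log-likelihood and the fitted model's discriminant AUC.
#' @export
fit_loglinear_ppm <- function(points, covariates, window, n_dummy = 80,
                              mode = "bilinear") {
  check_window(window)
  if (nrow(points) < 10) abort("Need at least 10 points to fit a ppm.")
  if (inherits(covariates, "spatial_raster")) {
    nm <- covariates$feature_class %||% "z"
    covariates <- stats::setNames(list(covariates), nm)
  }
  q <- bt_quadrature(points, window, n_dummy)
  zmat <- vapply(
    covariates, function(r) covariate_at_points(r, q$quad, mode = mode),
    numeric(nrow(q$quad))
  )
  colnames(zmat) <- names(covariates)
  if (any(apply(zmat, 2, stats::sd) == 0)) {
    abort("A covariate is constant over the quadrature points.")
  }
  X <- cbind(`(Intercept)` = 1, zmat)
  y <- ifelse(q$is_data, 1 / q$w, 0)
  fit <- suppressWarnings(stats::glm.fit(X, y,
    weights = q$w,
    family = stats::poisson(link = "log")
  ))
  if (!fit$converged) {
    abort(sprintf(
      "ppm fit did not converge after %d IRLS iterations (possible separation).",
      fit$iter
    ))
  }
  cf <- stats::coef(fit)
  # observed-information covariance from the final weighted QR decomposition
  R <- qr.R(fit$qr)
  vc <- chol2inv(R)
  dimnames(vc) <- list(colnames(X), colnames(X))
  alpha <- unname(cf[1])
  beta <- cf[-1]
  names(beta) <- names(covariates)
  se <- sqrt(diag(vc))[-1]
  # Poisson log-likelihood on the quadrature approximation
  eta <- alpha + as.vector(zmat %*% beta)
  loglik <- sum(eta[q$is_data]) - sum(q$w * exp(eta))
  # discriminant AUC of the fitted intensity surface
  lp_values <- Reduce(`+`, purrr::map2(
    covariates, beta,
    function(r, b) b * r$values
  ))
  lp_raster <- spatial_raster(alpha + lp_values,
    origin = covariates[[1]]$origin,
    cellsize = covariates[[1]]$cellsize, feature_class = "fitted_log_intensity"
  )
  roc <- roc_auc(points, lp_raster, window, high_intensity_at = "high")
  structure(
    list(
      intercept_alpha = alpha,
      slope_beta = beta,
      se_beta = se,
      vcov = vc,
      multiplier_per_km = exp(beta),
      percent_change_per_km = 100 * (1 - exp(beta)),
      loglik = loglik,
      auc = auc(roc),
      roc = roc,
      n = nrow(points),
      n_dummy = n_dummy,
      covariate_names = names(covariates)
    ),
    class = "ppm_fit"
  )
}

#' @export
print.ppm_fit <- function(x, ...) {
  cat(sprintf(
    "Log-linear Poisson point-process model (Berman-Turner, %d x %d dummy grid)\n",
    x$n_dummy, x$n_dummy
  ))
  cat(sprintf("  n = %d events; log-likelihood %.2f; AUC %.3f\n", x$n, x$loglik, x$auc))
  cat(sprintf("  alpha (log intensity at Z = 0): %.4f\n", x$intercept_alpha))
  for (k in seq_along(x$slope_beta)) {
    cat(sprintf(
      "  beta[%s] = %.4f (se %.4f); per-km multiplier %.3f (%.1f%% %s per km)\n",
      names(x$slope_beta)[k], x$slope_beta[k], x$se_beta[k],
      x$multiplier_per_km[k], abs(x$percent_change_per_km[k]),
      if (x$percent_change_per_km[k] >= 0) "decrease" else "increase"
    ))
  }
  invisible(x)
}

#' @export
tidy.ppm_fit <- function(x, ...) {
  est <- c(x$intercept_alpha, x$slope_beta)
  se <- c(sqrt(diag(x$vcov))[1], x$se_beta)
  stat <- est / se
  tibble(
    term = c("(Intercept)", names(x$slope_beta)),
    estimate = unname(est),
    std.error = unname(se),
    statistic = unname(stat),
    p.value = 2 * stats::pnorm(-abs(unname(stat)))
  )
}

#' @export
glance.ppm_fit <- function(x, ...) {
  tibble(
    logLik = x$loglik, auc = x$auc, nobs = x$n,
    n_dummy = x$n_dummy, n_covariates = length(x$slope_beta)
  )
}

#' Intensity multiplier per distance increment
#'
#' Converts a fitted log-linear slope into the multiplicative change in
#' sighting intensity over `delta_km` of the covariate, and the percentage
#' change ("sighting density decreased by X% per km" when the multiplier is
#' below 1).
#'
#' @param fit A [fit_loglinear_ppm()] result.
#' @param delta_km Covariate increment (km, default 1).
#' @param sanity_bound Warn when `|beta| * delta` exceeds this (likely a
#'   per-metre/per-km unit mix-up; default 50).
#' @return Tibble with `covariate`, `delta_km`, `multiplier`,
#'   `percent_change`, `direction`.
#' @export
intensity_multiplier <- function(fit, delta_km = 1, sanity_bound = 50) {
  stopifnot(inherits(fit, "ppm_fit"))
  b <- fit$slope_beta
  if (any(abs(b * delta_km) > sanity_bound)) {
    warn("Implausibly large |beta * delta|: check covariate units (km expected).")
  }
  m <- exp(b * delta_km)
  tibble(
    covariate = names(b),
    delta_km = delta_km,
    multiplier = unname(m),
    percent_change = unname(100 * abs(1 - m)),
    direction = unname(ifelse(m < 1, "decrease", ifelse(m > 1, "increase", "none")))
  )
}
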