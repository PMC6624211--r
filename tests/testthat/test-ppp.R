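# Fixtures used throughout: a window with a vertical line feature and its
# distance covariate.
ppp_fixture <- function(width = 20, height = 20, cellsize = 0.5) {
  w <- make_window(width, height)
  line <- tibble::tibble(
    x0 = width / 2, y0 = 0, x1 = width / 2, y1 = height
  )
  list(
    window = w,
    line = line,
    raster = distance_raster(line, w, cellsize = cellsize)
  )
}

test_that("Berman Z1 is centred, signed, and affine invariant", {
  w <- make_window(10, 10)
  # ramp covariate Z = x / 10: window mean 0.5 under equal cell weights
  cells <- window_cells(w)
  ramp <- spatial_raster(matrix(cells$x / 10, 10, 10), cellsize = 1)
  # 12 points at cell centres whose covariate values pair to sum 6
  pts <- tibble::tibble(
    x = rep(c(2.5, 7.5), 6),
    y = rep(seq(0.5, 5.5, 1), each = 2)
  )
  bt <- berman_test(pts, ramp, w, mode = "nearest")
  expect_equal(bt$statistic_Z1, 0, tolerance = 1e-9)
  expect_equal(bt$p_value, 1, tolerance = 1e-9)
  expect_equal(bt$covariate_mean, 0.5, tolerance = 1e-12)

  # affine rescaling z -> a z + b leaves Z1 unchanged (a > 0)
  ramp2 <- spatial_raster(3.7 * ramp$values + 2, cellsize = 1)
  pts2 <- tibble::tibble(x = runif(30, 0, 10), y = runif(30, 0, 10))
  b1 <- berman_test(pts2, ramp, w)
  b2 <- berman_test(pts2, ramp2, w)
  expect_equal(b1$statistic_Z1, b2$statistic_Z1, tolerance = 1e-9)

  # events pulled toward the feature give a strongly negative statistic
  fx <- ppp_fixture()
  ok <- vapply(1:50, function(s) {
    p <- simulate_ipp(fx$window, fx$raster, alpha = 1.5, beta = -3, seed = s)
    b <- berman_test(p, fx$raster, fx$window)
    b$statistic_Z1 < 0 && b$p_value < 0.001
  }, logical(1))
  expect_gte(mean(ok), 0.99)

  expect_error(
    berman_test(pts, spatial_raster(matrix(1, 10, 10)), w),
    "variance"
  )
})

test_that("Berman test holds its size under CSR", {
  fx <- ppp_fixture(width = 50, height = 50, cellsize = 1)
  rej <- vapply(1:200, function(s) {
    p <- simulate_ipp(fx$window, NULL, alpha = log(0.12), beta = 0, seed = 600 + s)
    berman_test(p, fx$raster, fx$window)$p_value < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.02)
  expect_lte(mean(rej), 0.09)
})

test_that("rho-hat reproduces a constant intensity under CSR", {
  fx <- ppp_fixture()
  frac <- vapply(1:50, function(s) {
    p <- simulate_ipp(fx$window, NULL, alpha = log(1.5), beta = 0, seed = 100 + s)
    rh <- rhohat(p, fx$raster, fx$window)
    base <- attr(rh, "baseline")
    mean(rh$lo <= base & base <= rh$hi)
  }, numeric(1))
  expect_gte(mean(frac), 0.90)
})

test_that("rho-hat recovers a known log-linear intensity", {
  w <- make_window(2, 428)
  line <- tibble::tibble(x0 = 1, y0 = 0, x1 = 1, y1 = 428)
  r <- distance_raster(line, w, cellsize = 0.25)
  pts <- simulate_ipp(w, r, alpha = 2, beta = -3, seed = 14)
  expect_gt(nrow(pts), 1500)
  rh <- rhohat(pts, r, w)
  zr <- range(rh$z)
  sel <- rh$z >= zr[1] + 0.1 * diff(zr) & rh$z <= zr[2] - 0.1 * diff(zr)
  rel_err <- abs(rh$rho[sel] - exp(2 - 3 * rh$z[sel])) / exp(2 - 3 * rh$z[sel])
  expect_lt(stats::median(rel_err), 0.15)
})

test_that("rho-hat bands are ordered, mass balances, degenerate input peaks", {
  fx <- ppp_fixture()
  p <- simulate_ipp(fx$window, fx$raster, alpha = 1, beta = -0.5, seed = 33)
  rh <- rhohat(p, fx$raster, fx$window)
  expect_true(all(rh$lo <= rh$rho + 1e-12 & rh$rho <= rh$hi + 1e-12))
  expect_true(all(rh$rho >= 0))

  # mass balance: integral of rho g |W| dz recovers the point count
  sub <- window_cells(fx$window, fx$raster$cellsize / 4)
  g <- koalasight:::kde1d_reflect(
    covariate_at_points(fx$raster, sub), rh$z, attr(rh, "bandwidth"),
    weights = sub$weight, support = range(rh$z)
  )
  mass <- sum(rh$rho * g) * diff(rh$z[1:2]) * attr(rh, "area")
  expect_lt(abs(mass - nrow(p)) / nrow(p), 0.05)

  # all events at one covariate value: the estimate peaks there
  z0_pts <- tibble::tibble(x = rep(13, 25), y = seq(1, 19, length.out = 25))
  rh0 <- rhohat(z0_pts, fx$raster, fx$window)
  z0 <- covariate_at_points(fx$raster, z0_pts[1, ])
  expect_lt(abs(rh0$z[which.max(rh0$rho)] - z0), diff(range(rh0$z)) / 50)

  expect_error(
    rhohat(p, spatial_raster(matrix(2, 40, 40), cellsize = 0.5), fx$window),
    "constant"
  )
  expect_error(rhohat(p[1:5, ], fx$raster, fx$window), "20")
})

test_that("ROC is monotone, flips exactly, and matches the probability form", {
  fx <- ppp_fixture()
  p <- simulate_ipp(fx$window, fx$raster, alpha = 1, beta = -2, seed = 44)
  roc <- roc_auc(p, fx$raster, fx$window)
  expect_true(all(diff(roc$area_fraction) >= 0))
  expect_true(all(diff(roc$point_fraction) >= -1e-12))
  expect_equal(range(roc$area_fraction), c(0, 1))
  expect_equal(range(roc$point_fraction), c(0, 1))
  expect_true(auc(roc) >= 0 && auc(roc) <= 1)

  # orientation flip maps auc to 1 - auc
  expect_equal(
    auc(roc_auc(p, fx$raster, fx$window, "high")),
    1 - auc(roc),
    tolerance = 1e-12
  )

  # all points in the 10% of area nearest the feature
  w <- make_window(10, 10)
  line <- tibble::tibble(x0 = 5, y0 = 0, x1 = 5, y1 = 10)
  r <- distance_raster(line, w, cellsize = 0.25)
  near <- tibble::tibble(x = runif(200, 4.6, 5.4), y = runif(200, 0, 10))
  roc_n <- roc_auc(near, r, w)
  expect_gte(auc(roc_n), 0.95)
  reach <- min(roc_n$area_fraction[roc_n$point_fraction >= 1 - 1e-12])
  expect_lte(reach, 0.1 + 1e-9)

  # probability-integral form on a 5 x 5 grid with ties, brute force
  set.seed(7)
  vals <- matrix(sample(1:5, 25, replace = TRUE), 5, 5)
  r5 <- spatial_raster(vals, cellsize = 1)
  w5 <- make_window(5, 5)
  pts5 <- tibble::tibble(x = c(0.5, 2.5, 2.5, 4.5), y = c(0.5, 0.5, 2.5, 4.5))
  z_pts <- covariate_at_points(r5, pts5, mode = "nearest")
  brute_auc <- mean(vapply(z_pts, function(z) {
    mean((as.vector(vals) > z) + 0.5 * (as.vector(vals) == z))
  }, numeric(1)))
  expect_equal(auc(roc_auc(pts5, r5, w5)), brute_auc, tolerance = 1e-12)
})

test_that("AUC is calibrated under CSR", {
  fx <- ppp_fixture(width = 50, height = 50, cellsize = 1)
  aucs <- vapply(1:40, function(s) {
    p <- simulate_ipp(fx$window, NULL, alpha = log(1), beta = 0, seed = 900 + s)
    auc(roc_auc(p, fx$raster, fx$window))
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.02)
})

test_that("ppm recovers the homogeneous closed form", {
  w <- make_window(10, 10)
  fx <- ppp_fixture(10, 10, cellsize = 0.5)
  p <- simulate_ipp(w, NULL, alpha = log(1), beta = 0, seed = 55)
  fit <- fit_loglinear_ppm(p, fx$raster, w, n_dummy = 60)
  expect_lt(abs(fit$slope_beta[1]), 2.5 * fit$se_beta[1])
  # with beta ~ 0 the intercept approaches log(n / |W|)
  se_alpha <- sqrt(fit$vcov[1, 1])
  expect_lt(abs(fit$intercept_alpha - log(nrow(p) / 100)), 3 * se_alpha)
})

test_that("ppm recovers a negative distance effect and its derived quantities", {
  fx <- ppp_fixture()
  p <- simulate_ipp(fx$window, fx$raster, alpha = 1.2, beta = -1, seed = 66)
  fit <- fit_loglinear_ppm(p, fx$raster, fx$window, n_dummy = 120)
  expect_lt(abs(fit$slope_beta[1] + 1), 4 * fit$se_beta[1])
  expect_equal(
    unname(fit$multiplier_per_km), unname(exp(fit$slope_beta)),
    tolerance = 1e-12
  )

  m <- intensity_multiplier(fit)
  expect_equal(m$multiplier, unname(exp(fit$slope_beta[1])), tolerance = 1e-12)
  expect_equal(m$percent_change, 100 * (1 - m$multiplier), tolerance = 1e-12)
  expect_equal(m$direction, "decrease")

  # multiplier composition over 2 km for beta = -ln 2
  fit2 <- fit
  fit2$slope_beta[] <- -log(2)
  m2 <- intensity_multiplier(fit2, delta_km = 2)
  expect_equal(m2$multiplier, 0.25, tolerance = 1e-12)
  expect_equal(m2$percent_change, 75, tolerance = 1e-12)

  # unit-misuse guard: per-metre slopes trip the sanity bound
  fit3 <- fit
  fit3$slope_beta[] <- -1000
  expect_warning(intensity_multiplier(fit3), "units")

  # tidy/glance follow the broom contract
  td <- tidy(fit)
  expect_equal(td$term[1], "(Intercept)")
  expect_equal(nrow(td), 2)
  expect_true(all(c("estimate", "std.error", "p.value") %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$nobs, nrow(p))
})

test_that("ppm quadrature converges as the dummy grid is refined", {
  fx <- ppp_fixture(10, 10, cellsize = 0.25)
  p <- simulate_ipp(fx$window, fx$raster, alpha = 2, beta = -1, seed = 77)
  b <- vapply(c(64, 128, 256), function(nd) {
    unname(fit_loglinear_ppm(p, fx$raster, fx$window, n_dummy = nd)$slope_beta[1])
  }, numeric(1))
  expect_lt(abs(b[3] - b[2]), abs(b[2] - b[1]) + 1e-6)
  expect_lt(abs(b[3] - b[2]), 1e-3)
})

test_that("rho-hat and ppm agree under the generative model", {
  # a strip window keeps the covariate range populated with events end to
  # end, so both estimators are informative across the whole z-grid
  w <- make_window(2, 428)
  line <- tibble::tibble(x0 = 1, y0 = 0, x1 = 1, y1 = 428)
  r <- distance_raster(line, w, cellsize = 0.25)
  p <- simulate_ipp(w, r, alpha = 2, beta = -3, seed = 88)
  rh <- rhohat(p, r, w)
  fit <- fit_loglinear_ppm(p, r, w, n_dummy = 160)
  zr <- range(rh$z)
  sel <- rh$z >= zr[1] + 0.1 * diff(zr) & rh$z <= zr[2] - 0.1 * diff(zr)
  par_curve <- exp(fit$intercept_alpha + fit$slope_beta[1] * rh$z)
  inside <- rh$lo[sel] <= par_curve[sel] & par_curve[sel] <= rh$hi[sel]
  expect_gte(mean(inside), 0.8)
})
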