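test_that("make_window builds the analysis grid and rejects degenerate input", {
  w <- make_window(10, 10)
  expect_equal(w$area, 100)
  cells <- window_cells(w)
  expect_equal(nrow(cells), 100)
  expect_true(all(cells$weight == 1))

  # non-integer window: grid ceil-covers, clipped cell areas sum to the area
  w2 <- make_window(240.75, 240)
  cells2 <- window_cells(w2)
  expect_equal(nrow(cells2), 241 * 240)
  expect_equal(sum(cells2$weight), 57780)

  expect_error(make_window(0, 5), "positive")
  expect_error(make_window(5, -1), "positive")
})

test_that("simulate_roads is seed-reproducible, clipped, and handles n = 0", {
  w <- make_window(10, 10)
  r1 <- simulate_roads(w, "tertiary", 5, seed = 1)
  r2 <- simulate_roads(w, "tertiary", 5, seed = 1)
  expect_identical(r1, r2)
  expect_false(identical(r1, simulate_roads(w, "tertiary", 5, seed = 2)))

  r0 <- simulate_roads(w, "primary", 0, seed = 1)
  expect_equal(nrow(r0), 0)
  expect_error(distance_raster(r0, w), "empty")

  r50 <- simulate_roads(w, "secondary", 50, seed = 3)
  expect_true(all(in_window_pts <- r50$x0 >= 0 & r50$x0 <= 10 &
    r50$y0 >= 0 & r50$y0 <= 10 & r50$x1 >= 0 & r50$x1 <= 10 &
    r50$y1 >= 0 & r50$y1 <= 10))
})

test_that("homogeneous thinning simulator matches the Poisson law", {
  w <- make_window(10, 10)
  counts <- vapply(
    1:500,
    function(s) nrow(simulate_ipp(w, NULL, alpha = log(2), beta = 0, seed = s)),
    numeric(1)
  )
  # mean within 3 standard errors of lambda |W| = 200
  expect_lt(abs(mean(counts) - 200), 3 * sqrt(200 / 500))
  # KS test of counts against the Poisson CDF (randomised PIT)
  set.seed(99)
  u <- stats::runif(length(counts))
  pit <- stats::ppois(counts - 1, 200) + u * stats::dpois(counts, 200)
  expect_gt(stats::ks.test(pit, "punif")$p.value, 0.01)
})

test_that("negative covariate slope pulls events toward the feature", {
  w <- make_window(20, 20)
  line <- tibble::tibble(x0 = 10, y0 = 0, x1 = 10, y1 = 20)
  r <- distance_raster(line, w, cellsize = 0.5)
  window_mean <- mean(r$values)
  zbar <- vapply(1:50, function(s) {
    pts <- simulate_ipp(w, r, alpha = 1, beta = -3, seed = s)
    mean(covariate_at_points(r, pts))
  }, numeric(1))
  expect_true(all(zbar < window_mean))
})

test_that("point patterns and record tables are bit-reproducible under seed", {
  scn <- tiny_scenario(seed = 5)
  s1 <- simulate_study(scn)
  s2 <- simulate_study(scn)
  expect_identical(s1$pattern, s2$pattern)
  expect_identical(s1$records, s2$records)
})

test_that("record attributes follow the scenario probabilities", {
  w <- make_window(50, 50)
  pts <- simulate_ipp(w, NULL, alpha = log(4.3), beta = 0, seed = 11)
  expect_gt(nrow(pts), 10000)
  scn <- tiny_scenario(seed = 1)
  scn$attribute_probs$sex <- c(male = 0.215, female = 0.215, unknown = 0.57)
  rec <- simulate_records(pts[1:10000, ], scn, seed = 12)
  truth <- attr(rec, "truth")
  share_unknown <- mean(rec$sex[seq_len(truth$n_points)] == "unknown")
  expect_lt(abs(share_unknown - 0.57), 0.02)
})

test_that("uniform seasonal profile yields uniform monthly counts", {
  scn <- tiny_scenario(seed = 2)
  scn$seasonal_profile <- rep(1 / 12, 12)
  scn$duplicate_fraction <- 0
  scn$corrupt_fraction <- 0
  w <- make_window(30, 30)
  reject <- vapply(1:100, function(s) {
    pts <- simulate_ipp(w, NULL, alpha = log(1), beta = 0, seed = 1000 + s)
    rec <- simulate_records(pts, scn, seed = 2000 + s)
    counts <- table(factor(as.integer(format(rec$date, "%m")), levels = 1:12))
    stats::chisq.test(counts)$p.value < 0.01
  }, logical(1))
  expect_lte(sum(reject), 2)
})

test_that("injected duplicates are exact (x, y, date) copies and nothing else", {
  scn <- tiny_scenario(seed = 3)
  scn$duplicate_fraction <- 0.1
  scn$corrupt_fraction <- 0
  w <- make_window(30, 30)
  pts <- simulate_ipp(w, NULL, alpha = log(1), beta = 0, seed = 21)
  rec <- simulate_records(pts, scn, seed = 22)
  truth <- attr(rec, "truth")
  expect_equal(nrow(rec), truth$n_points + truth$n_duplicates)
  key <- paste(rec$x, rec$y, rec$date)
  expect_equal(sum(duplicated(key)), truth$n_duplicates)

  # with both defect fractions zero the record count equals the pattern size
  scn$duplicate_fraction <- 0
  rec0 <- simulate_records(pts, scn, seed = 23)
  expect_equal(nrow(rec0), nrow(pts))
  expect_equal(attr(rec0, "truth")$n_duplicates, 0)
})

test_that("scenario validation rejects malformed profiles", {
  expect_error(
    simulation_scenario(seasonal_profile = rep(1 / 11, 11)),
    "seasonal_profile"
  )
  expect_error(
    simulation_scenario(seasonal_profile = c(rep(0.1, 11), 0.1)),
    "seasonal_profile"
  )
  bad <- default_attribute_probs()
  bad$sex <- c(male = 0.5, female = 0.6)
  expect_error(simulation_scenario(attribute_probs = bad), "sex")
})

test_that("scenario YAML round-trips", {
  scn <- tiny_scenario(seed = 9)
  path <- tempfile(fileext = ".yaml")
  write_scenario(scn, path)
  back <- read_scenario(path)
  expect_equal(back$window_width_km, scn$window_width_km)
  expect_equal(back$road_specs, scn$road_specs)
  expect_equal(back$intensity_slope_beta, scn$intensity_slope_beta)
  expect_equal(back$seasonal_profile, scn$seasonal_profile, tolerance = 1e-9)
  # generation from the round-tripped scenario is unchanged
  expect_equal(simulate_study(scn)$pattern, simulate_study(back)$pattern)
})
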