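# Synthetic study generator: landscape geometries, covariates and
# KoalaBASE-like sighting records with known generative structure, so every
# downstream stage (cleaning, temporal decomposition, density mapping,
# point-process inference) is testable end-to-end without external data.

#' Define a synthetic sighting-study scenario
#'
#' Bundles every knob of the synthetic generator. Defaults emulate the
#' South-East Queensland citizen-science study conditions: a 240.75 x 240 km
#' window (57,780 km^2), 17 years of records, attribute mixes matching the
#' reported sighting composition (57\% of koalas unsexed, 83\% adults, 87\%
#' seen in trees), a seasonal profile peaking in September–October, and
#' log-linear road-distance effects whose per-km intensity multipliers match
#' the reported 77/71/57\% decreases for primary/secondary/tertiary roads.
#'
#' @param window_width_km,window_height_km Window dimensions (km).
#' @param road_specs Tibble with columns `road_class`, `n_segments`.
#' @param habitat_specs Tibble with columns `suitability`, `n_patches`,
#'   `radius_km`.
#' @param intensity_intercept_alpha Log-intensity intercept (log events per
#'   km^2). If `NULL`, it is solved at simulation time so the expected count
#'   equals `target_n`.
#' @param intensity_slope_beta Named numeric vector of per-km log-intensity
#'   slopes, one entry per road class used as a generative covariate.
#' @param target_n Expected number of generated sightings when `alpha` is
#'   solved (default 14076).
#' @param seasonal_profile 12 non-negative monthly weights summing to 1.
#' @param attribute_probs Named list of probability vectors for `sex`,
#'   `age_class`, `physical_location`, `status`; each must sum to 1.
#' @param n_years,start_year Study period (default 17 years from 1997).
#' @param reporters_per_year Size of the annual reporter pool; `NULL` derives
#'   it from the year's record count at 1.4 sightings per reporter.
#' @param duplicate_fraction,corrupt_fraction Fractions of rows injected as
#'   exact (x, y, date) duplicates and as coordinate-corrupted rows, to
#'   exercise cleaning.
#' @param seed Integer master seed.
#' @return A `simulation_scenario` list.
#' @export
simulation_scenario <- function(window_width_km = 240.75,
                                window_height_km = 240,
                                road_specs = default_road_specs(),
                                habitat_specs = default_habitat_specs(),
                                intensity_intercept_alpha = NULL,
                                intensity_slope_beta = c(
                                  primary = log(1 - 0.77),
                                  secondary = log(1 - 0.71),
                                  tertiary = log(1 - 0.57)
                                ),
                                target_n = 14076,
                                seasonal_profile = default_seasonal_profile(),
                                attribute_probs = default_attribute_probs(),
                                n_years = 17,
                                start_year = 1997,
                                reporters_per_year = NULL,
                                duplicate_fraction = 0.02,
                                corrupt_fraction = 0.01,
                                seed = 1L) {
  stop_if_not_scalar_pos(window_width_km, "window_width_km")
  stop_if_not_scalar_pos(window_height_km, "window_height_km")
  if (length(seasonal_profile) != 12 || any(seasonal_profile < 0) ||
    abs(sum(seasonal_profile) - 1) > 1e-9) {
    abort("`seasonal_profile` needs 12 non-negative weights summing to 1.")
  }
  for (nm in c("sex", "age_class", "physical_location", "status")) {
    p <- attribute_probs[[nm]]
    if (is.null(p) || abs(sum(p) - 1) > 1e-9 || any(p < 0)) {
      abort(sprintf("`attribute_probs$%s` must be probabilities summing to 1.", nm))
    }
  }
  structure(
    list(
      window_width_km = window_width_km,
      window_height_km = window_height_km,
      road_specs = road_specs,
      habitat_specs = habitat_specs,
      intensity_intercept_alpha = intensity_intercept_alpha,
      intensity_slope_beta = intensity_slope_beta,
      target_n = target_n,
      seasonal_profile = seasonal_profile,
      attribute_probs = attribute_probs,
      n_years = as.integer(n_years),
      start_year = as.integer(start_year),
      reporters_per_year = reporters_per_year,
      duplicate_fraction = duplicate_fraction,
      corrupt_fraction = corrupt_fraction,
      seed = as.integer(seed)
    ),
    class = "simulation_scenario"
  )
}

#' @rdname simulation_scenario
#' @export
default_road_specs <- function() {
  tibble(
    road_class = c(
      "motorway", "primary", "secondary", "tertiary",
      "residential", "unclassified"
    ),
    n_segments = c(4L, 8L, 15L, 30L, 60L, 12L)
  )
}

#' @rdname simulation_scenario
#' @export
default_habitat_specs <- function() {
  tibble(
    suitability = c("highly_suitable", "suitable", "low_suitable"),
    n_patches = c(6L, 10L, 8L),
    radius_km = c(8, 10, 12)
  )
}

#' @rdname simulation_scenario
#' @export
default_seasonal_profile <- function() {
  # builds from June, peaks September-October, eases off by December
  raw <- c(6, 5.5, 5, 5, 5.5, 6.5, 8.5, 10.5, 13, 13, 10.5, 7.5)
  raw / sum(raw)
}

#' @rdname simulation_scenario
#' @export
default_attribute_probs <- function() {
  # sex/age/location mixes follow the reported composition of the 14,076
  # retained sightings; the status mix (applied before the live filter) is a
  # plausible, uncalibrated default.
  list(
    sex = c(male = 3076, female = 3134, unknown = 7866) / 14076,
    age_class = c(adult = 11708, subadult = 1615, young = 104, unknown = 649) / 14076,
    physical_location = c(tree = 11090, ground = 783, other = 861, unknown = 1342) / 14076,
    status = c(alive_sighting = 0.85, injured = 0.06, dead = 0.07, euthanized = 0.02)
  )
}

#' Simulate random road segments of one class
#'
#' Draws `n_segments` line segments with both endpoints uniform in the
#' window (so every segment lies wholly inside it), tagged with the road
#' class. Reproducible under `seed`.
#'
#' @param window A [make_window()] object.
#' @param class_name Road class label.
#' @param n_segments Number of segments (>= 0).
#' @param seed Integer seed.
#' @return Tibble with columns `road_class`, `x0`, `y0`, `x1`, `y1`.
#' @export
simulate_roads <- function(window, class_name, n_segments, seed = 1L) {
  check_window(window)
  if (n_segments < 0) abort("`n_segments` must be >= 0.")
  with_seed(seed, {
    n <- as.integer(n_segments)
    tibble(
      road_class = rep(class_name, n),
      x0 = stats::runif(n, 0, window$width),
      y0 = stats::runif(n, 0, window$height),
      x1 = stats::runif(n, 0, window$width),
      y1 = stats::runif(n, 0, window$height)
    )
  })
}

#' Simulate blob-shaped habitat patches of one suitability class
#'
#' Circular (24-gon) patches with uniform random centres, clipped to the
#' window.
#'
#' @param window A [make_window()] object.
#' @param suitability Suitability class label.
#' @param n_patches Number of patches.
#' @param radius_km Patch radius (km).
#' @param seed Integer seed.
#' @return Tibble with columns `suitability` and list-column `geometry`
#'   (two-column vertex matrices).
#' @export
simulate_habitat <- function(window, suitability, n_patches, radius_km,
                             seed = 1L) {
  check_window(window)
  with_seed(seed, {
    cx <- stats::runif(n_patches, 0, window$width)
    cy <- stats::runif(n_patches, 0, window$height)
    rings <- purrr::map(seq_len(n_patches), function(k) {
      clip_ring_to_window(circle_ring(cx[k], cy[k], radius_km), window)
    })
    keep <- !vapply(rings, is.null, logical(1))
    tibble(
      suitability = rep(suitability, sum(keep)),
      geometry = rings[keep]
    )
  })
}

#' Synthetic coastline for a study window
#'
#' The window's eastern edge as a single line segment, mirroring a coastal
#' study area whose sightings concentrate near the east coast.
#'
#' @param window A [make_window()] object.
#' @return A one-row segment tibble.
#' @export
simulate_coastline <- function(window) {
  check_window(window)
  tibble(
    class = "coastline",
    x0 = window$width, y0 = 0, x1 = window$width, y1 = window$height
  )
}

#' Synthetic elevation model rising away from the coast
#'
#' Elevation (m) as a piecewise-linear function of distance to the coastline:
#' near sea level within ~15 km of the coast, rising through the 100–200 m
#' band and up to ~1,280 m far inland, echoing the coastal-plain /
#' hinterland profile of the study region.
#'
#' @param window A [make_window()] object.
#' @param coastline Segment tibble (default [simulate_coastline()]).
#' @param cellsize Raster cell size (km).
#' @return A `spatial_raster` of elevations (m).
#' @export
simulate_dem <- function(window, coastline = simulate_coastline(window),
                         cellsize = 1) {
  d <- distance_raster(coastline, window, cellsize, feature_class = "coast")
  dmax <- max(max(d$values), 60)
  elev <- function(x) {
    stats::approx(
      x = c(0, 15, 40, dmax), y = c(5, 100, 200, 1280),
      xout = pmin(x, dmax), rule = 2
    )$y
  }
  spatial_raster(matrix(elev(d$values), nrow = nrow(d$values)),
    origin = d$origin, cellsize = d$cellsize, feature_class = "elevation_m"
  )
}

# Evaluate log-intensity alpha + sum_k beta_k Z_k(u) at points, given a
# single raster or a named list of rasters matching names(beta).
log_intensity_at <- function(points, covariate, alpha, beta) {
  lz <- rep(alpha, nrow(points))
  if (is.null(covariate)) {
    return(lz)
  }
  if (inherits(covariate, "spatial_raster")) {
    covariate <- list(covariate)
    beta <- unname(beta)[1]
    return(lz + beta * covariate_at_points(covariate[[1]], points))
  }
  for (nm in names(covariate)) {
    b <- beta[[nm]]
    if (is.null(b) || b == 0) next
    lz <- lz + b * covariate_at_points(covariate[[nm]], points)
  }
  lz
}

# Upper bound for exp(alpha + sum beta Z) over the window, computed on cell
# values. Bilinear sampling keeps any point's value inside the convex hull of
# its 4 cell corners, so the cell-value maximum bounds the point values.
log_intensity_max <- function(covariate, alpha, beta) {
  if (is.null(covariate)) {
    return(alpha)
  }
  if (inherits(covariate, "spatial_raster")) {
    return(alpha + max(unname(beta)[1] * covariate$values))
  }
  tot <- 0
  for (nm in names(covariate)) {
    b <- beta[[nm]]
    if (is.null(b) || b == 0) next
    tot <- tot + b * covariate[[nm]]$values
  }
  alpha + max(tot)
}

#' Simulate an inhomogeneous Poisson point pattern by thinning
#'
#' Draws a point pattern with intensity `lambda(u) = exp(alpha + beta *
#' Z(u))` by thinning a homogeneous Poisson process at the window-wide
#' intensity maximum — exact for bounded intensities. With `covariate =
#' NULL` (or `beta = 0`) the pattern is homogeneous Poisson (CSR) with
#' intensity `exp(alpha)`.
#'
#' @param window A [make_window()] object.
#' @param covariate A `spatial_raster`, a named list of them, or `NULL`.
#' @param alpha Log-intensity intercept (log events per km^2).
#' @param beta Slope (single raster) or named vector of slopes (list).
#' @param seed Integer seed.
#' @return Tibble of event locations `x`, `y` (class `point_pattern`).
#' @export
#' @examples
#' w <- make_window(10, 10)
#' pts <- simulate_ipp(w, NULL, alpha = log(2), beta = 0, seed = 1)
#' nrow(pts) # ~ Poisson(200)
simulate_ipp <- function(window, covariate = NULL, alpha, beta = 0, seed = 1L) {
  check_window(window)
  lmax <- log_intensity_max(covariate, alpha, beta)
  if (!is.finite(lmax)) abort("Maximum intensity is not finite over the window.")
  with_seed(seed, {
    n_cand <- stats::rpois(1, exp(lmax) * window$area)
    if (n_cand == 0) {
      return(structure(tibble(x = double(), y = double()),
        class = c("point_pattern", class(tibble()))
      ))
    }
    cand <- tibble(
      x = stats::runif(n_cand, 0, window$width),
      y = stats::runif(n_cand, 0, window$height)
    )
    keep <- stats::runif(n_cand) < exp(log_intensity_at(cand, covariate, alpha, beta) - lmax)
    structure(cand[keep, ], class = c("point_pattern", class(tibble())))
  })
}

# Solve alpha so that the expected count integral(exp(alpha + sum beta Z)) du
# equals target_n, using the window cell discretisation of the covariates.
solve_alpha <- function(window, covariate, beta, target_n, cellsize = 1) {
  if (is.null(covariate)) {
    return(log(target_n / window$area))
  }
  cells <- window_cells(window, cellsize)
  lz <- log_intensity_at(cells, covariate, 0, beta)
  log(target_n / sum(cells$weight * exp(lz)))
}

#' Simulate KoalaBASE-like sighting records for a point pattern
#'
#' Attaches dates, attributes and reporter identifiers to event locations,
#' and injects the data-quality defects that real citizen-science tables
#' carry: exact same-location same-date duplicate reports (multiple
#' observers) and rows with corrupted coordinates. Duplicates copy the
#' source row's location, date and koala attributes but get a fresh id and
#' reporter; they are only taken from live, uncorrupted rows so the
#' generator's bookkeeping matches the cleaning stage's exclusions exactly.
#'
#' @param pattern Point pattern tibble (from [simulate_ipp()]).
#' @param scenario A [simulation_scenario()].
#' @param seed Integer seed.
#' @return Tibble of sighting records with columns `id`, `date`, `x`, `y`,
#'   `sex`, `age_class`, `physical_location`, `status`, `reporter_id`, and a
#'   `truth` attribute recording `n_points`, `n_nonlive`, `n_duplicates`,
#'   `n_corrupt`.
#' @export
simulate_records <- function(pattern, scenario, seed = 1L) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  n <- nrow(pattern)
  ap <- scenario$attribute_probs
  with_seed(seed, {
    years <- scenario$start_year + sample.int(scenario$n_years, n, replace = TRUE) - 1L
    months <- sample.int(12L, n, replace = TRUE, prob = scenario$seasonal_profile)
    first <- as.Date(sprintf("%d-%02d-01", years, months))
    next_first <- as.Date(sprintf(
      "%d-%02d-01", years + (months == 12L), months %% 12L + 1L
    ))
    ndays <- as.integer(next_first - first)
    dates <- first + (sample.int(31L, n, replace = TRUE) - 1L) %% ndays

    draw <- function(p, n) sample(names(p), n, replace = TRUE, prob = p)
    rec <- tibble(
      id = sprintf("K%06d", seq_len(n)),
      date = dates,
      x = pattern$x,
      y = pattern$y,
      sex = draw(ap$sex, n),
      age_class = draw(ap$age_class, n),
      physical_location = draw(ap$physical_location, n),
      status = draw(ap$status, n)
    )

    # reporter pool per year, sightings-per-reporter heterogeneity via
    # 1/rank weights (a few prolific reporters, many occasional ones)
    rec$reporter_id <- NA_character_
    for (yr in sort(unique(years))) {
      idx <- which(years == yr)
      pool <- scenario$reporters_per_year %||% max(1L, ceiling(length(idx) / 1.4))
      wts <- 1 / seq_len(pool)
      rec$reporter_id[idx] <- sprintf(
        "P%d_%03d", yr,
        sample.int(pool, length(idx), replace = TRUE, prob = wts)
      )
    }

    # corrupt coordinates on a sample of rows
    n_corrupt <- round(scenario$corrupt_fraction * n)
    corrupt_idx <- if (n_corrupt > 0) sample.int(n, n_corrupt) else integer(0)
    rec$x[corrupt_idx] <- -9999
    rec$y[corrupt_idx] <- -9999

    # duplicates of live, uncorrupted rows: same (x, y, date), fresh id
    live_ok <- setdiff(which(rec$status == "alive_sighting"), corrupt_idx)
    n_dup <- min(length(live_ok), round(scenario$duplicate_fraction * n))
    dup_src <- if (n_dup > 0) sample(live_ok, n_dup) else integer(0)
    if (n_dup > 0) {
      dup <- rec[dup_src, ]
      dup$id <- sprintf("K%06d", n + seq_len(n_dup))
      dup$reporter_id <- paste0(dup$reporter_id, "x")
      rec <- dplyr::bind_rows(rec, dup)
    }

    # non-live count excludes coordinate-corrupted rows: the cleaning stage
    # drops those for their coordinates before it ever looks at status
    uncorrupted <- setdiff(seq_len(nrow(rec)), corrupt_idx)
    attr(rec, "truth") <- list(
      n_points = n,
      n_nonlive = sum(rec$status[uncorrupted] != "alive_sighting"),
      n_duplicates = n_dup,
      n_corrupt = n_corrupt
    )
    rec
  })
}

#' Run the full synthetic generator for a scenario
#'
#' Generates roads, habitat patches, coastline, elevation, the distance
#' covariates used by the generative intensity, the point pattern, and the
#' record table, each from its own substream of the scenario seed.
#'
#' @param scenario A [simulation_scenario()].
#' @param cellsize Raster resolution (km, default 1).
#' @return A list with `window`, `roads`, `habitat`, `coastline`, `dem`,
#'   `covariates` (named list of distance rasters), `alpha`, `pattern`,
#'   `records`.
#' @export
simulate_study <- function(scenario, cellsize = 1) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  window <- make_window(scenario$window_width_km, scenario$window_height_km)
  roads <- purrr::map2_dfr(
    scenario$road_specs$road_class, seq_len(nrow(scenario$road_specs)),
    function(cls, k) {
      simulate_roads(window, cls, scenario$road_specs$n_segments[k],
        seed = derive_seed(scenario$seed, k)
      )
    }
  )
  habitat <- purrr::map_dfr(seq_len(nrow(scenario$habitat_specs)), function(k) {
    simulate_habitat(
      window,
      scenario$habitat_specs$suitability[k],
      scenario$habitat_specs$n_patches[k],
      scenario$habitat_specs$radius_km[k],
      seed = derive_seed(scenario$seed, 100 + k)
    )
  })
  coastline <- simulate_coastline(window)
  dem <- simulate_dem(window, coastline, cellsize)

  beta <- scenario$intensity_slope_beta
  cov_classes <- names(beta)[beta != 0]
  covariates <- purrr::map(cov_classes, function(cls) {
    distance_raster(dplyr::filter(roads, .data$road_class == cls), window,
      cellsize,
      feature_class = cls
    )
  })
  names(covariates) <- cov_classes

  alpha <- scenario$intensity_intercept_alpha %||%
    solve_alpha(window, covariates, beta, scenario$target_n, cellsize)
  pattern <- simulate_ipp(window, covariates, alpha, beta,
    seed = derive_seed(scenario$seed, 200)
  )
  records <- simulate_records(pattern, scenario,
    seed = derive_seed(scenario$seed, 201)
  )
  list(
    window = window, roads = roads, habitat = habitat, coastline = coastline,
    dem = dem, covariates = covariates, alpha = alpha,
    pattern = pattern, records = records
  )
}
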