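# GeoJSON interchange for the package's vector geometries: line segments
# (roads, coastline) and polygon rings (habitat patches, regions).

#' Write line or polygon features as GeoJSON
#'
#' Segment tibbles become `LineString` features; polygon tibbles (with a
#' `geometry` list-column of vertex matrices) become `Polygon` features.
#' All non-geometry columns are carried as feature properties.
#'
#' @param features Segment or polygon tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_geojson <- function(features, path) {
  is_polygons <- "geometry" %in% names(features)
  props <- features[setdiff(names(features), c("geometry", "x0", "y0", "x1", "y1"))]
  feats <- purrr::map(seq_len(nrow(features)), function(k) {
    geom <- if (is_polygons) {
      ring <- as.matrix(features$geometry[[k]])
      if (!isTRUE(all.equal(ring[1, ], ring[nrow(ring), ], check.attributes = FALSE))) {
        ring <- rbind(ring, ring[1, ])
      }
      list(type = "Polygon", coordinates = list(unname(ring)))
    } else {
      list(type = "LineString", coordinates = unname(rbind(
        c(features$x0[k], features$y0[k]),
        c(features$x1[k], features$y1[k])
      )))
    }
    list(
      type = "Feature",
      properties = as.list(props[k, , drop = FALSE]),
      geometry = geom
    )
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = feats),
    path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read GeoJSON features written by [write_geojson()]
#'
#' @param path GeoJSON path.
#' @return A segment tibble (LineStrings) or polygon tibble (Polygons).
#' @export
read_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  if (!identical(gj$type, "FeatureCollection")) abort("Not a FeatureCollection.")
  feats <- gj$features
  types <- vapply(feats, function(f) f$geometry$type, "")
  get_props <- function(f) as_tibble(f$properties[lengths(f$properties) == 1])
  if (all(types == "LineString")) {
    purrr::map_dfr(feats, function(f) {
      cc <- f$geometry$coordinates
      dplyr::bind_cols(
        get_props(f),
        tibble(
          x0 = as.numeric(cc[[1]][[1]]), y0 = as.numeric(cc[[1]][[2]]),
          x1 = as.numeric(cc[[length(cc)]][[1]]), y1 = as.numeric(cc[[length(cc)]][[2]])
        )
      )
    })
  } else if (all(types == "Polygon")) {
    out <- purrr::map_dfr(feats, get_props)
    out$geometry <- purrr::map(feats, function(f) {
      ring <- f$geometry$coordinates[[1]]
      m <- do.call(rbind, purrr::map(ring, function(v) as.numeric(unlist(v))))
      colnames(m) <- c("x", "y")
      # GeoJSON rings are closed; return the open ring
      if (nrow(m) > 1 && all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
      m
    })
    out
  } else {
    abort("Mixed or unsupported geometry types.")
  }
}

#' Write / read a simulation scenario as YAML
#'
#' @param scenario A [simulation_scenario()].
#' @param path YAML path.
#' @return `write_scenario()` returns `path` invisibly; `read_scenario()`
#'   returns a `simulation_scenario`.
#' @export
write_scenario <- function(scenario, path) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  s <- unclass(scenario)
  s$road_specs <- as.list(as.data.frame(s$road_specs))
  s$habitat_specs <- as.list(as.data.frame(s$habitat_specs))
  s$attribute_probs <- purrr::map(s$attribute_probs, as.list)
  s$intensity_slope_beta <- as.list(s$intensity_slope_beta)
  yaml::write_yaml(s, path, precision = 15)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  s <- yaml::read_yaml(path)
  # YAML serialisation can shave trailing digits; renormalise tiny drift
  sp <- as.numeric(unlist(s$seasonal_profile))
  if (abs(sum(sp) - 1) < 1e-6) s$seasonal_profile <- sp / sum(sp)
  s$attribute_probs <- purrr::map(s$attribute_probs, function(p) {
    p <- unlist(p)
    if (abs(sum(p) - 1) < 1e-6) p / sum(p) else p
  })
  do.call(simulation_scenario, list(
    window_width_km = s$window_width_km,
    window_height_km = s$window_height_km,
    road_specs = tibble(
      road_class = unlist(s$road_specs$road_class),
      n_segments = as.integer(unlist(s$road_specs$n_segments))
    ),
    habitat_specs = tibble(
      suitability = unlist(s$habitat_specs$suitability),
      n_patches = as.integer(unlist(s$habitat_specs$n_patches)),
      radius_km = as.numeric(unlist(s$habitat_specs$radius_km))
    ),
    intensity_intercept_alpha = s$intensity_intercept_alpha,
    intensity_slope_beta = unlist(s$intensity_slope_beta),
    target_n = s$target_n,
    seasonal_profile = as.numeric(unlist(s$seasonal_profile)),
    attribute_probs = purrr::map(s$attribute_probs, unlist),
    n_years = s$n_years,
    start_year = s$start_year,
    reporters_per_year = s$reporters_per_year,
    duplicate_fraction = s$duplicate_fraction,
    corrupt_fraction = s$corrupt_fraction,
    seed = s$seed
  ))
}
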