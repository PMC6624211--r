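# Small fixtures shared across test files; everything is generated in code.

# a compact scenario that keeps simulation sizes test-friendly
tiny_scenario <- function(seed = 1L, ...) {
  simulation_scenario(
    window_width_km = 30,
    window_height_km = 30,
    road_specs = tibble::tibble(
      road_class = c("primary", "tertiary"),
      n_segments = c(3L, 6L)
    ),
    habitat_specs = tibble::tibble(
      suitability = "suitable", n_patches = 3L, radius_km = 4
    ),
    intensity_slope_beta = c(tertiary = -0.8),
    target_n = 400,
    n_years = 4,
    start_year = 2001,
    seed = seed,
    ...
  )
}

# hand-built record tibble for cleaning tests
records_fixture <- function() {
  tibble::tibble(
    id = sprintf("K%02d", 1:10),
    date = as.Date("2001-06-15") + c(0, 0, 0, 1, 2, 3, 4, 5, 6, 7),
    x = c(5, 5, 5, 5, 1, 2, 3, 4, 6, 7),
    y = c(5, 5, 5, 5, 1, 2, 3, 4, 6, 7),
    sex = c("male", "female", rep("unknown", 8)),
    age_class = rep("adult", 10),
    physical_location = c(rep("tree", 8), "ground", "other"),
    status = c(rep("alive_sighting", 7), "dead", "injured", "euthanized"),
    reporter_id = sprintf("P%d", c(1, 2, 3, 1, 1, 1, 2, 2, 3, 3))
  )
}

expect_tibble <- function(x) testthat::expect_s3_class(x, "tbl_df")
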