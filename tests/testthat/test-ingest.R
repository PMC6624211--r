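test_that("read_sightings parses, flags, and names missing columns", {
  w <- make_window(10, 10)
  rec <- records_fixture()
  path <- tempfile(fileext = ".csv")
  readr::write_csv(rec[1:5, ], path)
  got <- read_sightings(path, w)
  expect_equal(nrow(got), 5)
  expect_true(all(got$flag == "ok"))

  # out-of-window coordinate flagged, not dropped
  bad <- rec[1:3, ]
  bad$x[2] <- 99
  readr::write_csv(bad, path)
  got <- read_sightings(path, w)
  expect_equal(got$flag, c("ok", "bad_coords", "ok"))
  expect_equal(nrow(got), 3)

  # missing mandatory column is named in the error
  readr::write_csv(rec[, setdiff(names(rec), "date")], path)
  expect_error(read_sightings(path, w), "date")
})

test_that("filter_live keeps only live sightings and counts exclusions", {
  rec <- records_fixture() # 7 alive, 1 dead, 1 injured, 1 euthanized
  fl <- filter_live(rec)
  expect_equal(nrow(fl$records), 7)
  expect_true(all(fl$records$status == "alive_sighting"))
  expect_equal(sum(fl$excluded$n), 3)
  expect_setequal(fl$excluded$status, c("dead", "injured", "euthanized"))

  # all-alive input is the identity
  alive <- rec[rec$status == "alive_sighting", ]
  expect_identical(filter_live(alive)$records, alive)

  # brute-force recount on a random status draw
  set.seed(42)
  rec$status <- sample(c("alive_sighting", "dead", "injured"), 10, replace = TRUE)
  expect_equal(nrow(filter_live(rec)$records), sum(rec$status == "alive_sighting"))
})

test_that("deduplicate removes same-day same-location repeats, keeps lowest id", {
  rec <- records_fixture()
  # rows 1-3 share (5, 5) and the same date; row 4 same spot next day
  dd <- deduplicate(rec)
  expect_equal(dd$n_excluded, 2)
  expect_true("K01" %in% dd$records$id) # lowest id retained
  expect_false(any(c("K02", "K03") %in% dd$records$id))
  expect_true("K04" %in% dd$records$id) # different day survives

  # multi-animal flag exempts rows from removal
  rec$multi_animal <- c(FALSE, TRUE, TRUE, rep(FALSE, 7))
  dd2 <- deduplicate(rec)
  expect_equal(dd2$n_excluded, 0)
})

test_that("cleaning counts reconcile and match generator bookkeeping", {
  scn <- tiny_scenario(seed = 7)
  scn$duplicate_fraction <- 0.1
  scn$corrupt_fraction <- 0.05
  study <- simulate_study(scn)
  truth <- attr(study$records, "truth")
  cleaned <- clean_sightings(study$records, study$window)
  rep <- cleaned$report
  expect_equal(rep$n_excluded_coords, truth$n_corrupt)
  expect_equal(rep$n_excluded_status, truth$n_nonlive)
  expect_equal(rep$n_excluded_duplicate, truth$n_duplicates)
  expect_equal(
    rep$n_retained,
    rep$n_input - rep$n_excluded_coords - rep$n_excluded_status -
      rep$n_excluded_duplicate
  )
  # JSON sidecar round-trips the counts
  path <- tempfile(fileext = ".json")
  write_cleaning_report(rep, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$n_retained, rep$n_retained)
})

test_that("live-filter and deduplication commute on the retained set", {
  scn <- tiny_scenario(seed = 8)
  scn$duplicate_fraction <- 0.15
  study <- simulate_study(scn)
  rec <- validate_sightings(study$records, study$window)
  rec <- rec[rec$flag == "ok", ]
  a <- deduplicate(filter_live(rec)$records)$records
  b <- filter_live(deduplicate(rec)$records)$records
  expect_setequal(a$id, b$id)
})

test_that("attribute summaries use the stated denominators", {
  rec <- tibble::tibble(
    id = sprintf("K%d", 1:4),
    date = as.Date("2001-01-01") + 0:3,
    x = 1:4, y = 1:4,
    sex = c("male", "female", "unknown", "unknown"),
    age_class = c("adult", "adult", "subadult", "unknown"),
    physical_location = c("tree", "tree", "ground", "unknown"),
    status = "alive_sighting"
  )
  s <- summarize_attributes(rec)
  male <- s[s$variable == "sex" & s$level == "male", ]
  expect_equal(male$prop, 0.5) # over sexed records
  expect_equal(male$denominator, "sexed")
  unk <- s[s$variable == "sex" & s$level == "unknown", ]
  expect_equal(unk$prop, 0.5) # 2 of 4, over all records
  tree <- s[s$variable == "physical_location" & s$level == "tree", ]
  expect_equal(tree$prop, 0.5)

  # summaries are invariant to row order
  s2 <- summarize_attributes(rec[4:1, ])
  expect_equal(
    dplyr::arrange(s, variable, level),
    dplyr::arrange(s2, variable, level)
  )
})

test_that("reporter statistics aggregate per year and match a recount", {
  rec <- tibble::tibble(
    id = sprintf("K%d", 1:13),
    date = as.Date(c(rep("2001-06-01", 3), rep("2002-06-01", 2), rep("2003-06-01", 8))),
    x = 1, y = 1, sex = "unknown", age_class = "adult",
    physical_location = "tree", status = "alive_sighting",
    reporter_id = c(
      rep("A", 3), # 2001: 1 reporter, 3 sightings
      "B", "C", # 2002: 2 reporters, 1 each
      rep(c("D", "E", "F", "G"), 2) # 2003: 4 reporters, 8 sightings
    )
  )
  rs <- reporter_stats(rec)
  expect_equal(rs$per_year$n_reporters, c(1, 2, 4))
  expect_equal(rs$per_year$sightings_per_reporter, c(3, 1, 2))
  expect_equal(rs$n_missing_reporter, 0)

  # brute-force group-by recount on synthetic records
  scn <- tiny_scenario(seed = 4)
  study <- simulate_study(scn)
  rec2 <- study$records
  rs2 <- reporter_stats(rec2)
  brute <- tapply(rec2$reporter_id, format(rec2$date, "%Y"), function(v) length(unique(v)))
  expect_equal(rs2$per_year$n_reporters, unname(as.vector(brute)))
})
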