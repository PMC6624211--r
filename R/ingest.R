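# Record ingest and cleaning: read/validate sighting tables, apply the
# study's inclusion rules (live sightings only, same-day same-location
# duplicates removed), and compute attribute and reporter summaries.

sighting_columns <- c(
  "id", "date", "x", "y", "sex", "age_class", "physical_location", "status"
)

#' Read a sighting-record CSV
#'
#' Parses a sighting table with the documented header and validates dates
#' and coordinates against the study window. Defective rows are flagged
#' (column `flag`: `"ok"`, `"bad_date"` or `"bad_coords"`), never silently
#' dropped; [clean_sightings()] counts and removes them.
#'
#' @param path CSV path with header
#'   `id,date,x,y,sex,age_class,physical_location,status[,reporter_id]`.
#' @param window A [make_window()] object for coordinate validation.
#' @return Tibble of records with a `flag` column.
#' @export
read_sightings <- function(path, window) {
  check_window(window)
  # column presence is validated below, so readr's own missing-parser
  # warning is redundant noise
  rec <- suppressWarnings(readr::read_csv(path,
    col_types = readr::cols(
      id = readr::col_character(),
      date = readr::col_character(),
      x = readr::col_double(),
      y = readr::col_double(),
      .default = readr::col_character()
    )
  ))
  missing <- setdiff(sighting_columns, names(rec))
  if (length(missing) > 0) {
    abort(sprintf("Missing mandatory column(s): %s", paste(missing, collapse = ", ")))
  }
  validate_sightings(rec, window)
}

#' @rdname read_sightings
#' @param records In-memory record tibble (e.g. from [simulate_records()]).
#' @export
validate_sightings <- function(records, window) {
  check_window(window)
  date <- suppressWarnings(as.Date(as.character(records$date)))
  ok_coords <- !is.na(records$x) & !is.na(records$y) &
    in_window(window, records$x, records$y)
  records$date <- date
  records$flag <- dplyr::case_when(
    is.na(date) ~ "bad_date",
    !ok_coords ~ "bad_coords",
    TRUE ~ "ok"
  )
  records
}

#' Keep live sightings only
#'
#' The study's definition of a sighting is a live koala seen by a member of
#' the public; records of injured, dead or euthanized koalas are excluded.
#'
#' @param records Record tibble with a `status` column.
#' @return A list: `records` (rows with `status == "alive_sighting"`) and
#'   `excluded` (tibble of counts by excluded status).
#' @export
filter_live <- function(records) {
  keep <- records$status == "alive_sighting"
  excluded <- records[!keep, ] |>
    dplyr::count(.data$status, name = "n")
  list(records = records[keep, ], excluded = excluded)
}

#' Remove same-location same-day repeat reports
#'
#' Among records sharing an identical (x, y, date) — coordinates compared
#' after rounding to `precision_km` — exactly one is retained: the
#' lexicographically smallest id, a deterministic, auditable tie-break.
#' Records at the same location on different days are all kept. Rows with a
#' `TRUE` `multi_animal` flag (several animals genuinely reported at one
#' spot) are exempt when that column is present.
#'
#' @param records Record tibble with valid `x`, `y`, `date`.
#' @param precision_km Coordinate rounding used to define "same location"
#'   (default 0.001 km = 1 m).
#' @return A list: `records` (deduplicated) and `n_excluded`.
#' @export
deduplicate <- function(records, precision_km = 0.001) {
  if (nrow(records) == 0) {
    return(list(records = records, n_excluded = 0L))
  }
  exempt <- if ("multi_animal" %in% names(records)) {
    isTRUE_vec <- records$multi_animal %in% TRUE
    isTRUE_vec
  } else {
    rep(FALSE, nrow(records))
  }
  key <- paste(
    round(records$x / precision_km), round(records$y / precision_km),
    as.character(records$date)
  )
  ord <- order(key, records$id)
  dup <- duplicated(key[ord]) & !exempt[ord]
  keep_rows <- sort(ord[!dup])
  list(
    records = records[keep_rows, ],
    n_excluded = as.integer(sum(dup))
  )
}

#' Full cleaning pass with a reconciled report
#'
#' Applies coordinate/date validation, the live-sighting filter and
#' same-day same-location deduplication, and returns the retained records
#' with a `cleaning_report` whose counts reconcile exactly to the input
#' size.
#'
#' @param records Record tibble (raw, e.g. from [read_sightings()] or
#'   [simulate_records()]).
#' @param window A [make_window()] object.
#' @param precision_km Deduplication precision, see [deduplicate()].
#' @return List with `records` and `report` (class `cleaning_report`).
#' @export
clean_sightings <- function(records, window, precision_km = 0.001) {
  n_input <- nrow(records)
  rec <- validate_sightings(records, window)
  bad <- rec$flag != "ok"
  n_coords <- sum(bad)
  rec <- rec[!bad, ]
  fl <- filter_live(rec)
  n_status <- nrow(rec) - nrow(fl$records)
  dd <- deduplicate(fl$records, precision_km)
  report <- structure(
    list(
      n_input = n_input,
      n_excluded_coords = as.integer(n_coords),
      n_excluded_status = as.integer(n_status),
      n_excluded_duplicate = dd$n_excluded,
      n_retained = nrow(dd$records),
      excluded_by_status = fl$excluded
    ),
    class = "cleaning_report"
  )
  list(records = dd$records, report = report)
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<cleaning_report>\n  input: %d\n  excluded bad coords/date: %d\n",
      "  excluded non-live status: %d\n  excluded duplicates: %d\n  retained: %d\n"
    ),
    x$n_input, x$n_excluded_coords, x$n_excluded_status,
    x$n_excluded_duplicate, x$n_retained
  ))
  invisible(x)
}

#' Write a cleaning report as a JSON sidecar
#' @param report A `cleaning_report`.
#' @param path Output path.
#' @export
write_cleaning_report <- function(report, path) {
  jsonlite::write_json(
    report[c(
      "n_input", "n_excluded_coords", "n_excluded_status",
      "n_excluded_duplicate", "n_retained"
    )],
    path,
    auto_unbox = TRUE
  )
  invisible(path)
}

#' Attribute composition of cleaned sightings
#'
#' Counts and proportions per level of sex, age class and physical location.
#' Age and location shares use all records as the denominator; the
#' male/female split is reported over sexed records only (the convention
#' used when stating "out of the sexed koalas"), while the unknown-sex share
#' is over all records.
#'
#' @param records Cleaned record tibble.
#' @return Tibble with columns `variable`, `level`, `n`, `prop`,
#'   `denominator`.
#' @export
summarize_attributes <- function(records) {
  n_all <- nrow(records)
  one <- function(var) {
    records |>
      dplyr::count(level = .data[[var]], name = "n") |>
      dplyr::mutate(variable = var, .before = 1)
  }
  out <- dplyr::bind_rows(one("sex"), one("age_class"), one("physical_location"))
  n_sexed <- sum(out$n[out$variable == "sex" & out$level %in% c("male", "female")])
  out |>
    dplyr::mutate(
      denominator = dplyr::if_else(
        .data$variable == "sex" & .data$level %in% c("male", "female"),
        "sexed", "all"
      ),
      prop = dplyr::case_when(
        n_all == 0 ~ NA_real_,
        denominator == "sexed" & n_sexed > 0 ~ .data$n / n_sexed,
        denominator == "sexed" ~ NA_real_,
        TRUE ~ .data$n / n_all
      )
    )
}

#' Reporter participation statistics
#'
#' Distinct reporters and mean sightings per reporter, per calendar year and
#' overall. Rows without a reporter id are excluded from the statistic and
#' counted.
#'
#' @param records Cleaned record tibble with `reporter_id` (possibly partial).
#' @return List with `per_year` (tibble `year`, `n_reporters`,
#'   `sightings_per_reporter`), `overall_mean_reporters`,
#'   `overall_mean_sightings_per_reporter`, `n_missing_reporter`.
#' @export
reporter_stats <- function(records) {
  has_rep <- "reporter_id" %in% names(records)
  miss <- if (has_rep) sum(is.na(records$reporter_id)) else nrow(records)
  rec <- if (has_rep) records[!is.na(records$reporter_id), ] else records[0, ]
  per_year <- rec |>
    dplyr::mutate(year = as.integer(format(.data$date, "%Y"))) |>
    dplyr::group_by(.data$year) |>
    dplyr::summarise(
      n_reporters = dplyr::n_distinct(.data$reporter_id),
      sightings_per_reporter = dplyr::n() / dplyr::n_distinct(.data$reporter_id)
    ) |>
    dplyr::ungroup()
  list(
    per_year = per_year,
    overall_mean_reporters = mean(per_year$n_reporters),
    overall_mean_sightings_per_reporter = mean(per_year$sightings_per_reporter),
    n_missing_reporter = as.integer(miss)
  )
}
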