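#' Write an EHR dataset to a directory of delimited text files
#'
#' Writes the five tables as comma-delimited UTF-8 files with ISO-8601
#' dates (`practices.csv`, `patients.csv`, `episodes.csv`,
#' `care_events.csv`, `prescriptions.csv`).  Missing closing dates and
#' episode links are written as empty fields.  The written files
#' round-trip losslessly through [read_ehr_dataset()].
#'
#' @param dataset An [ehr_dataset()].
#' @param directory Output directory (created if absent).
#' @return Invisibly, a manifest tibble (`file`, `rows`).
#' @export
write_ehr_dataset <- function(dataset, directory) {
  stopifnot(inherits(dataset, "ehr_dataset"))
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(sprintf("I/O error: cannot create directory '%s'.",
                           directory))
  }
  tables <- c("practices", "patients", "episodes", "care_events",
              "prescriptions")
  files <- file.path(directory, paste0(tables, ".csv"))
  for (i in seq_along(tables)) {
    readr::write_csv(dataset[[tables[i]]], files[i], na = "")
  }
  invisible(tibble(
    file = files,
    rows = vapply(tables, function(t) nrow(dataset[[t]]), integer(1))
  ))
}

ehr_col_types <- list(
  practices = readr::cols(
    practice_id = readr::col_character(),
    year = readr::col_integer(),
    listed_patients = readr::col_integer(),
    registration_weeks = readr::col_double(),
    coded_fraction = readr::col_double()
  ),
  patients = readr::cols(
    patient_id = readr::col_character(),
    practice_id = readr::col_character(),
    sex = readr::col_character(),
    birth_year = readr::col_integer(),
    birth_quarter = readr::col_integer(),
    reg_start = readr::col_character(),
    reg_end = readr::col_character()
  ),
  episodes = readr::cols(
    episode_id = readr::col_character(),
    patient_id = readr::col_character(),
    icpc = readr::col_character(),
    start_date = readr::col_character(),
    end_date = readr::col_character()
  ),
  care_events = readr::cols(
    event_id = readr::col_character(),
    patient_id = readr::col_character(),
    episode_id = readr::col_character(),
    date = readr::col_character(),
    type = readr::col_character()
  ),
  prescriptions = readr::cols(
    rx_id = readr::col_character(),
    patient_id = readr::col_character(),
    atc = readr::col_character(),
    date = readr::col_character(),
    episode_id = readr::col_character()
  )
)

date_columns <- list(
  patients = c("reg_start", "reg_end"),
  episodes = c("start_date", "end_date"),
  care_events = "date",
  prescriptions = "date"
)

# strict ISO-8601 date parsing with row-numbered errors; NA allowed only
# where `allow_na`
parse_date_column <- function(x, table, column, allow_na = FALSE) {
  blank <- is.na(x) | x == ""
  parsed <- as.Date(rep(NA_real_, length(x)), origin = "1970-01-01")
  iso <- grepl("^\\d{4}-\\d{2}-\\d{2}$", x[!blank])
  val <- as.Date(x[!blank], format = "%Y-%m-%d")
  bad <- !iso | is.na(val)
  if (any(bad)) {
    row <- which(!blank)[which(bad)[1]]
    abort(sprintf("parse error: %s.csv row %d: invalid date '%s' in %s.",
                  table, row, x[!blank][which(bad)[1]], column))
  }
  if (!allow_na && any(blank)) {
    abort(sprintf("parse error: %s.csv row %d: missing date in %s.",
                  table, which(blank)[1], column))
  }
  parsed[!blank] <- val
  parsed
}

#' Read an EHR dataset from a directory of delimited text files
#'
#' Reads the five tables written by [write_ehr_dataset()], parses ISO-8601
#' dates strictly (reporting the offending row on failure), validates
#' care-event types, and verifies referential integrity.
#'
#' @param directory Directory containing the five CSV files.
#' @param window Length-2 `Date` study window the records must fall in.
#' @return A validated [ehr_dataset()].
#' @export
read_ehr_dataset <- function(directory,
                             window = as.Date(c("2002-01-01",
                                                "2014-12-31"))) {
  tables <- names(ehr_col_types)
  out <- list()
  for (t in tables) {
    f <- file.path(directory, paste0(t, ".csv"))
    if (!file.exists(f)) {
      abort(sprintf("missing-input error: required file '%s' not found.", f))
    }
    x <- readr::read_csv(f, col_types = ehr_col_types[[t]],
                         na = c("", "NA"), progress = FALSE)
    attr(x, "spec") <- NULL
    attr(x, "problems") <- NULL
    class(x) <- c("tbl_df", "tbl", "data.frame")
    out[[t]] <- x
  }
  for (t in names(date_columns)) {
    for (col in date_columns[[t]]) {
      allow_na <- col %in% c("end_date")
      out[[t]][[col]] <- parse_date_column(out[[t]][[col]], t, col, allow_na)
    }
  }
  if (nrow(out$care_events)) {
    bad <- !(out$care_events$type %in% event_types)
    if (any(bad)) {
      abort(sprintf(
        "parse error: care_events.csv row %d: unknown event type '%s'.",
        which(bad)[1], out$care_events$type[which(bad)[1]]))
    }
  }
  ehr_dataset(out$practices, out$patients, out$episodes, out$care_events,
              out$prescriptions, window)
}
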