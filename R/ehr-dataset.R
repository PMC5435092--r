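#' EHR dataset container
#'
#' An `ehr_dataset` bundles the five relational tables of a coded
#' primary-care registry extract together with the study window:
#'
#' * `practices`: per practice-year quality metrics (`practice_id`, `year`,
#'   `listed_patients`, `registration_weeks`, `coded_fraction`);
#' * `patients`: `patient_id`, `practice_id`, `sex`, `birth_year`,
#'   `birth_quarter`, registration interval `reg_start`/`reg_end`;
#' * `episodes`: ICPC-coded episodes of care (`episode_id`, `patient_id`,
#'   `icpc`, `start_date`, `end_date` -- `NA` when never closed);
#' * `care_events`: contacts (`event_id`, `patient_id`, `episode_id`
#'   possibly `NA`, `date`, `type` one of consultation, home visit,
#'   telephone, prescription);
#' * `prescriptions`: ATC-coded dispensings (`rx_id`, `patient_id`, `atc`,
#'   `date`, `episode_id` possibly `NA`).
#'
#' Prescriptions appear both as `prescriptions` rows and as care events of
#' type `"prescription"`: they are one observation viewed once as drug
#' evidence and once as a contact.
#'
#' @param practices,patients,episodes,care_events,prescriptions Tibbles
#'   with the columns above.
#' @param window Length-2 `Date` study window.
#' @return An `ehr_dataset` object.
#' @seealso [simulate_ehr()], [read_ehr_dataset()], [validate_ehr_dataset()]
#' @export
ehr_dataset <- function(practices, patients, episodes, care_events,
                        prescriptions, window) {
  x <- structure(
    list(
      practices = as_tibble(practices),
      patients = as_tibble(patients),
      episodes = as_tibble(episodes),
      care_events = as_tibble(care_events),
      prescriptions = as_tibble(prescriptions),
      window = as.Date(window)
    ),
    class = "ehr_dataset"
  )
  validate_ehr_dataset(x)
  x
}

event_types <- c("consultation", "home visit", "telephone", "prescription")

empty_ehr_tables <- function() {
  list(
    practices = tibble(practice_id = character(), year = integer(),
                       listed_patients = integer(),
                       registration_weeks = double(),
                       coded_fraction = double()),
    patients = tibble(patient_id = character(), practice_id = character(),
                      sex = character(), birth_year = integer(),
                      birth_quarter = integer(),
                      reg_start = as.Date(character()),
                      reg_end = as.Date(character())),
    episodes = tibble(episode_id = character(), patient_id = character(),
                      icpc = character(),
                      start_date = as.Date(character()),
                      end_date = as.Date(character())),
    care_events = tibble(event_id = character(), patient_id = character(),
                         episode_id = character(),
                         date = as.Date(character()), type = character()),
    prescriptions = tibble(rx_id = character(), patient_id = character(),
                           atc = character(), date = as.Date(character()),
                           episode_id = character())
  )
}

#' Validate an EHR dataset's referential and temporal integrity
#'
#' Checks that every foreign key resolves (patient to practice, event and
#' prescription to patient, episode links to episodes), that record dates
#' lie inside the study window, that episode start dates do not exceed
#' closing dates, that event types and ATC codes are well formed, and that
#' registration intervals are ordered.
#'
#' @param x An [ehr_dataset()].
#' @return `x`, invisibly; aborts with an integrity error otherwise.
#' @export
validate_ehr_dataset <- function(x) {
  stopifnot(inherits(x, "ehr_dataset"))
  ws <- x$window[1]; we <- x$window[2]
  p <- x$patients

  if (!all(p$practice_id %in% x$practices$practice_id)) {
    abort("integrity error: patient references an unknown practice.")
  }
  if (anyDuplicated(p$patient_id)) {
    abort("integrity error: duplicate patient ids.")
  }
  if (any(p$reg_start > p$reg_end)) {
    abort("integrity error: reg_start after reg_end.")
  }
  if (nrow(p) && !all(p$birth_quarter %in% 1:4)) {
    abort("integrity error: birth_quarter outside 1-4.")
  }
  for (tb in c("episodes", "care_events", "prescriptions")) {
    if (!all(x[[tb]]$patient_id %in% p$patient_id)) {
      abort(sprintf("integrity error: %s reference an unknown patient.", tb))
    }
  }
  ep <- x$episodes
  if (nrow(ep)) {
    if (any(ep$start_date < ws | ep$start_date > we)) {
      abort("integrity error: episode start outside the study window.")
    }
    closed <- !is.na(ep$end_date)
    if (any(ep$start_date[closed] > ep$end_date[closed])) {
      abort("integrity error: episode start after closing date.")
    }
  }
  for (tb in c("care_events", "prescriptions")) {
    t <- x[[tb]]
    if (nrow(t)) {
      if (any(t$date < ws | t$date > we)) {
        abort(sprintf("integrity error: %s date outside the study window.", tb))
      }
      linked <- !is.na(t$episode_id)
      if (!all(t$episode_id[linked] %in% ep$episode_id)) {
        abort(sprintf("integrity error: %s reference an unknown episode.", tb))
      }
    }
  }
  if (nrow(x$care_events) && !all(x$care_events$type %in% event_types)) {
    abort("integrity error: unknown care-event type.")
  }
  if (nrow(x$prescriptions) && !all(is_valid_atc(x$prescriptions$atc))) {
    abort("integrity error: malformed ATC code in prescriptions.")
  }
  invisible(x)
}

#' @export
print.ehr_dataset <- function(x, ...) {
  cat("<ehr_dataset>\n")
  cat(sprintf("  window: %s .. %s\n", format(x$window[1]), format(x$window[2])))
  for (tb in c("practices", "patients", "episodes", "care_events",
               "prescriptions")) {
    cat(sprintf("  %-13s %8d rows\n", tb, nrow(x[[tb]])))
  }
  invisible(x)
}
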