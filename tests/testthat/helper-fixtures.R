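# hand-built fixture constructors for small, fully controlled datasets

withr_local_tempdir <- function(env = parent.frame()) {
  dir <- tempfile("atopia-test-")
  dir.create(dir)
  withr::defer(unlink(dir, recursive = TRUE), envir = env)
  dir
}

study_window <- as.Date(c("2002-01-01", "2014-12-31"))

good_practice_years <- function(practice_id, years = 2002:2014,
                                listed = 2350L, weeks = 52, coded = 0.95) {
  tibble::tibble(
    practice_id = practice_id,
    year = as.integer(years),
    listed_patients = as.integer(listed),
    registration_weeks = weeks,
    coded_fraction = coded
  )
}

tpat <- function(patient_id, birth_year = 2003L, birth_quarter = 1L,
                 reg_start = "2003-02-15", reg_end = "2014-12-31",
                 practice_id = "PR001", sex = "F") {
  tibble::tibble(
    patient_id = patient_id, practice_id = practice_id, sex = sex,
    birth_year = as.integer(birth_year),
    birth_quarter = as.integer(birth_quarter),
    reg_start = as.Date(reg_start), reg_end = as.Date(reg_end)
  )
}

tep <- function(episode_id, patient_id, icpc = "S87", start,
                end = NA_character_) {
  tibble::tibble(
    episode_id = episode_id, patient_id = patient_id, icpc = icpc,
    start_date = as.Date(start),
    end_date = as.Date(end)
  )
}

tev <- function(event_id, patient_id, episode_id = NA_character_, date,
                type = "consultation") {
  tibble::tibble(event_id = event_id, patient_id = patient_id,
                 episode_id = episode_id, date = as.Date(date), type = type)
}

trx <- function(rx_id, patient_id, atc, date, episode_id = NA_character_) {
  tibble::tibble(rx_id = rx_id, patient_id = patient_id, atc = atc,
                 date = as.Date(date), episode_id = episode_id)
}

empty_of <- function(proto) proto[0, ]

make_dataset <- function(patients, episodes = NULL, care_events = NULL,
                         prescriptions = NULL, practices = NULL,
                         window = study_window) {
  if (is.null(episodes)) episodes <- empty_of(tep("x", "y", start = "2005-01-01"))
  if (is.null(care_events)) care_events <- empty_of(tev("x", "y", date = "2005-01-01"))
  if (is.null(prescriptions)) prescriptions <- empty_of(trx("x", "y", "D07AC01", "2005-01-01"))
  if (is.null(practices)) {
    ids <- unique(patients$practice_id)
    practices <- dplyr::bind_rows(lapply(ids, good_practice_years))
  }
  atopia::ehr_dataset(practices, patients, episodes, care_events,
                      prescriptions, window)
}

# cohort built directly from follow-up intervals, bypassing the filter
cohort_of <- function(patient_id, birth_year = 2000L, birth_quarter = 1L,
                      fu_start = as.Date("2002-01-01"),
                      fu_end = as.Date("2014-12-31")) {
  birth <- atopia:::mid_quarter_date(birth_year, birth_quarter)
  pt <- tibble::tibble(
    patient_id = patient_id, practice_id = "PR001", sex = "F",
    birth_year = as.integer(birth_year),
    birth_quarter = as.integer(birth_quarter),
    birth_imputed = birth,
    fu_start = as.Date(fu_start), fu_end = as.Date(fu_end),
    followup_days = as.numeric(as.Date(fu_end) - as.Date(fu_start))
  )
  cohort_selection(nrow(pt), 0L, 0L, patients = pt)
}

# validated-episode rows built by hand
vrow <- function(patient_id, disorder, strategy, start, end,
                 first_diagnosis = start, n_contacts = 2L,
                 n_relevant_rx = 2L) {
  tibble::tibble(
    patient_id = patient_id, disorder = disorder,
    strategy = as.integer(strategy),
    effective_start = as.Date(start), effective_end = as.Date(end),
    first_diagnosis = as.Date(first_diagnosis),
    n_contacts = as.integer(n_contacts),
    n_relevant_rx = as.integer(n_relevant_rx)
  )
}
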