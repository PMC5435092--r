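#' Assess a practice-year against the data-quality criteria
#'
#' A practice-year passes when it has at least `min_listed` listed
#' patients, complete morbidity registration (at least `min_weeks`
#' weeks/year) and sufficient ICPC coding of diagnostic information (at
#' least `min_coded` of recorded disease episodes labelled).  All
#' thresholds are inclusive.
#'
#' @param listed_patients,registration_weeks,coded_fraction Practice-year
#'   metrics (vectorised).
#' @param min_listed,min_weeks,min_coded Inclusive thresholds; defaults
#'   500 patients, 46 weeks/year, 0.70 coded.
#' @return A tibble with columns `pass` (logical) and `reasons`
#'   (list-column of character vectors naming every violated criterion:
#'   `"patient-count"`, `"registration-weeks"`, `"coding-fraction"`).
#' @examples
#' assess_practice_year(500, 46, 0.70)   # pass
#' assess_practice_year(499, 52, 0.95)   # fail: patient-count
#' @export
assess_practice_year <- function(listed_patients, registration_weeks,
                                 coded_fraction, min_listed = 500,
                                 min_weeks = 46, min_coded = 0.70) {
  if (any(registration_weeks < 0 | registration_weeks > 53)) {
    abort("registration_weeks must lie in [0, 53].")
  }
  if (any(coded_fraction < 0 | coded_fraction > 1)) {
    abort("coded_fraction must lie in [0, 1].")
  }
  n <- max(length(listed_patients), length(registration_weeks),
           length(coded_fraction))
  lp <- rep_len(listed_patients, n)
  rw <- rep_len(registration_weeks, n)
  cf <- rep_len(coded_fraction, n)
  ok_lp <- lp >= min_listed
  ok_rw <- rw >= min_weeks
  ok_cf <- cf >= min_coded
  reasons <- lapply(seq_len(n), function(i) {
    c(if (!ok_lp[i]) "patient-count",
      if (!ok_rw[i]) "registration-weeks",
      if (!ok_cf[i]) "coding-fraction")
  })
  tibble(pass = ok_lp & ok_rw & ok_cf, reasons = reasons)
}

#' Select the analysis cohort of children
#'
#' Applies the child-level eligibility rules with quality-first exclusion
#' precedence.  A child is:
#'
#' 1. *eligible* when its registration interval overlaps the study window
#'    and it is aged 0--18 years for some part of that overlap (ages from
#'    the mid-quarter imputed birth date, see [age_on()]);
#' 2. *excluded on quality* when its practice offers no passing
#'    practice-year over the child's observed years (with
#'    `strict_quality = TRUE`, when any overlapping practice-year fails);
#' 3. *excluded on follow-up* when the observed follow-up
#'    `min(reg_end, window end) - max(reg_start, window start)` is below
#'    `min_followup_days` (default 1095 days, i.e. 3 years).
#'
#' A child failing both is counted once, under quality, so the exclusion
#' counts sum exactly to eligible minus included.
#'
#' @param dataset An [ehr_dataset()].
#' @param window Length-2 `Date`; defaults to the dataset's window.
#' @param min_followup_days Minimum observed follow-up, in days.
#' @param strict_quality If `TRUE`, any failing overlapping practice-year
#'   excludes the child; default requires all overlapping years to fail.
#' @param min_listed,min_weeks,min_coded Practice-year quality thresholds,
#'   see [assess_practice_year()].
#' @return A `cohort_selection`; see [cohort_selection()].
#' @export
select_children <- function(dataset, window = dataset$window,
                            min_followup_days = 1095,
                            strict_quality = FALSE,
                            min_listed = 500, min_weeks = 46,
                            min_coded = 0.70) {
  stopifnot(inherits(dataset, "ehr_dataset"))
  window <- as.Date(window)
  ws <- window[1]; we <- window[2]
  p <- dataset$patients
  if (!all(p$practice_id %in% dataset$practices$practice_id)) {
    abort("referential-integrity error: child listed in an unknown practice.")
  }
  if (nrow(p) == 0) {
    return(cohort_selection(0L, 0L, 0L, patients = cohort_patient_columns(p)))
  }

  birth <- mid_quarter_date(p$birth_year, p$birth_quarter)
  fu_start <- pmax(p$reg_start, ws)
  fu_end <- pmin(p$reg_end, we)
  age_at_start <- age_completed_years(fu_start, birth)
  eligible <- fu_start <= fu_end & birth <= fu_end & age_at_start <= 18

  pt <- tibble(
    patient_id = p$patient_id, practice_id = p$practice_id, sex = p$sex,
    birth_year = p$birth_year, birth_quarter = p$birth_quarter,
    birth_imputed = birth, fu_start = fu_start, fu_end = fu_end,
    followup_days = as.numeric(fu_end - fu_start)
  )[eligible, ]

  # practice-year quality over each child's observed calendar years
  py <- dataset$practices
  py$pass <- assess_practice_year(py$listed_patients, py$registration_weeks,
                                  py$coded_fraction, min_listed, min_weeks,
                                  min_coded)$pass
  y0 <- year_of(pt$fu_start); y1 <- year_of(pt$fu_end)
  nyr <- y1 - y0 + 1L
  expand <- tibble(
    patient_id = rep(pt$patient_id, nyr),
    practice_id = rep(pt$practice_id, nyr),
    year = if (nrow(pt)) {
      unlist(lapply(seq_len(nrow(pt)),
                    function(i) seq.int(y0[i], y1[i])), use.names = FALSE)
    } else integer(0)
  )
  expand <- left_join(expand, py[, c("practice_id", "year", "pass")],
                      by = c("practice_id", "year"))
  expand$pass[is.na(expand$pass)] <- FALSE  # missing practice-year = failing
  qual <- expand %>%
    group_by(.data$patient_id) %>%
    summarise(any_pass = any(.data$pass), all_pass = all(.data$pass),
              .groups = "drop")
  pt <- left_join(pt, qual, by = "patient_id")
  quality_ok <- if (strict_quality) pt$all_pass else pt$any_pass

  followup_ok <- pt$followup_days >= min_followup_days

  excluded_quality <- pt$patient_id[!quality_ok]
  excluded_followup <- pt$patient_id[quality_ok & !followup_ok]
  included <- pt[quality_ok & followup_ok,
                 setdiff(names(pt), c("any_pass", "all_pass"))]

  cohort_selection(
    eligible_count = nrow(pt),
    excluded_quality_count = length(excluded_quality),
    excluded_followup_count = length(excluded_followup),
    patients = included,
    excluded_quality_ids = excluded_quality,
    excluded_followup_ids = excluded_followup
  )
}

cohort_patient_columns <- function(p) {
  tibble(patient_id = character(), practice_id = character(),
         sex = character(), birth_year = integer(),
         birth_quarter = integer(),
         birth_imputed = as.Date(character()),
         fu_start = as.Date(character()), fu_end = as.Date(character()),
         followup_days = double())
}

#' Cohort selection result
#'
#' Holds the attrition counts of the cohort selection and (optionally) the
#' included patients with their observed follow-up intervals.  The counts
#' satisfy `final = eligible - excluded_quality - excluded_followup`.
#'
#' @param eligible_count,excluded_quality_count,excluded_followup_count
#'   Attrition counts.
#' @param patients Optional tibble of included children (as produced by
#'   [select_children()]).
#' @param excluded_quality_ids,excluded_followup_ids Optional id vectors.
#' @return A `cohort_selection` object.
#' @examples
#' cohort_selection(660512, 24477, 157959)
#' @export
cohort_selection <- function(eligible_count, excluded_quality_count,
                             excluded_followup_count, patients = NULL,
                             excluded_quality_ids = NULL,
                             excluded_followup_ids = NULL) {
  counts <- c(eligible_count, excluded_quality_count, excluded_followup_count)
  if (any(counts < 0)) abort("cohort counts must be non-negative.")
  final <- eligible_count - excluded_quality_count - excluded_followup_count
  if (final < 0) abort("exclusions exceed the eligible count.")
  if (!is.null(patients) && nrow(patients) != final) {
    abort("included patient table is inconsistent with the counts.")
  }
  structure(
    list(
      eligible_count = as.integer(eligible_count),
      excluded_quality_count = as.integer(excluded_quality_count),
      excluded_followup_count = as.integer(excluded_followup_count),
      final_count = as.integer(final),
      patients = patients,
      excluded_quality_ids = excluded_quality_ids,
      excluded_followup_ids = excluded_followup_ids
    ),
    class = "cohort_selection"
  )
}

#' Included children of a cohort selection
#'
#' @param selection A [cohort_selection()].
#' @return Tibble of included children with imputed birth dates and
#'   observed follow-up intervals.
#' @export
cohort_patients <- function(selection) {
  stopifnot(inherits(selection, "cohort_selection"))
  if (is.null(selection$patients)) {
    abort("this selection carries counts only, no patient table.")
  }
  selection$patients
}

#' @export
print.cohort_selection <- function(x, ...) {
  cat("<cohort_selection>\n")
  cat(sprintf("  eligible:            %9d\n", x$eligible_count))
  cat(sprintf("  excluded (quality):  %9d\n", x$excluded_quality_count))
  cat(sprintf("  excluded (follow-up):%9d\n", x$excluded_followup_count))
  cat(sprintf("  included:            %9d\n", x$final_count))
  invisible(x)
}

#' Attrition table for a cohort selection
#'
#' Percentages are computed against the eligible count and rounded to one
#' decimal.
#'
#' @param selection A [cohort_selection()].
#' @return Tibble with columns `category`, `n`, `pct`.
#' @examples
#' attrition_report(cohort_selection(660512, 24477, 157959))
#' @export
attrition_report <- function(selection) {
  stopifnot(inherits(selection, "cohort_selection"))
  if (selection$eligible_count == 0) {
    abort("empty-cohort error: no eligible children.")
  }
  n <- c(selection$eligible_count, selection$excluded_quality_count,
         selection$excluded_followup_count, selection$final_count)
  tibble(
    category = c("eligible", "excluded_quality", "excluded_followup",
                 "included"),
    n = as.integer(n),
    pct = round(100 * n / selection$eligible_count, 1)
  )
}
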