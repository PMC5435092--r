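#' Merge the recorded episodes of one disorder for one child
#'
#' Collapses all recorded episodes of care sharing one patient and one
#' ICPC code into a canonical per-disorder record: the first-diagnosis
#' date is the minimum start date (a child is incident only once in its
#' life), overlapping or abutting intervals are unioned, and all episode
#' ids are retained so no linked events are lost.  An episode with a
#' missing closing date is treated as open (its union absorbs everything
#' after its start); the resulting interval keeps an `NA` end until a
#' strategy imputes the follow-up end.
#'
#' @param episodes Tibble of episodes (`episode_id`, `patient_id`, `icpc`,
#'   `start_date`, `end_date`) for a single patient and ICPC code.
#' @return A `disorder_record` list: `patient_id`, `icpc`,
#'   `first_diagnosis`, `intervals` (tibble `start`, `end`; `end` `NA`
#'   when open), `episode_ids`.
#' @export
merge_disorder_episodes <- function(episodes) {
  if (nrow(episodes) == 0) {
    abort("invalid-input error: no episodes to merge.")
  }
  if (length(unique(episodes$patient_id)) != 1 ||
      length(unique(episodes$icpc)) != 1) {
    abort("invalid-input error: episodes mix patients or ICPC codes.")
  }
  ints <- merge_date_intervals(episodes$start_date, episodes$end_date)
  structure(
    list(
      patient_id = episodes$patient_id[1],
      icpc = episodes$icpc[1],
      first_diagnosis = min(episodes$start_date),
      intervals = ints,
      episode_ids = episodes$episode_id
    ),
    class = "disorder_record"
  )
}

# Union of closed date intervals; `end` NA means open-ended.  Intervals
# are merged when they overlap or abut (next start <= previous end + 1
# day).  Returns a tibble (start, end) with NA ends preserved.
merge_date_intervals <- function(start, end) {
  far <- as.numeric(as.Date("9999-12-31"))
  s <- as.numeric(start)
  e <- ifelse(is.na(end), far, as.numeric(end))
  e <- pmax(e, s)
  o <- order(s, e)
  s <- s[o]; e <- e[o]; open <- is.na(end)[o]
  run_max <- cummax(e)
  grp <- cumsum(c(TRUE, s[-1] > run_max[-length(run_max)] + 1))
  out_s <- as.vector(tapply(s, grp, min))
  out_e <- as.vector(tapply(e, grp, max))
  out_open <- as.vector(tapply(open, grp, any))
  tibble(
    start = as.Date(out_s, origin = "1970-01-01"),
    end = as.Date(ifelse(out_open, NA, out_e), origin = "1970-01-01")
  )
}

new_validated_episode <- function(record, strategy, intervals,
                                  n_contacts = NA_integer_,
                                  n_relevant_rx = NA_integer_,
                                  disorder = NA_character_) {
  structure(
    list(
      patient_id = record$patient_id,
      icpc = record$icpc,
      disorder = disorder,
      strategy = as.integer(strategy),
      first_diagnosis = record$first_diagnosis,
      intervals = intervals,
      effective_start = min(intervals$start),
      effective_end = if (anyNA(intervals$end)) as.Date(NA) else
        max(intervals$end),
      n_contacts = as.integer(n_contacts),
      n_relevant_rx = as.integer(n_relevant_rx),
      episode_ids = record$episode_ids
    ),
    class = "validated_episode"
  )
}

#' Strategy 1: accept the recorded episodes of care as they stand
#'
#' The identity strategy: intervals are kept exactly as recorded (missing
#' closing dates imputed to the end of follow-up when `followup_end` is
#' given), and no care-seeking evidence is enforced, accepting the risk of
#' overestimation from provisional diagnoses.
#'
#' @param record A `disorder_record` from [merge_disorder_episodes()].
#' @param followup_end Optional `Date`: end of the child's observed
#'   follow-up, used to close open intervals.
#' @return A `validated_episode` with `strategy = 1`, or `NULL` when the
#'   record has no intervals.
#' @export
apply_strategy1 <- function(record, followup_end = NULL) {
  stopifnot(inherits(record, "disorder_record"))
  ints <- record$intervals
  if (nrow(ints) == 0) return(NULL)
  if (!is.null(followup_end)) {
    ints$end <- as.Date(ifelse(is.na(ints$end), as.numeric(followup_end),
                               as.numeric(ints$end)), origin = "1970-01-01")
  }
  new_validated_episode(record, 1L, ints)
}

#' Strategy 2: validate an episode record by care-seeking evidence
#'
#' A per-disorder record is accepted when the child has at least two
#' episode-related contacts (consultations, home visits, telephone calls
#' or prescriptions linked to any episode of the record) *and* at least
#' two relevant prescriptions -- prescriptions anywhere in the child's
#' record whose ATC code starts with one of the disorder's prefixes, since
#' EHRs do not always link prescriptions into the correct episode.
#' Accepted records keep their recorded intervals; rejected children
#' remain in the population at risk.
#'
#' @param record A `disorder_record`.
#' @param events Tibble of the patient's care events (`episode_id`, `date`,
#'   `type`).
#' @param prescriptions Tibble of the patient's prescriptions (`atc`,
#'   `date`).
#' @param definition One row of [atopic_definitions()] (disorder, icpc,
#'   atc prefixes).
#' @param followup_end Optional `Date` used to close open intervals.
#' @param strict_contacts If `TRUE`, prescription-type events do not count
#'   toward the two-contact criterion.
#' @param rx_window_days Only prescriptions within this many days of a
#'   recorded interval count; default `Inf` searches the whole record.
#' @return A `validated_episode` with `strategy = 2`, or `NULL` on
#'   rejection.
#' @export
apply_strategy2 <- function(record, events, prescriptions, definition,
                            followup_end = NULL, strict_contacts = FALSE,
                            rx_window_days = Inf) {
  stopifnot(inherits(record, "disorder_record"))
  if (is.null(definition) || nrow(definition) != 1 ||
      record$icpc != definition$icpc) {
    abort("configuration error: definition does not match the record's ICPC code.")
  }
  if (nrow(record$intervals) == 0) return(NULL)
  ev <- events[!is.na(events$episode_id) &
                 events$episode_id %in% record$episode_ids, , drop = FALSE]
  if (strict_contacts) ev <- ev[ev$type != "prescription", , drop = FALSE]
  n_contacts <- nrow(ev)

  rx <- prescriptions[atc_matches(prescriptions$atc, definition$atc[[1]]), ,
                      drop = FALSE]
  if (is.finite(rx_window_days) && nrow(rx)) {
    ints <- record$intervals
    e <- ifelse(is.na(ints$end),
                as.numeric(followup_end %||% as.Date("9999-12-31")),
                as.numeric(ints$end))
    keep <- vapply(as.numeric(rx$date), function(d) {
      any(d >= as.numeric(ints$start) - rx_window_days &
            d <= e + rx_window_days)
    }, logical(1))
    rx <- rx[keep, , drop = FALSE]
  }
  n_rx <- nrow(rx)

  if (n_contacts < 2 || n_rx < 2) return(NULL)
  ints <- record$intervals
  if (!is.null(followup_end)) {
    ints$end <- as.Date(ifelse(is.na(ints$end), as.numeric(followup_end),
                               as.numeric(ints$end)), origin = "1970-01-01")
  }
  new_validated_episode(record, 2L, ints, n_contacts, n_rx,
                        disorder = definition$disorder)
}

#' Treat a validated episode as chronic (strategies 3 and 4)
#'
#' Extends the closing date to the end of the child's follow-up, so pooled
#' per-age rates become cumulative incidences (approximating lifetime
#' prevalence when the full history is observed).  Strategy 1 becomes 3,
#' strategy 2 becomes 4.  The effective start (first diagnosis) is
#' unchanged and the interval is never shortened.
#'
#' @param validated A `validated_episode` with strategy 1 or 2.
#' @param followup_end `Date`: end of the child's observed follow-up.
#' @return A `validated_episode` with strategy 3 or 4 and a single
#'   interval from the first diagnosis to `followup_end`.
#' @export
make_chronic <- function(validated, followup_end) {
  stopifnot(inherits(validated, "validated_episode"))
  if (!validated$strategy %in% c(1L, 2L)) {
    abort("make_chronic expects a strategy 1 or 2 episode.")
  }
  followup_end <- as.Date(followup_end)
  if (followup_end < validated$effective_start) {
    abort("date-order error: follow-up ends before the episode starts.")
  }
  out <- validated
  out$strategy <- validated$strategy + 2L
  out$intervals <- tibble(start = validated$effective_start,
                          end = followup_end)
  out$effective_end <- followup_end
  out
}

#' Build an atopic-triad episode for one child
#'
#' A triad episode exists only when the child has validated episodes of
#' all three atopic disorders under the same strategy.  Its start is the
#' first date the child was diagnosed with at least one of the disorders;
#' its closing date is the last contact date recorded for one of the
#' atopic disorders (pass `last_contact`), falling back to the latest
#' effective end of the inputs.
#'
#' @param validated_list List of `validated_episode`s of one child, one
#'   strategy.
#' @param last_contact Optional `Date`: last recorded contact for any of
#'   the atopic disorders.
#' @return A `validated_episode` with `disorder = "triad"`, or `NULL`
#'   when fewer than three disorders are present.
#' @export
build_triad <- function(validated_list, last_contact = NULL) {
  stopifnot(all(vapply(validated_list, inherits, logical(1),
                       "validated_episode")))
  if (length(validated_list) == 0) return(NULL)
  strategies <- unique(vapply(validated_list, `[[`, integer(1), "strategy"))
  patients <- unique(vapply(validated_list, `[[`, character(1), "patient_id"))
  if (length(strategies) != 1 || length(patients) != 1) {
    abort("invalid-input error: triad inputs mix strategies or children.")
  }
  icpcs <- unique(vapply(validated_list, `[[`, character(1), "icpc"))
  if (length(icpcs) < 3) return(NULL)
  starts <- as.Date(vapply(validated_list, function(v)
    as.numeric(v$first_diagnosis), numeric(1)), origin = "1970-01-01")
  ends <- as.Date(vapply(validated_list, function(v)
    as.numeric(v$effective_end), numeric(1)), origin = "1970-01-01")
  start <- min(starts)
  end <- if (!is.null(last_contact)) as.Date(last_contact) else max(ends)
  if (end < start) end <- start
  record <- list(patient_id = patients, icpc = "triad",
                 first_diagnosis = start, episode_ids = character(0))
  new_validated_episode(record, strategies, tibble(start = start, end = end),
                        disorder = "triad")
}
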