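#' Reconstruct validated episodes for a whole cohort
#'
#' Dataset-wide driver for the four strategies.  For every included child
#' and disorder it merges the recorded episodes ([merge_disorder_episodes()]),
#' counts the care-seeking evidence, and emits the effective intervals
#' under the requested strategies:
#'
#' * strategies 1 and 2 keep the recorded (merged) intervals, with missing
#'   closing dates imputed to the end of the child's observed follow-up;
#' * strategy 2 keeps only records with at least two episode-linked
#'   contacts and at least two relevant prescriptions anywhere in the
#'   child's record (ATC prefix match);
#' * strategies 3 and 4 extend the accepted records of strategies 1 and 2
#'   to a single chronic interval from the first diagnosis to the end of
#'   follow-up.
#'
#' @param dataset An [ehr_dataset()].
#' @param cohort A [cohort_selection()] from [select_children()].
#' @param strategies Integer subset of 1:4.
#' @param definitions Case definitions, see [atopic_definitions()].
#' @param strict_contacts If `TRUE`, prescription-type events do not count
#'   toward the two-contact criterion.
#' @param rx_window_days Only prescriptions within this many days of a
#'   recorded interval count as relevant; default `Inf` (whole record).
#' @return Tibble with one row per effective interval: `patient_id`,
#'   `disorder`, `strategy`, `effective_start`, `effective_end`,
#'   `first_diagnosis`, `n_contacts`, `n_relevant_rx`.
#' @export
validate_episodes <- function(dataset, cohort, strategies = 1:4,
                              definitions = atopic_definitions(),
                              strict_contacts = FALSE,
                              rx_window_days = Inf) {
  stopifnot(inherits(dataset, "ehr_dataset"))
  if (!all(strategies %in% 1:4)) {
    abort("configuration error: strategies must be a subset of 1:4.")
  }
  validate_definitions(definitions)
  ch <- cohort_patients(cohort)

  empty <- tibble(patient_id = character(), disorder = character(),
                  strategy = integer(),
                  effective_start = as.Date(character()),
                  effective_end = as.Date(character()),
                  first_diagnosis = as.Date(character()),
                  n_contacts = integer(), n_relevant_rx = integer())

  eps <- dataset$episodes %>%
    inner_join(definitions[, c("disorder", "icpc")], by = "icpc") %>%
    semi_join(ch, by = "patient_id") %>%
    left_join(ch[, c("patient_id", "fu_end")], by = "patient_id")
  if (nrow(eps) == 0) return(empty)

  # open (never closed) episodes run to the end of follow-up
  eps <- eps %>%
    mutate(end_imp = dplyr::coalesce(.data$end_date, .data$fu_end),
           end_imp = pmax(.data$end_imp, .data$start_date))

  # union of overlapping/abutting intervals per child and disorder
  merged <- eps %>%
    arrange(.data$patient_id, .data$disorder, .data$start_date,
            .data$end_imp) %>%
    group_by(.data$patient_id, .data$disorder) %>%
    mutate(grp = cumsum(as.numeric(.data$start_date) >
                          lag(cummax(as.numeric(.data$end_imp)),
                              default = -Inf) + 1)) %>%
    group_by(.data$patient_id, .data$disorder, .data$grp) %>%
    summarise(int_start = min(.data$start_date),
              int_end = max(.data$end_imp),
              fu_end = first(.data$fu_end), .groups = "drop_last") %>%
    mutate(first_diagnosis = min(.data$int_start)) %>%
    ungroup()

  # evidence: episode-linked contacts per child x disorder
  ev <- dataset$care_events %>% filter(!is.na(.data$episode_id))
  if (strict_contacts) ev <- ev %>% filter(.data$type != "prescription")
  contact_counts <- ev %>%
    inner_join(eps[, c("episode_id", "patient_id", "disorder")],
               by = c("episode_id", "patient_id")) %>%
    count(.data$patient_id, .data$disorder, name = "n_contacts")

  # evidence: relevant prescriptions anywhere in the child's record
  rx <- dataset$prescriptions %>% semi_join(ch, by = "patient_id")
  rx_counts <- lapply(seq_len(nrow(definitions)), function(i) {
    hit <- rx[atc_matches(rx$atc, definitions$atc[[i]]), , drop = FALSE]
    if (is.finite(rx_window_days) && nrow(hit)) {
      ints <- merged[merged$disorder == definitions$disorder[i], ]
      hit <- hit %>%
        inner_join(ints[, c("patient_id", "int_start", "int_end")],
                   by = "patient_id", relationship = "many-to-many") %>%
        filter(.data$date >= .data$int_start - rx_window_days,
               .data$date <= .data$int_end + rx_window_days) %>%
        distinct(.data$rx_id, .data$patient_id)
    }
    hit %>%
      count(.data$patient_id, name = "n_relevant_rx") %>%
      mutate(disorder = definitions$disorder[i])
  }) %>% dplyr::bind_rows()

  merged <- merged %>%
    left_join(contact_counts, by = c("patient_id", "disorder")) %>%
    left_join(rx_counts, by = c("patient_id", "disorder")) %>%
    mutate(n_contacts = dplyr::coalesce(.data$n_contacts, 0L),
           n_relevant_rx = dplyr::coalesce(.data$n_relevant_rx, 0L))

  accepted2 <- merged$n_contacts >= 2 & merged$n_relevant_rx >= 2

  out <- list()
  if (1 %in% strategies) {
    out$s1 <- merged %>%
      mutate(strategy = 1L, effective_start = .data$int_start,
             effective_end = .data$int_end)
  }
  if (2 %in% strategies) {
    out$s2 <- merged[accepted2, ] %>%
      mutate(strategy = 2L, effective_start = .data$int_start,
             effective_end = .data$int_end)
  }
  chronic <- merged %>%
    group_by(.data$patient_id, .data$disorder) %>%
    summarise(first_diagnosis = first(.data$first_diagnosis),
              fu_end = first(.data$fu_end),
              n_contacts = first(.data$n_contacts),
              n_relevant_rx = first(.data$n_relevant_rx),
              .groups = "drop") %>%
    mutate(effective_start = .data$first_diagnosis,
           effective_end = pmax(.data$fu_end, .data$first_diagnosis))
  if (3 %in% strategies) out$s3 <- chronic %>% mutate(strategy = 3L)
  if (4 %in% strategies) {
    ok <- merged[accepted2, c("patient_id", "disorder")] %>% distinct()
    out$s4 <- chronic %>% semi_join(ok, by = c("patient_id", "disorder")) %>%
      mutate(strategy = 4L)
  }

  dplyr::bind_rows(out) %>%
    select("patient_id", "disorder", "strategy", "effective_start",
           "effective_end", "first_diagnosis", "n_contacts",
           "n_relevant_rx") %>%
    arrange(.data$strategy, .data$disorder, .data$patient_id,
            .data$effective_start)
}

#' Append atopic-triad episodes to a validated-episode table
#'
#' For each strategy present, a child with validated episodes of all three
#' disorders receives a `"triad"` row starting at the earliest first
#' diagnosis across the three disorders.  Under strategies 1 and 2 the
#' triad closes at the last contact date recorded for any of the atopic
#' disorders; under strategies 3 and 4 it is chronic and runs to the end
#' of follow-up.
#'
#' @param validated Output of [validate_episodes()].
#' @param dataset The [ehr_dataset()] (for last atopic contact dates).
#' @param cohort The [cohort_selection()].
#' @param definitions Case definitions.
#' @return `validated` with `"triad"` rows appended.
#' @export
add_triads <- function(validated, dataset, cohort,
                       definitions = atopic_definitions()) {
  ch <- cohort_patients(cohort)
  disorders <- definitions$disorder

  atopic_eps <- dataset$episodes %>%
    semi_join(definitions, by = "icpc") %>%
    semi_join(ch, by = "patient_id")
  last_contact <- dataset$care_events %>%
    filter(!is.na(.data$episode_id)) %>%
    semi_join(atopic_eps, by = c("episode_id", "patient_id")) %>%
    group_by(.data$patient_id) %>%
    summarise(last_contact = max(.data$date), .groups = "drop")

  triads <- validated %>%
    filter(.data$disorder %in% disorders) %>%
    group_by(.data$patient_id, .data$strategy) %>%
    summarise(n_disorders = dplyr::n_distinct(.data$disorder),
              triad_start = min(.data$first_diagnosis),
              max_end = max(.data$effective_end), .groups = "drop") %>%
    filter(.data$n_disorders == length(disorders)) %>%
    left_join(last_contact, by = "patient_id") %>%
    left_join(ch[, c("patient_id", "fu_end")], by = "patient_id") %>%
    mutate(
      effective_end = dplyr::if_else(
        .data$strategy %in% c(3L, 4L),
        pmax(.data$fu_end, .data$triad_start),
        pmax(dplyr::coalesce(.data$last_contact, .data$max_end),
             .data$triad_start)),
      disorder = "triad",
      effective_start = .data$triad_start,
      first_diagnosis = .data$triad_start,
      n_contacts = NA_integer_,
      n_relevant_rx = NA_integer_
    ) %>%
    select("patient_id", "disorder", "strategy", "effective_start",
           "effective_end", "first_diagnosis", "n_contacts",
           "n_relevant_rx")

  dplyr::bind_rows(validated, triads)
}
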