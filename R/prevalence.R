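#' Per-age annual point prevalence pooled over the study window
#'
#' For every January 1 inside the study window, the denominator at age *a*
#' is the number of cohort children registered on that date and aged *a*
#' completed years (0--18, from the mid-quarter imputed birth date); the
#' numerator is the subset with an effective validated interval covering
#' the date (closed interval: `effective_start <= Jan 1 <= effective_end`).
#' Per-age rates pool all years by summing numerators and denominators;
#' `per_year = TRUE` keeps the calendar year as a column instead.
#'
#' An age with a zero denominator is reported with `percent = NA`
#' (undefined), never 0.
#'
#' @param cohort A [cohort_selection()] from [select_children()].
#' @param validated Validated-episode table from [validate_episodes()]
#'   (optionally with triad rows from [add_triads()]).
#' @param strategy Single strategy in 1:4 to tabulate.
#' @param window Length-2 `Date` study window.
#' @param disorders Disorders to tabulate; defaults to all present.
#' @param ages Integer ages, default 0:18.
#' @param per_year Keep per-calendar-year rows instead of pooling.
#' @param digits Rounding for the `percent` column (default 1; the triad
#'   is conventionally reported with 2 decimals).
#' @return A `prevalence_table` tibble: `disorder`, `strategy`, `age`
#'   (and `year` if `per_year`), `numerator`, `denominator`, `percent`.
#' @export
point_prevalence <- function(cohort, validated, strategy,
                             window = as.Date(c("2002-01-01", "2014-12-31")),
                             disorders = NULL, ages = 0:18,
                             per_year = FALSE, digits = 1) {
  if (length(strategy) != 1 || !strategy %in% 1:4) {
    abort("configuration error: `strategy` must be one of 1, 2, 3, 4.")
  }
  ch <- cohort_patients(cohort)
  v <- validated[validated$strategy == strategy, , drop = FALSE]
  if (is.null(disorders)) {
    disorders <- unique(v$disorder)
    if (length(disorders) == 0) disorders <- atopic_definitions()$disorder
  }
  window <- as.Date(window)
  years <- year_of(window[1]):year_of(window[2])
  jan1 <- as.Date(sprintf("%d-01-01", years))
  jan1 <- jan1[jan1 >= window[1] & jan1 <= window[2]]

  rows <- list()
  for (i in seq_along(jan1)) {
    d <- jan1[i]
    reg <- ch$fu_start <= d & ch$fu_end >= d
    age <- age_completed_years(d, ch$birth_imputed)
    keep <- reg & age %in% ages
    if (!any(keep)) next
    denom <- tibble(patient_id = ch$patient_id[keep], age = age[keep])
    open <- v[v$effective_start <= d & v$effective_end >= d, , drop = FALSE]
    hit <- denom %>%
      inner_join(distinct(open[, c("patient_id", "disorder")]),
                 by = "patient_id", relationship = "many-to-many")
    den_tab <- denom %>% count(.data$age, name = "denominator")
    num_tab <- hit %>% count(.data$disorder, .data$age, name = "numerator")
    grid <- tidyr::expand_grid(disorder = disorders, den_tab)
    rows[[i]] <- grid %>%
      left_join(num_tab, by = c("disorder", "age")) %>%
      mutate(numerator = dplyr::coalesce(.data$numerator, 0L),
             year = year_of(d))
  }
  tab <- dplyr::bind_rows(rows)
  if (nrow(tab) == 0) {
    tab <- tibble(disorder = character(), age = integer(),
                  denominator = integer(), numerator = integer(),
                  year = integer())
  }

  group_cols <- if (per_year) c("disorder", "year", "age") else
    c("disorder", "age")
  grid_full <- if (per_year) {
    tidyr::expand_grid(disorder = disorders, year = as.integer(years),
                       age = as.integer(ages))
  } else {
    tidyr::expand_grid(disorder = disorders, age = as.integer(ages))
  }
  out <- tab %>%
    group_by(dplyr::across(dplyr::all_of(group_cols))) %>%
    summarise(numerator = sum(.data$numerator),
              denominator = sum(.data$denominator), .groups = "drop") %>%
    left_join(x = grid_full, y = ., by = group_cols) %>%
    mutate(numerator = dplyr::coalesce(.data$numerator, 0L),
           denominator = dplyr::coalesce(.data$denominator, 0L),
           strategy = as.integer(strategy),
           percent = dplyr::if_else(
             .data$denominator > 0,
             round(100 * .data$numerator / .data$denominator, digits),
             NA_real_)) %>%
    select(dplyr::all_of(c("disorder", "strategy",
                           if (per_year) "year", "age",
                           "numerator", "denominator", "percent"))) %>%
    arrange(.data$disorder, .data$age)
  class(out) <- c("prevalence_table", class(out))
  out
}

#' Per-age cumulative (lifetime) incidence
#'
#' Identical to [point_prevalence()] applied to chronically extended
#' episodes (strategies 3 and 4): a child counts in the numerator at every
#' January 1 at or after its first diagnosis, for as long as it is
#' registered, so on a closed cohort the per-age curve is non-decreasing
#' and approximates a cumulative lifetime prevalence.
#'
#' @inheritParams point_prevalence
#' @param strategy 3 or 4.
#' @return A `prevalence_table`, see [point_prevalence()].
#' @export
cumulative_incidence <- function(cohort, validated, strategy,
                                 window = as.Date(c("2002-01-01",
                                                    "2014-12-31")),
                                 disorders = NULL, ages = 0:18,
                                 per_year = FALSE, digits = 1) {
  if (length(strategy) != 1 || !strategy %in% 3:4) {
    abort("configuration error: cumulative incidence needs strategy 3 or 4.")
  }
  point_prevalence(cohort, validated, strategy, window, disorders, ages,
                   per_year, digits)
}

#' Prevalence-by-age table for several strategies
#'
#' Convenience wrapper running [point_prevalence()] for each requested
#' strategy and binding the results.
#'
#' @inheritParams point_prevalence
#' @param strategies Integer subset of 1:4.
#' @return A `prevalence_table`.
#' @export
prevalence_by_age <- function(cohort, validated, strategies = 1:4,
                              window = as.Date(c("2002-01-01",
                                                 "2014-12-31")),
                              disorders = NULL, ages = 0:18,
                              per_year = FALSE, digits = 1) {
  out <- dplyr::bind_rows(lapply(strategies, function(s) {
    point_prevalence(cohort, validated, s, window, disorders, ages,
                     per_year, digits)
  }))
  class(out) <- c("prevalence_table", class(out))
  out
}

#' Plot prevalence-by-age curves
#'
#' One panel per disorder, one line per strategy, mirroring the standard
#' presentation of per-age prevalence under the four strategies.
#'
#' @param tab A `prevalence_table`.
#' @return A ggplot object.
#' @export
plot_prevalence <- function(tab) {
  ggplot2::ggplot(tab,
                  ggplot2::aes(x = .data$age, y = .data$percent,
                               colour = factor(.data$strategy))) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~disorder, scales = "free_y") +
    ggplot2::labs(x = "age (years)", y = "prevalence (%)",
                  colour = "strategy") +
    ggplot2::theme_minimal()
}
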