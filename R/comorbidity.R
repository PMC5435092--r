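#' Period case status per child
#'
#' For each cohort child, determines which atopic disorders it had at
#' least one validated episode of during the study period, under one
#' strategy.  Children rejected by the strategy (population at risk)
#' receive `FALSE` on every disorder but stay in the table: they belong to
#' the denominator.
#'
#' @param cohort A [cohort_selection()].
#' @param validated Validated-episode table (one strategy, or pass
#'   `strategy` to filter).
#' @param strategy Strategy to filter `validated` on (default 2, the
#'   paper-style corrected episodes).
#' @param disorders Character vector of disorders to tabulate.
#' @return Tibble: `patient_id` plus one logical column per disorder.
#' @export
period_case_status <- function(cohort, validated, strategy = 2,
                               disorders = c("eczema", "asthma",
                                             "rhinitis")) {
  ch <- cohort_patients(cohort)
  v <- validated[validated$strategy == strategy &
                   validated$disorder %in% disorders, , drop = FALSE]
  status <- tibble(patient_id = ch$patient_id)
  for (d in disorders) {
    status[[d]] <- status$patient_id %in% v$patient_id[v$disorder == d]
  }
  status
}

#' Venn-region counts for three-disorder co-occurrence
#'
#' Tallies the eight regions of the three-set Venn diagram (each single
#' disorder only, each pair only, all three, none).  Region counts
#' partition the cohort and every marginal equals the sum of its four
#' regions.
#'
#' @param status Output of [period_case_status()]: `patient_id` plus three
#'   logical columns.
#' @return A `venn_counts` list: `regions` (named integer vector with
#'   names like `"eczema"`, `"eczema+asthma"`, `"eczema+asthma+rhinitis"`,
#'   `"none"`), `marginals` (named integer), `total`.
#' @export
venn_counts <- function(status) {
  if (anyDuplicated(status$patient_id)) {
    abort("invalid-input error: duplicate patient ids in status table.")
  }
  disorders <- setdiff(names(status), "patient_id")
  if (length(disorders) != 3) {
    abort("venn_counts expects exactly three disorder columns.")
  }
  m <- as.matrix(status[, disorders])
  key <- m %*% (2L^(seq_along(disorders) - 1L))
  combos <- 0:7
  labels <- vapply(combos, function(k) {
    on <- disorders[bitwAnd(k, 2L^(seq_along(disorders) - 1L)) > 0]
    if (length(on) == 0) "none" else paste(on, collapse = "+")
  }, character(1))
  counts <- vapply(combos, function(k) sum(key == k), integer(1))
  names(counts) <- labels
  marginals <- vapply(disorders, function(d) sum(status[[d]]), integer(1))
  structure(
    list(regions = counts, marginals = marginals, total = nrow(status)),
    class = "venn_counts"
  )
}

#' @export
print.venn_counts <- function(x, ...) {
  cat("<venn_counts> total:", x$total, "\n")
  for (i in seq_along(x$regions)) {
    cat(sprintf("  %-28s %8d\n", names(x$regions)[i], x$regions[i]))
  }
  invisible(x)
}

#' Triad prevalence expected under independence
#'
#' Product of the three per-disorder period prevalences: the proportion of
#' children expected to carry all three disorders if the disorders
#' occurred independently.
#'
#' @param p_eczema,p_asthma,p_rhinitis Proportions in \[0, 1\].
#' @return Expected proportion with all three disorders.
#' @examples
#' expected_by_chance(0.061, 0.061, 0.059)  # ~0.00022, i.e. 0.022%
#' @export
expected_by_chance <- function(p_eczema, p_asthma, p_rhinitis) {
  for (p in list(p_eczema, p_asthma, p_rhinitis)) {
    if (any(p < 0 | p > 1)) abort("prevalences must lie in [0, 1].")
  }
  p_eczema * p_asthma * p_rhinitis
}

#' Fold enrichment of observed over expected co-occurrence
#'
#' @param observed,expected Proportions; `expected` must be positive.
#' @return `observed / expected`.
#' @examples
#' fold_enrichment(1251 / 478076, expected_by_chance(0.061, 0.061, 0.059))
#' @export
fold_enrichment <- function(observed, expected) {
  if (any(expected <= 0)) {
    abort("undefined-ratio error: expected proportion must be > 0.")
  }
  observed / expected
}

#' Co-occurrence summary: marginals, observed and expected triad, fold
#'
#' @param status Output of [period_case_status()].
#' @return Tibble with per-disorder period prevalences, the observed and
#'   independence-expected triad proportions, and the fold enrichment
#'   (unrounded, with the integer-rounded headline alongside).
#' @export
co_occurrence_stats <- function(status) {
  vc <- venn_counts(status)
  disorders <- names(vc$marginals)
  p <- vc$marginals / vc$total
  triple <- vc$regions[[paste(disorders, collapse = "+")]]
  observed <- triple / vc$total
  expected <- expected_by_chance(p[[1]], p[[2]], p[[3]])
  fold <- if (expected > 0) fold_enrichment(observed, expected) else NA_real_
  tibble(
    disorder = c(disorders, "triad_observed", "triad_expected"),
    n = c(vc$marginals, triple, NA_integer_),
    proportion = c(p, observed, expected),
    percent = round(100 * c(p, observed, expected),
                    c(1, 1, 1, 2, 3)),
    fold_enrichment = c(rep(NA_real_, 3), fold, NA_real_),
    fold_rounded = c(rep(NA_real_, 3), round(fold), NA_real_)
  )
}

#' Remission rate from the strategy contrast
#'
#' The relative gap between the cumulative lifetime prevalence under the
#' chronic corrected strategy (4) and the current point prevalence under
#' the corrected strategy (2) at the same age:
#' `100 * (cumulative - point) / cumulative`, rounded to an integer
#' percent.  It estimates the share of ever-diagnosed children showing
#' complete reduction of symptoms by that age.
#'
#' @param point Strategy-2 point prevalence at the age, in percent.
#' @param cumulative Strategy-4 cumulative prevalence at the age, in
#'   percent; must be positive and at least `point`.
#' @return Integer percent(s) in \[0, 100\].
#' @examples
#' remission_rate(2.5, 24.0)  # 90
#' remission_rate(3.6, 19.3)  # 81
#' remission_rate(5.7, 16.0)  # 64
#' @export
remission_rate <- function(point, cumulative) {
  if (any(cumulative <= 0)) {
    abort("remission rate undefined: cumulative prevalence must be > 0.")
  }
  if (any(point > cumulative)) {
    abort(paste("inconsistency error: point prevalence exceeds cumulative",
                "prevalence (violates the strategy ordering)."))
  }
  if (any(point < 0)) abort("point prevalence must be >= 0.")
  round(100 * (cumulative - point) / cumulative)
}

#' Remission rates by disorder and age from prevalence tables
#'
#' Contrasts the strategy-2 point prevalence with the strategy-4
#' cumulative prevalence at the requested ages.
#'
#' @param prev_s2,prev_s4 `prevalence_table`s for strategies 2 and 4.
#' @param ages Ages at which to report remission.
#' @return Tibble: `disorder`, `age`, `point_s2`, `cumulative_s4`,
#'   `remission_pct`.
#' @export
remission_by_age <- function(prev_s2, prev_s4, ages = c(10, 18)) {
  s2 <- prev_s2 %>%
    filter(.data$age %in% ages) %>%
    select("disorder", "age", point_s2 = "percent")
  s4 <- prev_s4 %>%
    filter(.data$age %in% ages) %>%
    select("disorder", "age", cumulative_s4 = "percent")
  inner_join(s2, s4, by = c("disorder", "age")) %>%
    filter(!is.na(.data$point_s2), !is.na(.data$cumulative_s4),
           .data$cumulative_s4 > 0) %>%
    mutate(remission_pct = remission_rate(pmin(.data$point_s2,
                                               .data$cumulative_s4),
                                          .data$cumulative_s4))
}
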