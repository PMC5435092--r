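#' Constant-by-age annual hazard vector
#'
#' Convenience constructor for the age-indexed incidence hazards used by
#' [sim_config()]: a length-19 vector (ages 0--18) equal to `h` on `ages`
#' and 0 elsewhere.
#'
#' @param h Annual probability of first diagnosis while the child is the
#'   given age.
#' @param ages Integer ages (subset of 0:18) on which the hazard is `h`.
#' @return Named numeric vector of length 19 (names `"0"` .. `"18"`).
#' @examples
#' constant_hazard(0.03, ages = 0:2)
#' @export
constant_hazard <- function(h, ages = 0:18) {
  stopifnot(all(ages %in% 0:18))
  out <- setNames(numeric(19), as.character(0:18))
  out[as.character(ages)] <- h
  out
}

default_incidence <- function() {
  list(
    # eczema: concentrated in infancy, tapering
    eczema = setNames(c(0.06, 0.05, 0.04, rep(0.02, 4), rep(0.01, 12)),
                      as.character(0:18)),
    # asthma: early childhood onset
    asthma = setNames(c(rep(0.04, 3), rep(0.02, 5), rep(0.005, 11)),
                      as.character(0:18)),
    # rhinitis: rising with age
    rhinitis = setNames(c(rep(0.003, 5), rep(0.01, 7), rep(0.02, 7)),
                        as.character(0:18))
  )
}

#' Configuration for the synthetic primary-care EHR generator
#'
#' Defines the simulated registry: practice and list sizes, the study
#' window, age-specific annual first-diagnosis hazards and annual remission
#' hazards per disorder, care-seeking intensity, prescription behaviour,
#' practice-level data-quality defects, and list turnover.  All randomness
#' derives from `seed`: identical configurations produce byte-identical
#' datasets.
#'
#' @param n_practices Number of practices.
#' @param patients_per_practice Children listed per practice.
#' @param study_window Length-2 `Date`: observation window (default the
#'   2002--2014 calendar window).
#' @param incidence Named list (`eczema`, `asthma`, `rhinitis`) of
#'   length-19 vectors: annual probability of first diagnosis at each age
#'   0--18.  See [constant_hazard()].
#' @param remission Named numeric: annual probability an open episode
#'   remits (is closed at its last contact).
#' @param contacts_per_episode_year Mean number of episode-linked contacts
#'   per open episode-year (beyond the opening encounter).
#' @param relevant_rx_prob Probability an episode contact carries a
#'   definition-matching ATC prescription.
#' @param irrelevant_rx_rate Mean non-matching prescriptions per child-year.
#' @param unlinked_rx_fraction Fraction of relevant prescriptions left
#'   unlinked to their episode, emulating EHRs that do not link
#'   prescriptions into episodes.
#' @param background_contact_rate Mean non-episode GP contacts per
#'   child-year; the default 1.5 gives roughly 78% of children at least one
#'   contact a year, matching the Dutch benchmark that GPs see about 77%
#'   of patients annually.
#' @param quality_defect_fractions Named numeric (`patients`, `weeks`,
#'   `coding`): fractions of practices violating, respectively, the
#'   500-listed-patients, 46-registration-weeks and 70%-ICPC-coding
#'   criteria in every year.
#' @param turnover Annual probability a child deregisters.
#' @param atopy_fraction,atopy_rr Fraction of children carrying a latent
#'   atopic predisposition and the hazard multiplier it confers on all
#'   three disorders; this shared factor induces the co-occurrence
#'   enrichment seen in real registries.  Set `atopy_rr = 1` for
#'   independent disorders.
#' @param birth_window Length-2 `Date`: birth dates are drawn uniformly on
#'   this interval.  `NULL` (default) spans from 18 years before the window
#'   start to the window end, so all ages 0--18 are represented throughout.
#' @param seed Integer RNG seed.
#' @return A validated `atopia_sim_config` list.
#' @examples
#' cfg <- sim_config(n_practices = 2, patients_per_practice = 50, seed = 7)
#' @export
sim_config <- function(n_practices = 20,
                       patients_per_practice = 250,
                       study_window = as.Date(c("2002-01-01", "2014-12-31")),
                       incidence = default_incidence(),
                       remission = c(eczema = 0.15, asthma = 0.12,
                                     rhinitis = 0.08),
                       contacts_per_episode_year = 1.5,
                       relevant_rx_prob = 0.7,
                       irrelevant_rx_rate = 0.5,
                       unlinked_rx_fraction = 0.1,
                       background_contact_rate = 1.5,
                       quality_defect_fractions = c(patients = 0.05,
                                                    weeks = 0.05,
                                                    coding = 0.05),
                       turnover = 0.04,
                       atopy_fraction = 0.04,
                       atopy_rr = 8,
                       birth_window = NULL,
                       seed = 1L) {
  n_practices <- check_count(n_practices, "n_practices")
  patients_per_practice <- check_count(patients_per_practice,
                                       "patients_per_practice")
  study_window <- as.Date(study_window)
  if (length(study_window) != 2 || anyNA(study_window) ||
      study_window[1] >= study_window[2]) {
    abort("configuration error: `study_window` must be two ordered dates.")
  }
  if (!is.list(incidence) ||
      !all(c("eczema", "asthma", "rhinitis") %in% names(incidence))) {
    abort("configuration error: `incidence` needs eczema, asthma and rhinitis entries.")
  }
  for (d in names(incidence)) {
    if (length(incidence[[d]]) != 19) {
      abort(sprintf(
        "configuration error: `incidence$%s` must give a hazard for every age 0-18.", d))
    }
    check_probability(incidence[[d]], paste0("incidence$", d))
  }
  for (d in names(remission)) {
    check_probability(remission[[d]], paste0("remission$", d))
  }
  if (contacts_per_episode_year < 0) {
    abort("configuration error: `contacts_per_episode_year` must be >= 0.")
  }
  check_probability(relevant_rx_prob, "relevant_rx_prob")
  if (irrelevant_rx_rate < 0) {
    abort("configuration error: `irrelevant_rx_rate` must be >= 0.")
  }
  check_probability(unlinked_rx_fraction, "unlinked_rx_fraction")
  if (background_contact_rate < 0) {
    abort("configuration error: `background_contact_rate` must be >= 0.")
  }
  if (!all(c("patients", "weeks", "coding") %in%
           names(quality_defect_fractions))) {
    abort("configuration error: `quality_defect_fractions` needs patients, weeks and coding entries.")
  }
  check_probability(quality_defect_fractions, "quality_defect_fractions")
  check_probability(turnover, "turnover")
  check_probability(atopy_fraction, "atopy_fraction")
  if (atopy_rr < 0) abort("configuration error: `atopy_rr` must be >= 0.")
  if (is.null(birth_window)) {
    birth_window <- c(
      seq(study_window[1], by = "-18 years", length.out = 2)[2],
      study_window[2]
    )
  }
  birth_window <- as.Date(birth_window)
  if (length(birth_window) != 2 || anyNA(birth_window) ||
      birth_window[1] > birth_window[2]) {
    abort("configuration error: `birth_window` must be two ordered dates.")
  }
  seed <- check_count(seed, "seed")

  structure(
    list(
      n_practices = n_practices,
      patients_per_practice = patients_per_practice,
      study_window = study_window,
      incidence = incidence,
      remission = remission,
      contacts_per_episode_year = contacts_per_episode_year,
      relevant_rx_prob = relevant_rx_prob,
      irrelevant_rx_rate = irrelevant_rx_rate,
      unlinked_rx_fraction = unlinked_rx_fraction,
      background_contact_rate = background_contact_rate,
      quality_defect_fractions = quality_defect_fractions,
      turnover = turnover,
      atopy_fraction = atopy_fraction,
      atopy_rr = atopy_rr,
      birth_window = birth_window,
      seed = seed
    ),
    class = "atopia_sim_config"
  )
}

#' @export
print.atopia_sim_config <- function(x, ...) {
  cat("<atopia_sim_config>\n")
  cat(sprintf("  practices: %d x %d children; window %s .. %s; seed %d\n",
              x$n_practices, x$patients_per_practice,
              format(x$study_window[1]), format(x$study_window[2]), x$seed))
  invisible(x)
}
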