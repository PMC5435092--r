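#' Generate a synthetic primary-care EHR dataset
#'
#' Simulates a coded registry with the structure the prevalence analysis
#' assumes: practices with per-year quality metrics (a configurable
#' fraction deliberately violating each quality criterion), children with
#' quarter-coarsened birth dates and registration intervals subject to
#' list turnover, ICPC-coded episodes of care arising from age-specific
#' first-diagnosis hazards (at most one first diagnosis per child and
#' disorder), episode-linked contacts, relevant ATC-coded prescriptions
#' (a configurable fraction left unlinked to their episode), background
#' consultations and irrelevant prescriptions.
#'
#' Remission closes an episode at its last contact date; episodes that
#' never remit are exported with an empty closing date.  After a remitted
#' episode, a child may experience one relapse episode of the same
#' disorder, so recorded episodes can be multiple per disorder while the
#' first diagnosis stays unique.  All prescriptions are emitted twice:
#' once in the prescriptions table and once as a care event of type
#' `"prescription"` (the same observation viewed as a contact).
#'
#' Identical configurations (including seed) yield identical datasets; the
#' caller's RNG state is left untouched.
#'
#' @param config A [sim_config()].
#' @return A validated [ehr_dataset()].
#' @examples
#' d <- simulate_ehr(sim_config(n_practices = 2, patients_per_practice = 40,
#'                              seed = 7))
#' d
#' @export
simulate_ehr <- function(config = sim_config()) {
  if (!inherits(config, "atopia_sim_config")) {
    abort("configuration error: `config` must come from sim_config().")
  }
  with_preserved_seed(config$seed, generate_dataset(config))
}

relevant_atc_pool <- list(
  eczema   = c("D07AC01", "D07AB02", "D07AA02"),
  asthma   = c("R03AC02", "R03BA02", "R03AK06"),
  rhinitis = c("R01AC01", "R01AD09", "R06AE07", "R06AX13")
)
irrelevant_atc_pool <- c("J01CA04", "N02BE01", "D01AC08", "A07CA01",
                         "H02AB06", "S01AA01")

generate_dataset <- function(config) {
  ws <- config$study_window[1]
  we <- config$study_window[2]
  empty <- empty_ehr_tables()

  if (config$n_practices == 0) {
    return(ehr_dataset(empty$practices, empty$patients, empty$episodes,
                       empty$care_events, empty$prescriptions,
                       config$study_window))
  }

  pr <- gen_practices(config)
  if (config$patients_per_practice == 0) {
    return(ehr_dataset(pr, empty$patients, empty$episodes,
                       empty$care_events, empty$prescriptions,
                       config$study_window))
  }

  pat <- gen_patients(config, pr)

  eps_l <- list(); con_l <- list()
  for (d in c("eczema", "asthma", "rhinitis")) {
    s <- sim_disorder(pat, d, config)
    eps_l[[d]] <- s$episodes
    con_l[[d]] <- s$contacts
  }
  eps <- dplyr::bind_rows(eps_l)
  con <- dplyr::bind_rows(con_l)

  # stable episode ids: by patient, disorder code, start date
  if (nrow(eps)) {
    o <- order(eps$pat_idx, eps$icpc, eps$start, eps$ep_key)
    eps <- eps[o, ]
    eps$episode_id <- sprintf("E%06d", seq_len(nrow(eps)))
  } else {
    eps$episode_id <- character(0)
  }

  episodes <- tibble(
    episode_id = eps$episode_id,
    patient_id = pat$patient_id[eps$pat_idx],
    icpc = eps$icpc,
    start_date = eps$start,
    end_date = eps$end_exported
  )

  # contacts -> care events (+ prescription rows for contacts carrying one)
  con$episode_id <- eps$episode_id[match(con$ep_key, eps$ep_key)]
  con$patient_id <- pat$patient_id[con$pat_idx]
  contact_events <- tibble(
    patient_id = con$patient_id,
    episode_id = con$episode_id,
    date = con$date,
    type = con$type
  )
  has_rx <- !is.na(con$rx_atc)
  rx_rel <- tibble(
    patient_id = con$patient_id[has_rx],
    atc = con$rx_atc[has_rx],
    date = con$date[has_rx],
    episode_id = as.character(ifelse(con$rx_linked[has_rx],
                                     con$episode_id[has_rx],
                                     NA_character_))
  )
  rx_rel_events <- tibble(
    patient_id = rx_rel$patient_id,
    episode_id = rx_rel$episode_id,
    date = rx_rel$date,
    type = rep("prescription", nrow(rx_rel))
  )

  fu_years <- as.numeric(pat$reg_end - pat$reg_start) / 365.25

  # background (non-episode) consultations
  n_bg <- rpois(nrow(pat), config$background_contact_rate * fu_years)
  bg_rows <- rep.int(seq_len(nrow(pat)), n_bg)
  bg_events <- tibble(
    patient_id = pat$patient_id[bg_rows],
    episode_id = rep(NA_character_, length(bg_rows)),
    date = pat$reg_start[bg_rows] +
      floor(runif(length(bg_rows)) *
              (as.numeric(pat$reg_end - pat$reg_start)[bg_rows] + 1)),
    type = if (length(bg_rows)) {
      sample(c("consultation", "telephone", "home visit"),
             length(bg_rows), replace = TRUE, prob = c(0.80, 0.15, 0.05))
    } else character(0)
  )

  # irrelevant prescriptions (never definition-matching, never linked)
  n_irr <- rpois(nrow(pat), config$irrelevant_rx_rate * fu_years)
  irr_rows <- rep.int(seq_len(nrow(pat)), n_irr)
  rx_irr <- tibble(
    patient_id = pat$patient_id[irr_rows],
    atc = if (length(irr_rows)) {
      sample(irrelevant_atc_pool, length(irr_rows), replace = TRUE)
    } else character(0),
    date = pat$reg_start[irr_rows] +
      floor(runif(length(irr_rows)) *
              (as.numeric(pat$reg_end - pat$reg_start)[irr_rows] + 1)),
    episode_id = rep(NA_character_, length(irr_rows))
  )
  rx_irr_events <- tibble(
    patient_id = rx_irr$patient_id,
    episode_id = rx_irr$episode_id,
    date = rx_irr$date,
    type = rep("prescription", nrow(rx_irr))
  )

  care_events <- dplyr::bind_rows(contact_events, rx_rel_events, bg_events,
                                  rx_irr_events)
  o <- order(care_events$patient_id, care_events$date, care_events$type,
             care_events$episode_id, method = "radix", na.last = TRUE)
  care_events <- care_events[o, ]
  care_events <- tibble(
    event_id = sprintf("CE%07d", seq_len(nrow(care_events))),
    patient_id = care_events$patient_id,
    episode_id = care_events$episode_id,
    date = care_events$date,
    type = care_events$type
  )

  prescriptions <- dplyr::bind_rows(rx_rel, rx_irr)
  o <- order(prescriptions$patient_id, prescriptions$date, prescriptions$atc,
             method = "radix")
  prescriptions <- prescriptions[o, ]
  prescriptions <- tibble(
    rx_id = sprintf("RX%07d", seq_len(nrow(prescriptions))),
    patient_id = prescriptions$patient_id,
    atc = prescriptions$atc,
    date = prescriptions$date,
    episode_id = prescriptions$episode_id
  )

  patients <- tibble(
    patient_id = pat$patient_id,
    practice_id = pat$practice_id,
    sex = pat$sex,
    birth_year = year_of(pat$birth),
    birth_quarter = (as.integer(format(pat$birth, "%m")) - 1L) %/% 3L + 1L,
    reg_start = pat$reg_start,
    reg_end = pat$reg_end
  )

  ehr_dataset(pr, patients, episodes, care_events, prescriptions,
              config$study_window)
}

gen_practices <- function(config) {
  np <- config$n_practices
  years <- year_of(config$study_window[1]):year_of(config$study_window[2])
  f <- config$quality_defect_fractions
  pick <- function(fr) {
    k <- round(fr * np)
    seq_len(np) %in% (if (k > 0) sample.int(np, k) else integer(0))
  }
  d_pat <- pick(f[["patients"]])
  d_wk <- pick(f[["weeks"]])
  d_cod <- pick(f[["coding"]])

  idx <- rep(seq_len(np), each = length(years))
  nr <- length(idx)
  listed <- integer(nr); weeks <- double(nr); coded <- double(nr)
  bad_p <- d_pat[idx]; bad_w <- d_wk[idx]; bad_c <- d_cod[idx]
  listed[bad_p] <- sample(150:480, sum(bad_p), replace = TRUE)
  listed[!bad_p] <- pmax(600L,
                         as.integer(round(stats::rnorm(sum(!bad_p), 2350, 200))))
  weeks[bad_w] <- sample(30:45, sum(bad_w), replace = TRUE)
  weeks[!bad_w] <- 52
  coded[bad_c] <- round(runif(sum(bad_c), 0.30, 0.65), 3)
  coded[!bad_c] <- round(runif(sum(!bad_c), 0.85, 0.99), 3)

  tibble(
    practice_id = sprintf("PR%03d", idx),
    year = rep(years, times = np),
    listed_patients = listed,
    registration_weeks = weeks,
    coded_fraction = coded
  )
}

gen_patients <- function(config, practices) {
  ws <- config$study_window[1]; we <- config$study_window[2]
  np <- config$n_practices
  n <- np * config$patients_per_practice
  bw <- config$birth_window
  birth <- bw[1] + floor(runif(n) * (as.numeric(bw[2] - bw[1]) + 1))
  reg_start <- pmax(birth, ws)
  if (config$turnover > 0) {
    dur_days <- floor((rgeom(n, config$turnover) + runif(n)) * 365.25)
    reg_end <- pmax(reg_start, pmin(we, reg_start + dur_days))
  } else {
    reg_end <- rep(we, n)
  }
  latent <- runif(n) < config$atopy_fraction
  tibble(
    patient_id = sprintf("PT%06d", seq_len(n)),
    practice_id = rep(sprintf("PR%03d", seq_len(np)),
                      each = config$patients_per_practice),
    sex = sample(c("F", "M"), n, replace = TRUE),
    birth = birth,
    reg_start = reg_start,
    reg_end = reg_end,
    mult = ifelse(latent, config$atopy_rr, 1)
  )
}

# First-diagnosis process for one disorder: at each completed age 0-18 an
# undiagnosed child is first diagnosed with probability hazard(age) (times
# the latent-atopy multiplier).  The diagnosis enters the record only when
# it falls inside the child's registration interval, mirroring a registry
# that observes what the GP saw.
sim_disorder <- function(pat, disorder, config) {
  n <- nrow(pat)
  h <- as.numeric(config$incidence[[disorder]])
  r <- unname(config$remission[[disorder]])
  icpc <- atopic_definitions()$icpc[match(disorder,
                                          atopic_definitions()$disorder)]

  H <- pmin(outer(pat$mult, h), 1)
  U <- matrix(runif(n * 19L), n, 19L)
  hit <- U < H
  any_hit <- rowSums(hit) > 0
  first <- rep(NA_integer_, n)
  if (any(any_hit)) {
    first[any_hit] <- max.col(hit[any_hit, , drop = FALSE],
                              ties.method = "first")
  }
  age_dx <- first - 1L
  dx_date <- pat$birth + floor((age_dx + runif(n)) * 365.25)
  ok <- any_hit & !is.na(dx_date) &
    dx_date >= pat$reg_start & dx_date <= pat$reg_end
  idx <- which(ok)

  b1 <- gen_episode_block(idx, dx_date[idx], pat, r, disorder, config, "a")

  # one possible relapse episode after a remitted first episode
  if (nrow(b1$episodes)) {
    cap <- pat$reg_end[b1$episodes$pat_idx]
    room <- b1$episodes$remitted &
      (as.numeric(cap - b1$episodes$last_contact) > 240)
    rel <- room & (runif(nrow(b1$episodes)) < 0.4)
    rel_start <- b1$episodes$last_contact + 30L +
      floor(runif(nrow(b1$episodes)) * 335)
    rel <- rel & rel_start <= cap
    b2 <- gen_episode_block(b1$episodes$pat_idx[rel], rel_start[rel],
                            pat, r, disorder, config, "b")
  } else {
    b2 <- gen_episode_block(integer(0), as.Date(character()), pat, r,
                            disorder, config, "b")
  }

  episodes <- dplyr::bind_rows(b1$episodes, b2$episodes)
  contacts <- dplyr::bind_rows(b1$contacts, b2$contacts)
  episodes$icpc <- rep(icpc, nrow(episodes))
  list(episodes = episodes, contacts = contacts)
}

# One block of episodes (first or relapse) with their contacts and
# relevant prescriptions.  Remission truncates the open interval; the
# exported closing date is the last contact of a remitted episode, NA for
# episodes still open at the end of registration.
gen_episode_block <- function(pat_idx, start, pat, r, disorder, config, tag) {
  k <- length(pat_idx)
  if (k == 0) {
    return(list(
      episodes = tibble(pat_idx = integer(), ep_key = character(),
                        start = as.Date(character()),
                        end_exported = as.Date(character()),
                        remitted = logical(),
                        last_contact = as.Date(character())),
      contacts = tibble(pat_idx = integer(), ep_key = character(),
                        date = as.Date(character()), type = character(),
                        rx_atc = character(), rx_linked = logical())
    ))
  }
  cap <- pat$reg_end[pat_idx]
  open_dur <- if (r > 0) {
    floor((rgeom(k, r) + runif(k)) * 365.25)
  } else {
    rep(1e7, k)
  }
  natural_end <- start + pmin(open_dur, 40000)
  remitted <- natural_end < cap
  open_end <- pmin(natural_end, cap)

  ep_key <- sprintf("%s-%s-%06d", disorder, tag, seq_len(k))

  dur_y <- as.numeric(open_end - start) / 365.25
  n_extra <- rpois(k, config$contacts_per_episode_year * dur_y)
  rows <- rep.int(seq_len(k), n_extra)
  extra_date <- start[rows] +
    floor(runif(length(rows)) * (as.numeric(open_end - start)[rows] + 1))

  c_ep <- c(seq_len(k), rows)
  c_date <- c(start, extra_date)
  c_type <- c(rep("consultation", k),
              if (length(rows)) {
                sample(c("consultation", "home visit", "telephone"),
                       length(rows), replace = TRUE, prob = c(0.75, 0.05, 0.20))
              } else character(0))

  m <- length(c_ep)
  carries_rx <- runif(m) < config$relevant_rx_prob
  rx_atc <- rep(NA_character_, m)
  rx_atc[carries_rx] <- sample(relevant_atc_pool[[disorder]],
                               sum(carries_rx), replace = TRUE)
  rx_linked <- rep(NA, m)
  rx_linked[carries_rx] <- runif(sum(carries_rx)) >= config$unlinked_rx_fraction

  last_contact <- start
  if (length(rows)) {
    mx <- tapply(as.numeric(extra_date), rows, max)
    j <- as.integer(names(mx))
    last_contact[j] <- pmax(last_contact[j],
                            as.Date(as.numeric(mx), origin = "1970-01-01"))
  }
  end_exported <- as.Date(ifelse(remitted, as.numeric(last_contact), NA),
                          origin = "1970-01-01")

  list(
    episodes = tibble(pat_idx = pat_idx, ep_key = ep_key, start = start,
                      end_exported = end_exported, remitted = remitted,
                      last_contact = last_contact),
    contacts = tibble(pat_idx = pat_idx[c_ep], ep_key = ep_key[c_ep],
                      date = c_date, type = c_type, rx_atc = rx_atc,
                      rx_linked = rx_linked)
  )
}
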