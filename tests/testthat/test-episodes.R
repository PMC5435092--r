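defs <- atopic_definitions()
def_of <- function(d) defs[defs$disorder == d, ]

test_that("merging per-disorder episodes keeps the earliest diagnosis and unions intervals", {
  two_disjoint <- dplyr::bind_rows(
    tep("E1", "P1", start = "2004-01-10", end = "2004-06-01"),
    tep("E2", "P1", start = "2008-02-01", end = "2008-09-01"))
  rec <- merge_disorder_episodes(two_disjoint)
  expect_identical(rec$first_diagnosis, as.Date("2004-01-10"))
  expect_identical(nrow(rec$intervals), 2L)
  expect_setequal(rec$episode_ids, c("E1", "E2"))

  single <- tep("E1", "P1", start = "2004-01-10", end = "2004-06-01")
  rec1 <- merge_disorder_episodes(single)
  expect_identical(rec1$intervals$start, as.Date("2004-01-10"))
  expect_identical(rec1$intervals$end, as.Date("2004-06-01"))

  overlapping <- dplyr::bind_rows(
    tep("E1", "P1", start = "2004-01-10", end = "2004-06-01"),
    tep("E2", "P1", start = "2004-05-01", end = "2004-12-01"))
  rec2 <- merge_disorder_episodes(overlapping)
  expect_identical(nrow(rec2$intervals), 1L)
  expect_identical(rec2$intervals$start, as.Date("2004-01-10"))
  expect_identical(rec2$intervals$end, as.Date("2004-12-01"))

  mixed <- dplyr::bind_rows(
    tep("E1", "P1", icpc = "S87", start = "2004-01-10"),
    tep("E2", "P1", icpc = "R96", start = "2004-02-10"))
  expect_error(merge_disorder_episodes(mixed), "invalid-input")
})

test_that("interval union agrees with an independent ranges oracle", {
  set.seed(42)
  for (rep in 1:25) {
    k <- sample(1:8, 1)
    s <- as.Date("2005-01-01") + sample(0:400, k, replace = TRUE)
    e <- s + sample(0:90, k, replace = TRUE)
    got <- atopia:::merge_date_intervals(s, e)
    ora <- IRanges::reduce(IRanges::IRanges(as.integer(s), as.integer(e)),
                           min.gapwidth = 1L)
    expect_identical(as.integer(got$start), IRanges::start(ora))
    expect_identical(as.integer(got$end), IRanges::end(ora))
  }
})

test_that("strategy 1 is the identity and enforces no evidence", {
  rec <- merge_disorder_episodes(
    tep("E1", "P1", start = "2004-01-10", end = "2004-06-01"))
  v <- apply_strategy1(rec)
  expect_identical(v$strategy, 1L)
  expect_identical(v$intervals, rec$intervals)

  # zero contacts: still accepted (overestimation risk is accepted)
  expect_false(is.null(v))

  # an open episode is closed at the end of follow-up
  open_rec <- merge_disorder_episodes(
    tep("E1", "P1", start = "2004-01-10"))
  v2 <- apply_strategy1(open_rec, followup_end = as.Date("2014-12-31"))
  expect_identical(v2$effective_end, as.Date("2014-12-31"))

  # a record with no intervals yields nothing
  empty_rec <- structure(list(patient_id = "P1", icpc = "S87",
                              first_diagnosis = as.Date(NA),
                              intervals = tibble::tibble(
                                start = as.Date(character()),
                                end = as.Date(character())),
                              episode_ids = character(0)),
                         class = "disorder_record")
  expect_null(apply_strategy1(empty_rec))
})

test_that("strategy 2 needs two episode contacts and two matching prescriptions", {
  rec <- merge_disorder_episodes(
    tep("E1", "P1", icpc = "R96", start = "2005-01-10", end = "2005-09-01"))

  # one consultation, no prescriptions: rejected
  one_ev <- tev("C1", "P1", "E1", "2005-01-10")
  no_rx <- trx("R0", "P1", "R03AC02", "2005-01-10")[0, ]
  expect_null(apply_strategy2(rec, one_ev, no_rx, def_of("asthma")))

  # two linked consultations + two R03-prefixed prescriptions anywhere:
  # accepted with the recorded interval
  two_ev <- dplyr::bind_rows(one_ev, tev("C2", "P1", "E1", "2005-02-10"))
  two_rx <- dplyr::bind_rows(
    trx("R1", "P1", "R03AC02", "2005-01-10"),
    trx("R2", "P1", "R03BA02", "2008-06-01"))  # unlinked, years later
  v <- apply_strategy2(rec, two_ev, two_rx, def_of("asthma"))
  expect_identical(v$strategy, 2L)
  expect_identical(v$n_contacts, 2L)
  expect_identical(v$n_relevant_rx, 2L)
  expect_identical(v$effective_start, as.Date("2005-01-10"))
  expect_identical(v$effective_end, as.Date("2005-09-01"))

  # prefix discipline: R06 antihistamines are not eczema evidence
  ecz <- merge_disorder_episodes(
    tep("E9", "P1", icpc = "S87", start = "2005-01-10", end = "2005-09-01"))
  r06 <- dplyr::bind_rows(
    trx("R1", "P1", "R06AE07", "2005-01-10"),
    trx("R2", "P1", "R06AX13", "2005-02-10"))
  ev9 <- dplyr::bind_rows(tev("C1", "P1", "E9", "2005-01-10"),
                          tev("C2", "P1", "E9", "2005-02-10"))
  expect_null(apply_strategy2(ecz, ev9, r06, def_of("eczema")))

  # two prescription-type contacts carrying R03 codes satisfy both criteria
  rx_ev <- dplyr::bind_rows(
    tev("C1", "P1", "E1", "2005-01-10", type = "prescription"),
    tev("C2", "P1", "E1", "2005-02-10", type = "prescription"))
  rx_rx <- dplyr::bind_rows(
    trx("R1", "P1", "R03AC02", "2005-01-10", episode_id = "E1"),
    trx("R2", "P1", "R03AC02", "2005-02-10", episode_id = "E1"))
  expect_false(is.null(apply_strategy2(rec, rx_ev, rx_rx, def_of("asthma"))))
  # ... but not when prescription events are barred from the contact count
  expect_null(apply_strategy2(rec, rx_ev, rx_rx, def_of("asthma"),
                              strict_contacts = TRUE))

  # definition must match the record's ICPC code
  expect_error(apply_strategy2(rec, two_ev, two_rx, def_of("eczema")),
               "configuration error")
})

test_that("a prescription date window restricts record-wide evidence", {
  rec <- merge_disorder_episodes(
    tep("E1", "P1", icpc = "R96", start = "2005-01-10", end = "2005-09-01"))
  ev <- dplyr::bind_rows(tev("C1", "P1", "E1", "2005-01-10"),
                         tev("C2", "P1", "E1", "2005-02-10"))
  rx <- dplyr::bind_rows(
    trx("R1", "P1", "R03AC02", "2005-01-15"),
    trx("R2", "P1", "R03AC02", "2008-06-01"))
  expect_false(is.null(apply_strategy2(rec, ev, rx, def_of("asthma"))))
  expect_null(apply_strategy2(rec, ev, rx, def_of("asthma"),
                              rx_window_days = 30))
})

test_that("make_chronic extends to follow-up end and increments the strategy", {
  rec <- merge_disorder_episodes(
    tep("E1", "P1", start = "2004-01-10", end = "2004-06-01"))
  v1 <- apply_strategy1(rec)
  v3 <- make_chronic(v1, as.Date("2014-12-31"))
  expect_identical(v3$strategy, 3L)
  expect_identical(v3$effective_start, as.Date("2004-01-10"))
  expect_identical(v3$effective_end, as.Date("2014-12-31"))

  # an episode already open to the follow-up end keeps its interval
  open_rec <- merge_disorder_episodes(tep("E1", "P1", start = "2004-01-10"))
  v1o <- apply_strategy1(open_rec, followup_end = as.Date("2014-12-31"))
  v3o <- make_chronic(v1o, as.Date("2014-12-31"))
  expect_identical(v3o$effective_start, v1o$effective_start)
  expect_identical(v3o$effective_end, v1o$effective_end)

  # never shortens: chronic coverage contains every recorded date
  expect_lte(as.numeric(v3$effective_start), as.numeric(v1$effective_start))
  expect_gte(as.numeric(v3$effective_end), as.numeric(v1$effective_end))

  # strategy 2 becomes 4
  ev <- dplyr::bind_rows(tev("C1", "P1", "E1", "2004-01-10"),
                         tev("C2", "P1", "E1", "2004-02-10"))
  rx <- dplyr::bind_rows(trx("R1", "P1", "D07AC01", "2004-01-10"),
                         trx("R2", "P1", "D07AB02", "2004-02-10"))
  v2 <- apply_strategy2(rec, ev, rx, def_of("eczema"))
  expect_identical(make_chronic(v2, as.Date("2014-12-31"))$strategy, 4L)

  # follow-up ending before the start is a date-order error
  expect_error(make_chronic(v1, as.Date("2003-01-01")), "date-order")
  # and chronic episodes cannot be made chronic again
  expect_error(make_chronic(v3, as.Date("2014-12-31")), "strategy 1 or 2")
})

test_that("a triad episode needs all three disorders and spans first to last contact", {
  mk <- function(icpc, start, end, id) {
    apply_strategy1(merge_disorder_episodes(
      tep(id, "P1", icpc = icpc, start = start, end = end)))
  }
  s87 <- mk("S87", "2004-03-01", "2005-01-01", "E1")
  r96 <- mk("R96", "2006-05-01", "2007-01-01", "E2")
  r97 <- mk("R97", "2008-09-01", "2009-01-01", "E3")

  tri <- build_triad(list(s87, r96, r97),
                     last_contact = as.Date("2010-01-15"))
  expect_identical(tri$disorder, "triad")
  expect_identical(tri$effective_start, as.Date("2004-03-01"))
  expect_identical(tri$effective_end, as.Date("2010-01-15"))

  expect_null(build_triad(list(s87, r96)))

  same <- list(mk("S87", "2004-03-01", "2005-01-01", "E1"),
               mk("R96", "2004-03-01", "2005-01-01", "E2"),
               mk("R97", "2004-03-01", "2005-01-01", "E3"))
  expect_identical(build_triad(same)$effective_start, as.Date("2004-03-01"))

  mixed <- list(s87, r96, make_chronic(r97, as.Date("2014-12-31")))
  expect_error(build_triad(mixed), "mix strategies")
})

test_that("dataset-wide validation obeys the strategy lattice", {
  d <- simulate_ehr(sim_config(n_practices = 5, patients_per_practice = 100,
                               seed = 21))
  sel <- select_children(d)
  v <- validate_episodes(d, sel)

  keyz <- function(s) {
    unique(paste(v$patient_id[v$strategy == s], v$disorder[v$strategy == s]))
  }
  expect_true(all(keyz(2) %in% keyz(1)))
  expect_true(all(keyz(4) %in% keyz(3)))
  expect_setequal(keyz(3), keyz(1))
  expect_setequal(keyz(4), keyz(2))

  # chronic episodes cover every recorded date of the same child-disorder
  s1 <- v[v$strategy == 1, ]
  s3 <- v[v$strategy == 3, ]
  j <- dplyr::inner_join(s1, s3, by = c("patient_id", "disorder"),
                         suffix = c("_1", "_3"),
                         relationship = "many-to-many")
  expect_true(all(j$effective_start_3 <= j$effective_start_1))
  expect_true(all(j$effective_end_3 >= j$effective_end_1))

  # triad children are exactly the triple-diagnosed children per strategy
  vt <- add_triads(v, d, sel)
  for (s in 1:4) {
    per <- table(unique(v[v$strategy == s,
                          c("patient_id", "disorder")])$patient_id)
    expect_setequal(vt$patient_id[vt$strategy == s & vt$disorder == "triad"],
                    names(per)[per == 3])
  }
})

test_that("strategy-2 acceptance equals a brute-force enumeration on small cohorts", {
  for (seed in c(301, 302, 303)) {
    d <- simulate_ehr(sim_config(n_practices = 1, patients_per_practice = 20,
                                 contacts_per_episode_year = 0.8,
                                 relevant_rx_prob = 0.4, seed = seed))
    sel <- select_children(d)
    got <- validate_episodes(d, sel, strategies = 2)
    got_keys <- sort(unique(paste(got$patient_id, got$disorder)))

    want <- character(0)
    for (pid in cohort_patients(sel)$patient_id) {
      for (i in seq_len(nrow(defs))) {
        eps <- d$episodes[d$episodes$patient_id == pid &
                            d$episodes$icpc == defs$icpc[i], ]
        if (nrow(eps) == 0) next
        n_ev <- 0
        for (r in seq_len(nrow(d$care_events))) {
          e <- d$care_events$episode_id[r]
          if (!is.na(e) && e %in% eps$episode_id) n_ev <- n_ev + 1
        }
        rx <- d$prescriptions[d$prescriptions$patient_id == pid, ]
        n_rx <- 0
        for (a in rx$atc) {
          if (any(startsWith(a, defs$atc[[i]]))) n_rx <- n_rx + 1
        }
        if (n_ev >= 2 && n_rx >= 2) {
          want <- c(want, paste(pid, defs$disorder[i]))
        }
      }
    }
    expect_identical(got_keys, sort(want))
  }
})
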