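test_that("ages come from the mid-quarter imputed birth date", {
  # frozen from calendar arithmetic: Q1 imputes Feb 15, Q4 imputes Nov 15
  expect_identical(age_on(as.Date("2005-01-01"), 2000, 1), 4L)
  expect_identical(age_on(as.Date("2000-02-15"), 2000, 1), 0L)
  expect_identical(age_on(as.Date("2019-01-01"), 2000, 4), 18L)
  # independent oracle: completed years = anniversaries passed
  oracle <- function(date, by, bq) {
    birth <- atopia:::mid_quarter_date(by, bq)
    length(seq(birth, as.Date(date), by = "1 year")) - 1L
  }
  set.seed(9)
  for (i in 1:50) {
    by <- sample(1990:2010, 1); bq <- sample(1:4, 1)
    date <- atopia:::mid_quarter_date(by, bq) + sample(0:8000, 1)
    expect_identical(age_on(date, by, bq), oracle(date, by, bq))
  }
  expect_error(age_on(as.Date("2000-01-01"), 2000, 1), "negative")
})

test_that("point prevalence is numerator over registered children on Jan 1", {
  # 10 children aged 5 on 2005-01-01; 2 with open validated eczema episodes
  ids <- sprintf("P%02d", 1:10)
  cohort <- cohort_of(ids, birth_year = 1999L, birth_quarter = 2L)
  v <- dplyr::bind_rows(
    vrow("P01", "eczema", 1, "2004-06-01", "2005-06-01"),
    vrow("P02", "eczema", 1, "2004-12-30", "2005-01-01"))
  tab <- point_prevalence(cohort, v, strategy = 1,
                          window = as.Date(c("2005-01-01", "2005-12-31")))
  row5 <- tab[tab$age == 5 & tab$disorder == "eczema", ]
  expect_identical(row5$numerator, 2L)
  expect_identical(row5$denominator, 10L)
  expect_identical(row5$percent, 20)

  # ages with no registered children are undefined, not zero
  row0 <- tab[tab$age == 0, ]
  expect_identical(row0$denominator, 0L)
  expect_true(is.na(row0$percent))

  # no open episodes anywhere: 0% wherever the denominator is positive
  tab0 <- point_prevalence(cohort, v[0, ], strategy = 1,
                           window = as.Date(c("2005-01-01", "2005-12-31")))
  expect_true(all(tab0$percent[tab0$denominator > 0] == 0))

  # an interval covers Jan 1 inclusively on both ends
  v_edge <- vrow("P01", "eczema", 1, "2005-01-01", "2005-01-01")
  tab_e <- point_prevalence(cohort, v_edge, strategy = 1,
                            window = as.Date(c("2005-01-01", "2005-12-31")))
  expect_identical(tab_e$numerator[tab_e$age == 5], 1L)

  expect_error(point_prevalence(cohort, v, strategy = 5), "strategy")
})

test_that("a 6% seeded case rate is recovered within binomial error at n = 10,000", {
  n <- 10000
  ids <- sprintf("P%05d", seq_len(n))
  cohort <- cohort_of(ids, birth_year = 1999L, birth_quarter = 2L)
  set.seed(61)
  case <- runif(n) < 0.06
  v <- tibble::tibble(
    patient_id = ids[case], disorder = "eczema", strategy = 1L,
    effective_start = as.Date("2004-06-01"),
    effective_end = as.Date("2005-06-01"),
    first_diagnosis = as.Date("2004-06-01"),
    n_contacts = 2L, n_relevant_rx = 2L)
  tab <- point_prevalence(cohort, v, strategy = 1,
                          window = as.Date(c("2005-01-01", "2005-12-31")),
                          digits = 4)
  p_hat <- tab$percent[tab$age == 5] / 100
  se <- sqrt(0.06 * 0.94 / n)
  expect_lt(abs(p_hat - 0.06), 3 * se)
})

test_that("cumulative incidence counts a child from diagnosis onward, once", {
  # closed single-child cohort observed birth to age 18
  cohort <- cohort_of("P1", birth_year = 2002L, birth_quarter = 1L,
                      fu_start = as.Date("2002-02-15"),
                      fu_end = as.Date("2020-12-31"))
  # two recorded eczema episodes -> one chronic record from the earlier start
  v3 <- vrow("P1", "eczema", 3, "2004-05-01", "2020-12-31",
             first_diagnosis = "2004-05-01")
  tab <- cumulative_incidence(cohort, v3, strategy = 3,
                              window = as.Date(c("2002-01-01",
                                                 "2020-12-31")))
  ecz <- tab[tab$disorder == "eczema", ]
  # diagnosed while aged 2 (mid-2004): first counted at the Jan 1 it is
  # age 2 (2005-01-01), then at every later attained age
  expect_true(all(ecz$numerator[ecz$age %in% 0:1 & ecz$denominator > 0] == 0))
  expect_true(all(ecz$numerator[ecz$age >= 2 & ecz$denominator > 0] == 1))
  expect_true(all(ecz$denominator[ecz$age <= 18] <= 1))

  expect_error(cumulative_incidence(cohort, v3, strategy = 1), "3 or 4")
})

test_that("zero diagnoses give a flat 0% cumulative curve", {
  cohort <- cohort_of(c("P1", "P2"), birth_year = 2002L)
  tab <- cumulative_incidence(cohort, vrow("x", "eczema", 3,
                                           "2004-01-01", "2004-01-02")[0, ],
                              strategy = 3)
  expect_true(all(tab$percent[tab$denominator > 0] == 0))
})

test_that("the strategy lattice holds per age on simulated data", {
  d <- simulate_ehr(sim_config(n_practices = 4, patients_per_practice = 150,
                               seed = 31))
  sel <- select_children(d)
  v <- validate_episodes(d, sel)
  tabs <- lapply(1:4, function(s) point_prevalence(sel, v, s, digits = 6))
  key <- function(t) paste(t$disorder, t$age)
  expect_identical(key(tabs[[1]]), key(tabs[[2]]))
  ok <- tabs[[1]]$denominator > 0
  expect_true(all(tabs[[2]]$numerator[ok] <= tabs[[1]]$numerator[ok]))
  expect_true(all(tabs[[4]]$numerator[ok] <= tabs[[3]]$numerator[ok]))
  expect_true(all(tabs[[3]]$numerator[ok] >= tabs[[1]]$numerator[ok]))
  expect_true(all(tabs[[4]]$numerator[ok] >= tabs[[2]]$numerator[ok]))
})

test_that("cumulative curves are monotone on a closed simulated cohort", {
  cfg <- sim_config(
    n_practices = 4, patients_per_practice = 250,
    study_window = as.Date(c("2002-01-01", "2021-12-31")),
    birth_window = as.Date(c("2002-01-01", "2002-12-31")),
    turnover = 0, seed = 41)
  d <- simulate_ehr(cfg)
  sel <- select_children(d, window = cfg$study_window)
  v <- validate_episodes(d, sel)
  for (s in 3:4) {
    tab <- cumulative_incidence(sel, v, s, window = cfg$study_window,
                                digits = 6)
    for (dis in unique(tab$disorder)) {
      cur <- tab[tab$disorder == dis & tab$denominator > 0, ]
      expect_true(all(diff(cur$numerator / cur$denominator) >= -1e-12))
    }
  }
})
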