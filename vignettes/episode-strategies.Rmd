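---
title: "Episode-of-care strategies for atopic-disorder prevalence in primary-care EHRs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Episode-of-care strategies for atopic-disorder prevalence in primary-care EHRs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atopia)
```

## The estimation problem

Dutch general practitioners record morbidity as ICPC-coded *episodes of
care*: one labelled interval per health problem, collecting all related
consultations, home visits, telephone contacts and prescriptions, with a
start and (sometimes) a closing date. Because nearly everyone is listed
with a practice whether or not they visit it, the practice list gives a
valid denominator, and coded episodes give a numerator — an attractive
setting for estimating the prevalence of childhood atopic disorders:
atopic eczema (ICPC S87), asthma (R96) and allergic rhinitis (R97).

Two opposing biases make the naive estimate unreliable. GPs work with
*probability diagnoses*, so recorded episodes overestimate clinically
relevant disease; and the choice between an *annual point prevalence* and
a *lifetime cumulative prevalence* changes the estimate several-fold,
because these disorders frequently remit. `atopia` implements the four
case-definition strategies that bracket these choices:

| Strategy | Start of episode | End of episode |
|---|---|---|
| 1 | as recorded | as recorded |
| 2 | recorded, validated by evidence | as recorded |
| 3 | as recorded | extended: disorder treated as chronic |
| 4 | validated as in 2 | extended: chronic |

Strategy 2 accepts a child's per-disorder record only when it has **at
least two episode-related contacts** and **at least two relevant
prescriptions**. Relevance is an ATC prefix match: D07 (dermatological
corticosteroids) for eczema, R03 (obstructive-airway drugs) for asthma,
and R01AC, R01AD or R06 for rhinitis. Because EHRs do not reliably link
prescriptions into the correct episode, the prescription search is
record-wide; the contact count, in contrast, requires an episode link.
A child rejected by strategy 2 stays in the *population at risk* — it
still belongs to every denominator.

Strategies 3 and 4 extend the closing date to the end of the child's
follow-up. Since a child is incident only once per disorder (the first
diagnosis date), the pooled per-age rates under these strategies are
cumulative incidences, and — where the full early history is observed —
approximate lifetime prevalences.

## Estimands and conventions

**Point prevalence.** For every January 1 inside the study window and
every age 0–18, the denominator is the number of cohort children
registered on that date with that age; the numerator is the subset with
an effective episode interval covering the date (closed interval,
date precision). Per-age rates pool calendar years by summing numerators
and denominators, producing one curve per disorder and strategy;
per-year output is available via `per_year = TRUE`. An age with a zero
denominator is *undefined* (`NA`), never 0.

**Ages.** Records carry only year and quarter of birth. All age logic
uses a deterministic mid-quarter imputation — day 15 of the quarter's
middle month — the least biased single-date choice given
quarter-coarsened data, and the same convention is used by eligibility
filtering and prevalence so the two cannot disagree.

**Case status under strategy 2** is retrospective: a child validated
anywhere in its record is a case on every January 1 its recorded episode
covers. Episodes are corrected first, prevalence computed second; there
is no time-dependent validation.

**Missing closing dates** (episodes never closed by the GP) are treated
as open until the end of the child's follow-up, for strategies 1 and 2.
This is the permissive reading; it only matters for the point-prevalence
strategies, since 3 and 4 extend every episode anyway.

**Contacts and prescriptions can be the same record.** A
prescription-type contact counts toward the two-contact criterion *and*
its ATC code counts toward the two-prescription criterion; the data model
views one dispensing both as drug evidence and as a contact. A
`strict_contacts` flag restricts the contact count to non-prescription
events for sensitivity analyses, and `rx_window_days` optionally
restricts record-wide prescriptions to a window around the recorded
intervals. The two-contact rule counts records, not distinct dates.

**Exclusion precedence.** Cohort selection is quality-first: a child in
a practice with no passing practice-year (at least 500 listed patients,
at least 46 registration-weeks/year, at least 70% of episodes ICPC-coded;
all thresholds inclusive) is excluded under *quality*; among the
survivors, observed follow-up below 1095 days (the calendar-day reading
of "3 years") excludes under *follow-up*. A child failing both is counted
once, under quality, so counts sum exactly. By default a practice-year
failing the criteria removes only that year's standing and a child is
quality-excluded only when **all** its overlapping years fail;
`strict_quality = TRUE` excludes on any failing year.

**Remission.** The contrast between the validated point prevalence
(strategy 2) and the validated cumulative prevalence (strategy 4) at one
age estimates the share of ever-diagnosed children in complete remission:
`100 * (s4 - s2) / s4`, rounded to an integer percent. The formula is an
interpretation adopted because it exactly reproduces the published age-18
rates from their published inputs (90%, 81% and 64% for eczema, asthma
and rhinitis from 2.5|24.0, 3.6|19.3 and 5.7|16.0).

**Co-occurrence.** Period case status over the whole window (strategy 2)
feeds a three-set Venn partition; the triad prevalence expected under
independence is the product of the three marginals, and the fold
enrichment is observed/expected, reported unrounded with the
integer-rounded headline alongside.

## The synthetic registry generator

No real registry extract ships with the package. `simulate_ehr()`
generates one with the structural features the analysis must cope with,
and with known truth for calibration:

* **Incidence** per disorder is an age-indexed annual first-diagnosis
  hazard, ages 0–18 (`constant_hazard()` builds the common cases). A
  child is incident at most once per disorder; the diagnosis enters the
  record only if it falls inside the registration interval, which is how
  registration bias arises in real registries. Defaults emulate the
  textbook shapes: eczema concentrated in infancy (0.06→0.01/yr),
  asthma in early childhood (0.04→0.005/yr), rhinitis rising with age
  (0.003→0.02/yr), giving cumulative incidences by age 18 of roughly
  30%, 25% and 20% under full observation.
* **Remission** closes an open episode at its last contact date with a
  per-disorder annual hazard (defaults 0.15/0.12/0.08 per year for
  eczema/asthma/rhinitis, reflecting that eczema remits most and
  rhinitis least); an episode that never remits is exported with an
  *empty closing date*, deliberately exercising the downstream
  missing-closing-date rule. After remission a child may relapse once,
  so children can have several recorded episodes per disorder while the
  first diagnosis stays unique.
* **Care seeking**: each open episode-year generates a mean of 1.5
  linked contacts beyond the opening encounter; each contact carries a
  relevant prescription with probability 0.7, and 10% of relevant
  prescriptions are left unlinked to their episode (EHRs do not reliably
  link them). Background, non-episode consultations arrive at 1.5 per
  child-year, so that about 78% of children see the GP at least once a
  year, matching the Dutch benchmark of ~77%; irrelevant prescriptions
  (never definition-matching ATC codes) arrive at 0.5 per child-year.
* **Quality defects**: 5% of practices per criterion violate, in every
  year, the listed-patients, registration-weeks or coding-fraction
  criterion.
* **Demography**: births uniform over the 18 years before the window
  start through the window end (all ages represented throughout);
  annual deregistration probability 0.04. Exact birth dates are drawn
  internally but only year+quarter is exported, forcing all downstream
  age logic through the coarsened field.
* **Shared atopy factor**: 4% of children carry a latent predisposition
  multiplying all three hazards by 8, which induces the co-occurrence
  enrichment seen in real data; setting `atopy_rr = 1` gives independent
  disorders.

Identical configuration and seed yield byte-identical datasets, and the
generator leaves the caller's RNG stream untouched.

### What the generator does *not* emulate

Realistic Dutch demography, practice-level clustering of prescribing
styles, seasonality, free-text notes, and miscoded or missing ICPC codes
(the R03-wheeze-without-R96 under-ascertainment problem) are all out of
scope. Passing tests on this generator therefore demonstrate the
*internal* correctness of the episode logic and estimators under known
truth — not that the estimates transfer to any particular real registry.

## A property worth knowing: exposure-time confounding

While validating the independence property we measured fold enrichments
near 1.75 on cohorts generated with *independent* disorders. This is not
a bug in the statistic or the generator: on an open cohort with staggered
entry and turnover, children differ in observed person-time, and longer
observation raises the chance of *each* diagnosis. Shared exposure time
therefore induces positive co-occurrence between independent disorders in
any period-prevalence design. The package's independence check
accordingly uses an equal-exposure closed cohort (a single birth year, no
turnover, a window covering ages 0–18), where the measured fold is 1.02,
within Monte-Carlo error of 1. Real-data fold enrichments computed over
heterogeneous observation windows should be read with the same caveat.

## Numerical choices and degenerate inputs

* Interval unions merge overlapping **or abutting** intervals (next
  start ≤ previous end + 1 day), on closed date intervals.
* Percentages are rounded to 1 decimal (the conventional reporting
  precision; the triad, being an order of magnitude rarer, is shown with
  2–3 decimals in the co-occurrence table); `digits` overrides.
* A zero denominator yields `NA`, a zero expected proportion makes the
  fold enrichment an error rather than `Inf`, and an empty cohort makes
  the attrition report an error rather than a table of `NaN`.
* `remission_rate()` rejects point > cumulative as an inconsistency: the
  strategy lattice (2 ≤ 1, 4 ≤ 3, 3 ≥ 1, 4 ≥ 2 at every age) guarantees
  it cannot occur in tables produced by the package itself.
* All randomness in the generator flows from one integer seed;
  simulation sizes in the test-suite calibration checks use 10,000
  children, at which 3 binomial standard errors are below one percentage
  point for the rates being checked.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config(seed = 42)          # 20 practices x 250 children, 2002-2014
d <- simulate_ehr(cfg)
sel <- select_children(d)             # quality + eligibility + attrition
v <- add_triads(validate_episodes(d, sel), d, sel)

prev <- prevalence_by_age(sel, v)     # all four strategies, pooled years
plot_prevalence(prev)

st <- period_case_status(sel, v)      # strategy-2 period status, 2002-2014
co_occurrence_stats(st)               # marginals, Venn triple, fold
remission_by_age(point_prevalence(sel, v, 2),
                 point_prevalence(sel, v, 4), ages = c(10, 18))
```

## Known limitations

* Follow-up for a child aging past 18 ends at deregistration or the
  window end, not the 19th birthday; ages above 18 simply drop out of
  the 0–18 tabulation (they affect no numerator or denominator).
* Strategy-2 validation is retrospective; a time-dependent variant
  (validated-by-the-prevalence-date) would need additional bookkeeping
  and is not implemented.
* Confidence intervals are not computed; numerators and denominators are
  always reported so any binomial interval can be attached downstream.
* Episodes created from medication-only evidence (e.g. R03 prescriptions
  without an R96 episode) are out of scope: the engine corrects recorded
  episodes, it does not create new ones.
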