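# atopia

Episode-based prevalence estimation for childhood atopic disorders —
atopic eczema, asthma and allergic rhinitis — from coded primary-care
electronic health records.

## The problem

Primary-care registries record morbidity as ICPC-coded *episodes of care*
(S87 eczema, R96 asthma, R97 allergic rhinitis) over a listed population,
so they carry both a numerator and a valid denominator for prevalence
estimation. Two decisions dominate the estimate: whether to trust the
GP's recorded (often provisional) diagnosis, and whether to treat the
disorder as current or lifelong. `atopia` implements the four strategies
that bracket these choices and everything around them:

* a **synthetic registry generator** (`simulate_ehr()`) with configurable
  age-specific incidence hazards, remission, care-seeking intensity,
  practice-level quality defects and list turnover — seeded and
  byte-reproducible;
* **quality and eligibility filtering** (`select_children()`): practices
  need ≥ 500 listed patients, ≥ 46 registration-weeks/year and ≥ 70%
  ICPC-coded episodes; children need ≥ 3 years (1095 days) of observed
  follow-up and ages 0–18 in the window; attrition is reported with
  quality-first precedence;
* **episode reconstruction** under four strategies
  (`validate_episodes()`): (1) episodes as recorded; (2) validated —
  at least two episode-related contacts *and* at least two relevant
  prescriptions (ATC prefix match: D07 eczema, R03 asthma,
  R01AC/R01AD/R06 rhinitis, searched record-wide); (3) and (4) the same
  with the disorder treated as chronic (closing date extended to the end
  of follow-up), plus atopic-triad episodes (`add_triads()`);
* **estimation**: per-age annual point prevalence on January 1 pooled
  over calendar years (`point_prevalence()`), cumulative lifetime
  incidence (`cumulative_incidence()`), three-set Venn co-occurrence
  with the independence expectation `p_e * p_a * p_r` and its fold
  enrichment (`co_occurrence_stats()`), and remission rates from the
  strategy contrast `100 * (s4 - s2) / s4` (`remission_rate()`).

## Worked example

```r
library(atopia)

d   <- simulate_ehr(sim_config(seed = 42))   # 20 practices x 250 children, 2002-2014
sel <- select_children(d)
sel
#> <cohort_selection>
#>   eligible:                 4998
#>   excluded (quality):        750
#>   excluded (follow-up):      923
#>   included:                 3325

v    <- add_triads(validate_episodes(d, sel), d, sel)
prev <- prevalence_by_age(sel, v)
subset(as.data.frame(prev), disorder == "eczema" & age == 2)
#>   disorder strategy age numerator denominator percent
#>     eczema        1   2       173        1561    11.1
#>     eczema        2   2       168        1561    10.8
#>     eczema        3   2       207        1561    13.3
#>     eczema        4   2       188        1561    12.0
```

The four rows show the bracket the strategies put around "how many
2-year-olds have eczema": validation (strategy 2) trims the recorded
point prevalence from 11.1% to 10.8%, while treating eczema as chronic
(strategies 3–4) raises it to 12–13.3% — on real registry data the gap
between point and lifetime readings grows much larger with age.

```r
st <- period_case_status(sel, v)   # strategy-2 case status over the window
co_occurrence_stats(st)
#>         disorder   n proportion percent fold_enrichment fold_rounded
#>           eczema 399    0.12000  12.000              NA           NA
#>           asthma 338    0.10165  10.200              NA           NA
#>         rhinitis 281    0.08451   8.500              NA           NA
#>   triad_observed  16    0.00481   0.480            4.67            5
#>   triad_expected  NA    0.00103   0.103              NA           NA
```

Sixteen children carry all three disorders — about 5-fold more than the
product of the marginals predicts, driven by the generator's latent
shared atopy factor.

```r
remission_by_age(point_prevalence(sel, v, 2),
                 point_prevalence(sel, v, 4), ages = 18)
#>   disorder age point_s2 cumulative_s4 remission_pct
#>     asthma  18      1.8           2.6            31
#>     eczema  18      3.2           4.2            24
#>   rhinitis  18      8.6          10.4            17
```

A command-line front end over the same functions ships in
`inst/cli/atopia.R` (subcommands `simulate`, `filter`, `episodes`,
`prevalence`, `comorbidity`, `remission`, `run`).

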