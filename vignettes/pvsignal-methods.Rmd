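---
title: "Disproportionality analysis of spontaneous reports with pvsignal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality analysis of spontaneous reports with pvsignal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvsignal)
```

## The problem

Spontaneous adverse-event databases such as the FDA Adverse Event Reporting
System (FAERS) collect voluntary reports of suspected drug adverse events.
Because the number of patients actually exposed to each drug is unknown,
incidence cannot be estimated; what can be estimated is *disproportionality*
— whether an event is reported more often with a drug of interest than with
a comparator. `pvsignal` implements this workflow for report-level data: it
was built around a study of cardiovascular adverse events reported for the
inhaled long-acting muscarinic antagonists (LAMAs) aclidinium,
glycopyrronium, tiotropium and umeclidinium between January 2020 and
September 2023, and generalizes to any drug/event configuration supplied
through its vocabulary and study-configuration files.

## The reporting odds ratio

Reports are cross-classified by exposure (target drug vs comparator) and by
whether they carry at least one event term from the outcome group:

|            | event | no event |
|------------|-------|----------|
| target     | a     | b        |
| comparator | c     | d        |

The reporting odds ratio is the cross-product ratio

$$\mathrm{ROR} = \frac{a/b}{c/d} = \frac{ad}{bc},$$

with log-scale standard error
$\mathrm{SE} = \sqrt{1/a + 1/b + 1/c + 1/d}$ and 95% Wald interval
$\exp(\ln \mathrm{ROR} \pm 1.959964\,\mathrm{SE})$. A result is flagged as a
**signal** when the lower confidence bound strictly exceeds 1 and the
estimate rests on at least 3 event cases. The case floor guards against
signals driven by one or two reports; the strict inequality makes a bound of
exactly 1 a non-signal.

Counting is *case-level*: a report listing three qualifying cardiac terms
contributes one case, not three, because reports — not event mentions — are
the sampling unit of the database.

Two conventions deserve explicit statement:

* **Direction.** The ROR is the odds of the event *given the target drug*
  divided by the odds *given the comparator*. For the LAMA analysis the
  comparator is tiotropium, so values above 1 mean the newer LAMA attracts
  proportionally more cardiac reports than tiotropium. The numerically
  verified published contrasts (e.g. aclidinium 1.60, 95% CI 1.36–1.89 from
  the 188/1254 vs 1238/12472 cohorts) follow exactly this orientation.
* **Interval method.** The Wald interval on the log scale with
  $z = 1.959964$ reproduces, from the cohort counts alone, all six published
  interval bounds of the LAMA-vs-tiotropium forest after half-up rounding to
  2 decimals, which is why it is the package's (only) interval method.

### Numerical choices

* Zero cells make the estimator undefined; `ror()` raises a degenerate-table
  error naming the offending cell. An optional Haldane–Anscombe correction
  (`correction = "haldane_half"`) adds 0.5 to every cell when any cell is
  zero — useful for exploratory tabulation, but since the signal rule
  requires at least 3 cases, corrected estimates never create signals from
  near-empty cells. The reported case count is always the uncorrected `a`.
* Display rounding is half *away from zero* (`round_half_up()`), 2 decimals
  for odds ratios and bounds, 1 decimal for percentages. Internal values are
  never rounded; exported CSVs carry full precision.
* No multiplicity adjustment is applied across the many drug–event
  contrasts of a study run. This matches common practice in exploratory
  pharmacovigilance screening but inflates the family-wise false-signal
  rate; treat signals as hypotheses, not findings.
* Stratified output (`stratified_rors()`) is per-stratum only. No
  Mantel–Haenszel pooling is attempted: strata in spontaneous data are
  often wildly unbalanced, and a pooled estimate would suggest an
  adjusted effect the design cannot support. Degenerate strata are reported
  with their counts and a reason code rather than dropped.

## The report model

A report has a stable `case_id`, a per-version `report_id`, a version
number, a receipt date, sex, an age band, one or more drug mentions (with
their verbatim names and role codes) and a non-empty set of event preferred
terms.

* **Deduplication** keeps, per case, the highest version, breaking ties by
  latest receipt date and then largest report id. Latest-wins matches how
  case resubmissions supersede earlier versions in FAERS practice; the
  operation is deterministic and idempotent. Whether and how the original
  analysis deduplicated versions is not documented; this rule is the
  package's explicit choice.
* **Age** is stored as a band (`under18`, `18to64`, `65to85`, `over85`,
  `NS`) because spontaneous-report summaries are published in bands. An
  age-in-years column is binned with boundaries 18, 65, 85; age 85 belongs
  to `65to85` since the published bands are "65–85" and "more than 85".
* **Partial dates** (`202001`, `2021-06`) are coerced to the first of the
  period so window filtering is total; the study window filter is inclusive
  at both ends.
* Reports with no event term cannot enter any contingency cell and are
  dropped at load with a warning.

## Vocabulary

MedDRA is licensed and cannot be redistributed, so event-group membership is
user configuration: a YAML file maps products to synonyms, ingredients and
classes, and event groups to flat term sets. The bundled demo vocabulary
covers the LAMA study design — the generic-name synonym lists for the four
LAMAs and ipratropium, the dual/triple fixed-dose combination products, a
cardiac-disorders group and the three narrower arrhythmia, cardiac-failure
and ischaemic-heart-disease queries — with an illustrative few dozen terms.
Matching is exact (case-insensitive, trimmed): no fuzzy matching, no
hierarchy traversal. Combination exposure is recognized only through
combination *product* entries, not inferred from co-occurring
monocomponents, because monotherapy-vs-combination cohorts in report data
are product-name-driven. Exposure defaults to suspect (and role-unknown)
drug mentions, the standard disproportionality convention.

## The study pipeline

`run_study()` executes load → deduplicate → window filter → descriptive
tables → configured comparisons, deterministically, and writes `totals.csv`,
`cohorts.csv`, `subgroups.csv` and `forest.csv`. Two tabulation rules keep
description and inference separate:

* Descriptive cohort tables count a report under *every* product it
  mentions; a dual-exposed report appears in both product rows.
* Inferential comparisons apply the design's `exclusive` rule (default on):
  reports exposed to both target and comparator are dropped from both
  cohorts, since they carry no contrast. The dropped count is logged.

Subgroup percentages use the *sum of the subgroup counts* as denominator.
The three queries overlap on reports carrying terms from several subgroups
and do not exhaust the broad cardiac group, so the subgroup sum is the only
denominator under which the three percentages are guaranteed to total 100;
it is also the denominator that reproduces the published breakdown cells.

## The synthetic generator

`generate_reports()` produces report files with known ground truth so every
stage — parsing, dedup, vocabulary matching, cohort assembly, estimation —
is testable without access to a real database. Ground truth is defined on
the **odds scale**: each product's event odds are a baseline odds times a
product multiplier, so the expected ROR of product vs baseline equals the
multiplier ratio exactly, with no probability-scale distortion.

Defaults emulate the LAMA study conditions: cohort sizes equal the observed
per-drug report counts (12,472 / 1,254 / 1,883 / 2,599), baseline odds equal
the tiotropium cardiac odds 1238/11234 ≈ 0.110, multipliers default to 1 (a
global null), sex and age mixtures approximate the observed overall strata.
The generator also reproduces the messy structural features of spontaneous
data: multiple cardiac terms per case (`1 + Poisson(0.3)` draws, exercising
case-level counting), synonym-verbatim names (probability 0.5), resubmitted
duplicate versions (0.02) and dual exposures (0.01). Generation is a pure
function of the parameters including the seed — identical parameters give
byte-identical files.

`table1_fixture()` is the deterministic counterpart: a minimal report set
whose per-drug report/case marginals and subgroup composition equal the
published cohorts exactly, so the full pipeline reproduces the published
forest end to end. Where the published subgroup counts exceed the case count
(aclidinium, glycopyrronium) the surplus cases carry an arrhythmia *and* an
ischaemia term; where they fall short (tiotropium, umeclidinium) the
remainder carry a cardiac term outside all three queries. Case sex labels
follow the published split; the published age-band cells are not internally
consistent in the available table text, so fixture age bands are `NS`.

What the generator does **not** emulate: reporting delay, stimulated
reporting after safety communications, masking by competing signals,
channeling bias, narrative text, or country/reporter effects. Passing tests
on synthetic data therefore validate the *computational* pipeline and the
estimator's sampling behaviour, not the epidemiological interpretability of
any real-data signal.

## Validation problem sizes

The test suite validates the estimator's statistical guarantees at sizes
chosen to make Monte-Carlo noise negligible relative to the property being
checked: exact formula equivalence on all 1,296 tables with cells 1–6;
interval coverage at the null on 1,000 simulated tables of two 600-report
cohorts with event probability 0.08 (expected coverage 95%, accepted
93–97%); parameter recovery of odds multipliers 0.5, 1 and 2 over 200
generator replicates of two 5,000-report cohorts (mean log-ROR within 3
standard errors of the injected log-multiplier); and null calibration of the
signal rule over 400 replicates of two 1,000-report cohorts (the rule fires
in at most 5% of replicates; the expected rate for a one-sided 97.5% bound
is ≈2.5%).

## Limitations

Disproportionality measures association among *reports*, not risk among
*patients*: no denominator of exposed patients exists, reporting is
voluntary and biased, and a signal is a screening hypothesis. The package
accordingly implements no causal adjustment; only crude and
singly-stratified contrasts are provided, and only the ROR family — PRR,
Bayesian shrinkage estimators (IC/EBGM) and time-to-onset methods are out
of scope.
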