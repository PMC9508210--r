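---
title: "Line-of-therapy sequencing and comorbidity burden in claims cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Line-of-therapy sequencing and comorbidity burden in claims cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

txpathways characterizes a newly diagnosed patient population in
insurance-claims data: who enters the cohort, which comorbidities they carry
at diagnosis, and in what order they receive treatments. The motivating
application is autism spectrum disorder (ASD), where patients receive a wide
mix of behavioral therapy and psychotropic pharmacotherapy and where the
sequencing of those interventions — first treatment, switches, add-ons — is
the quantity of clinical interest. The package operates on five OMOP-style
tables (persons, observation periods, condition occurrences, drug exposures
with days' supply, procedure occurrences) with diagnosis and drug codes
already mapped to category labels; it performs no vocabulary translation.

Because the claims databases such analyses are usually run on are licensed
and cannot be redistributed, the package ships a synthetic claims generator
with the statistical structure the analysis assumes. Every stage is
therefore testable end-to-end, and the generator doubles as the ground truth
for parameter-recovery checks.

## The cohort entry algorithm

A patient enters the incident cohort when all four of the following hold,
with every day count configurable via `cohort_criteria()`:

1. **Two coded diagnoses** on distinct calendar dates, at most 365 days
   apart (inclusive), with the first falling in the study entry window
   (2015-01-01 to 2016-12-31 by default). Two claims on the same date count
   as one encounter — duplicate claims are ubiquitous and the intent of the
   two-diagnosis rule is two separate encounters.
2. **Washout**: a single observation period covering the 180 days before the
   first diagnosis with no gap. Continuous enrollment is what makes the
   diagnosis interpretable as incident.
3. **Follow-up**: observation covering the 1095 days after the index date.
   Here abutting enrollment segments (next start = previous end + 1 day) may
   be chained, because claims enrollment commonly renews at period
   boundaries; `allow_abutting_followup = FALSE` restores the single-period
   reading.
4. **Incidence**: no coded diagnosis anywhere in the patient's observed
   history before the index. A weaker reading — clean washout window only —
   is available as `strict_incidence = FALSE`; the strict reading is the
   default because "newly diagnosed" is the stronger claim.

The index date is the first qualifying diagnosis. Age at index is index year
minus birth year, which is all a claims feed carries. The fine age bins are
[0,4], [5,9], [10,14], [15,17], [18+): published cohort tables sometimes
print overlapping labels ("0–5", "5–9"), and bins must partition, so age 5
is owned by the second bin.

## Baseline comorbidity prevalence

For each condition category, a cohort patient counts once if they have at
least one occurrence dated in `[index − 180, index]` — the window includes
the index date itself, and it deliberately coincides with the washout the
cohort already guarantees, so every patient contributes a full window.
Output is the prevalence proportion overall and stratified by coarse age
group (0–9, 10–17, 18+) and sex, with exact numerator/denominator columns
so every percentage is recomputable.

## Era construction: the persistence-gap rule

Raw dispensings are noisy: refills arrive early or late, and a 30-day gap
between the end of one supply and the next fill usually means continued
therapy, not discontinuation. `build_drug_eras()` therefore covers each
dispensing's closed interval `[start, start + days_supply]` and chains
events of the same patient and treatment class whenever the next start is at
most `gap_days` (default 30, inclusive) past the running covered end. Era
end is the last covered day of the chain. Treatments are captured at the
class level, so in-class switches merge silently into one era.

Two details are deliberate:

- **Overlapping fills** extend coverage as the union of covered days; early
  refills do not stockpile supply. The day-grid oracle the tests use defines
  this semantics independently.
- **Procedure visits** (behavioral therapy, brain stimulation) carry no
  duration, so each visit is given a `session_persistence_days` window
  (default 30, chosen for symmetry with the drug gap; it is the single most
  assumption-laden constant in the package and is prominently configurable).
  Weekly therapy schedules then merge into one era, as they should.

Missing days' supply is imputed at 30 days (the commonest dispensing
quantum) and counted in an attribute. Negative supply is a data error.

## Line assignment: combination, switch, first instance

`assign_lines()` turns one patient's eras into an ordered sequence of
regimens:

- Only eras starting between 30 days before index and 3 years after are
  eligible; the short pre-index lead captures treatment begun at the
  diagnosing encounter before the claim that carries the code.
- Each treatment class contributes only its **earliest** era; later returns
  to a class are invisible (a patient moving SNRI → SSRI → SNRI is captured
  as a single switch SNRI → SSRI).
- Eras are scanned in start order (ties broken by class label, C collation,
  for determinism). An era **joins** the current regimen only if it overlaps
  every current member by at least 30 days (`min(ends) − max(starts)`,
  inclusive at exactly 30); otherwise it **opens the next line**, even if
  earlier treatments are still running — a sub-threshold overlap is a
  switch, and lines may therefore overlap in calendar time.
- Pairwise overlap with *every* member (rather than with the line's seed
  only) is the stricter and order-stable reading of "overlap of more than
  one treatment"; it also settles what happens when a third drug joins an
  established pair: it must overlap both, otherwise it starts a new line.
- The first-instance filter runs *before* grouping. The alternative order
  (group first, then dedupe) differs only for patients whose repeat era
  would have joined a combination; applying it first keeps the rule "one
  era per class, the earliest" exact and testable.

`assign_lines()` itself keeps all lines; the sunburst aggregation truncates
at four. This split lets the per-patient line list stay complete while the
tree matches the four-ring report.

`aggregate_pathways()` counts regimen-sequence prefixes into a tree whose
depth-k ring is the k-th line; at every node the count equals the sum of its
children plus the patients who stop there, and the depth-1 counts sum to the
treated total. Marginal tables report, per line, the patients whose regimen
contains each class, with the treated count as denominator — the convention
treatment-line tables use, with each line's own n printed alongside.

## The synthetic generator

`generate_claims()` emulates the data-generating reality behind such a
study, not any proprietary file layout:

- Enrollment spans are uniform over a configurable date and length range;
  the first diagnosis is aimed at the entry window with room for washout and
  follow-up where the span allows it (patients whose spans cannot host an
  eligible index still get diagnoses and become attrition).
- A condition-positive patient (Bernoulli per configured prevalence,
  optionally age-specific) always receives one occurrence uniform in the
  baseline window, plus Poisson-distributed repeat codings anywhere in
  enrollment. This makes the effective baseline rate equal the configured
  prevalence exactly, so recovery tests have an analytic target.
- Treatment follows a regimen process: an initial class drawn from
  `treatment_init_probs` at a uniform lag around index, then, at
  exponentially distributed dwell times (mean 240 days, minimum 30), an
  action drawn from a row-stochastic map: stop, switch the regimen to a new
  class, or add a class. Drug classes emit back-to-back dispensings (30- or
  90-day supplies; refill gaps configurable, default 0) over their active
  span; behavioral therapy emits weekly visits. A switch starts the new
  class 1–45 days after the previous regimen's covered end, so switches are
  identifiable as switches.
- Defaults are the study conditions: 85% true-ASD, 90% confirmatory second
  diagnosis within a year, 87% ever treated, 76% male, behavioral therapy
  first for 55% of initiators, comorbidity prevalences near published
  Medicaid autism cohort values (ADHD 0.48, anxiety 0.18, mood disorder
  0.17, developmental delay 0.15, seizure disorder 0.08).

What the generator does *not* emulate: claim adjudication, billing-code
detail, inpatient/outpatient distinctions, dose or strength, seasonality,
age-dependent treatment choice, or correlation between comorbidity and
treatment. Passing tests therefore demonstrate that the *algorithms*
implement their rules exactly and recover known parameters — not that the
synthetic margins match any real population.

One interaction is worth knowing about when designing recovery experiments.
Under a switch-only transition map, a sequence A → B → A with a short middle
dwell lets A's two spans re-merge through the 30-day persistence gap, so the
switch surfaces as an apparent combination. The parameter-recovery test
fixes the minimum dwell at 90 days — larger than gap + supply + switch lag —
which makes every configured transition identifiable as a line change; the
arithmetic, not the test outcome, dictates the constant. The study-default
simulation keeps the 30-day minimum, since such re-merging is real claims
behavior. Relatedly, the generator's combination share *declines* with line
number (its add-actions are a first-order process), whereas real cohorts
show it rising; the pathway engine is indifferent to the direction.

## Numerical and engineering choices

- Dates are `Date` objects (integer days) everywhere; files carry ISO-8601.
  All intervals are closed; a "gap" is `next start − covered end` and a
  threshold of 30 is inclusive on merge and on overlap, exclusive one day
  past it. These boundary semantics are pinned by dedicated tests.
- All randomness flows from one seed; identical configuration and seed give
  byte-identical output files. Character ordering uses C collation
  explicitly (`method = "radix"`), so output does not depend on the session
  locale.
- Problem sizes: the simulated study runs at 5,000 patients (a few seconds
  to generate, ~20 s end-to-end); oracle-equivalence suites use 1,000
  random instances per operation; binomial recovery checks use 3-standard-
  error bands at n = 5,000. These sizes make every stochastic check tight
  while keeping the full suite in a few minutes.
- Testing is dual-route throughout: the era builder is checked against a
  day-grid brute force, the line engine against a recursive restatement of
  its five rules, the cohort builder against a literal per-patient checker,
  and the whole pipeline against a 20-patient hand-computed golden fixture
  shipped under `inst/extdata/golden/`.

## Known limitations

- Age is year-resolution (claims carry birth year), so patients near bin
  boundaries can be mis-binned by up to a year.
- The entry algorithm does not distinguish claim settings (the published
  two-*outpatient*-diagnosis qualifier is collapsed; the synthetic data has
  no claim-type axis).
- No person-time incidence, treatment-duration, time-to-switch, dose, or
  adherence measures: the pipeline reports *which* regimens occur and in
  what order, not how long patients stayed on them.
- Prescription claims carry no indication, so no link between a treatment
  and a comorbidity is drawn anywhere.
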