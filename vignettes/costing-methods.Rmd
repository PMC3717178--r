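---
title: "Methods: classifying and costing nutritional care plans for children starting ART"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: classifying and costing nutritional care plans for children starting ART}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ncpcost)
```

## The problem

HIV programmes in resource-constrained settings must budget not only for
antiretroviral therapy (ART) but also for the nutritional management of the
children they initiate. WHO guidance stratifies HIV-infected children aged 6
months to 14 years into three Nutritional Care Plans: **NCP-A** for children
growing adequately (an extra 10% of dietary energy, met from household food,
at zero supplement cost), **NCP-B** for children with poor weight gain or
increased nutritional needs (an extra 20–30% of energy, supplied as
supplements), and **NCP-C** for severe acute malnutrition (SAM; an extra
50–100% of energy as therapeutic feeds). `ncpcost` turns that guidance into a
reproducible pipeline: classify a cohort at ART initiation, compute the
supplemental energy each plan prescribes, price it with locally available
products, compare the result with the cost of supplying first-line ART to
the same children, and explore how the total moves under shorter
supplementation durations.

## Anthropometric classification

Weight-based indicators use the LMS (Box–Cox) transformation
$z = \frac{(X/M)^L - 1}{L\,S}$, with $L, M, S$ linearly interpolated in the
index variable (age in months for weight-for-age, height in cm for
weight-for-height) between the bracketing reference rows. Beyond $|z| = 3$
the WHO restricted-z adjustment is applied: the score is expressed as the
distance past the ±3 SD bound in units of the outermost 1-SD gap, which
keeps extreme scores linear in the measurement and robust to the tail shape
of the Box–Cox distribution. Index values outside the reference range raise
an error; the package never extrapolates a growth reference.

The bundled reference table (`ncp_growth_reference()`) is **synthetic**: a
smooth LMS surface with realistic magnitudes, shipped so the package is
self-contained and testable. Real WHO tables with the same schema
(`indicator, sex, index, L, M, S`) are drop-in replacements via
`load_growth_reference()`, and should be used for any clinical application.

Classification rules, with precedence C > B > A:

* **SAM (→ NCP-C)**: WHZ < −3, MUAC strictly below the age-band cutoff
  (115 mm at 6–60 months, 129 mm at 5–9 years, 160 mm at 10–14 years),
  visible severe wasting, or bilateral pedal oedema.
* **NCP-B triggers**: moderate undernutrition (WAZ ≤ −2 or WHZ ≤ −2 without
  SAM), confirmed weight loss (> 5% since the previous visit), growth-curve
  flattening (non-positive change short of the 5% loss), prevalent TB,
  another condition with increased needs (chronic lung disease, persistent
  diarrhoea, opportunistic infection or malignancy), or WHO clinical stage
  3/4 (configurable off).
* **NCP-A** only when every B trigger is determinably false.
* **UNASSIGNED** when no positive trigger fires but one cannot be ruled out:
  either no usable anthropometry, or TB, comorbidity and stage all
  unrecorded.

Two design points deserve emphasis. First, **WAZ-only assessment is a
first-class path**: many programmes lack stadiometers and MUAC tapes, so
WHZ- and MUAC-based criteria are *skipped*, not failed, when their inputs
are absent, and every skipped indicator is listed in `missing_fields`.
Second, **a positive trigger always beats missingness**: a child with
WAZ ≤ −2 and no morbidity data is NCP-B, not unassigned. The moderate
threshold is inclusive (≤ −2) by default, matching the headline eligibility
definition; a strict `< -2` variant is available because guideline texts
vary on the boundary.

## Energy model

Daily supplemental energy comes from a five-band age table
(`default_energy_tables()`). NCP-B amounts are absolute and
weight-independent (upper bound 150/190/280/380/400 kcal/day; lower
120/160/200/260/340). NCP-C amounts are weight-based *totals*
(upper 220/220/220/100/90 kcal/kg/day; lower 150/150/150/75/60), of which
half — `ncp_c_supplement_fraction = 0.5` — is supplied as supplementation,
the remainder assumed to come from household provision. The default policy
costs the **upper** bound of each range, a deliberate compensation for
household food insecurity in the setting the defaults emulate; the lower
bound is one switch away and is never more expensive (a tested invariant).

## Feeding courses and costing

* NCP-B-only children receive one porridge phase of 26 weeks, taken as
  **182 days**.
* SAM children receive 10 weeks (70 days) of ready-to-use food at the NCP-C
  rate, then a rehabilitation porridge phase at the NCP-B rate for
  **112.5 days** — half a 365-day year (182.5 days) minus the 70-day
  stabilisation phase. Both durations are explicit config constants, not
  buried arithmetic.
* During rehabilitation the child's age band is advanced by the
  stabilisation-phase length (70 days ≈ 2.3 months at 30.4375 days/month),
  so infants aged 6–11 months at course start draw the 12–23-month NCP-B
  rate in phase 2 — children age into the next band during stabilisation.
  `course_durations(band_advance = FALSE)` freezes the band at course start
  instead.

Costs are energy × product ZAR/kcal (Sibusiso ready-to-use food 0.021,
Future Life Porridge 0.009, both derived from 500 g unit prices), rounded
**half away from zero to whole ZAR** at the aggregation level of the
published tables: per child for the NCP-B-only group (all children in a
band share one weight-independent course) and per band row and phase for
the SAM group (whose courses are weight-dependent). USD conversions use the
2010 mid-year rate 1 ZAR = 0.129 USD and are rounded to whole dollars.

One numerical guard matters here: ties like 769.5 must round *up*, but in
binary floating point `85500 * 0.009` is fractionally below 769.5. The
rounding helper therefore snaps values to 6 decimals past the target digit
before applying the half-away rule (`round_half_away()`), making whole-ZAR
results reproducible across platforms.

## The ART comparator and proportional cost

First-line regimens are abacavir + lamivudine + lopinavir/ritonavir
(liquid) for children aged ≤ 3 years — inclusive at exactly 36 months — and
abacavir + lamivudine + efavirenz (tablets) above. Per-drug 26-week
per-child costs are config inputs, since unit prices and weight-band dosing
arithmetic are programme-specific; the group mean weights (9.8 kg and
21.6 kg) travel as metadata only. The proportional cost is
$100 \times \text{supplement ZAR} / (\text{ART ZAR}_{26wk} \times h/26)$
for horizon $h \in \{26, 52\}$ weeks, reported to one decimal: because
supplementation is needed at most once per year while ART is continuous,
the 52-week percentage is exactly half the 26-week one before rounding.

## Duration-sensitivity scenarios

Children often reach exit criteria before 26 weeks (moderate undernutrition
by roughly 12 weeks, SAM by 12–16), so `run_scenario()` rescales the base
aggregate costs linearly in duration, per group, and re-derives USD and
proportional costs. Scaling operates on aggregates rather than re-deriving
per-child courses — matching how such sensitivity arithmetic is normally
done on published totals — while a per-child route is available by simply
re-running `cohort_cost_table()` with altered `course_durations()`.
TB-stratified scenarios (continue 26-week NCP-B for children on TB
treatment, shorten it for the rest) require TB-stratified base costs, which
`cohort_cost_table()` provides whenever the cohort carries TB flags; asking
for a stratified scenario without them is a configuration error, not a
silent fallback. Note that a stratified total depends on the *joint*
TB-by-age composition of the NCP-B group, so two cohorts with identical
marginals can price differently under the same stratified scenario.

## Exit criteria

`ncp_b_exit()` and `ncp_c_downgrade()` implement the longitudinal step-down
rules: NCP-B → NCP-A requires a latest WAZ or WHZ above −1 *and* strictly
increasing weight over a run of at least two consecutive visits spanning at
least 30 calendar days *and* resolution of any qualifying comorbidity;
NCP-C → NCP-B requires oedema loss + appetite recovery + WHZ ≥ −1, or a 15%
weight gain over the post-oedema baseline, or a mean gain of at least
5 g/kg/day (the floor of the 5–15 g/kg/day in-hospital band is used as the
pass threshold; the upper bound is a feeding-rate ceiling, not a failure
criterion). In the base costing these rules are evaluative only — the
published-style analysis costs fixed durations — but they drive duration in
longitudinal simulations. "Approximately 30 days" is implemented as ≥ 30
calendar days between the first and last visit of the qualifying run.

## Synthetic cohorts

`generate_cohort()` emulates a 2010 rural South African paediatric
ART-initiation cohort. Ages are drawn over the five energy bands, WAZ from
a normal model (mean −0.95, SD 1.15 for non-SAM children; −3.3, 0.6 for
SAM), and weights are **back-computed from the sampled WAZ through the
growth reference** — the exact inverse of the classifier's z computation,
so generated records round-trip to their target z within 10⁻⁶. SAM
(prevalence 25/251) presents through clinical signs; TB prevalence is
44/251; other comorbidity 0.13587 conditional on no TB; and the TB,
comorbidity and stage fields are masked *jointly*, completely at random, at
rate 0.11335 — after generation, so the truth remains recoverable from
`attr(cohort, "truth")`. Those four rates were calibrated jointly so the
expected plan counts over many replicates are 88 NCP-B, 25 NCP-C, 21
unassigned and 117 NCP-A out of 251. Heights and MUAC are fully missing by
default, mirroring a programme without the equipment to measure them.

What the generator does **not** emulate: correlation between TB and age or
WAZ, informative (non-random) missingness, seasonal or secular trends, and
the within-band reason composition of the NCP-B group (the calibration
targets plan counts, not reason counts). Passing tests therefore show the
pipeline recovers the *marginal* composition it was pointed at, not that it
would reproduce every cross-tabulation of a real programme database.

`fixture_cohort_2010()` is different in kind: a deterministic, hand-laid
cohort of 251 records whose classification reproduces a known composition
exactly (plan counts, reason counts, band counts, TB totals, the 92/159
age split). SAM weights are solved from per-band stabilisation-phase
calorie totals — band weight sum = kcal / (rate × 0.5 × 70) — including one
infant carried at an imputed 6.5 kg because no weight was recorded; any
weight vector matching the band totals is equally valid, and the individual
values are the package's choice. Likewise the ages of the 21 unassigned
children are a modelling choice constrained only by the overall age split;
because the upper-limit estimate (all unassigned treated as NCP-B) depends
on those unknown ages, the default config carries the increment as a
supplied constant (`upper_limit_increment_zar`), with
`upper_limit_mode = "derive"` recomputing it from ages when they are
trusted.

## Numerical and degenerate-input choices

* Rounding: half away from zero with the 6-decimal pre-snap described
  above; percentages to 1 decimal; whole-currency totals.
* A missing measurement is data, never an exception; errors are reserved
  for structurally invalid input (ages outside 6–179 months, non-positive
  weights, duplicate child identifiers, non-chronological visit dates,
  out-of-range growth-reference lookups, unknown products).
* Empty cohorts yield a zero-cost summary; plan-A and unassigned children
  yield empty (zero-cost) courses, not errors.
* All randomness flows through a single seed in `cohort_spec()`; the RNG
  state is restored afterwards, and re-running the pipeline on fixed inputs
  is byte-identical apart from the log timestamp.

## Problem sizes used by the test suite

The suite exercises the classifier invariants on 1,000 randomized records,
generator calibration on 200 replicates of 251 children, and oracle
equivalence of the z-score path on every bundled reference row at five
measurement multiples; the full costing tables are reproduced from the
251-child fixture. These sizes were chosen to make sampling error in the
calibration checks small relative to the asserted tolerances.

## Limitations

The package costs *purchases only*: staff training, transport, storage,
wastage, inpatient care and carers' opportunity costs are out of scope, as
are procurement logistics and multi-year budget projection with
discounting. ART eligibility itself is taken as given — the cohort is
assumed to be initiating. The bundled growth reference is synthetic, and
the generator's independence assumptions are stated above; conclusions
about any real programme require its own database, product prices and WHO
reference tables.
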