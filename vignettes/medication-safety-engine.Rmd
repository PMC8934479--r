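---
title: "Detecting and tracking medication-related problems with selfaudit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and tracking medication-related problems with selfaudit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(selfaudit)
```

## The problem

Primary-care populations accumulate *medication-related problems* (MRPs):
therapeutic duplications, combinations under regulatory safety alerts (the
Spanish AEMPS alerts, including the "Triple Whammy" of NSAID +
renin-angiotensin-system inhibitor + diuretic), drugs contraindicated by a
recorded diagnosis or an altered clinical value, excessive treatment
durations, drugs inadvisable in geriatrics, avoidable medication, and
polymedication in patients over 65. Clinical decision support systems
embedded in the electronic clinical workstation detect these situations from
active-prescription extracts, offer the prescriber a recommendation, and are
re-evaluated between two time points in the year — an April baseline, when
the clinical content and the incentive goals are fixed, and a December
final — so that resolved and newly generated problems can be counted. A
pay-for-performance *safety indicator* links the three most clinically
relevant MRP types (relevant duplications, regulatory safety alerts,
qualifying polymedication) to per-physician reduction goals.

`selfaudit` re-implements that pipeline as an auditable rule engine:

1. **Cohort model** (`load_cohort()`, `build_patient_state()`): validated
   tabular extracts (prescriptions, patients, diagnoses, clinical values)
   and the per-patient evaluation context at a snapshot date.
2. **Rule catalog** (`builtin_catalog()`, `load_rule_catalog()`): the
   year-versioned clinical content as data, not code.
3. **Detection engine** (`run_snapshot()`, `evaluate_rule()` and the
   dedicated detectors): one alert per problem instance, with a stable
   identity key.
4. **Resolution tracker** (`compare_snapshots()`, `compute_variation()`):
   resolved / persisting / new classification and the published variation
   arithmetic.
5. **Safety indicator** (`indicator_counts()`, `evaluate_indicator()`,
   `indicator_aggregate()`): per-physician goals and aggregates.
6. **Synthetic population** (`generate_cohort()`, `audit_ground_truth()`):
   seeded cohorts with exact ground truth.

## Conventions the engine commits to

Several conventions the published system description leaves open had to be
fixed; they are decisions of this package, encoded once and tested:

* **Drug coding** is ATC level 5; combination products carry several
  component principles. **Diagnoses** are ICD-10, matched dot-insensitively
  by prefix against named concept sets (e.g. heart failure = `I50*`)
  declared in the catalog, because the clinical criteria name concepts, not
  code lists. The packaged concept sets and the packaged drug catalog are
  illustrative defaults, not curated clinical content.
* **Activity** of a prescription at a snapshot date follows the half-open
  interval `[start_date, end_date)`: a drug started on the snapshot day is
  active, one ended on it is not. An absent end date means ongoing.
* **Age** is completed years at the snapshot date. Printed comparators are
  encoded exactly as printed: "over 65" is strict, "≥ 75 years" inclusive.
* **Doses** arrive as a single mg/day number. A dose rule never fires on a
  missing dose: the prescription is skipped and a warning is emitted.
* **Duration thresholds** use calendar-safe integers: 5 years = 1826 days,
  12 months = 365 days. For double antiplatelet therapy the clinically
  relevant quantity is the *concurrent* time on therapy, so the engine
  requires each antiplatelet drug to have reached the threshold, which
  makes the pairwise overlap (the minimum of the durations) reach it too.
* **One alert per basis.** A duplication alert is emitted per shared active
  principle, or per shared duplication-group tag when the drugs share no
  principle (the principle basis wins for pairs duplicated at both levels).
  The Triple Whammy emits at most one alert per patient, carrying the
  lexicographically smallest representative triple so its identity is
  stable across snapshots. Alert identity is
  `(patient, rule, sorted triggering drugs)`; this is what makes
  longitudinal matching possible even though the source system did not
  follow individual patients over time.
* **Polymedication thresholds** resolve a wording tension in the published
  definitions ("more than 10" vs "10 or more") as ≥ 10 drugs in 2016–2017 and
  ≥ 8 in 2018, with the comparator held in the catalog so either reading
  can be configured.
* **Resolution reasons**: a resolved alert is attributed to
  `diagnosis_resolved` when every triggering diagnosis was closed by the
  final date — the more specific event, checked first — else to
  `drug_dropped` when a triggering drug left the active prescription.
  Resolutions explained by neither channel (a dose reduction, a birthday
  crossing an age threshold) keep the default reason and are flagged
  `unattributed` rather than silently bucketed.
* **Cross-year comparisons are refused.** The clinical content changes
  yearly, so counts from different catalog years are not commensurable;
  `compare_snapshots()` raises an error instead.
* **Indicator goal form.** The goal is "a specific number of MRPs less than
  the baseline"; both an absolute count (default) and a fraction of
  baseline are supported. For the aggregate, pooled-count variation is the
  default over the mean of per-category percentages, which is the reading
  consistent with the published yearly sums.

## The year-versioned catalogs

`builtin_catalog("2016")`, `"2017"` and `"2018"` package the clinical
content: 13 regulatory-alert drug blocks per year (citalopram and
escitalopram dose/QT criteria, aliskiren, cilostazol, trimetazidine,
raloxifene/bazedoxifene, coxibs, diclofenac, aceclofenac, agomelatine,
ivabradine + verapamil, the Triple Whammy, and strontium ranelate until
2017 / canagliflozin from 2018), duration rules, the geriatric and
avoidable lists, anticholinergic combinations, clinical-variable
contraindications, eleven duplication groups (one of them, insulins, a
"dose-adjustment" duplication that is detected but not indicator-linked),
and the year's polymedication rule. Rules live in YAML; validation is
total, so a malformed catalog fails with an error naming the rule and
field, never a crash.

```{r catalogs}
builtin_catalog("2016")
builtin_catalog("2018")$polymedication_threshold
```

## What the synthetic generator emulates

No real extract can ship with the package, so `generate_cohort()` builds a
primary-care population in which every alert is planted deliberately:

* each planted patient receives exactly the drugs, diagnoses, clinical
  values and age needed to satisfy *one* target rule, plus inert background
  prescriptions carrying no catalog tags — so planted triggers are
  mutually disjoint and recall / false positives are exactly measurable;
* baseline-planted problems resolve before the final snapshot with
  probability `resolution_probability` (default 0.35, between the
  published 9% overall and 41% indicator-linked yearly resolutions), split
  80/20 between drug withdrawal and diagnosis closure
  (`drug_dropped_fraction` = 0.8: withdrawal is the dominant published
  resolution channel); the diagnosis channel applies only to plants that
  carry a diagnosis;
* previously clean patients gain a new problem with probability
  `new_mrp_rate` (default 0.05); duration-based rules are excluded there
  because a between-snapshot onset cannot satisfy a multi-month duration
  threshold;
* default prevalence spreads a total of 0.5 uniformly over all plantable
  targets, and one planted problem per patient keeps triggers disjoint
  (prevalences summing above 1 are refused);
* dates default to the April 1 / December 1 convention of the catalog
  year; all randomness derives from one integer seed and the global random
  state is restored afterwards.

What it does **not** emulate: demographic realism, realistic
drug-utilization frequencies, co-occurring problems in one patient
(available only through manual editing, as the audit tests do), seasonal
prescribing, or the post-evaluation rebound of the real system. Passing
recall/recovery tests therefore demonstrate the *engine's* correctness on
controlled inputs, not detection performance on real extracts.

```{r generate}
cat16 <- builtin_catalog("2016")
sim <- generate_cohort(generator_config(n_patients = 300, seed = 42), cat16)
audit_ground_truth(sim$cohort, cat16, sim$ground_truth)
```

## Longitudinal tracking and the indicator

```{r longitudinal}
sb <- run_snapshot(sim$cohort, cat16, sim$baseline_date)
sf <- run_snapshot(sim$cohort, cat16, sim$final_date)
cmp <- compare_snapshots(sb, sf, sim$cohort)
glance(cmp)
head(build_category_report(cmp))

cfg <- indicator_config("2016", goal_reduction = 1)
ind <- evaluate_indicator(
  sb, lapply(cfg$checkpoint_dates, function(d)
    run_snapshot(sim$cohort, cat16, d)), cfg)
head(glance(ind))
```

`tidy()` / `glance()` methods return tibbles for every result type, and
`autoplot()` draws the standard summaries (per-category counts, baseline
vs final, per-physician indicator outcomes).

## Verifying the published arithmetic

The published evaluation printed April/December counts per problem
category and per regulatory alert, prevalence among ~9.5 million active
prescriptions, and indicator-linked resolution sums.
`verify_reported_arithmetic()` treats those printed counts (packaged under
`inst/extdata/reported/`) as inputs and recomputes every variation,
percentage, share and sum with the package's own arithmetic:

```{r verify}
verify_reported_arithmetic()
```

Printed cells whose published value is internally inconsistent (a handful
of percentage cells disagree between the published tables and their
accompanying text, or use a different denominator than the rest of the
table) are omitted from the fixture rather than guessed.

## Numerical choices and problem sizes

Percentages round half away from zero (−65.64 → −66, 2.25 → 2.3), which
reproduces every checkable printed cell; base R's round-half-to-even does
not. A percentage variation on a zero baseline is an error, not a NaN —
except `0/0`, reported as 0. Alert tables are always ordered by
`(patient, rule, identity key)`, so equal inputs give byte-identical
outputs.

The test suite exercises the engine against independent brute-force
oracles on 1000 random patient states, recovers planted alerts on
2000-patient cohorts under the 2016 and 2018 catalogs, and replays
longitudinal recovery over 10 seeds at 250 patients; these sizes keep the
binomial planting counts large enough (≈ 25+ expected instances per rule
at n = 2000) for every rule to be exercised while the whole suite stays
fast.

## Known limitations

* The drug catalog and ICD-10 concept sets are small illustrative
  defaults; production use requires a curated formulary and code lists.
* Dose rules see one daily dose per prescription; regimen parsing
  (alternating doses, PRN) is out of scope.
* The engine evaluates snapshots; it is not an online prescribing-time
  alert system.
* Identity-based resolution tracking will count a switch to a different
  drug within the same rule as a resolution plus a new problem, which is
  also how the published two-point accounting behaves.
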