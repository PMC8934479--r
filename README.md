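# selfaudit

A medication-safety rule engine for primary-care prescription audits.

Electronic prescribing systems accumulate *medication-related problems*
(MRPs): therapeutic duplications, drug combinations under regulatory safety
alerts (the "Triple Whammy" of NSAID + renin-angiotensin-system inhibitor +
diuretic being the largest), drugs contraindicated by a recorded diagnosis
or an altered clinical value (potassium, glomerular filtration), excessive
treatment durations, drugs inadvisable in geriatrics, avoidable medication,
and polymedication in patients over 65. `selfaudit` is for
pharmacoepidemiologists and medication-safety teams who want to detect
these problems in active-prescription snapshots, track their resolution
between two time points, and compute an incentive-based per-physician
safety indicator — with a declarative, year-versioned rule catalog and a
seeded synthetic-cohort generator so every step is testable without real
patient data.

## The model

A cohort is four tables: prescriptions (patient, ATC level-5 drug code,
daily dose in mg, `[start, end)` interval), patients (assigned physician,
birth date, sex), diagnoses (ICD-10, onset/resolution dates) and clinical
values. At a snapshot date *t*, a patient's state is their completed age,
the prescriptions active at *t* under the half-open convention, the open
diagnoses, and the latest clinical value per variable.

The rule catalog of year *y* is data, not code: dose thresholds with age or
comorbidity qualifiers (citalopram > 40 mg/day; > 20 mg/day over age 65 or
with liver dysfunction), age restrictions (agomelatine ≥ 75), comorbidity
contraindications over named ICD-10 concept sets, co-prescription rules
(ivabradine + verapamil; cilostazol + two other antiplatelet agents),
clinical-variable rules, list memberships, duration rules (bisphosphonates
≥ 1826 days; double antiplatelet therapy ≥ 365 days concurrent), the
composite Triple Whammy (three groups + age ≥ 75 or antidiabetic
treatment), duplication groups and the polymedication rule (> 65 years,
≥ 10 drugs in 2016–17 / ≥ 8 in 2018, plus a qualifying sub-alert). Each
detected problem is one alert with identity
`(patient, rule, sorted triggering drugs)`.

Between an April baseline and a December final snapshot, an alert is
**resolved** when its identity key disappears — attributed to the
triggering diagnosis being closed, else to a triggering drug leaving the
prescription — **persisting** when it remains, and **new** when it appears.
Counts per category give the published arithmetic: `variation = final −
baseline` and `pct = 100·variation/baseline`, rounded half away from zero.
The safety indicator counts only high-relevance duplications, regulatory
alerts and polymedication, grouped by physician, with a goal of a fixed
reduction below the physician's April count.

## Worked example

```r
library(selfaudit)

cat16 <- builtin_catalog("2016")
sim <- generate_cohort(generator_config(n_patients = 500, seed = 2024), cat16)

sb <- run_snapshot(sim$cohort, cat16, sim$baseline_date)
sb
#> <sa_snapshot> 2016-04-01 (catalog 2016): 256 alerts in 8 categories

sf  <- run_snapshot(sim$cohort, cat16, sim$final_date)
cmp <- compare_snapshots(sb, sf, sim$cohort)
glance(cmp)
#>   baseline_date final_date year_label n_baseline n_final n_resolved
#> 1    2016-04-01 2016-12-01       2016        256     167        100
#>   n_persisting n_new variation pct
#> 1          156    11       -89 -35
```

256 problems were detected in April; by December 100 had resolved, 11 new
ones appeared, so the net variation is −89 (−35%). Per category:

```r
build_category_report(cmp)
#>   year                    category baseline final variation pct
#> 1 2016                 aemps_alert      112    73       -39 -35
#> 2 2016 anticholinergic_combination       12     7        -5 -42
#> ...
#> 9 2016                       Total      256   167       -89 -35
```

The generator records every planted alert, so the engine can be audited
exactly — recall 1 and zero unplanned alerts on a fresh cohort:

```r
audit_ground_truth(sim$cohort, cat16, sim$ground_truth)
#> <sa_audit> recall 1, 0 unplanned alert(s)
```

The same arithmetic applied to the published deployment counts:

```r
compute_variation(46242, 41589)   # duplications, April -> December 2016
#>   baseline final variation   pct
#> 1    46242 41589     -4653   -10
mrp_prevalence(210916, 9.5e6)     # problems per active prescription, 2016
#> [1] 2.2
```

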