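Package: selfaudit
Title: Medication-Safety Rule Engine for Primary-Care Prescription Audits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects medication-related problems (MRPs) in active-prescription
    snapshots of a primary-care population using a declarative, year-versioned
    rule catalog (therapeutic duplications, regulatory safety alerts such as the
    Triple Whammy, clinical-variable contraindications, excessive treatment
    duration, drugs inadvisable in geriatrics, avoidable medication, and
    polymedication in the elderly). Tracks the resolution of each detected
    problem between two snapshot dates, distinguishing drug withdrawal from
    diagnosis resolution, and computes an incentive-based per-physician safety
    indicator over the three most clinically relevant problem types. Includes a
    seeded synthetic-cohort generator with ground-truth bookkeeping so
    detection recall, false-positive rates and longitudinal recovery are
    exactly measurable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
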