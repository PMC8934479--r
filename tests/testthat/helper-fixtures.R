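## Shared fixture builders. Everything is constructed in code; no data files.

empty_rx_tbl <- function() {
  tibble::tibble(patient_id = character(), drug_code = character(),
                 daily_dose_mg = numeric(),
                 start_date = as.Date(character()),
                 end_date = as.Date(character()))
}

empty_dx_tbl <- function() {
  tibble::tibble(patient_id = character(), icd10_code = character(),
                 onset_date = as.Date(character()),
                 resolved_date = as.Date(character()))
}

empty_cl_tbl <- function() {
  tibble::tibble(patient_id = character(), variable_code = character(),
                 value = numeric(), measured_date = as.Date(character()))
}

mini_cohort <- function(patients, prescriptions = NULL, diagnoses = NULL,
                        clinical = NULL) {
  load_cohort(
    prescriptions = if (is.null(prescriptions)) empty_rx_tbl() else prescriptions,
    patients = patients,
    diagnoses = if (is.null(diagnoses)) empty_dx_tbl() else diagnoses,
    clinical = clinical,
    drug_catalog = builtin_drug_catalog()
  )
}

## One-patient evaluation context. `drugs` is a list of list(code, dose,
## start_offset, end_offset) entries (positional, later entries optional:
## dose defaults NA, start -180 days, end open).
state_with <- function(drugs = list(), age = 60, dxs = character(0),
                       clinical = NULL, date = "2016-06-01") {
  date <- as.Date(date)
  yr <- as.integer(format(date, "%Y"))
  patients <- tibble::tibble(
    patient_id = "P1", physician_id = "D1",
    birth_date = as.Date(sprintf("%d-01-15", yr - age)), sex = "female")
  rx <- if (length(drugs)) {
    tibble::tibble(
      patient_id = "P1",
      drug_code = vapply(drugs, function(d) as.character(d[[1]]), character(1)),
      daily_dose_mg = vapply(drugs, function(d)
        if (length(d) >= 2) as.numeric(d[[2]]) else NA_real_, numeric(1)),
      start_date = date + vapply(drugs, function(d)
        if (length(d) >= 3) as.integer(d[[3]]) else -180L, integer(1)),
      end_date = date + vapply(drugs, function(d)
        if (length(d) >= 4 && !is.na(d[[4]])) as.integer(d[[4]]) else
          NA_integer_, integer(1)))
  } else empty_rx_tbl()
  dx <- if (length(dxs)) {
    tibble::tibble(patient_id = "P1", icd10_code = dxs,
                   onset_date = date - 400L,
                   resolved_date = as.Date(NA))
  } else empty_dx_tbl()
  cl <- if (!is.null(clinical)) {
    tibble::tibble(patient_id = "P1",
                   variable_code = names(clinical),
                   value = as.numeric(clinical),
                   measured_date = date - 30L)
  } else empty_cl_tbl()
  cohort <- mini_cohort(patients, rx, dx, cl)
  build_patient_state(cohort, "P1", date)
}

get_rule <- function(catalog, rule_id) {
  for (r in catalog$rules) if (identical(r$rule_id, rule_id)) return(r)
  stop("no rule ", rule_id)
}

rule_ids <- function(catalog) {
  vapply(catalog$rules, function(r) r$rule_id, character(1))
}

## Synthetic snapshot carrying b indicator-linked alerts per physician;
## used to exercise the indicator arithmetic without a cohort.
counts_snapshot <- function(counts, date, year_label = "2016") {
  rows <- lapply(names(counts), function(phys) {
    b <- counts[[phys]]
    if (b == 0) return(NULL)
    tibble::tibble(
      patient_id = paste0("P_", phys, "_", seq_len(b)),
      physician_id = phys,
      rule_id = "cital_dose_high",
      category = "aemps_alert",
      relevance = "high",
      indicator_linked = TRUE,
      triggering_drugs = "N06AB04",
      triggering_diagnoses = "",
      snapshot_date = as.Date(date),
      identity_key = paste0("P_", phys, "_", seq_len(b),
                            "|cital_dose_high|N06AB04"))
  })
  alerts <- dplyr::bind_rows(rows)
  if (!nrow(alerts)) {
    alerts <- tibble::tibble(
      patient_id = character(), physician_id = character(),
      rule_id = character(), category = character(), relevance = character(),
      indicator_linked = logical(), triggering_drugs = character(),
      triggering_diagnoses = character(),
      snapshot_date = as.Date(character()), identity_key = character())
  }
  structure(
    list(snapshot_date = as.Date(date), year_label = year_label,
         alerts = alerts,
         per_category_counts = dplyr::count(alerts, category,
                                            name = "n_alerts"),
         per_physician_counts = dplyr::count(alerts, physician_id,
                                             name = "n_alerts")),
    class = "sa_snapshot")
}
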