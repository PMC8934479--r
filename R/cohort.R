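#' Load and validate a prescription cohort
#'
#' Reads the four tabular extracts that emulate an electronic clinical
#' workstation — active prescriptions, patient demographics, diagnoses and
#' clinical-variable measurements — cross-validates them, and returns a
#' cohort container every other function in the package consumes.
#'
#' Each argument may be a file path to a CSV or a data frame with the same
#' columns, so generated cohorts can be passed without touching disk.
#' Expected columns:
#'
#' * `patients`: `patient_id, physician_id, birth_date, sex`
#' * `prescriptions`: `patient_id, drug_code, daily_dose_mg, start_date, end_date`
#'   (empty `end_date` = ongoing; empty `daily_dose_mg` allowed)
#' * `diagnoses`: `patient_id, icd10_code, onset_date, resolved_date`
#'   (empty `resolved_date` = still active)
#' * `clinical`: `patient_id, variable_code, value, measured_date`
#'
#' Structural problems (a missing column, a duplicated `patient_id`) abort.
#' Row-level problems — an unparseable date, a drug code that is not ATC
#' level 5, a record that references an unknown patient or predates the
#' patient's birth — reject that row; every rejection is listed with its file
#' and row number in the attached validation report.
#'
#' @param prescriptions,patients,diagnoses File path or data frame.
#' @param clinical File path or data frame, or `NULL` when no
#'   clinical-variable extract exists.
#' @param drug_catalog A drug catalog tibble as returned by
#'   [builtin_drug_catalog()] or [load_drug_catalog()]; drug codes absent
#'   from it are still accepted (they evaluate as untagged single-principle
#'   drugs) but are counted in the report.
#' @return An object of class `sa_cohort`: a list with tibbles `patients`,
#'   `prescriptions`, `diagnoses`, `clinical`, the `drug_catalog`, and a
#'   `report` tibble (one row per file: records read / accepted / rejected)
#'   whose `"rejects"` attribute details each rejected row.
#' @examples
#' cat <- builtin_catalog("2016")
#' sim <- generate_cohort(generator_config(n_patients = 20, seed = 1), cat)
#' cohort <- sim$cohort
#' cohort$report
#' @export
load_cohort <- function(prescriptions, patients, diagnoses, clinical = NULL,
                        drug_catalog = builtin_drug_catalog()) {
  pat <- read_extract(patients, "patients.csv",
                      c("patient_id", "physician_id", "birth_date", "sex"))
  rx  <- read_extract(prescriptions, "prescriptions.csv",
                      c("patient_id", "drug_code", "daily_dose_mg",
                        "start_date", "end_date"))
  dx  <- read_extract(diagnoses, "diagnoses.csv",
                      c("patient_id", "icd10_code", "onset_date",
                        "resolved_date"))
  cl <- if (is.null(clinical)) {
    tibble::tibble(patient_id = character(), variable_code = character(),
                   value = numeric(), measured_date = as.Date(character()))
  } else {
    read_extract(clinical, "clinical.csv",
                 c("patient_id", "variable_code", "value", "measured_date"))
  }

  rejects <- list()
  note <- function(file, rows, reason) {
    if (length(rows) == 0) return()
    rejects[[length(rejects) + 1]] <<-
      tibble::tibble(file = file, row = rows, reason = reason)
  }

  ## -- patients ------------------------------------------------------------
  if (anyDuplicated(pat$patient_id)) {
    dup <- unique(pat$patient_id[duplicated(pat$patient_id)])
    abort(paste0("duplicate patient_id in patients file: ",
                 paste(utils::head(dup, 5), collapse = ", ")))
  }
  n_pat_read <- nrow(pat)
  pat$birth_date <- as_date_strict(pat$birth_date)
  bad <- which(is.na(pat$birth_date))
  note("patients.csv", bad, "unparseable birth_date")
  bad_sex <- which(!pat$sex %in% c("female", "male", "unknown"))
  note("patients.csv", bad_sex, "sex not one of female/male/unknown")
  pat <- pat[setdiff(seq_len(nrow(pat)), union(bad, bad_sex)), ]

  birth_of <- stats::setNames(pat$birth_date, pat$patient_id)
  known <- pat$patient_id

  ## -- prescriptions -------------------------------------------------------
  n_rx_read <- nrow(rx)
  rx$daily_dose_mg <- suppressWarnings(as.numeric(rx$daily_dose_mg))
  rx$start_date <- as_date_strict(rx$start_date)
  rx$end_date <- as_date_strict(rx$end_date)
  drop <- integer(0)
  mark <- function(drop, idx, file, reason) {
    idx <- setdiff(idx, drop)
    note(file, idx, reason)
    union(drop, idx)
  }
  drop <- mark(drop, which(is.na(rx$start_date)),
               "prescriptions.csv", "unparseable start_date")
  drop <- mark(drop, which(!rx$patient_id %in% known),
               "prescriptions.csv", "unknown patient_id")
  drop <- mark(drop, which(!is_atc5(rx$drug_code)),
               "prescriptions.csv", "drug_code not an ATC level-5 code")
  drop <- mark(drop, which(!is.na(rx$end_date) & rx$end_date < rx$start_date),
               "prescriptions.csv", "end_date before start_date")
  drop <- mark(drop, which(!is.na(rx$daily_dose_mg) & rx$daily_dose_mg < 0),
               "prescriptions.csv", "negative daily_dose_mg")
  drop <- mark(drop,
               which(rx$patient_id %in% known &
                       rx$start_date <= birth_of[rx$patient_id]),
               "prescriptions.csv", "start_date not after birth_date")
  rx <- rx[setdiff(seq_len(nrow(rx)), drop), ]

  ## -- diagnoses -----------------------------------------------------------
  n_dx_read <- nrow(dx)
  dx$onset_date <- as_date_strict(dx$onset_date)
  dx$resolved_date <- as_date_strict(dx$resolved_date)
  drop <- integer(0)
  drop <- mark(drop, which(is.na(dx$onset_date)),
               "diagnoses.csv", "unparseable onset_date")
  drop <- mark(drop, which(!dx$patient_id %in% known),
               "diagnoses.csv", "unknown patient_id")
  drop <- mark(drop, which(!is.na(dx$resolved_date) &
                             dx$resolved_date < dx$onset_date),
               "diagnoses.csv", "resolved_date before onset_date")
  drop <- mark(drop,
               which(dx$patient_id %in% known &
                       dx$onset_date <= birth_of[dx$patient_id]),
               "diagnoses.csv", "onset_date not after birth_date")
  dx <- dx[setdiff(seq_len(nrow(dx)), drop), ]

  ## -- clinical ------------------------------------------------------------
  n_cl_read <- nrow(cl)
  cl$value <- suppressWarnings(as.numeric(cl$value))
  cl$measured_date <- as_date_strict(cl$measured_date)
  drop <- integer(0)
  drop <- mark(drop, which(is.na(cl$measured_date)),
               "clinical.csv", "unparseable measured_date")
  drop <- mark(drop, which(!cl$patient_id %in% known),
               "clinical.csv", "unknown patient_id")
  drop <- mark(drop,
               which(cl$variable_code %in% c("potassium", "egfr") &
                       (!is.finite(cl$value) | cl$value < 0)),
               "clinical.csv", "potassium/egfr value not finite non-negative")
  cl <- cl[setdiff(seq_len(nrow(cl)), drop), ]

  rejects <- if (length(rejects)) dplyr::bind_rows(rejects) else
    tibble::tibble(file = character(), row = integer(), reason = character())

  report <- tibble::tibble(
    file = c("patients.csv", "prescriptions.csv", "diagnoses.csv",
             "clinical.csv"),
    read = c(n_pat_read, n_rx_read, n_dx_read, n_cl_read),
    accepted = c(nrow(pat), nrow(rx), nrow(dx), nrow(cl))
  )
  report$rejected <- report$read - report$accepted
  attr(report, "rejects") <- rejects
  attr(report, "unknown_drug_codes") <-
    sort(setdiff(unique(rx$drug_code), drug_catalog$drug_code))

  structure(
    list(patients = tibble::as_tibble(pat),
         prescriptions = tibble::as_tibble(rx),
         diagnoses = tibble::as_tibble(dx),
         clinical = tibble::as_tibble(cl),
         drug_catalog = drug_catalog,
         report = report),
    class = "sa_cohort"
  )
}

read_extract <- function(x, label, required) {
  df <- if (is.character(x) && length(x) == 1) {
    if (!file.exists(x)) abort(paste0("file not found: ", x))
    readr::read_csv(x, col_types = readr::cols(.default = readr::col_character()),
                    progress = FALSE)
  } else if (is.data.frame(x)) {
    x
  } else {
    abort(paste0(label, ": expected a file path or a data frame"))
  }
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    abort(paste0(label, ": missing required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  df <- tibble::as_tibble(df)[required]
  df$patient_id <- as.character(df$patient_id)
  df
}

#' @export
print.sa_cohort <- function(x, ...) {
  cat("<sa_cohort> ", nrow(x$patients), " patients, ",
      nrow(x$prescriptions), " prescriptions, ",
      nrow(x$diagnoses), " diagnoses, ",
      nrow(x$clinical), " clinical measurements\n", sep = "")
  invisible(x)
}

#' Write a cohort to CSV extracts
#'
#' Serializes a cohort back to the four-file CSV layout accepted by
#' [load_cohort()], with ISO-8601 dates and empty strings for open end /
#' resolution dates.
#'
#' @param cohort An `sa_cohort`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written (named character vector).
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sa_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    patients = file.path(dir, "patients.csv"),
    prescriptions = file.path(dir, "prescriptions.csv"),
    diagnoses = file.path(dir, "diagnoses.csv"),
    clinical = file.path(dir, "clinical.csv")
  )
  readr::write_csv(cohort$patients, paths["patients"], na = "", progress = FALSE)
  readr::write_csv(cohort$prescriptions, paths["prescriptions"], na = "",
                   progress = FALSE)
  readr::write_csv(cohort$diagnoses, paths["diagnoses"], na = "",
                   progress = FALSE)
  readr::write_csv(cohort$clinical, paths["clinical"], na = "",
                   progress = FALSE)
  invisible(paths)
}

#' Load a cohort from a directory of CSV extracts
#'
#' Convenience wrapper around [load_cohort()] for the directory layout
#' written by [write_cohort()].
#'
#' @param dir Directory containing `patients.csv`, `prescriptions.csv`,
#'   `diagnoses.csv` and (optionally) `clinical.csv`.
#' @inheritParams load_cohort
#' @return An `sa_cohort`.
#' @export
load_cohort_dir <- function(dir, drug_catalog = builtin_drug_catalog()) {
  cl <- file.path(dir, "clinical.csv")
  load_cohort(
    prescriptions = file.path(dir, "prescriptions.csv"),
    patients = file.path(dir, "patients.csv"),
    diagnoses = file.path(dir, "diagnoses.csv"),
    clinical = if (file.exists(cl)) cl else NULL,
    drug_catalog = drug_catalog
  )
}

#' Build the evaluation context for one patient at one date
#'
#' Assembles everything a rule can see for a patient on a snapshot date: age
#' in completed years, the prescriptions active that day (half-open
#' convention `[start_date, end_date)`, so a prescription starting on the
#' snapshot date is active and one ending on it is not), the set of active
#' diagnoses, and the most recent clinical value per variable measured on or
#' before the date.
#'
#' @param cohort An `sa_cohort`.
#' @param patient_id Patient identifier present in the cohort.
#' @param snapshot_date A `Date` (or string coercible to one).
#' @return An object of class `sa_patient_state`: a list with `patient_id`,
#'   `physician_id`, `snapshot_date`, `age_years`, `rx` (active prescriptions
#'   with `duration_days` and catalog annotations `principles`/`tags`
#'   list-columns), `active_diagnoses` (character vector of ICD-10 codes) and
#'   `clinical` (latest value per variable).
#' @export
build_patient_state <- function(cohort, patient_id, snapshot_date) {
  stopifnot(inherits(cohort, "sa_cohort"))
  snapshot_date <- as.Date(snapshot_date)
  i <- match(patient_id, cohort$patients$patient_id)
  if (is.na(i)) abort(paste0("unknown patient_id: ", patient_id))
  make_patient_state(
    patient_id = patient_id,
    physician_id = cohort$patients$physician_id[i],
    birth_date = cohort$patients$birth_date[i],
    rx = cohort$prescriptions[cohort$prescriptions$patient_id == patient_id, ],
    dx = cohort$diagnoses[cohort$diagnoses$patient_id == patient_id, ],
    cl = cohort$clinical[cohort$clinical$patient_id == patient_id, ],
    snapshot_date = snapshot_date,
    lookup = catalog_lookup(cohort$drug_catalog)
  )
}

## Internal constructor shared with run_snapshot()'s pre-split fast path.
make_patient_state <- function(patient_id, physician_id, birth_date,
                               rx, dx, cl, snapshot_date, lookup) {
  active <- rx$start_date <= snapshot_date &
    (is.na(rx$end_date) | rx$end_date > snapshot_date)
  rx <- rx[active, , drop = FALSE]
  rx$duration_days <- as.integer(snapshot_date - rx$start_date)
  ann <- lookup(rx$drug_code)
  rx$principles <- ann$principles
  rx$tags <- ann$tags

  dx_active <- dx$onset_date <= snapshot_date &
    (is.na(dx$resolved_date) | dx$resolved_date > snapshot_date)
  active_dx <- unique(dx$icd10_code[dx_active])

  cl <- cl[cl$measured_date <= snapshot_date, , drop = FALSE]
  if (nrow(cl)) {
    cl <- cl[order(cl$variable_code, cl$measured_date), , drop = FALSE]
    cl <- cl[!duplicated(cl$variable_code, fromLast = TRUE), , drop = FALSE]
  }

  structure(
    list(patient_id = patient_id,
         physician_id = physician_id,
         snapshot_date = snapshot_date,
         age_years = age_at(birth_date, snapshot_date),
         rx = tibble::as_tibble(rx),
         active_diagnoses = active_dx,
         clinical = tibble::as_tibble(cl)),
    class = "sa_patient_state"
  )
}

#' @export
print.sa_patient_state <- function(x, ...) {
  cat("<sa_patient_state> ", x$patient_id, " @ ",
      format(x$snapshot_date), ": age ", x$age_years, ", ",
      nrow(x$rx), " active prescriptions, ",
      length(x$active_diagnoses), " active diagnoses\n", sep = "")
  invisible(x)
}

#' Assert the internal invariants of a patient state
#'
#' Checks that every active prescription straddles the snapshot date under
#' the half-open convention, that durations are consistent, that age is
#' non-negative, and that at most one clinical value per variable is kept
#' (the latest measured on or before the snapshot date). Used by the test
#' suite; aborts with a message on the first violation.
#'
#' @param state An `sa_patient_state`.
#' @return `state`, invisibly.
#' @export
validate_patient_state <- function(state) {
  stopifnot(inherits(state, "sa_patient_state"))
  d <- state$snapshot_date
  if (nrow(state$rx)) {
    if (!all(state$rx$start_date <= d))
      abort("active prescription starts after snapshot_date")
    if (!all(is.na(state$rx$end_date) | state$rx$end_date > d))
      abort("active prescription ended on or before snapshot_date")
    if (!all(state$rx$duration_days == as.integer(d - state$rx$start_date)))
      abort("duration_days inconsistent with snapshot_date")
  }
  if (is.na(state$age_years) || state$age_years < 0)
    abort("age_years negative or missing")
  if (anyDuplicated(state$clinical$variable_code))
    abort("more than one latest value for a clinical variable")
  if (nrow(state$clinical) && !all(state$clinical$measured_date <= d))
    abort("clinical value measured after snapshot_date")
  invisible(state)
}
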