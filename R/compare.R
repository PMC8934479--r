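#' Variation between two counts
#'
#' The study's headline arithmetic: `variation = final - baseline`, and the
#' percentage variation `100 * variation / baseline` rounded half away from
#' zero to an integer. A zero baseline with a non-zero variation has no
#' defined percentage and raises an error; a zero baseline with zero
#' variation reports 0%.
#'
#' @param baseline_count,final_count Non-negative integer vectors (recycled
#'   to a common length).
#' @return A tibble with columns `baseline`, `final`, `variation`, `pct`.
#' @examples
#' compute_variation(46242, 41589) # -4653, -10
#' @export
compute_variation <- function(baseline_count, final_count) {
  stopifnot(all(baseline_count >= 0), all(final_count >= 0))
  n <- max(length(baseline_count), length(final_count))
  baseline <- rep_len(as.integer(baseline_count), n)
  final <- rep_len(as.integer(final_count), n)
  variation <- final - baseline
  if (any(baseline == 0 & variation != 0))
    abort("percentage variation undefined: baseline count is 0 with a non-zero variation")
  pct <- integer(n)
  nz <- baseline != 0
  pct[nz] <- as.integer(round_half_away(100 * variation[nz] / baseline[nz]))
  tibble::tibble(baseline = baseline, final = final,
                 variation = variation, pct = pct)
}

#' Problem prevalence among active prescriptions
#'
#' Share of detected medication-related problems in the total number of
#' active prescriptions, as a percentage with one decimal (half away from
#' zero).
#'
#' @param mrp_count Number of detected problems.
#' @param active_prescription_count Total active prescriptions (> 0).
#' @return A length-one numeric percentage.
#' @examples
#' mrp_prevalence(210916, 9.5e6) # 2.2
#' @export
mrp_prevalence <- function(mrp_count, active_prescription_count) {
  if (any(active_prescription_count <= 0))
    abort("active_prescription_count must be positive")
  round_half_away(100 * mrp_count / active_prescription_count, digits = 1)
}

#' Integer percentage share
#'
#' `100 * part / whole` rounded half away from zero to an integer; used for
#' shares such as "the Triple Whammy represented 89% of alerts".
#'
#' @param part,whole Numeric; `whole` must be non-zero.
#' @return Integer percentage.
#' @export
pct_share <- function(part, whole) {
  if (any(whole == 0)) abort("whole must be non-zero")
  as.integer(round_half_away(100 * part / whole))
}

#' Compare two snapshots of the same catalog year
#'
#' Classifies every baseline alert as resolved or persisting by its identity
#' key (patient, rule, triggering drug set) and collects the alerts newly
#' present at the final date. A resolved alert's reason is
#' `diagnosis_resolved` when every triggering diagnosis is registered as
#' resolved on or before the final date — the more specific event, checked
#' first — otherwise `drug_dropped` when at least one triggering drug is no
#' longer on the patient's active prescription. Resolutions explained by
#' neither channel (e.g. a dose reduction or a crossed age threshold) keep
#' the default `drug_dropped` reason and are flagged `unattributed`.
#'
#' Snapshots from different catalog years refuse to compare: the clinical
#' content differs, so the counts are not commensurable.
#'
#' @param baseline,final `sa_snapshot` objects with
#'   `baseline$snapshot_date < final$snapshot_date` and equal `year_label`.
#' @param cohort_at_final The `sa_cohort` describing prescriptions and
#'   diagnoses as of the final date (used to attribute resolution reasons).
#' @return An object of class `sa_comparison`: list with `baseline_date`,
#'   `final_date`, `year_label`, tibbles `resolved` (with
#'   `resolution_reason`, `unattributed`), `persisting`, `new`, and
#'   `per_category_variation`.
#' @export
compare_snapshots <- function(baseline, final, cohort_at_final) {
  stopifnot(inherits(baseline, "sa_snapshot"), inherits(final, "sa_snapshot"),
            inherits(cohort_at_final, "sa_cohort"))
  if (!identical(baseline$year_label, final$year_label))
    abort(paste0("snapshots come from different catalog years (",
                 baseline$year_label, " vs ", final$year_label,
                 "); cross-year comparison is not meaningful"))
  if (!(baseline$snapshot_date < final$snapshot_date))
    abort("baseline snapshot must predate the final snapshot")

  b <- baseline$alerts
  f <- final$alerts
  gone <- !b$identity_key %in% f$identity_key
  resolved <- b[gone, ]
  persisting <- b[!gone, ]
  new <- f[!f$identity_key %in% b$identity_key, ]

  if (nrow(resolved)) {
    reasons <- attribute_resolutions(resolved, cohort_at_final,
                                     final$snapshot_date)
    resolved$resolution_reason <- reasons$reason
    resolved$unattributed <- reasons$unattributed
  } else {
    resolved$resolution_reason <- character(0)
    resolved$unattributed <- logical(0)
  }

  cats <- sort(unique(c(b$category, f$category)))
  per_cat <- compute_variation(
    vapply(cats, function(cc) sum(b$category == cc), integer(1)),
    vapply(cats, function(cc) sum(f$category == cc), integer(1))
  )
  per_cat <- tibble::tibble(category = cats, per_cat)

  structure(
    list(baseline_date = baseline$snapshot_date,
         final_date = final$snapshot_date,
         year_label = baseline$year_label,
         resolved = resolved, persisting = persisting, new = new,
         per_category_variation = per_cat),
    class = "sa_comparison"
  )
}

attribute_resolutions <- function(resolved, cohort, final_date) {
  dx_tab <- cohort$diagnoses
  rx_tab <- cohort$prescriptions
  reason <- character(nrow(resolved))
  unattributed <- logical(nrow(resolved))
  for (i in seq_len(nrow(resolved))) {
    pid <- resolved$patient_id[i]
    dxs <- split_codes(resolved$triggering_diagnoses[i])
    drugs <- split_codes(resolved$triggering_drugs[i])

    dx_resolved <- length(dxs) > 0 && all(vapply(dxs, function(code) {
      rows <- dx_tab$patient_id == pid & dx_tab$icd10_code == code
      any(rows) && all(!is.na(dx_tab$resolved_date[rows]) &
                         dx_tab$resolved_date[rows] <= final_date)
    }, logical(1)))
    if (dx_resolved) {
      reason[i] <- "diagnosis_resolved"
      next
    }
    drug_gone <- length(drugs) > 0 && any(vapply(drugs, function(code) {
      rows <- rx_tab$patient_id == pid & rx_tab$drug_code == code
      !any(rows & rx_tab$start_date <= final_date &
             (is.na(rx_tab$end_date) | rx_tab$end_date > final_date))
    }, logical(1)))
    reason[i] <- "drug_dropped"
    unattributed[i] <- !drug_gone
  }
  list(reason = reason, unattributed = unattributed)
}

#' @export
print.sa_comparison <- function(x, ...) {
  cat("<sa_comparison> ", format(x$baseline_date), " -> ",
      format(x$final_date), " (catalog ", x$year_label, "): ",
      nrow(x$resolved), " resolved, ", nrow(x$persisting), " persisting, ",
      nrow(x$new), " new\n", sep = "")
  invisible(x)
}

#' Per-category report across one or more snapshot comparisons
#'
#' One row per category and comparison with baseline, final, variation and
#' percentage, plus a `Total` row per comparison whose entries are the
#' column sums (the percentage is recomputed from the summed counts, as in
#' the published tables).
#'
#' @param comparisons A single `sa_comparison` or a list of them; list names
#'   label the `year` column (defaulting to each comparison's year label).
#' @return A tibble with columns `year`, `category`, `baseline`, `final`,
#'   `variation`, `pct`.
#' @export
build_category_report <- function(comparisons) {
  if (inherits(comparisons, "sa_comparison")) comparisons <- list(comparisons)
  labels <- names(comparisons) %||%
    vapply(comparisons, function(x) x$year_label, character(1))
  if (is.null(names(comparisons))) names(comparisons) <- labels

  purrr::list_rbind(purrr::imap(comparisons, function(cmp, label) {
    tab <- cmp$per_category_variation
    total <- compute_variation(sum(tab$baseline), sum(tab$final))
    dplyr::bind_rows(
      tibble::tibble(year = label, tab),
      tibble::tibble(year = label, category = "Total", total)
    )
  }))
}
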