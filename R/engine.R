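## Alert assembly ------------------------------------------------------------
##
## Internally alerts travel as plain list "records" and are materialized into
## a tibble once per patient/snapshot; building a tibble per alert is two
## orders of magnitude slower and dominates cohort-scale runs.

.empty_alerts <- tibble::tibble(
  patient_id = character(), physician_id = character(),
  rule_id = character(), category = character(), relevance = character(),
  indicator_linked = logical(), triggering_drugs = character(),
  triggering_diagnoses = character(), snapshot_date = as.Date(character()),
  identity_key = character()
)

empty_alerts <- function() .empty_alerts

new_record <- function(state, rule_id, category, relevance, indicator_linked,
                       drugs, diagnoses = character(0)) {
  drugs <- sort(unique(drugs))
  list(
    patient_id = state$patient_id,
    physician_id = state$physician_id %||% NA_character_,
    rule_id = rule_id,
    category = category,
    relevance = relevance,
    indicator_linked = indicator_linked,
    triggering_drugs = paste(drugs, collapse = "|"),
    triggering_diagnoses = paste(sort(unique(diagnoses)), collapse = "|"),
    snapshot_date = as.numeric(state$snapshot_date),
    identity_key = paste(state$patient_id, rule_id,
                         paste(drugs, collapse = "+"), sep = "|")
  )
}

records_to_tibble <- function(recs) {
  if (!length(recs)) return(.empty_alerts)
  chr <- function(f) vapply(recs, `[[`, character(1), f)
  out <- tibble::new_tibble(list(
    patient_id = chr("patient_id"),
    physician_id = chr("physician_id"),
    rule_id = chr("rule_id"),
    category = chr("category"),
    relevance = chr("relevance"),
    indicator_linked = vapply(recs, `[[`, logical(1), "indicator_linked"),
    triggering_drugs = chr("triggering_drugs"),
    triggering_diagnoses = chr("triggering_diagnoses"),
    snapshot_date = as.Date(vapply(recs, `[[`, numeric(1), "snapshot_date"),
                            origin = "1970-01-01"),
    identity_key = chr("identity_key")
  ), nrow = length(recs))
  out[order(out$rule_id, out$identity_key), ]
}

## Distinct active drug codes matched by a {codes: [...]} / {tag: x} spec.
matched_codes <- function(state, spec) {
  codes <- state$rx$drug_code
  if (!is.null(spec$codes)) {
    sort(unique(codes[codes %in% unlist(spec$codes)]))
  } else {
    tag <- spec$tag
    hit <- vapply(state$rx$tags, function(t) tag %in% t, logical(1))
    sort(unique(codes[hit]))
  }
}

concept_prefixes <- function(catalog, concepts) {
  unique(unlist(catalog$icd10_concept_sets[unlist(concepts)]))
}

matching_diagnoses <- function(state, catalog, concepts) {
  dx <- state$active_diagnoses
  if (!length(dx)) return(character(0))
  sort(unique(dx[icd10_matches(dx, concept_prefixes(catalog, concepts))]))
}

## Record-producing rule evaluators ------------------------------------------

rule_records <- function(rule, state, catalog) {
  p <- rule$parameters
  mk <- function(drugs, dx = character(0)) {
    new_record(state, rule$rule_id, rule$category, rule$relevance,
               rule$indicator_linked, drugs, dx)
  }
  switch(rule$kind,
    dose_threshold = {
      codes <- matched_codes(state, p)
      out <- list()
      for (code in codes) {
        doses <- state$rx$daily_dose_mg[state$rx$drug_code == code]
        if (anyNA(doses))
          warn(paste0("rule ", rule$rule_id, ": prescription of ", code,
                      " for ", state$patient_id,
                      " has no daily_dose_mg; skipped"),
               class = "selfaudit_missing_dose")
        if (!any(doses > p$threshold_mg_per_day, na.rm = TRUE)) next
        if (!is.null(p$age) &&
              !cmp_apply(state$age_years, p$age$comparator, p$age$years)) next
        dx <- character(0)
        if (!is.null(p$concept)) {
          dx <- matching_diagnoses(state, catalog, p$concept)
          if (!length(dx)) next
        }
        out[[length(out) + 1]] <- mk(code, dx)
      }
      out
    },
    age_restriction = {
      if (cmp_apply(state$age_years, p$age$comparator, p$age$years)) {
        lapply(matched_codes(state, p), mk)
      } else list()
    },
    comorbidity_contraindication = {
      dx <- matching_diagnoses(state, catalog, p$concepts)
      if (length(dx)) lapply(matched_codes(state, p), mk, dx = dx) else list()
    },
    co_prescription = {
      lapply(co_prescription_sets(state, p$groups), mk)
    },
    clinical_variable = {
      i <- match(p$variable, state$clinical$variable_code)
      if (!is.na(i) &&
            cmp_apply(state$clinical$value[i], p$comparator, p$threshold)) {
        lapply(matched_codes(state, p), mk)
      } else list()
    },
    list_membership = {
      lapply(matched_codes(state, p), mk)
    },
    abort(paste0("rule kind '", rule$kind, "' has a dedicated operation"))
  )
}

## All distinct drug sets satisfying a co-prescription group spec: choose
## min_count distinct codes from each group, all distinct across groups.
co_prescription_sets <- function(state, groups) {
  cand <- lapply(groups, matched_codes, state = state)
  k <- vapply(groups, function(g) as.integer(g$min_count %||% 1L), integer(1))
  if (any(lengths(cand) < k)) return(list())
  per_group <- Map(function(cds, kk) utils::combn(cds, kk, simplify = FALSE),
                   cand, k)
  sets <- Reduce(function(acc, choices) {
    out <- list()
    for (a in acc) for (ch in choices) {
      if (!any(ch %in% a)) out[[length(out) + 1]] <- c(a, ch)
    }
    out
  }, per_group, init = list(character(0)))
  unique(lapply(sets, function(s) sort(unique(s))))
}

tw_records <- function(state, rule, catalog) {
  p <- rule$parameters
  qualifies <- cmp_apply(state$age_years, p$age$comparator, p$age$years) ||
    length(matched_codes(state, list(tag = p$treatment_tag))) > 0
  if (!qualifies) return(list())
  cand <- list(matched_codes(state, list(tag = p$groups$nsaid)),
               matched_codes(state, list(tag = p$groups$ras)),
               matched_codes(state, list(tag = p$groups$diuretic)))
  if (any(lengths(cand) == 0)) return(list())
  ## smallest distinct triple in lexicographic (nsaid, ras, diuretic) order
  for (a in cand[[1]]) for (b in cand[[2]]) for (d in cand[[3]]) {
    if (length(unique(c(a, b, d))) == 3) {
      return(list(new_record(state, rule$rule_id, rule$category,
                             rule$relevance, rule$indicator_linked,
                             c(a, b, d))))
    }
  }
  list()
}

duration_records <- function(state, rule, catalog) {
  p <- rule$parameters
  codes <- matched_codes(state, p)
  long <- codes[vapply(codes, function(code) {
    any(state$rx$duration_days[state$rx$drug_code == code] >= p$min_days)
  }, logical(1))]
  mk <- function(drugs) {
    new_record(state, rule$rule_id, rule$category, rule$relevance,
               rule$indicator_linked, drugs)
  }
  if (identical(p$variant, "per_drug")) {
    lapply(long, mk)
  } else if (length(long) >= as.integer(p$min_count %||% 2L)) {
    ## concurrent: every drug in the alert has been active for min_days, so
    ## the overlap (min of the durations) also reaches min_days
    list(mk(long))
  } else {
    list()
  }
}

dup_records <- function(state, catalog) {
  rx <- state$rx
  out <- list()
  if (nrow(rx) < 2) return(out)
  ## principle bases
  pr <- unlist(rx$principles)
  row_of <- rep(seq_len(nrow(rx)), lengths(rx$principles))
  for (principle in sort(unique(pr))) {
    rows <- row_of[pr == principle]
    if (length(rows) >= 2) {
      out[[length(out) + 1]] <- new_record(
        state, paste0("dup_principle_", principle), "duplicate_therapy",
        "high", TRUE, rx$drug_code[rows])
    }
  }
  ## group-tag bases: only pairs without a shared principle
  dg <- catalog$duplication_groups
  for (g in seq_len(nrow(dg))) {
    rows <- which(vapply(rx$tags, function(t) dg$tag[g] %in% t, logical(1)))
    if (length(rows) < 2) next
    in_pair <- rep(FALSE, length(rows))
    for (i in seq_along(rows)) for (j in seq_along(rows)) {
      if (i < j &&
            !any(rx$principles[[rows[i]]] %in% rx$principles[[rows[j]]])) {
        in_pair[i] <- TRUE
        in_pair[j] <- TRUE
      }
    }
    if (any(in_pair)) {
      relevant <- dg$clinically_relevant[g]
      out[[length(out) + 1]] <- new_record(
        state, paste0("dup_group_", dg$group_id[g]), "duplicate_therapy",
        if (relevant) "high" else "low", relevant,
        rx$drug_code[rows[in_pair]])
    }
  }
  out
}

poly_records <- function(state, rule, catalog, sub_records) {
  p <- rule$parameters
  if (!cmp_apply(state$age_years, p$age$comparator, p$age$years))
    return(list())
  n_drugs <- length(unique(state$rx$drug_code))
  if (!cmp_apply(n_drugs,
                 p$count_comparator %||% catalog$polymedication_comparator,
                 catalog$polymedication_threshold))
    return(list())
  qualifying <- unlist(p$qualifying_rules)
  qual <- sub_records[vapply(sub_records, function(r)
    r$rule_id %in% qualifying, logical(1))]
  if (!length(qual)) return(list())
  drugs <- unique(unlist(lapply(qual, function(r)
    split_codes(r$triggering_drugs))))
  list(new_record(state, rule$rule_id, rule$category, rule$relevance,
                  rule$indicator_linked, drugs))
}

patient_records <- function(state, catalog) {
  simple <- c("dose_threshold", "age_restriction",
              "comorbidity_contraindication", "co_prescription",
              "clinical_variable", "list_membership")
  recs <- list()
  poly_rules <- list()
  for (rule in catalog$rules) {
    add <- if (rule$kind %in% simple) {
      rule_records(rule, state, catalog)
    } else if (rule$kind == "composite_triple_whammy") {
      tw_records(state, rule, catalog)
    } else if (rule$kind == "duration") {
      duration_records(state, rule, catalog)
    } else if (rule$kind == "polymedication") {
      poly_rules[[length(poly_rules) + 1]] <- rule
      list()
    } else {
      list()
    }
    if (length(add)) recs <- c(recs, add)
  }
  recs <- c(recs, dup_records(state, catalog))
  for (rule in poly_rules)
    recs <- c(recs, poly_records(state, rule, catalog, recs))
  recs
}

## Public rule evaluation -----------------------------------------------------

#' Evaluate one simple rule against a patient state
#'
#' Dispatches the simple rule kinds — `dose_threshold`, `age_restriction`,
#' `comorbidity_contraindication`, `co_prescription`, `clinical_variable`
#' and `list_membership` — and returns one alert per distinct triggering
#' drug set. Dose rules fire when the daily dose strictly exceeds the
#' threshold under the rule's age or comorbidity qualifier; prescriptions
#' with a missing dose are skipped with a warning (a dose alert is never
#' raised on an unknown dose). Co-prescription rules require all their drug
#' groups to be simultaneously active with distinct drugs across groups.
#' Clinical-variable rules compare the latest measurement on or before the
#' snapshot date against the rule threshold.
#'
#' The composite kinds have dedicated entry points:
#' [detect_triple_whammy()], [detect_duration()], [detect_duplications()],
#' [detect_polymedication()].
#'
#' @param rule A rule definition from an `sa_catalog`.
#' @param state An `sa_patient_state` from [build_patient_state()].
#' @param catalog The `sa_catalog` the rule came from (supplies ICD-10
#'   concept sets).
#' @return A tibble of alerts (possibly empty), ordered by
#'   `(rule_id, identity_key)`.
#' @export
evaluate_rule <- function(rule, state, catalog) {
  dedicated <- c("composite_triple_whammy", "duration", "duplication_group",
                 "polymedication")
  if (rule$kind %in% dedicated)
    abort(paste0("rule kind '", rule$kind, "' has a dedicated operation"))
  records_to_tibble(rule_records(rule, state, catalog))
}

#' Detect the Triple Whammy combination
#'
#' Fires when at least one NSAID, one renin-angiotensin-system inhibitor and
#' one diuretic are simultaneously active (three distinct drugs) and the
#' patient is 75 or older or under antidiabetic treatment. At most one alert
#' per patient is emitted, carrying the lexicographically smallest
#' representative triple so the alert identity is stable across snapshots.
#'
#' @inheritParams evaluate_rule
#' @return A tibble with zero or one alert.
#' @export
detect_triple_whammy <- function(state, rule, catalog) {
  stopifnot(identical(rule$kind, "composite_triple_whammy"))
  records_to_tibble(tw_records(state, rule, catalog))
}

#' Detect excessive treatment duration
#'
#' Two variants. `per_drug` fires one alert per tagged drug whose time on
#' prescription reaches the threshold (bisphosphonates at five years,
#' encoded as 1826 days). `concurrent` fires one alert when at least
#' `min_count` tagged drugs have each been active for the threshold time
#' (double antiplatelet therapy at 12 months, 365 days) — the pairwise
#' overlap, the minimum of the individual durations, then also reaches the
#' threshold; the alert carries every tagged drug meeting it.
#'
#' @inheritParams evaluate_rule
#' @return A tibble of alerts.
#' @export
detect_duration <- function(state, rule, catalog) {
  stopifnot(identical(rule$kind, "duration"))
  records_to_tibble(duration_records(state, rule, catalog))
}

#' Detect therapeutic duplications
#'
#' A duplication basis is either a shared active principle across two or
#' more active prescriptions (including combination products) or a shared
#' duplication-group tag across prescriptions with no common principle. One
#' alert is emitted per basis; when a pair duplicates at both levels the
#' principle basis wins. Principle-level duplications are always treated as
#' clinically relevant; group-level duplications inherit the group's
#' `clinically_relevant` flag, which decides both the relevance field and
#' the link to the safety indicator.
#'
#' @inheritParams evaluate_rule
#' @return A tibble of alerts with rule ids `dup_principle_<principle>` /
#'   `dup_group_<group_id>`.
#' @export
detect_duplications <- function(state, catalog) {
  records_to_tibble(dup_records(state, catalog))
}

#' Detect qualifying polymedication in the elderly
#'
#' Fires for patients over 65 whose count of distinct active drugs reaches
#' the catalog's polymedication threshold (10 in the 2016/2017 content, 8
#' in 2018) and who additionally present at least one qualifying problem —
#' long double antiplatelet therapy, an anticholinergic combination, or
#' avoidable medication — detected at the same snapshot. The alert's
#' triggering drugs are those of the qualifying sub-alerts, so resolving
#' the qualifying problem resolves the polymedication alert.
#'
#' @inheritParams evaluate_rule
#' @param sub_alerts Tibble of this patient's alerts from the other rules
#'   at the same snapshot date.
#' @return A tibble with zero or one alert.
#' @export
detect_polymedication <- function(state, rule, catalog, sub_alerts) {
  stopifnot(identical(rule$kind, "polymedication"))
  subs <- lapply(seq_len(nrow(sub_alerts)), function(i)
    list(rule_id = sub_alerts$rule_id[i],
         triggering_drugs = sub_alerts$triggering_drugs[i]))
  records_to_tibble(poly_records(state, rule, catalog, subs))
}

#' Evaluate every catalog rule for one patient
#'
#' Runs the full rule set against a single patient state in the order the
#' engine uses cohort-wide: simple rules, Triple Whammy, duration rules,
#' duplications, then polymedication (which consumes the earlier alerts).
#'
#' @inheritParams evaluate_rule
#' @return A tibble of alerts ordered by `(rule_id, identity_key)`.
#' @export
evaluate_patient <- function(state, catalog) {
  records_to_tibble(patient_records(state, catalog))
}

## Full snapshot -------------------------------------------------------------

#' Run a full cohort snapshot
#'
#' Builds every patient's state at the snapshot date and applies the whole
#' rule catalog, returning the alert table with per-category and
#' per-physician counts. Output is deterministic for fixed inputs: alerts
#' are ordered by `(patient_id, rule_id, identity_key)`. Missing-dose
#' warnings raised during rule evaluation are collapsed into a single
#' summary warning.
#'
#' @param cohort An `sa_cohort`.
#' @param catalog An `sa_catalog`.
#' @param snapshot_date A `Date` (or string coercible to one).
#' @return An object of class `sa_snapshot`: list with `snapshot_date`,
#'   `year_label`, `alerts` (tibble), `per_category_counts` and
#'   `per_physician_counts` tibbles.
#' @examples
#' cat <- builtin_catalog("2016")
#' sim <- generate_cohort(generator_config(n_patients = 50, seed = 7), cat)
#' snap <- run_snapshot(sim$cohort, cat, sim$baseline_date)
#' glance(snap)
#' @export
run_snapshot <- function(cohort, catalog, snapshot_date) {
  stopifnot(inherits(cohort, "sa_cohort"), inherits(catalog, "sa_catalog"))
  snapshot_date <- as.Date(snapshot_date)
  lookup <- catalog_lookup(cohort$drug_catalog)

  levels <- cohort$patients$patient_id
  rx_split <- split(cohort$prescriptions,
                    factor(cohort$prescriptions$patient_id, levels = levels))
  dx_split <- split(cohort$diagnoses,
                    factor(cohort$diagnoses$patient_id, levels = levels))
  cl_split <- split(cohort$clinical,
                    factor(cohort$clinical$patient_id, levels = levels))

  n_dose_warn <- 0L
  recs <- withCallingHandlers(
    lapply(seq_len(nrow(cohort$patients)), function(i) {
      state <- make_patient_state(
        patient_id = cohort$patients$patient_id[i],
        physician_id = cohort$patients$physician_id[i],
        birth_date = cohort$patients$birth_date[i],
        rx = rx_split[[i]], dx = dx_split[[i]], cl = cl_split[[i]],
        snapshot_date = snapshot_date, lookup = lookup
      )
      patient_records(state, catalog)
    }),
    selfaudit_missing_dose = function(w) {
      n_dose_warn <<- n_dose_warn + 1L
      invokeRestart("muffleWarning")
    }
  )
  if (n_dose_warn > 0)
    warn(paste0(n_dose_warn,
                " prescription(s) without daily_dose_mg skipped by dose rules"))

  alerts <- records_to_tibble(unlist(recs, recursive = FALSE))
  alerts <- alerts[order(alerts$patient_id, alerts$rule_id,
                         alerts$identity_key), ]

  structure(
    list(
      snapshot_date = snapshot_date,
      year_label = catalog$year_label,
      alerts = alerts,
      per_category_counts = dplyr::count(alerts, .data$category,
                                         name = "n_alerts"),
      per_physician_counts = dplyr::count(alerts, .data$physician_id,
                                          name = "n_alerts")
    ),
    class = "sa_snapshot"
  )
}

#' @export
print.sa_snapshot <- function(x, ...) {
  cat("<sa_snapshot> ", format(x$snapshot_date), " (catalog ", x$year_label,
      "): ", nrow(x$alerts), " alerts in ", nrow(x$per_category_counts),
      " categories\n", sep = "")
  invisible(x)
}

#' Write a snapshot to disk
#'
#' Serializes the alert table to `alerts.csv` and the summary counts to
#' `summary.json` in a machine-readable layout that [read_snapshot()]
#' round-trips.
#'
#' @param snapshot An `sa_snapshot`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_snapshot <- function(snapshot, dir) {
  stopifnot(inherits(snapshot, "sa_snapshot"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  alerts_path <- file.path(dir, "alerts.csv")
  summary_path <- file.path(dir, "summary.json")
  readr::write_csv(snapshot$alerts, alerts_path, na = "", progress = FALSE)
  jsonlite::write_json(
    list(
      snapshot_date = format(snapshot$snapshot_date),
      year_label = snapshot$year_label,
      n_alerts = nrow(snapshot$alerts),
      per_category_counts = snapshot$per_category_counts,
      per_physician_counts = snapshot$per_physician_counts
    ),
    summary_path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(c(alerts = alerts_path, summary = summary_path))
}

#' Read a snapshot written by [write_snapshot()]
#'
#' @param dir Directory containing `alerts.csv` and `summary.json`.
#' @return An `sa_snapshot`.
#' @export
read_snapshot <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "summary.json"))
  alerts <- readr::read_csv(
    file.path(dir, "alerts.csv"),
    col_types = readr::cols(
      indicator_linked = readr::col_logical(),
      snapshot_date = readr::col_date(),
      .default = readr::col_character()
    ), progress = FALSE)
  alerts$triggering_diagnoses[is.na(alerts$triggering_diagnoses)] <- ""
  structure(
    list(
      snapshot_date = as.Date(meta$snapshot_date),
      year_label = meta$year_label,
      alerts = alerts,
      per_category_counts = dplyr::count(alerts, .data$category,
                                         name = "n_alerts"),
      per_physician_counts = dplyr::count(alerts, .data$physician_id,
                                          name = "n_alerts")
    ),
    class = "sa_snapshot"
  )
}
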