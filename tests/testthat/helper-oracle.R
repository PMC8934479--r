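## Independent brute-force re-implementations of the rule predicates, written
## directly from the criterion definitions as nested loops over prescriptions
## and diagnoses. They share no code with the engine; agreement on random
## states is asserted property-style.

oracle_cmp <- function(v, comparator, t) {
  if (comparator == "gt") v > t
  else if (comparator == "ge") v >= t
  else if (comparator == "lt") v < t
  else if (comparator == "le") v <= t
  else stop("bad comparator")
}

oracle_icd_match <- function(code, prefixes) {
  code <- gsub(".", "", toupper(code), fixed = TRUE)
  for (p in prefixes) {
    p <- gsub(".", "", toupper(p), fixed = TRUE)
    if (substr(code, 1, nchar(p)) == p) return(TRUE)
  }
  FALSE
}

oracle_dx_hits <- function(state, catalog, concepts) {
  prefixes <- unique(unlist(catalog$icd10_concept_sets[unlist(concepts)]))
  hits <- character(0)
  for (code in state$active_diagnoses) {
    if (oracle_icd_match(code, prefixes)) hits <- c(hits, code)
  }
  sort(unique(hits))
}

oracle_code_in_spec <- function(state, row, spec) {
  if (!is.null(spec$codes)) {
    state$rx$drug_code[row] %in% unlist(spec$codes)
  } else {
    spec$tag %in% state$rx$tags[[row]]
  }
}

oracle_spec_codes <- function(state, spec) {
  out <- character(0)
  for (row in seq_len(nrow(state$rx))) {
    if (oracle_code_in_spec(state, row, spec))
      out <- c(out, state$rx$drug_code[row])
  }
  sort(unique(out))
}

## Each oracle returns a data frame (rule_id, triggering_drugs,
## triggering_diagnoses) directly comparable to the engine alert tibble.
oracle_alert_frame <- function(rule_id, drug_sets, dx_sets = NULL) {
  if (!length(drug_sets)) {
    return(data.frame(rule_id = character(), triggering_drugs = character(),
                      triggering_diagnoses = character(),
                      stringsAsFactors = FALSE))
  }
  if (is.null(dx_sets)) dx_sets <- rep(list(character(0)), length(drug_sets))
  out <- data.frame(
    rule_id = rule_id,
    triggering_drugs = vapply(drug_sets, function(s)
      paste(sort(unique(s)), collapse = "|"), character(1)),
    triggering_diagnoses = vapply(dx_sets, function(s)
      paste(sort(unique(s)), collapse = "|"), character(1)),
    stringsAsFactors = FALSE)
  out <- out[order(out$triggering_drugs), , drop = FALSE]
  rownames(out) <- NULL
  out
}

oracle_simple_rule <- function(rule, state, catalog) {
  p <- rule$parameters
  if (rule$kind == "dose_threshold") {
    fired <- character(0)
    dx_hit <- if (!is.null(p$concept))
      oracle_dx_hits(state, catalog, p$concept) else character(0)
    for (row in seq_len(nrow(state$rx))) {
      if (!oracle_code_in_spec(state, row, p)) next
      dose <- state$rx$daily_dose_mg[row]
      if (is.na(dose) || dose <= p$threshold_mg_per_day) next
      if (!is.null(p$age) &&
            !oracle_cmp(state$age_years, p$age$comparator, p$age$years)) next
      if (!is.null(p$concept) && length(dx_hit) == 0) next
      fired <- c(fired, state$rx$drug_code[row])
    }
    fired <- sort(unique(fired))
    return(oracle_alert_frame(rule$rule_id, as.list(fired),
                              rep(list(dx_hit), length(fired))))
  }
  if (rule$kind == "age_restriction") {
    if (!oracle_cmp(state$age_years, p$age$comparator, p$age$years))
      return(oracle_alert_frame(rule$rule_id, list()))
    return(oracle_alert_frame(rule$rule_id,
                              as.list(oracle_spec_codes(state, p))))
  }
  if (rule$kind == "comorbidity_contraindication") {
    dx_hit <- oracle_dx_hits(state, catalog, p$concepts)
    if (!length(dx_hit)) return(oracle_alert_frame(rule$rule_id, list()))
    codes <- oracle_spec_codes(state, p)
    return(oracle_alert_frame(rule$rule_id, as.list(codes),
                              rep(list(dx_hit), length(codes))))
  }
  if (rule$kind == "co_prescription") {
    return(oracle_alert_frame(rule$rule_id,
                              oracle_co_prescription(state, p$groups)))
  }
  if (rule$kind == "clinical_variable") {
    i <- which(state$clinical$variable_code == p$variable)
    ok <- length(i) == 1 &&
      oracle_cmp(state$clinical$value[i], p$comparator, p$threshold)
    if (!ok) return(oracle_alert_frame(rule$rule_id, list()))
    return(oracle_alert_frame(rule$rule_id,
                              as.list(oracle_spec_codes(state, p))))
  }
  if (rule$kind == "list_membership") {
    return(oracle_alert_frame(rule$rule_id,
                              as.list(oracle_spec_codes(state, p))))
  }
  stop("oracle: unsupported kind ", rule$kind)
}

## Co-prescription as exact cover: a drug set S (|S| = total required) fires
## iff S can be partitioned so each group receives min_count matching drugs.
oracle_co_prescription <- function(state, groups) {
  k <- vapply(groups, function(g) {
    if (is.null(g$min_count)) 1L else as.integer(g$min_count)
  }, integer(1))
  total <- sum(k)
  all_codes <- sort(unique(state$rx$drug_code))
  if (length(all_codes) < total) return(list())
  satisfies <- function(code, g) {
    rows <- which(state$rx$drug_code == code)
    any(vapply(rows, function(r) oracle_code_in_spec(state, r, g),
               logical(1)))
  }
  can_partition <- function(set, gi) {
    if (gi > length(groups)) return(length(set) == 0)
    ok <- set[vapply(set, satisfies, logical(1), g = groups[[gi]])]
    if (length(ok) < k[gi]) return(FALSE)
    for (pick in utils::combn(ok, k[gi], simplify = FALSE)) {
      if (can_partition(setdiff(set, pick), gi + 1)) return(TRUE)
    }
    FALSE
  }
  out <- list()
  for (s in utils::combn(all_codes, total, simplify = FALSE)) {
    if (can_partition(s, 1)) out[[length(out) + 1]] <- s
  }
  out
}

oracle_triple_whammy <- function(state, rule, catalog) {
  p <- rule$parameters
  has_treatment <- length(oracle_spec_codes(
    state, list(tag = p$treatment_tag))) > 0
  if (!(oracle_cmp(state$age_years, p$age$comparator, p$age$years) ||
          has_treatment))
    return(list())
  valid <- list()
  nsaids <- oracle_spec_codes(state, list(tag = p$groups$nsaid))
  rass <- oracle_spec_codes(state, list(tag = p$groups$ras))
  diuretics <- oracle_spec_codes(state, list(tag = p$groups$diuretic))
  for (a in nsaids) for (b in rass) for (d in diuretics) {
    if (a != b && a != d && b != d)
      valid[[length(valid) + 1]] <- sort(c(a, b, d))
  }
  unique(valid)
}

## Pairwise duplication oracle: every pair of active prescriptions either
## shares a principle (principle bases) or shares duplication tags without a
## shared principle (group bases).
oracle_duplications <- function(state, catalog) {
  rx <- state$rx
  bases <- list()
  add <- function(id, codes) {
    bases[[id]] <<- sort(unique(c(bases[[id]], codes)))
  }
  n <- nrow(rx)
  if (n >= 2) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      shared_p <- intersect(rx$principles[[i]], rx$principles[[j]])
      if (length(shared_p)) {
        for (p in shared_p)
          add(paste0("dup_principle_", p), c(rx$drug_code[i], rx$drug_code[j]))
      } else {
        shared_t <- intersect(rx$tags[[i]], rx$tags[[j]])
        shared_t <- shared_t[shared_t %in% catalog$duplication_groups$tag]
        for (tg in shared_t) {
          gid <- catalog$duplication_groups$group_id[
            catalog$duplication_groups$tag == tg]
          add(paste0("dup_group_", gid), c(rx$drug_code[i], rx$drug_code[j]))
        }
      }
    }
  }
  ids <- sort(names(bases))
  if (!length(ids)) {
    return(data.frame(rule_id = character(), triggering_drugs = character(),
                      triggering_diagnoses = character(),
                      stringsAsFactors = FALSE))
  }
  out <- data.frame(
    rule_id = ids,
    triggering_drugs = vapply(ids, function(id)
      paste(bases[[id]], collapse = "|"), character(1)),
    triggering_diagnoses = rep("", length(ids)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out <- out[order(out$rule_id, out$triggering_drugs), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## Random evaluation contexts covering dose/age/comorbidity boundaries,
## duplicate prescriptions of the same drug, and tagged/untagged mixes.
random_states <- function(n, seed, date = as.Date("2016-06-01")) {
  set.seed(seed)
  dc <- builtin_drug_catalog()
  pool <- c(dc$drug_code, sprintf("V03AB%02d", 1:5))
  dx_pool <- c("K70", "K74", "E11", "I61", "I472", "I50", "G20", "I26",
               "I80", "C54", "I20", "I25", "I63", "I70", "K50", "Z89",
               "E115", "A00", "J45")
  doses <- c(NA, 5, 10, 15, 20, 21, 25, 30, 40, 41, 45, 60, 100, 200)
  offsets <- c(-2000L, -1826L, -400L, -365L, -100L, -10L, 0L)
  ages <- c(40:64, 65, 66, 70, 74, 75, 76, 80, 90)
  yr <- as.integer(format(date, "%Y"))

  pats <- tibble::tibble(
    patient_id = sprintf("R%04d", seq_len(n)),
    physician_id = "D1",
    birth_date = as.Date(sprintf("%d-01-15", yr - sample(ages, n, TRUE))),
    sex = "female")
  rx <- list(); dx <- list(); cl <- list()
  for (i in seq_len(n)) {
    k <- sample(0:6, 1)
    if (k > 0) {
      rx[[length(rx) + 1]] <- tibble::tibble(
        patient_id = pats$patient_id[i],
        drug_code = sample(pool, k, replace = TRUE),
        daily_dose_mg = sample(doses, k, replace = TRUE),
        start_date = date + sample(offsets, k, replace = TRUE),
        end_date = as.Date(NA))
    }
    j <- sample(0:2, 1)
    if (j > 0) {
      dx[[length(dx) + 1]] <- tibble::tibble(
        patient_id = pats$patient_id[i],
        icd10_code = sample(dx_pool, j),
        onset_date = date - 400L, resolved_date = as.Date(NA))
    }
    if (stats::runif(1) < 0.3) {
      cl[[length(cl) + 1]] <- tibble::tibble(
        patient_id = pats$patient_id[i], variable_code = "potassium",
        value = sample(c(4, 5.5, 6.2), 1), measured_date = date - 30L)
    }
    if (stats::runif(1) < 0.3) {
      cl[[length(cl) + 1]] <- tibble::tibble(
        patient_id = pats$patient_id[i], variable_code = "egfr",
        value = sample(c(20, 30, 80), 1), measured_date = date - 30L)
    }
  }
  cohort <- mini_cohort(pats,
                        dplyr::bind_rows(empty_rx_tbl(), rx),
                        dplyr::bind_rows(empty_dx_tbl(), dx),
                        dplyr::bind_rows(empty_cl_tbl(), cl))
  lapply(pats$patient_id, function(pid)
    build_patient_state(cohort, pid, date))
}

## Reduce an engine alert tibble to the comparable (rule_id, drugs, dx) frame.
engine_frame <- function(alerts) {
  out <- data.frame(
    rule_id = alerts$rule_id,
    triggering_drugs = alerts$triggering_drugs,
    triggering_diagnoses = alerts$triggering_diagnoses,
    stringsAsFactors = FALSE)
  out <- out[order(out$rule_id, out$triggering_drugs), , drop = FALSE]
  rownames(out) <- NULL
  out
}
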