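#' Configuration for the synthetic cohort generator
#'
#' Describes a primary-care population with controlled problem prevalence
#' and controlled longitudinal dynamics between the April baseline and the
#' December final snapshot. All randomness derives from the single integer
#' `seed`; the global random state is left untouched.
#'
#' @param n_patients Number of patients.
#' @param n_physicians Number of physicians patients are assigned to.
#' @param seed Integer seed controlling all randomness.
#' @param elderly_fraction Fraction of unplanted patients drawn from the
#'   elderly (70-90) age band; the rest are 25-64.
#' @param per_rule_prevalence Named probabilities, one entry per plantable
#'   target (catalog rule ids plus `dup_group_<id>` duplication bases and
#'   the `dup_principle_omeprazole` same-principle basis). Defaults to a
#'   uniform allocation of a total prevalence of 0.5. Must sum to at most 1:
#'   each patient receives at most one planted problem so planted triggers
#'   stay disjoint.
#' @param background_rx_rate Mean number of inert background prescriptions
#'   per patient (Poisson), carrying no catalog tags.
#' @param resolution_probability Probability that a baseline-planted problem
#'   is resolved before the final snapshot.
#' @param drug_dropped_fraction,diagnosis_resolved_fraction Split of planned
#'   resolutions between withdrawing the triggering drugs and registering
#'   the triggering diagnosis as resolved (must sum to 1; the diagnosis
#'   channel applies only to plants that carry a diagnosis).
#' @param new_mrp_rate Probability that an otherwise clean patient gains a
#'   newly generated problem between the two snapshots.
#' @return An object of class `sa_generator_config`.
#' @export
generator_config <- function(n_patients = 2000,
                             n_physicians = 40,
                             seed = 1,
                             elderly_fraction = 0.25,
                             per_rule_prevalence = NULL,
                             background_rx_rate = 4,
                             resolution_probability = 0.35,
                             drug_dropped_fraction = 0.8,
                             diagnosis_resolved_fraction = 0.2,
                             new_mrp_rate = 0.05) {
  probs <- c(elderly_fraction, resolution_probability, drug_dropped_fraction,
             diagnosis_resolved_fraction, new_mrp_rate)
  if (any(probs < 0 | probs > 1))
    abort("all generator probabilities must lie in [0, 1]")
  if (abs(drug_dropped_fraction + diagnosis_resolved_fraction - 1) > 1e-9)
    abort("drug_dropped_fraction and diagnosis_resolved_fraction must sum to 1")
  if (!is.null(per_rule_prevalence)) {
    if (is.null(names(per_rule_prevalence)) ||
          any(!nzchar(names(per_rule_prevalence))))
      abort("per_rule_prevalence must be a named vector")
    if (any(per_rule_prevalence < 0 | per_rule_prevalence > 1))
      abort("per_rule_prevalence entries must lie in [0, 1]")
  }
  structure(
    list(n_patients = as.integer(n_patients),
         n_physicians = as.integer(n_physicians),
         seed = as.integer(seed),
         elderly_fraction = elderly_fraction,
         per_rule_prevalence = per_rule_prevalence,
         background_rx_rate = background_rx_rate,
         resolution_probability = resolution_probability,
         drug_dropped_fraction = drug_dropped_fraction,
         diagnosis_resolved_fraction = diagnosis_resolved_fraction,
         new_mrp_rate = new_mrp_rate),
    class = "sa_generator_config"
  )
}

## ATC shorthands used by the trigger recipes.
.d <- list(
  citalopram = "N06AB04", escitalopram = "N06AB10", amiodarone = "C01BD01",
  haloperidol = "N05AD01", aliskiren = "C09XA02", enalapril = "C09AA02",
  losartan = "C09CA01", cilostazol = "B01AC23", aspirin = "B01AC06",
  clopidogrel = "B01AC04", acenocoumarol = "B01AA07",
  trimetazidine = "C01EB15", raloxifene = "G03XC01", celecoxib = "M01AH01",
  diclofenac = "M01AB05", aceclofenac = "M01AB16", ibuprofen = "M01AE01",
  naproxen = "M01AE02", agomelatine = "N06AX22", ivabradine = "C01EB17",
  verapamil = "C08DA01", canagliflozin = "A10BK02", metformin = "A10BA02",
  insulin_h = "A10AB01", insulin_a = "A10AB05", strontium = "M05BX03",
  furosemide = "C03CA01", hctz = "C03AA03", indapamide = "C03BA11",
  alendronate = "M05BA04", omeprazole = "A02BC01", pantoprazole = "A02BC02",
  amitriptyline = "N06AA09", paroxetine = "N06AB05", oxybutynin = "G04BD04",
  solifenacin = "G04BD08", diazepam = "N05BA01", clorazepate = "N05BA05",
  beclometasone = "R03BA01", budesonide = "R03BA02", alfuzosin = "G04CA01",
  tamsulosin = "G04CA02", paracetamol = "N02BE01", propacetamol = "N02BE05",
  zolpidem = "N05CF02", citicoline = "N06BX06", glucosamine = "M01AX05"
)

#' Plantable targets of a catalog
#'
#' The identifiers the generator can plant: every catalog rule id except
#' `duplication_group` placeholders, plus one `dup_group_<id>` target per
#' duplication group and the same-principle target
#' `dup_principle_omeprazole`.
#'
#' @param catalog An `sa_catalog`.
#' @return Character vector of target ids.
#' @export
plantable_targets <- function(catalog) {
  c(vapply(catalog$rules, function(r) r$rule_id, character(1)),
    paste0("dup_group_", catalog$duplication_groups$group_id),
    "dup_principle_omeprazole")
}

## Trigger recipe for one target: the minimal drug/diagnosis/clinical set
## that satisfies exactly that target under the built-in catalogs, plus the
## alerts it is expected to raise. Doses in mg/day; start offsets in days
## relative to the baseline date (negative = before).
trigger_recipe <- function(target, catalog) {
  d <- .d
  rx <- function(...) {
    rows <- list(...)
    tibble::tibble(
      drug_code = vapply(rows, `[[`, character(1), 1),
      daily_dose_mg = as.numeric(vapply(rows, function(r) as.numeric(r[[2]]), numeric(1))),
      start_offset = vapply(rows, function(r)
        if (length(r) >= 3) as.integer(r[[3]]) else -180L, integer(1))
    )
  }
  al <- function(rule_id, drugs, dxs = character(0)) {
    list(rule_id = rule_id, drugs = sort(unlist(drugs)), dxs = sort(dxs))
  }
  rec <- function(age, rx_tab = NULL, dx = character(0), clinical = NULL,
                  alerts = list(), n_inert = 0L, new_eligible = TRUE) {
    list(age = age,
         rx = rx_tab %||% tibble::tibble(drug_code = character(),
                                         daily_dose_mg = numeric(),
                                         start_offset = integer()),
         dx = dx, clinical = clinical, alerts = alerts,
         n_inert = n_inert, new_eligible = new_eligible)
  }
  cl <- function(variable, value) tibble::tibble(variable_code = variable,
                                                 value = value)

  if (startsWith(target, "dup_group_")) {
    pair <- switch(sub("^dup_group_", "", target),
      ras_inhibitors = c(d$enalapril, d$losartan),
      anti_inflammatories = c(d$ibuprofen, d$naproxen),
      benzodiazepines_long = c(d$diazepam, d$clorazepate),
      inhaled_glucocorticoids = c(d$beclometasone, d$budesonide),
      alpha_blockers = c(d$alfuzosin, d$tamsulosin),
      gastric_protectors = c(d$omeprazole, d$pantoprazole),
      antidepressants = c(d$amitriptyline, d$paroxetine),
      urinary_antispasmodics = c(d$oxybutynin, d$solifenacin),
      thiazide_diuretics = c(d$hctz, d$indapamide),
      paracetamol = c(d$paracetamol, d$propacetamol),
      insulins = c(d$insulin_h, d$insulin_a),
      abort(paste0("no trigger recipe for duplication group target: ", target))
    )
    return(rec(60, rx(list(pair[1], 10), list(pair[2], 10)),
               alerts = list(al(target, pair))))
  }

  switch(target,
    dup_principle_omeprazole = rec(
      60, rx(list(d$omeprazole, 20, -180L), list(d$omeprazole, 20, -90L)),
      alerts = list(al("dup_principle_omeprazole", d$omeprazole))),
    cital_dose_high = rec(45, rx(list(d$citalopram, 60)),
      alerts = list(al("cital_dose_high", d$citalopram))),
    cital_dose_age = rec(72, rx(list(d$citalopram, 30)),
      alerts = list(al("cital_dose_age", d$citalopram))),
    cital_dose_liver = rec(45, rx(list(d$citalopram, 30)), dx = "K70",
      alerts = list(al("cital_dose_liver", d$citalopram, "K70"))),
    cital_qt = rec(45, rx(list(d$citalopram, 10), list(d$amiodarone, 200)),
      alerts = list(al("cital_qt", c(d$citalopram, d$amiodarone)))),
    escital_dose_age = rec(72, rx(list(d$escitalopram, 15)),
      alerts = list(al("escital_dose_age", d$escitalopram))),
    escital_qt = rec(45, rx(list(d$escitalopram, 10), list(d$haloperidol, 2)),
      alerts = list(al("escital_qt", c(d$escitalopram, d$haloperidol)))),
    aliskiren_diabetes_dx = rec(60, rx(list(d$aliskiren, 150)), dx = "E11",
      alerts = list(al("aliskiren_diabetes_dx", d$aliskiren, "E11"))),
    aliskiren_antidiabetic = rec(60,
      rx(list(d$aliskiren, 150), list(d$metformin, 1000)),
      alerts = list(al("aliskiren_antidiabetic", c(d$aliskiren, d$metformin)))),
    aliskiren_ace = rec(60, rx(list(d$aliskiren, 150), list(d$enalapril, 10)),
      alerts = list(al("aliskiren_ace", c(d$aliskiren, d$enalapril)))),
    cilostazol_contra = rec(60, rx(list(d$cilostazol, 200)), dx = "I50",
      alerts = list(al("cilostazol_contra", d$cilostazol, "I50"))),
    cilostazol_dual_antiplatelet = rec(60,
      rx(list(d$cilostazol, 200, -100L), list(d$aspirin, 100, -100L),
         list(d$clopidogrel, 75, -100L)),
      alerts = list(al("cilostazol_dual_antiplatelet",
                       c(d$cilostazol, d$aspirin, d$clopidogrel)))),
    cilostazol_antiplatelet_anticoagulant = rec(60,
      rx(list(d$cilostazol, 200, -100L), list(d$aspirin, 100, -100L),
         list(d$acenocoumarol, 2, -100L)),
      alerts = list(al("cilostazol_antiplatelet_anticoagulant",
                       c(d$cilostazol, d$aspirin, d$acenocoumarol)))),
    trimetazidine_movement = rec(60, rx(list(d$trimetazidine, 60)), dx = "G20",
      alerts = list(al("trimetazidine_movement", d$trimetazidine, "G20"))),
    serm_contra = rec(60, rx(list(d$raloxifene, 60)), dx = "I80",
      alerts = list(al("serm_contra", d$raloxifene, "I80"))),
    coxib_contra = rec(60, rx(list(d$celecoxib, 200)), dx = "I25",
      alerts = list(al("coxib_contra", d$celecoxib, "I25"))),
    diclofenac_contra = rec(60, rx(list(d$diclofenac, 100)), dx = "I25",
      alerts = list(al("diclofenac_contra", d$diclofenac, "I25"))),
    aceclofenac_contra = rec(60, rx(list(d$aceclofenac, 200)), dx = "I63",
      alerts = list(al("aceclofenac_contra", d$aceclofenac, "I63"))),
    agomelatine_age = rec(78, rx(list(d$agomelatine, 25)),
      alerts = list(al("agomelatine_age", d$agomelatine))),
    ivabradine_verapamil = rec(60,
      rx(list(d$ivabradine, 10), list(d$verapamil, 240)),
      alerts = list(al("ivabradine_verapamil", c(d$ivabradine, d$verapamil)))),
    triple_whammy = rec(80,
      rx(list(d$ibuprofen, 1200), list(d$losartan, 50), list(d$furosemide, 40)),
      alerts = list(al("triple_whammy",
                       c(d$ibuprofen, d$losartan, d$furosemide)))),
    strontium_cardiovascular = rec(60, rx(list(d$strontium, 2000)), dx = "I25",
      alerts = list(al("strontium_cardiovascular", d$strontium, "I25"))),
    canagliflozin_amputation = rec(60, rx(list(d$canagliflozin, 300)),
      dx = "Z89",
      alerts = list(al("canagliflozin_amputation", d$canagliflozin, "Z89"))),
    bisphosphonate_5y = rec(68, rx(list(d$alendronate, 70, -2000L)),
      alerts = list(al("bisphosphonate_5y", d$alendronate)),
      new_eligible = FALSE),
    dapt_12m = rec(60,
      rx(list(d$aspirin, 100, -400L), list(d$clopidogrel, 75, -400L)),
      alerts = list(al("dapt_12m", c(d$aspirin, d$clopidogrel))),
      new_eligible = FALSE),
    antichol_combo = rec(60,
      rx(list(d$oxybutynin, 10), list(d$amitriptyline, 50)),
      alerts = list(al("antichol_combo", c(d$oxybutynin, d$amitriptyline)))),
    geriatric_list = rec(80, rx(list(d$zolpidem, 10)),
      alerts = list(al("geriatric_list", d$zolpidem))),
    avoidable_list = rec(60, rx(list(d$glucosamine, 1500)),
      alerts = list(al("avoidable_list", d$glucosamine))),
    ras_hyperkalaemia = rec(60, rx(list(d$losartan, 50)),
      clinical = cl("potassium", 6.2),
      alerts = list(al("ras_hyperkalaemia", d$losartan))),
    nsaid_renal_impairment = rec(60, rx(list(d$naproxen, 500)),
      clinical = cl("egfr", 22),
      alerts = list(al("nsaid_renal_impairment", d$naproxen))),
    polymedication = rec(72,
      rx(list(d$oxybutynin, 10), list(d$amitriptyline, 50)),
      alerts = list(
        al("antichol_combo", c(d$oxybutynin, d$amitriptyline)),
        al("polymedication", c(d$oxybutynin, d$amitriptyline))),
      n_inert = max(0L, catalog$polymedication_threshold - 2L)),
    abort(paste0("no trigger recipe for target: ", target))
  )
}

#' Generate a synthetic cohort with ground truth
#'
#' Builds a seeded cohort whose planted problems, longitudinal transitions
#' and expected alerts are all recorded, so detection recall, false-positive
#' counts and resolution classification can be scored exactly. Each planted
#' patient receives only the drugs, diagnoses and clinical values needed to
#' satisfy one target rule, plus inert background prescriptions that carry
#' no catalog tags; planted triggers are therefore mutually disjoint and no
#' accidental co-triggering occurs.
#'
#' Baseline-planted problems resolve before the final snapshot with the
#' configured probability, by drug withdrawal (the triggering prescriptions
#' end between the snapshots) or — for plants carrying a diagnosis — by
#' registering the diagnosis as resolved. Newly generated problems appear on
#' previously clean patients with all their triggers starting after the
#' baseline; duration-based targets are not eligible, since a between-
#' snapshot onset cannot satisfy a multi-month duration threshold.
#'
#' @param config An [generator_config()].
#' @param catalog An `sa_catalog` (decides plantable targets, polymedication
#'   threshold, and the default April/December snapshot dates of its year).
#' @param drug_catalog Drug catalog used for the cohort.
#' @param baseline_date,final_date Snapshot dates; default April 1 and
#'   December 1 of the catalog year.
#' @param dir Optional output directory: when given, the four cohort CSVs
#'   and `ground_truth.json` are written there.
#' @return A list with `cohort` (validated `sa_cohort`), `ground_truth`
#'   (`sa_ground_truth`), `baseline_date`, `final_date`.
#' @export
generate_cohort <- function(config, catalog,
                            drug_catalog = builtin_drug_catalog(),
                            baseline_date = NULL, final_date = NULL,
                            dir = NULL) {
  stopifnot(inherits(config, "sa_generator_config"),
            inherits(catalog, "sa_catalog"))
  year <- suppressWarnings(as.integer(catalog$year_label))
  if (is.null(baseline_date))
    baseline_date <- as.Date(paste0(year, "-04-01"))
  if (is.null(final_date))
    final_date <- as.Date(paste0(year, "-12-01"))
  baseline_date <- as.Date(baseline_date)
  final_date <- as.Date(final_date)
  stopifnot(baseline_date < final_date)

  targets <- plantable_targets(catalog)
  prev <- config$per_rule_prevalence
  if (is.null(prev)) {
    prev <- stats::setNames(rep(0.5 / length(targets), length(targets)),
                            targets)
  }
  unknown <- setdiff(names(prev), targets)
  if (length(unknown))
    abort(paste0("per_rule_prevalence names not plantable under this catalog: ",
                 paste(unknown, collapse = ", ")))
  if (sum(prev) > 1)
    abort(paste0("prevalence targets infeasible: per-rule prevalences sum to ",
                 signif(sum(prev), 3),
                 " > 1; lower them (one planted problem per patient keeps ",
                 "triggers disjoint)"))

  recipes <- lapply(stats::setNames(nm = names(prev)), trigger_recipe,
                    catalog = catalog)
  new_eligible <- names(prev)[vapply(recipes, `[[`, logical(1), "new_eligible")]
  inert_pool <- sprintf("V03AB%02d", 1:99)

  ## Rows are accumulated as parallel vectors (dates as day numbers) and
  ## materialized into tibbles once; building a tibble per patient is too
  ## slow at cohort scale.
  out <- local_seed(config$seed, {
    n <- config$n_patients
    pat <- list(pid = character(n), phys = character(n),
                birth = numeric(n), sex = character(n))
    rx <- list(); dx <- list(); cl <- list(); gt <- list()
    base_num <- as.numeric(baseline_date)
    add_rx <- function(pid, code, dose, start, end) {
      rx[[length(rx) + 1]] <<- list(pid = rep(pid, length(code)), code = code,
                                    dose = rep_len(dose, length(code)),
                                    start = rep_len(start, length(code)),
                                    end = rep_len(end, length(code)))
    }

    cum <- cumsum(prev)
    for (i in seq_len(n)) {
      pid <- sprintf("P%05d", i)
      phys <- sprintf("D%03d", sample.int(config$n_physicians, 1))
      pat$pid[i] <- pid
      pat$phys[i] <- phys
      pat$sex[i] <- sample(c("female", "male"), 1)

      u <- stats::runif(1)
      target <- NA_character_
      phase <- NA_character_
      if (u < cum[length(cum)]) {
        target <- names(prev)[which(u < cum)[1]]
        phase <- "baseline"
      } else if (stats::runif(1) < config$new_mrp_rate &&
                   length(new_eligible)) {
        target <- sample(new_eligible, 1)
        phase <- "new"
      }

      if (is.na(target)) {
        age <- if (stats::runif(1) < config$elderly_fraction)
          sample(70:90, 1) else sample(25:64, 1)
        pat$birth[i] <- as.numeric(as.Date(paste0(year - age, "-01-15")))
        n_bg <- stats::rpois(1, config$background_rx_rate)
        if (age > 65) n_bg <- min(n_bg, catalog$polymedication_threshold - 1L)
        if (n_bg > 0)
          add_rx(pid, sample(inert_pool, n_bg), 100, base_num - 300, NA_real_)
        next
      }

      recipe <- recipes[[target]]
      pat$birth[i] <- as.numeric(as.Date(paste0(year - recipe$age, "-01-15")))

      ## longitudinal plan
      status <- "persisting"
      reason <- NA_character_
      if (phase == "baseline") {
        if (stats::runif(1) < config$resolution_probability) {
          status <- "resolved"
          reason <- if (length(recipe$dx) > 0 &&
                          stats::runif(1) < config$diagnosis_resolved_fraction)
            "diagnosis_resolved" else "drug_dropped"
        }
      } else {
        status <- "new"
      }

      rx_start <- if (phase == "baseline")
        base_num + recipe$rx$start_offset else
        rep(base_num + 60, nrow(recipe$rx))
      rx_end <- if (identical(reason, "drug_dropped"))
        rep(base_num + 60, nrow(recipe$rx)) else
        rep(NA_real_, nrow(recipe$rx))
      add_rx(pid, recipe$rx$drug_code, recipe$rx$daily_dose_mg,
             rx_start, rx_end)

      n_extra <- recipe$n_inert +
        if (recipe$n_inert == 0 && stats::runif(1) < 0.5) 2L else 0L
      if (n_extra > 0)
        add_rx(pid, sample(inert_pool, n_extra), 100,
               if (phase == "baseline") base_num - 300 else base_num + 60,
               NA_real_)

      if (length(recipe$dx)) {
        dx[[length(dx) + 1]] <- list(
          pid = rep(pid, length(recipe$dx)), code = recipe$dx,
          onset = rep(if (phase == "baseline") base_num - 400 else
            base_num + 60, length(recipe$dx)),
          resolved = rep(if (identical(reason, "diagnosis_resolved"))
            base_num + 60 else NA_real_, length(recipe$dx)))
      }
      if (!is.null(recipe$clinical)) {
        cl[[length(cl) + 1]] <- list(
          pid = rep(pid, nrow(recipe$clinical)),
          variable = recipe$clinical$variable_code,
          value = recipe$clinical$value,
          measured = rep(if (phase == "baseline") base_num - 30 else
            base_num + 60, nrow(recipe$clinical)))
      }

      for (a in recipe$alerts) {
        gt[[length(gt) + 1]] <- list(
          patient_id = pid, physician_id = phys, target_id = target,
          rule_id = a$rule_id, phase = phase, status = status,
          reason = reason,
          triggering_drugs = paste(a$drugs, collapse = "|"),
          triggering_diagnoses = paste(a$dxs, collapse = "|"),
          identity_key = paste(pid, a$rule_id,
                               paste(a$drugs, collapse = "+"), sep = "|"))
      }
    }

    col <- function(lst, f) unlist(lapply(lst, `[[`, f), use.names = FALSE)
    gcol <- function(f) vapply(gt, `[[`, character(1), f)
    list(
      pat = tibble::tibble(patient_id = pat$pid, physician_id = pat$phys,
                           birth_date = as.Date(pat$birth, origin = "1970-01-01"),
                           sex = pat$sex),
      rx = tibble::tibble(
        patient_id = col(rx, "pid"), drug_code = col(rx, "code"),
        daily_dose_mg = col(rx, "dose"),
        start_date = as.Date(col(rx, "start"), origin = "1970-01-01"),
        end_date = as.Date(col(rx, "end"), origin = "1970-01-01")),
      dx = tibble::tibble(
        patient_id = col(dx, "pid"), icd10_code = col(dx, "code"),
        onset_date = as.Date(col(dx, "onset"), origin = "1970-01-01"),
        resolved_date = as.Date(col(dx, "resolved"), origin = "1970-01-01")),
      cl = tibble::tibble(
        patient_id = col(cl, "pid"), variable_code = col(cl, "variable"),
        value = col(cl, "value"),
        measured_date = as.Date(col(cl, "measured"), origin = "1970-01-01")),
      gt = if (length(gt)) tibble::tibble(
        patient_id = gcol("patient_id"), physician_id = gcol("physician_id"),
        target_id = gcol("target_id"), rule_id = gcol("rule_id"),
        phase = gcol("phase"), status = gcol("status"),
        reason = vapply(gt, function(g) g$reason %||% NA_character_,
                        character(1)),
        triggering_drugs = gcol("triggering_drugs"),
        triggering_diagnoses = gcol("triggering_diagnoses"),
        identity_key = gcol("identity_key")) else NULL
    )
  })

  empty_rx <- tibble::tibble(patient_id = character(), drug_code = character(),
                             daily_dose_mg = numeric(),
                             start_date = as.Date(character()),
                             end_date = as.Date(character()))
  empty_dx <- tibble::tibble(patient_id = character(), icd10_code = character(),
                             onset_date = as.Date(character()),
                             resolved_date = as.Date(character()))
  empty_cl <- tibble::tibble(patient_id = character(),
                             variable_code = character(), value = numeric(),
                             measured_date = as.Date(character()))
  cohort <- load_cohort(
    prescriptions = dplyr::bind_rows(empty_rx, out$rx),
    patients = out$pat,
    diagnoses = dplyr::bind_rows(empty_dx, out$dx),
    clinical = dplyr::bind_rows(empty_cl, out$cl),
    drug_catalog = drug_catalog
  )
  if (sum(cohort$report$rejected) > 0)
    abort("internal error: generated cohort failed validation")

  ground_truth <- structure(
    list(plants = out$gt %||% tibble::tibble(),
         year_label = catalog$year_label,
         baseline_date = baseline_date, final_date = final_date,
         seed = config$seed),
    class = "sa_ground_truth"
  )

  if (!is.null(dir)) {
    write_cohort(cohort, dir)
    jsonlite::write_json(
      list(year_label = ground_truth$year_label,
           baseline_date = format(baseline_date),
           final_date = format(final_date),
           seed = config$seed, plants = ground_truth$plants),
      file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
  }

  list(cohort = cohort, ground_truth = ground_truth,
       baseline_date = baseline_date, final_date = final_date)
}

#' @export
print.sa_ground_truth <- function(x, ...) {
  cat("<sa_ground_truth> ", nrow(x$plants), " planted alerts (",
      sum(x$plants$phase == "baseline"), " baseline, ",
      sum(x$plants$phase == "new"), " new), catalog ", x$year_label,
      ", seed ", x$seed, "\n", sep = "")
  invisible(x)
}

## Expected identity keys at a phase of the study.
expected_keys <- function(ground_truth, when = c("baseline", "final")) {
  when <- match.arg(when)
  p <- ground_truth$plants
  if (!nrow(p)) return(character(0))
  if (when == "baseline") p$identity_key[p$phase == "baseline"]
  else p$identity_key[p$status %in% c("persisting", "new")]
}

#' Audit a generated cohort against its ground truth
#'
#' Runs the detection engine on the generated cohort at both snapshot dates
#' and cross-checks the alert sets against the planted expectations.
#' Discrepancies are report content, not errors: `missed` lists planted
#' alerts the engine did not raise (recall losses), `unplanned` lists
#' engine alerts that were never planted (leakage / false positives).
#'
#' @param cohort The generated `sa_cohort`.
#' @param catalog The `sa_catalog` used for generation.
#' @param ground_truth The `sa_ground_truth` from [generate_cohort()].
#' @return An object of class `sa_audit`: list with per-date tibbles
#'   `missed` and `unplanned`, the two snapshots, and summary fields
#'   `recall` and `n_false_positive`.
#' @export
audit_ground_truth <- function(cohort, catalog, ground_truth) {
  stopifnot(inherits(ground_truth, "sa_ground_truth"))
  snap_b <- run_snapshot(cohort, catalog, ground_truth$baseline_date)
  snap_f <- run_snapshot(cohort, catalog, ground_truth$final_date)
  exp_b <- expected_keys(ground_truth, "baseline")
  exp_f <- expected_keys(ground_truth, "final")

  missed <- dplyr::bind_rows(
    tibble::tibble(when = "baseline",
                   identity_key = setdiff(exp_b, snap_b$alerts$identity_key)),
    tibble::tibble(when = "final",
                   identity_key = setdiff(exp_f, snap_f$alerts$identity_key))
  )
  unplanned <- dplyr::bind_rows(
    tibble::tibble(when = "baseline",
                   identity_key = setdiff(snap_b$alerts$identity_key, exp_b)),
    tibble::tibble(when = "final",
                   identity_key = setdiff(snap_f$alerts$identity_key, exp_f))
  )
  n_expected <- length(exp_b) + length(exp_f)
  recall <- if (n_expected == 0) 1 else 1 - nrow(missed) / n_expected

  structure(
    list(missed = missed, unplanned = unplanned,
         baseline_snapshot = snap_b, final_snapshot = snap_f,
         recall = recall, n_false_positive = nrow(unplanned)),
    class = "sa_audit"
  )
}

#' @export
print.sa_audit <- function(x, ...) {
  cat("<sa_audit> recall ", format(x$recall), ", ",
      x$n_false_positive, " unplanned alert(s)\n", sep = "")
  invisible(x)
}
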