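cat16 <- builtin_catalog("2016")
cat18 <- builtin_catalog("2018")

test_that("citalopram dose criterion fires strictly above 40 mg/day", {
  high <- state_with(list(list("N06AB04", 60)), age = 50)
  a <- evaluate_rule(get_rule(cat16, "cital_dose_high"), high, cat16)
  expect_equal(nrow(a), 1)
  expect_equal(a$triggering_drugs, "N06AB04")
  expect_equal(a$identity_key, "P1|cital_dose_high|N06AB04")

  ok <- state_with(list(list("N06AB04", 20)), age = 50)
  expect_equal(nrow(evaluate_patient(ok, cat16)), 0)

  # the age-qualified 20 mg criterion needs age over 65 (strict)
  r_age <- get_rule(cat16, "cital_dose_age")
  expect_equal(nrow(evaluate_rule(
    r_age, state_with(list(list("N06AB04", 30)), age = 66), cat16)), 1)
  expect_equal(nrow(evaluate_rule(
    r_age, state_with(list(list("N06AB04", 30)), age = 65), cat16)), 0)

  # boundary: exactly the threshold never fires
  expect_equal(nrow(evaluate_rule(
    get_rule(cat16, "cital_dose_high"),
    state_with(list(list("N06AB04", 40)), age = 50), cat16)), 0)
})

test_that("missing dose skips the prescription with a warning, never alerts", {
  st <- state_with(list(list("N06AB04", NA)), age = 50)
  expect_warning(
    a <- evaluate_rule(get_rule(cat16, "cital_dose_high"), st, cat16),
    class = "selfaudit_missing_dose")
  expect_equal(nrow(a), 0)
})

test_that("co-prescription criteria need all groups active with distinct drugs", {
  r <- get_rule(cat16, "ivabradine_verapamil")
  both <- state_with(list(list("C01EB17", 10), list("C08DA01", 240)))
  a <- evaluate_rule(r, both, cat16)
  expect_equal(a$triggering_drugs, "C01EB17|C08DA01")
  one <- state_with(list(list("C01EB17", 10)))
  expect_equal(nrow(evaluate_rule(r, one, cat16)), 0)

  # citalopram QT rule cannot use citalopram itself as the QT partner
  r_qt <- get_rule(cat16, "cital_qt")
  alone <- state_with(list(list("N06AB04", 20)))
  expect_equal(nrow(evaluate_rule(r_qt, alone, cat16)), 0)
  with_qt <- state_with(list(list("N06AB04", 20), list("C01BD01", 200)))
  expect_equal(evaluate_rule(r_qt, with_qt, cat16)$triggering_drugs,
               "C01BD01|N06AB04")

  # cilostazol + "2 antiplatelet agents" means two other antiplatelets
  r_dap <- get_rule(cat16, "cilostazol_dual_antiplatelet")
  two <- state_with(list(list("B01AC23", 200, -100), list("B01AC06", 100, -100)))
  expect_equal(nrow(evaluate_rule(r_dap, two, cat16)), 0)
  three <- state_with(list(list("B01AC23", 200, -100), list("B01AC06", 100, -100),
                           list("B01AC04", 75, -100)))
  expect_equal(evaluate_rule(r_dap, three, cat16)$triggering_drugs,
               "B01AC04|B01AC06|B01AC23")
})

test_that("age restriction fires at the printed inclusive boundary", {
  r <- get_rule(cat16, "agomelatine_age")
  expect_equal(nrow(evaluate_rule(
    r, state_with(list(list("N06AX22", 25)), age = 75), cat16)), 1)
  expect_equal(nrow(evaluate_rule(
    r, state_with(list(list("N06AX22", 25)), age = 74), cat16)), 0)
})

test_that("comorbidity contraindications record their triggering diagnoses", {
  r <- get_rule(cat16, "trimetazidine_movement")
  st <- state_with(list(list("C01EB15", 60)), dxs = c("G20", "J45"))
  a <- evaluate_rule(r, st, cat16)
  expect_equal(a$triggering_drugs, "C01EB15")
  expect_equal(a$triggering_diagnoses, "G20")
  # ICD-10 prefix matching is dot-insensitive
  st2 <- state_with(list(list("C01EB15", 60)), dxs = "G20.9")
  expect_equal(evaluate_rule(r, st2, cat16)$triggering_diagnoses, "G20.9")
})

test_that("clinical-variable contraindication uses the latest value", {
  r <- get_rule(cat16, "ras_hyperkalaemia")
  hot <- state_with(list(list("C09CA01", 50)), clinical = c(potassium = 6.2))
  expect_equal(evaluate_rule(r, hot, cat16)$triggering_drugs, "C09CA01")
  at_threshold <- state_with(list(list("C09CA01", 50)),
                             clinical = c(potassium = 5.5))
  expect_equal(nrow(evaluate_rule(r, at_threshold, cat16)), 0)
  no_value <- state_with(list(list("C09CA01", 50)))
  expect_equal(nrow(evaluate_rule(r, no_value, cat16)), 0)
})

test_that("Triple Whammy needs the three groups and the age/diabetes qualifier", {
  r <- get_rule(cat16, "triple_whammy")
  triple <- list(list("M01AE01", 1200), list("C09AA02", 10), list("C03CA01", 40))
  old <- state_with(triple, age = 80)
  a <- detect_triple_whammy(old, r, cat16)
  expect_equal(a$triggering_drugs, "C03CA01|C09AA02|M01AE01")
  young <- state_with(triple, age = 50)
  expect_equal(nrow(detect_triple_whammy(young, r, cat16)), 0)
  young_dm <- state_with(c(triple, list(list("A10BA02", 1000))), age = 50)
  expect_equal(nrow(detect_triple_whammy(young_dm, r, cat16)), 1)
  missing_group <- state_with(list(list("M01AE01", 1200), list("C03CA01", 40)),
                              age = 80)
  expect_equal(nrow(detect_triple_whammy(missing_group, r, cat16)), 0)
  # at most one alert per patient, the lexicographically minimal triple
  many <- state_with(c(triple, list(list("M01AE02", 500), list("C09CA01", 50))),
                     age = 80)
  a2 <- detect_triple_whammy(many, r, cat16)
  expect_equal(nrow(a2), 1)
  expect_equal(a2$triggering_drugs, "C03CA01|C09AA02|M01AE01")
})

test_that("duration criteria: bisphosphonate years and antiplatelet overlap", {
  r_b <- get_rule(cat16, "bisphosphonate_5y")
  six_years <- state_with(list(list("M05BA04", 70, -2200)))
  expect_equal(detect_duration(six_years, r_b, cat16)$triggering_drugs,
               "M05BA04")
  two_years <- state_with(list(list("M05BA04", 70, -730)))
  expect_equal(nrow(detect_duration(two_years, r_b, cat16)), 0)

  r_d <- get_rule(cat16, "dapt_12m")
  dapt <- state_with(list(list("B01AC06", 100, -400), list("B01AC04", 75, -380)))
  a <- detect_duration(dapt, r_d, cat16)
  expect_equal(a$triggering_drugs, "B01AC04|B01AC06")
  short_overlap <- state_with(list(list("B01AC06", 100, -400),
                                   list("B01AC04", 75, -100)))
  expect_equal(nrow(detect_duration(short_overlap, r_d, cat16)), 0)
})

test_that("duplication bases: shared principle wins over shared group tag", {
  two_same <- state_with(list(list("A02BC01", 20), list("A02BC01", 20, -90)))
  a <- detect_duplications(two_same, cat16)
  expect_equal(a$rule_id, "dup_principle_omeprazole")
  expect_equal(a$triggering_drugs, "A02BC01")
  expect_true(a$indicator_linked)

  group_pair <- state_with(list(list("M01AE01", 1200), list("M01AE02", 500)))
  a2 <- detect_duplications(group_pair, cat16)
  expect_equal(a2$rule_id, "dup_group_anti_inflammatories")
  expect_equal(a2$triggering_drugs, "M01AE01|M01AE02")

  single <- state_with(list(list("M01AE01", 1200)))
  expect_equal(nrow(detect_duplications(single, cat16)), 0)

  # combination product duplicates the plain product at principle level only
  combo <- state_with(list(list("N02BE01", 2000), list("N02BE51", 1000)))
  a3 <- detect_duplications(combo, cat16)
  expect_equal(a3$rule_id, "dup_principle_paracetamol")

  # dose-adjustment groups are detected but not indicator-linked
  insulins <- state_with(list(list("A10AB01", 40), list("A10AB05", 30)))
  a4 <- detect_duplications(insulins, cat16)
  expect_equal(a4$rule_id, "dup_group_insulins")
  expect_false(a4$indicator_linked)
  expect_equal(a4$relevance, "low")
})

test_that("polymedication needs age over 65, the drug count, and a qualifying sub-alert", {
  r16 <- get_rule(cat16, "polymedication")
  fill <- lapply(1:9, function(i) list(sprintf("V03AB%02d", i), 100))
  antichol <- list(list("G04BD04", 10), list("N06AA09", 50))

  st <- state_with(c(antichol, fill), age = 70)              # 11 drugs
  sub <- evaluate_patient(st, cat16)
  expect_true("antichol_combo" %in% sub$rule_id)
  expect_true("polymedication" %in% sub$rule_id)
  poly <- sub[sub$rule_id == "polymedication", ]
  expect_equal(poly$triggering_drugs, "G04BD04|N06AA09")

  young <- state_with(c(antichol, fill), age = 60)           # age gate
  expect_false("polymedication" %in% evaluate_patient(young, cat16)$rule_id)

  few <- state_with(c(antichol, fill[1:5]), age = 70)        # 7 drugs
  expect_false("polymedication" %in% evaluate_patient(few, cat16)$rule_id)

  no_sub <- state_with(c(list(list("N06AB04", 10)), fill), age = 70)
  expect_false("polymedication" %in% evaluate_patient(no_sub, cat16)$rule_id)
})

test_that("the 2018 threshold of 8 drugs lowers the polymedication gate", {
  fill <- lapply(1:7, function(i) list(sprintf("V03AB%02d", i), 100))
  st <- state_with(c(list(list("G04BD04", 10), list("N06AA09", 50)), fill),
                   age = 70)                                  # 9 drugs
  expect_false("polymedication" %in% evaluate_patient(st, cat16)$rule_id)
  expect_true("polymedication" %in% evaluate_patient(st, cat18)$rule_id)
})

test_that("canagliflozin amputation-risk rule exists only in the 2018 content", {
  st <- state_with(list(list("A10BK02", 300)), dxs = "Z89")
  expect_false("canagliflozin_amputation" %in%
                 evaluate_patient(st, cat16)$rule_id)
  expect_true("canagliflozin_amputation" %in%
                evaluate_patient(st, cat18)$rule_id)
})

test_that("snapshots are deterministic and their counts are conserved", {
  sim <- generate_cohort(generator_config(n_patients = 120, seed = 5), cat16)
  s1 <- run_snapshot(sim$cohort, cat16, sim$baseline_date)
  s2 <- run_snapshot(sim$cohort, cat16, sim$baseline_date)
  expect_identical(readr::format_csv(s1$alerts), readr::format_csv(s2$alerts))
  expect_equal(sum(s1$per_category_counts$n_alerts), nrow(s1$alerts))
  expect_equal(sum(s1$per_physician_counts$n_alerts), nrow(s1$alerts))
  expect_true(all(s1$alerts$triggering_drugs != "" |
                    s1$alerts$triggering_diagnoses != ""))

  dir <- withr::local_tempdir()
  write_snapshot(s1, dir)
  back <- read_snapshot(dir)
  expect_equal(back$alerts$identity_key, s1$alerts$identity_key)
  expect_equal(back$year_label, s1$year_label)
})

test_that("an empty cohort yields an empty snapshot", {
  empty <- mini_cohort(tibble::tibble(
    patient_id = character(), physician_id = character(),
    birth_date = as.Date(character()), sex = character()))
  s <- run_snapshot(empty, cat16, "2016-04-01")
  expect_equal(nrow(s$alerts), 0)
})

test_that("alerts are monotone under prescription removal and inert addition", {
  set.seed(9)
  states <- random_states(40, seed = 31)
  for (st in states[1:20]) {
    alerts <- suppressWarnings(evaluate_patient(st, cat16))
    if (nrow(st$rx) == 0) next
    drop_code <- st$rx$drug_code[1]
    st2 <- st
    keep <- st2$rx$drug_code != drop_code
    st2$rx <- st2$rx[keep, , drop = FALSE]
    alerts2 <- suppressWarnings(evaluate_patient(st2, cat16))
    involved <- vapply(alerts$triggering_drugs, function(s)
      drop_code %in% strsplit(s, "|", fixed = TRUE)[[1]], logical(1))
    n_with <- sum(involved)
    n_with2 <- sum(vapply(alerts2$triggering_drugs, function(s)
      drop_code %in% strsplit(s, "|", fixed = TRUE)[[1]], logical(1)))
    expect_lte(n_with2, n_with)
    # alerts whose triggers do not involve the removed drug survive, except
    # polymedication, whose drug-count gate may drop below threshold
    surviving <- alerts$identity_key[!involved &
                                       alerts$rule_id != "polymedication"]
    expect_true(all(surviving %in% alerts2$identity_key))
  }
})

test_that("engine matches the brute-force oracles on random states", {
  states <- random_states(150, seed = 77)
  simple <- Filter(function(r) r$kind %in%
                     c("dose_threshold", "age_restriction",
                       "comorbidity_contraindication", "co_prescription",
                       "clinical_variable", "list_membership"), cat16$rules)
  for (st in states) {
    for (r in simple) {
      eng <- engine_frame(suppressWarnings(evaluate_rule(r, st, cat16)))
      ora <- oracle_simple_rule(r, st, cat16)
      expect_equal(eng, ora, label = paste("rule", r$rule_id))
    }
    eng_dup <- engine_frame(detect_duplications(st, cat16))
    expect_equal(eng_dup, oracle_duplications(st, cat16))
    tw <- get_rule(cat16, "triple_whammy")
    eng_tw <- detect_triple_whammy(st, tw, cat16)
    valid <- oracle_triple_whammy(st, tw, cat16)
    expect_equal(nrow(eng_tw), as.integer(length(valid) > 0))
    if (nrow(eng_tw)) {
      expect_true(eng_tw$triggering_drugs %in%
                    vapply(valid, paste, character(1), collapse = "|"))
    }
  }
})
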