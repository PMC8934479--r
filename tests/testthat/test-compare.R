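test_that("variation arithmetic reproduces the published table rows", {
  expect_equal(unlist(compute_variation(46242, 41589)[c("variation", "pct")]),
               c(variation = -4653, pct = -10))
  expect_equal(unlist(compute_variation(232463, 210916)[c("variation", "pct")]),
               c(variation = -21547, pct = -9))
  expect_equal(unlist(compute_variation(37359, 37421)[c("variation", "pct")]),
               c(variation = 62, pct = 0))
  expect_equal(unlist(compute_variation(4394, 4508)[c("variation", "pct")]),
               c(variation = 114, pct = 3))
  expect_equal(compute_variation(1234, 1234)$pct, 0L)
  expect_error(compute_variation(0, 5), "undefined")
  expect_equal(compute_variation(0, 0)$pct, 0L)
})

test_that("percentages round half away from zero", {
  expect_equal(round_half_away(-65.64), -66)
  expect_equal(round_half_away(6.53), 7)
  expect_equal(round_half_away(-0.5), -1)
  expect_equal(round_half_away(0.5), 1)
  expect_equal(round_half_away(2.25, 1), 2.3)
  expect_equal(round_half_away(-2.25, 1), -2.3)
  expect_equal(round(2.25, 1), 2.2)  # base R banker's rounding differs here
})

test_that("prevalence and share arithmetic match the published figures", {
  expect_equal(mrp_prevalence(210916, 9.5e6), 2.2)
  expect_equal(mrp_prevalence(227856, 9.6e6), 2.4)
  expect_equal(mrp_prevalence(0, 1000), 0)
  expect_error(mrp_prevalence(1, 0), "positive")
  expect_equal(pct_share(9767, 11035), 89L)
  expect_equal(pct_share(3260, 4460), 73L)
})

test_that("pct sign follows variation sign", {
  set.seed(4)
  for (i in 1:200) {
    b <- sample(1:10000, 1)
    f <- sample(0:10000, 1)
    v <- compute_variation(b, f)
    expect_true(v$pct == 0 || sign(v$pct) == sign(v$variation))
    expect_equal(v$pct == 0, abs(v$variation) / b < 1 / 200)
  }
})

cat16 <- builtin_catalog("2016")

test_that("identical snapshots compare to all-persisting", {
  sim <- generate_cohort(generator_config(n_patients = 80, seed = 21,
                                          resolution_probability = 0,
                                          new_mrp_rate = 0),
                         cat16)
  sb <- run_snapshot(sim$cohort, cat16, sim$baseline_date)
  sf <- run_snapshot(sim$cohort, cat16, sim$final_date)
  cmp <- compare_snapshots(sb, sf, sim$cohort)
  expect_equal(nrow(cmp$resolved), 0)
  expect_equal(nrow(cmp$new), 0)
  expect_equal(nrow(cmp$persisting), nrow(sb$alerts))
})

test_that("resolution reasons follow the drug-dropped / diagnosis-resolved channels", {
  pats <- tibble::tibble(
    patient_id = c("P1", "P2"), physician_id = "D1",
    birth_date = as.Date("1950-01-15"), sex = "female")
  rx <- tibble::tibble(
    patient_id = c("P1", "P2"),
    drug_code = c("C01EB17", "C01EB15"),
    daily_dose_mg = c(10, 60),
    start_date = as.Date("2016-01-01"),
    end_date = as.Date(c("2016-06-01", NA)))
  rx <- dplyr::bind_rows(rx, tibble::tibble(
    patient_id = "P1", drug_code = "C08DA01", daily_dose_mg = 240,
    start_date = as.Date("2016-01-01"), end_date = as.Date(NA)))
  dx <- tibble::tibble(
    patient_id = "P2", icd10_code = "G20",
    onset_date = as.Date("2015-01-01"),
    resolved_date = as.Date("2016-07-01"))
  cohort <- mini_cohort(pats, rx, dx)
  sb <- run_snapshot(cohort, cat16, "2016-04-01")
  sf <- run_snapshot(cohort, cat16, "2016-12-01")
  expect_setequal(sb$alerts$rule_id,
                  c("ivabradine_verapamil", "trimetazidine_movement"))
  cmp <- compare_snapshots(sb, sf, cohort)
  expect_equal(nrow(cmp$resolved), 2)
  res <- cmp$resolved[order(cmp$resolved$patient_id), ]
  expect_equal(res$resolution_reason, c("drug_dropped", "diagnosis_resolved"))
  expect_false(any(res$unattributed))
})

test_that("unexplained resolutions keep the default reason but are flagged", {
  # dose reduced below threshold: neither channel explains the resolution
  pats <- tibble::tibble(patient_id = "P1", physician_id = "D1",
                         birth_date = as.Date("1970-01-15"), sex = "male")
  rx <- tibble::tibble(
    patient_id = "P1", drug_code = "N06AB04",
    daily_dose_mg = c(60, 20),
    start_date = as.Date(c("2016-01-01", "2016-06-01")),
    end_date = as.Date(c("2016-06-01", NA)))
  cohort <- mini_cohort(pats, rx)
  sb <- run_snapshot(cohort, cat16, "2016-04-01")
  sf <- run_snapshot(cohort, cat16, "2016-12-01")
  cmp <- compare_snapshots(sb, sf, cohort)
  expect_equal(cmp$resolved$rule_id, "cital_dose_high")
  expect_equal(cmp$resolved$resolution_reason, "drug_dropped")
  expect_true(cmp$resolved$unattributed)
})

test_that("cross-year snapshots refuse to compare", {
  sim <- generate_cohort(generator_config(n_patients = 20, seed = 2), cat16)
  sb <- run_snapshot(sim$cohort, cat16, sim$baseline_date)
  sf18 <- run_snapshot(sim$cohort, builtin_catalog("2018"), sim$final_date)
  expect_error(compare_snapshots(sb, sf18, sim$cohort), "different catalog years")
  expect_error(compare_snapshots(sb, sb, sim$cohort), "predate")
})

test_that("comparison conserves alerts and matches generator bookkeeping", {
  sim <- generate_cohort(generator_config(n_patients = 250, seed = 13), cat16)
  sb <- run_snapshot(sim$cohort, cat16, sim$baseline_date)
  sf <- run_snapshot(sim$cohort, cat16, sim$final_date)
  cmp <- compare_snapshots(sb, sf, sim$cohort)
  # conservation by identity key
  expect_setequal(c(cmp$resolved$identity_key, cmp$persisting$identity_key),
                  sb$alerts$identity_key)
  expect_setequal(c(cmp$persisting$identity_key, cmp$new$identity_key),
                  sf$alerts$identity_key)
  # per-category table sums to the snapshot totals
  expect_equal(sum(cmp$per_category_variation$baseline), nrow(sb$alerts))
  expect_equal(sum(cmp$per_category_variation$final), nrow(sf$alerts))
  # generator bookkeeping recovered exactly
  gt <- sim$ground_truth$plants
  expect_setequal(cmp$resolved$identity_key,
                  gt$identity_key[gt$status == "resolved"])
  expect_setequal(cmp$new$identity_key, gt$identity_key[gt$status == "new"])
})

test_that("category report totals equal column sums", {
  sim <- generate_cohort(generator_config(n_patients = 150, seed = 8), cat16)
  sb <- run_snapshot(sim$cohort, cat16, sim$baseline_date)
  sf <- run_snapshot(sim$cohort, cat16, sim$final_date)
  cmp <- compare_snapshots(sb, sf, sim$cohort)
  rep <- build_category_report(list(y2016 = cmp))
  tot <- rep[rep$category == "Total", ]
  part <- rep[rep$category != "Total", ]
  expect_equal(tot$baseline, sum(part$baseline))
  expect_equal(tot$final, sum(part$final))
  expect_equal(tot$variation, sum(part$variation))
  expect_equal(tidy(cmp) |> nrow(),
               nrow(cmp$resolved) + nrow(cmp$persisting) + nrow(cmp$new))
})
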