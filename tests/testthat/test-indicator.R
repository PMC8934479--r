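cat16 <- builtin_catalog("2016")

test_that("indicator counts only the linked alerts, grouped by physician", {
  # planted cohort: relevant duplications + regulatory alerts + polymedication
  # are linked; geriatric / avoidable / insulin-duplication alerts are not
  prev <- c(dup_group_ras_inhibitors = 0.15, cital_dose_high = 0.1,
            polymedication = 0.05, geriatric_list = 0.1,
            avoidable_list = 0.1, dup_group_insulins = 0.1)
  sim <- generate_cohort(
    generator_config(n_patients = 300, seed = 19, per_rule_prevalence = prev,
                     resolution_probability = 0, new_mrp_rate = 0),
    cat16)
  snap <- run_snapshot(sim$cohort, cat16, sim$baseline_date)
  counts <- indicator_counts(snap)
  gt <- sim$ground_truth$plants
  linked_rules <- c("dup_group_ras_inhibitors", "cital_dose_high",
                    "polymedication", "antichol_combo")
  # antichol_combo rides along with polymedication plants but is not linked
  expected <- table(gt$physician_id[gt$rule_id %in%
                                      setdiff(linked_rules, "antichol_combo")])
  got <- stats::setNames(counts$n_linked, counts$physician_id)
  expect_equal(sort(names(got)), sort(names(expected)))
  expect_equal(as.integer(got[names(expected)]), as.integer(expected))
  expect_equal(sum(counts$n_linked), sum(snap$alerts$indicator_linked))
})

test_that("unlinked-only snapshots count zero and empty snapshots give an empty map", {
  prev <- c(geriatric_list = 0.3, avoidable_list = 0.2)
  sim <- generate_cohort(
    generator_config(n_patients = 100, seed = 23, per_rule_prevalence = prev),
    cat16)
  snap <- run_snapshot(sim$cohort, cat16, sim$baseline_date)
  expect_gt(nrow(snap$alerts), 0)
  expect_equal(nrow(indicator_counts(snap)), 0)
  empty <- counts_snapshot(list(), "2016-04-01")
  expect_equal(nrow(indicator_counts(empty)), 0)
})

test_that("goal attainment follows the definition at each checkpoint", {
  cfg <- indicator_config("2016", goal_reduction = 2)
  base <- counts_snapshot(list(D1 = 10), "2016-04-01")
  res8 <- evaluate_indicator(
    base, list(counts_snapshot(list(D1 = 9), "2016-09-01"),
               counts_snapshot(list(D1 = 8), "2016-12-01")), cfg)
  expect_equal(res8$results$goal_met, c(FALSE, TRUE))
  expect_equal(res8$summary$final_variation, -2L)
  expect_equal(res8$summary$final_pct, -20L)
  expect_true(res8$summary$goal_met_final)

  # degenerate goal of 0: met whenever the count does not rise
  cfg0 <- indicator_config("2016", goal_reduction = 0)
  res0 <- evaluate_indicator(
    base, list(counts_snapshot(list(D1 = 10), "2016-09-01"),
               counts_snapshot(list(D1 = 11), "2016-12-01")), cfg0)
  expect_equal(res0$results$goal_met, c(TRUE, FALSE))

  expect_error(evaluate_indicator(
    base, list(counts_snapshot(list(D1 = 9), "2016-09-01")), cfg),
    "2016-12-01")
})

test_that("default evaluation calendars match the study years", {
  expect_equal(format(indicator_config("2016")$checkpoint_dates),
               c("2016-09-01", "2016-12-01"))
  expect_equal(format(indicator_config("2018")$checkpoint_dates),
               c("2018-06-01", "2018-09-01", "2018-12-01"))
})

test_that("lowering a checkpoint count never breaks an attained goal", {
  cfg <- indicator_config("2016", goal_reduction = 3)
  base <- counts_snapshot(list(D1 = 12), "2016-04-01")
  for (count in 12:0) {
    res <- evaluate_indicator(
      base, list(counts_snapshot(list(D1 = count), "2016-09-01"),
                 counts_snapshot(list(D1 = count), "2016-12-01")), cfg)
    met <- res$results$goal_met[2]
    if (count <= 9) expect_true(met) else expect_false(met)
  }
})

test_that("fractional goals scale with the baseline", {
  cfg <- indicator_config("2016", goal_reduction = 0.25,
                          goal_type = "fraction")
  base <- counts_snapshot(list(D1 = 8, D2 = 4), "2016-04-01")
  res <- evaluate_indicator(
    base, list(counts_snapshot(list(D1 = 6, D2 = 4), "2016-09-01"),
               counts_snapshot(list(D1 = 6, D2 = 3), "2016-12-01")), cfg)
  sept <- res$results[res$results$checkpoint_date == as.Date("2016-09-01"), ]
  expect_equal(sept$goal_met, c(TRUE, FALSE))   # 6 <= 6, 4 > 3
  dec <- res$results[res$results$checkpoint_date == as.Date("2016-12-01"), ]
  expect_equal(dec$goal_met, c(TRUE, TRUE))
})

test_that("indicator aggregation sums the three linked categories", {
  expect_equal(indicator_aggregate(c(duplicate_therapy = 5413,
                                     aemps_alert = 6815,
                                     polymedication = 5130))$total_resolved,
               17358L)
  expect_equal(indicator_aggregate(c(duplicate_therapy = 3485,
                                     aemps_alert = 1735,
                                     polymedication = 2915))$total_resolved,
               8135L)
  expect_equal(indicator_aggregate(c(duplicate_therapy = 0, aemps_alert = 0,
                                     polymedication = 0))$total_resolved, 0L)
  agg <- indicator_aggregate(c(duplicate_therapy = 5413, aemps_alert = 6815,
                               polymedication = 5130),
                             baseline_linked_total = 42337)
  expect_equal(agg$pct, 41L)
  expect_error(indicator_aggregate(c(duplicate_therapy = 1, aemps_alert = 1)),
               "exactly")
  expect_error(indicator_aggregate(c(a = 1, b = 2, c = 3)), "exactly")
})

test_that("goal-met fraction matches the analytic expectation on planted cohorts", {
  # one indicator-linked rule, resolution probability p, no new problems:
  # a physician with b baseline alerts meets a goal of 1 with probability
  # 1 - (1-p)^b
  p <- 0.2
  sim <- generate_cohort(
    generator_config(n_patients = 1200, n_physicians = 60, seed = 55,
                     per_rule_prevalence = c(cital_dose_high = 0.2),
                     resolution_probability = p, new_mrp_rate = 0),
    cat16)
  sb <- run_snapshot(sim$cohort, cat16, sim$baseline_date)
  sf <- run_snapshot(sim$cohort, cat16, sim$final_date)
  cfg <- indicator_config("2016", goal_reduction = 1,
                          checkpoint_dates = sim$final_date)
  res <- evaluate_indicator(sb, list(sf), cfg)
  b_i <- res$summary$baseline_count
  expect_true(all(b_i > 0))
  q_i <- 1 - (1 - p)^b_i
  expected <- mean(q_i)
  observed <- mean(res$summary$goal_met_final)
  se <- sqrt(sum(q_i * (1 - q_i))) / length(q_i)
  expect_lt(abs(observed - expected), 3 * se)
})
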