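cs <- code_sets()

test_that("office BP criterion applies the two-arm threshold rule", {
  expect_true(bp_criteria_met(bp("A", 165, 88), cs))                     # single-reading arm
  expect_true(bp_criteria_met(bp("A", 130, 101), cs))                    # diastolic alone
  expect_true(bp_criteria_met(rbind(bp("A", 144, 92, "2016-01-01"),
                                    bp("A", 141, 85, "2016-01-30")), cs))
  # same calendar date never satisfies the two-day arm
  expect_false(bp_criteria_met(rbind(bp("A", 144, 92, "2016-01-01"),
                                     bp("A", 150, 95, "2016-01-01")), cs))
  expect_false(bp_criteria_met(bp("A", 139, 89), cs))
  expect_false(bp_criteria_met(bp("A", 120, 80)[0, ], cs))               # empty
  # "and" mode requires both components to cross
  cs_and <- code_sets(bp_rule = "and")
  expect_false(bp_criteria_met(bp("A", 165, 88), cs_and))
  expect_true(bp_criteria_met(bp("A", 165, 101), cs_and))
})

test_that("hypertension tiers follow claims > problem list > BP precedence", {
  claims_and_pl <- rbind(dx("A", "I10"), dx("A", "I10", source = "problem_list"))
  expect_identical(hypertension_tier(claims_and_pl, NULL, cs), "claims")
  expect_identical(hypertension_tier(dx("A", "I10", source = "problem_list"), NULL, cs),
                   "problem_list")
  readings <- rbind(bp("A", 150, 95, "2016-01-01"), bp("A", 142, 90, "2016-01-08"))
  expect_identical(hypertension_tier(NULL, readings, cs), "bp_criteria")
  expect_identical(hypertension_tier(dx("A", "I10"), readings, cs), "claims")
  expect_identical(hypertension_tier(dx("A", "J44.9"), NULL, cs), "none")
  # prefix matching is on the undotted code: I11.9 matches the I11 prefix
  expect_identical(hypertension_tier(dx("A", "I11.9"), NULL, cs), "claims")
})

test_that("comorbidity flags record the earliest evidence level", {
  f <- condition_flags(NULL, meas("A", "bmi", 31.2), cs)
  expect_identical(unname(f["obesity"]), "plus_clinical")
  f <- condition_flags(dx("A", "E66.9"), NULL, cs)
  expect_identical(unname(f["obesity"]), "claims_only")
  # chronicity: a single low eGFR is not CKD
  f <- condition_flags(NULL, meas("A", "egfr", 45), cs)
  expect_identical(unname(f["ckd"]), "none")
  f <- condition_flags(NULL, rbind(meas("A", "egfr", 45, "2016-01-10"),
                                   meas("A", "egfr", 50, "2016-05-10")), cs)
  expect_identical(unname(f["ckd"]), "plus_clinical")
  # two low eGFRs only 30 days apart fail the 90-day requirement
  f <- condition_flags(NULL, rbind(meas("A", "egfr", 45, "2016-01-10"),
                                   meas("A", "egfr", 50, "2016-02-09")), cs)
  expect_identical(unname(f["ckd"]), "none")
  # diabetes by two fasting glucose results on distinct dates
  f <- condition_flags(NULL, rbind(meas("A", "fasting_glucose", 130, "2016-01-10"),
                                   meas("A", "fasting_glucose", 127, "2016-01-10")), cs)
  expect_identical(unname(f["diabetes"]), "none")
  f <- condition_flags(NULL, rbind(meas("A", "fasting_glucose", 130, "2016-01-10"),
                                   meas("A", "fasting_glucose", 127, "2016-03-10")), cs)
  expect_identical(unname(f["diabetes"]), "plus_clinical")
})

test_that("observed prevalence enumerates admissible tiers at each level", {
  patients <- rbind(pt("E1"), pt("E2"), pt("E3"), pt("E4"))
  x <- cohort(patients,
              encounters = rbind(visit("E1"), visit("E2"), visit("E3"), visit("E4")),
              diagnoses = rbind(dx("E1", "I10"), dx("E2", "I10", source = "problem_list")),
              bp_readings = rbind(bp("E3", 165, 95)),
              observation_year = 2016)
  el <- eligible_patients(x)
  expect_equal(observed_prevalence(x, el, "claims_only")$value, 0.25)
  expect_equal(observed_prevalence(x, el, "plus_problem_list")$value, 0.50)
  expect_equal(observed_prevalence(x, el, "plus_clinical")$value, 0.75)

  # all none -> 0 everywhere
  x0 <- cohort(patients, encounters = rbind(visit("E1"), visit("E2"), visit("E3"), visit("E4")),
               observation_year = 2016)
  for (lv in c("claims_only", "plus_problem_list", "plus_clinical")) {
    expect_equal(observed_prevalence(x0, eligible_patients(x0), lv)$value, 0)
  }
})

test_that("comorbidity count buckets enumerate correctly", {
  patients <- rbind(pt("F1"), pt("F2"), pt("F3"))
  x <- cohort(patients, encounters = rbind(visit("F1"), visit("F2"), visit("F3")),
              diagnoses = rbind(dx("F1", "E66.9"),
                                dx("F2", "E66.9"), dx("F2", "E11.9")),
              observation_year = 2016)
  d <- comorbidity_distribution(x, eligible_patients(x), "claims_only")
  expect_equal(unname(d$buckets), c(1 / 3, 1 / 3, 1 / 3), tolerance = 1e-12)
  x0 <- cohort(patients, encounters = rbind(visit("F1"), visit("F2"), visit("F3")),
               observation_year = 2016)
  d0 <- comorbidity_distribution(x0, eligible_patients(x0), "claims_only")
  expect_equal(unname(d0$buckets), c(1, 0, 0))
  expect_equal(sum(d$buckets), 1, tolerance = 1e-12)
})

test_that("tier exclusivity: tier counts sum to the eligible denominator", {
  x <- random_cohort(99, n = 120)
  el <- eligible_patients(x)
  asc <- ascertain_cohort(x, el)
  expect_identical(nrow(asc), length(el))
  expect_true(all(asc$htn_tier %in% c("none", "claims", "problem_list", "bp_criteria")))
  expect_identical(sum(table(asc$htn_tier)), length(el))
})

test_that("vectorized ascertainment equals the brute-force oracle on random cohorts", {
  for (s in 1:40) {
    x <- random_cohort(seed = 5000 + s, n = sample(20:200, 1))
    el <- eligible_patients(x)
    if (length(el) == 0) next
    asc <- ascertain_cohort(x, el)
    for (id in el) {
      row <- asc[asc$patient_id == id, ]
      expect_identical(row$htn_tier, oracle_tier_one(x, id, cs),
                       label = sprintf("tier, seed %d, %s", s, id))
      fl <- oracle_flags_one(x, id, cs)
      expect_identical(row$obesity_level, unname(fl["obesity"]))
      expect_identical(row$diabetes_level, unname(fl["diabetes"]))
      expect_identical(row$ckd_level, unname(fl["ckd"]))
    }
  }
})

test_that("observed prevalence and per-condition prevalence are monotone in evidence level", {
  for (s in 1:30) {
    x <- random_cohort(seed = 7000 + s, n = 80)
    el <- eligible_patients(x)
    if (length(el) == 0) next
    asc <- ascertain_cohort(x, el)
    obs <- vapply(c("claims_only", "plus_problem_list", "plus_clinical"),
                  function(lv) observed_prevalence(x, el, lv, ascertainment = asc)$value,
                  numeric(1))
    expect_true(all(diff(obs) >= 0))
    dists <- lapply(c("claims_only", "plus_problem_list", "plus_clinical"),
                    function(lv) comorbidity_distribution(x, el, lv, ascertainment = asc))
    conds <- do.call(rbind, lapply(dists, `[[`, "conditions"))
    expect_true(all(apply(conds, 2, function(v) all(diff(v) >= 0))))
    # 2-3-condition bucket share is non-decreasing across levels too
    expect_true(all(diff(vapply(dists, function(d) d$buckets[["two_or_three"]], numeric(1))) >= -1e-12))
  }
})

test_that("claims-level prevalence recovers sensitivity x true prevalence", {
  p <- sim_params(n_patients = 20000, org_count = 4, true_htn_prevalence = 0.35,
                  claims_sensitivity = c(hypertension = 0.85, obesity = 0.24,
                                         diabetes = 0.69, ckd = 0.46),
                  org_effect_sd = 0, seed = 3)
  sim <- generate_cohort(p)
  obs <- observed_prevalence(sim$cohort, level = "claims_only")
  se3 <- 3 * sqrt(0.2975 * (1 - 0.2975) / 20000)
  expect_lt(abs(obs$value - 0.2975), se3)
})

test_that("BP-screening gap counts patients with no in-year reading", {
  ids <- sprintf("G%02d", 1:10)
  patients <- do.call(rbind, lapply(ids, pt))
  encounters <- do.call(rbind, lapply(ids, visit))
  readings <- do.call(rbind, lapply(ids[1:8], function(i) bp(i, 120, 80)))
  # out-of-year readings do not count as screened
  readings <- rbind(readings, bp(ids[9], 120, 80, "2015-06-01"))
  x <- cohort(patients, encounters, bp_readings = readings, observation_year = 2016)
  g <- bp_screening_gap(x)
  expect_equal(g$overall, 0.20)
  x2 <- cohort(patients, encounters,
               bp_readings = do.call(rbind, lapply(ids, function(i) bp(i, 120, 80))),
               observation_year = 2016)
  expect_equal(bp_screening_gap(x2)$overall, 0)
})
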