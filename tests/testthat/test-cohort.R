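test_that("cohort CSV round-trip reproduces the tables exactly", {
  x <- fixture_cohort_10()
  dir <- withr::local_tempdir()
  write_cohort(x, dir)
  y <- read_cohort(dir, 2016)
  for (tb in c("patients", "encounters", "diagnoses", "bp_readings", "measurements")) {
    expect_identical(y[[tb]], x[[tb]], label = tb)
  }
})

test_that("an empty cohort round-trips as five header-only files", {
  x <- cohort(pt("Z1")[0, ], observation_year = 2016)
  dir <- withr::local_tempdir()
  write_cohort(x, dir)
  files <- list.files(dir)
  expect_setequal(files, c("patients.csv", "encounters.csv", "diagnoses.csv",
                           "bp_readings.csv", "measurements.csv"))
  for (f in files) expect_length(readLines(file.path(dir, f)), 1L)
  y <- read_cohort(dir, 2016)
  expect_identical(nrow(y$patients), 0L)
})

test_that("a generated 1000-patient cohort round-trips field by field", {
  sim <- generate_cohort(sim_params(n_patients = 1000, org_count = 4, seed = 1))
  dir <- withr::local_tempdir()
  write_cohort(sim$cohort, dir)
  y <- read_cohort(dir, 2016)
  for (tb in c("patients", "encounters", "diagnoses", "bp_readings", "measurements")) {
    expect_identical(y[[tb]], sim$cohort[[tb]], label = tb)
  }
})

test_that("rows violating invariants are rejected with row-level diagnostics", {
  x <- fixture_cohort_10()
  dir <- withr::local_tempdir()
  write_cohort(x, dir)

  # unknown patient_id in diagnoses
  dxf <- file.path(dir, "diagnoses.csv")
  writeLines(c(readLines(dxf), "GHOST,2016-02-01,I10,claim"), dxf)
  err <- expect_error(read_cohort(dir, 2016), "diagnoses row 5")
  expect_match(conditionMessage(err), "not in patients table")

  # diastolic >= systolic
  write_cohort(x, dir)
  bpf <- file.path(dir, "bp_readings.csv")
  writeLines(c(readLines(bpf), "B1,2016-02-01,80,120"), bpf)
  expect_error(read_cohort(dir, 2016), "diastolic outside|diastolic not below")

  # malformed header
  write_cohort(x, dir)
  pf <- file.path(dir, "patients.csv")
  lines <- readLines(pf)
  lines[1] <- "patient_id,org_id,sex,years,race_ethnicity"
  writeLines(lines, pf)
  expect_error(read_cohort(dir, 2016), "malformed header")

  # missing file
  file.remove(file.path(dir, "measurements.csv"))
  expect_error(read_cohort(dir, 2016), "missing file.*measurements")
})

test_that("constructor rejects out-of-enum and malformed values", {
  expect_error(cohort(pt("A", sex = "unknown"), observation_year = 2016), "sex")
  expect_error(cohort(pt("A", age = -3), observation_year = 2016), "age")
  expect_error(cohort(rbind(pt("A"), pt("A")), observation_year = 2016), "duplicate")
  expect_error(
    cohort(pt("A"), diagnoses = dx("A", "invalid-code"), observation_year = 2016),
    "ICD-10-CM")
})

test_that("eligibility applies the age band and in-year ambulatory E&M rule", {
  x <- fixture_cohort_10()
  el <- eligible_patients(x)
  expect_setequal(el, c("B1", "B2", "B3", "B4", "B5", "B6"))
  expect_false("A1" %in% el)  # age 17 with a visit
  expect_true("B1" %in% el)   # age 30, in-year ambulatory visit
  expect_false("C1" %in% el)  # only 'other' encounters
  expect_false("D1" %in% el)  # visit dated in prior year
})

test_that("eligibility matches a brute-force filter on random cohorts", {
  for (s in 1:25) {
    x <- random_cohort(seed = 1000 + s, n = sample(20:200, 1))
    expect_setequal(eligible_patients(x), oracle_eligible(x))
  }
})

test_that("age bands partition [18, 85]: every integer maps to exactly one band", {
  expect_identical(age_group(44), "18-44")
  expect_identical(age_group(45), "45-64")
  expect_identical(age_group(85), "75-85")
  bands <- age_group(18:85)
  expect_false(anyNA(bands))
  expect_identical(sort(unique(bands)), sort(c("18-44", "45-64", "65-74", "75-85")))
  counts <- table(bands)
  expect_identical(sum(counts), 68L)  # 18..85 inclusive, each exactly once
  expect_error(age_group(17), "\\[18, 85\\]")
  expect_error(age_group(86), "\\[18, 85\\]")
})

test_that("demographic percentages are non-negative and sum to 100 per characteristic", {
  patients <- rbind(pt("S1"), pt("S2"), pt("S3", sex = "male"), pt("S4", sex = "male"))
  x <- cohort(patients, encounters = rbind(visit("S1"), visit("S2"), visit("S3"), visit("S4")),
              observation_year = 2016)
  dem <- summarize_demographics(x)
  sexrow <- dem[dem$org_id == "overall" & dem$characteristic == "sex", ]
  expect_equal(sexrow$percent[sexrow$level == "female"], 50)
  expect_equal(sexrow$percent[sexrow$level == "male"], 50)
  race <- dem[dem$org_id == "overall" & dem$characteristic == "race_ethnicity", ]
  expect_equal(race$percent[race$level == "nh_white"], 100)
  expect_equal(sum(race$percent[race$level != "nh_white"]), 0)

  x2 <- random_cohort(7, n = 150)
  dem2 <- summarize_demographics(x2)
  for (org in unique(dem2$org_id)) {
    for (ch in c("age_group", "sex", "race_ethnicity")) {
      block <- dem2[dem2$org_id == org & dem2$characteristic == ch, ]
      expect_true(all(block$percent >= 0))
      expect_equal(sum(block$percent), 100, tolerance = 1e-9)
    }
  }
  expect_error(summarize_demographics(x, eligible = character(0)), "empty")
})

test_that("generated cohorts reproduce the configured sex mix (Monte Carlo)", {
  sim <- generate_cohort(sim_params(n_patients = 10000, org_count = 5, seed = 1))
  dem <- summarize_demographics(sim$cohort, sim$cohort$patients$patient_id)
  fem <- dem$percent[dem$org_id == "overall" & dem$characteristic == "sex" &
                       dem$level == "female"]
  # 3 binomial SE of p = 0.573 at n = 10,000 is about 1.5 percentage points
  expect_lt(abs(fem - 57.3), 3 * 100 * sqrt(0.573 * 0.427 / 10000))
})
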