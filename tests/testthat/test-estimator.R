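# uniform joint reference table built directly (prevalence p everywhere)
uniform_reference <- function(p = 0.4, se = 0, buckets_share = c(1 / 3, 1 / 3, 1 / 3)) {
  grid <- expand.grid(sex = c("female", "male"),
                      race_ethnicity = c("nh_white", "nh_black", "hispanic", "other"),
                      age_group = c("18-44", "45-64", "65-74", "75-85"),
                      count_bucket = c("zero", "one", "two_or_three"),
                      stringsAsFactors = FALSE)
  grid$prevalence <- p
  grid$se <- se
  bk <- unique(grid[c("sex", "race_ethnicity", "age_group")])
  bk <- bk[rep(seq_len(nrow(bk)), each = 3), ]
  bk$count_bucket <- rep(c("zero", "one", "two_or_three"), 32)
  bk$share <- rep(buckets_share, 32)
  reference_table(grid, buckets = bk, mode = "joint")
}

test_that("stratum weights count patients and normalize", {
  patients <- rbind(pt("W1"), pt("W2"))
  x <- cohort(patients, encounters = rbind(visit("W1"), visit("W2")),
              observation_year = 2016)
  w <- stratum_weights(x, use_comorbidity = FALSE)
  expect_identical(nrow(as.data.frame(w)), 1L)  # identical stratum
  expect_equal(w$weight, 1)

  patients2 <- rbind(pt("W1"), pt("W2", sex = "male"))
  x2 <- cohort(patients2, encounters = rbind(visit("W1"), visit("W2")),
               observation_year = 2016)
  w2 <- stratum_weights(x2, use_comorbidity = FALSE)
  expect_equal(sort(w2$weight), c(0.5, 0.5))
})

test_that("missing race/ethnicity is redistributed within cells, preserving proportions", {
  set.seed(14)
  n <- 100
  patients <- data.frame(
    patient_id = sprintf("M%03d", 1:n), org_id = "org1",
    sex = sample(c("female", "male"), n, TRUE),
    age = sample(18:85, n, TRUE),
    race_ethnicity = c(rep("missing", 10),
                       sample(c("nh_white", "nh_black", "hispanic", "other"), 90, TRUE,
                              prob = c(.6, .2, .1, .1))),
    stringsAsFactors = FALSE)
  x <- cohort(patients, encounters = do.call(rbind, lapply(patients$patient_id, visit)),
              observation_year = 2016)
  w <- stratum_weights(x, use_comorbidity = FALSE)
  expect_equal(sum(w$weight), 1, tolerance = 1e-12)
  expect_true(all(w$race_ethnicity != "missing"))
  # brute-force reallocation: within each sex x age cell the known-race
  # proportions are preserved
  df <- data.frame(sex = patients$sex, age_group = age_group(patients$age),
                   race = patients$race_ethnicity)
  for (cell in unique(paste(df$sex, df$age_group))) {
    sub <- df[paste(df$sex, df$age_group) == cell, ]
    known <- sub$race[sub$race != "missing"]
    wc <- w[paste(w$sex, w$age_group) == cell, ]
    if (length(known) > 0) {
      expected <- nrow(sub) * table(known) / length(known)
      got <- stats::setNames(wc$weight * 100, wc$race_ethnicity)
      for (r in names(expected)) {
        expect_equal(unname(got[r]), unname(expected[r]), tolerance = 1e-9,
                     label = paste("cell", cell, "race", r))
      }
    }
  }
})

test_that("predicted prevalence is the weighted stratum mean with propagated SE", {
  ref <- uniform_reference(p = 0.4, se = 0)
  # overwrite two strata to 0.20 / 0.40 and weight them half-and-half
  st <- ref$strata
  st$prevalence[1] <- 0.20
  st$prevalence[2] <- 0.40
  ref2 <- reference_table(st, buckets = ref$buckets, mode = "joint")
  w <- st[1:2, c("sex", "race_ethnicity", "age_group", "count_bucket")]
  w$weight <- c(0.5, 0.5)
  est <- predicted_prevalence(w, ref2, n = 1000)
  expect_equal(est$value, 0.30, tolerance = 1e-12)
  expect_equal(est$ci_low, 0.30, tolerance = 1e-12)
  expect_equal(est$ci_high, 0.30, tolerance = 1e-12)

  # single stratum: identity
  w1 <- st[5, c("sex", "race_ethnicity", "age_group", "count_bucket")]
  w1$weight <- 1
  st$prevalence[5] <- 0.335
  ref3 <- reference_table(st, buckets = ref$buckets, mode = "joint")
  expect_equal(predicted_prevalence(w1, ref3, n = 10)$value, 0.335, tolerance = 1e-12)
})

test_that("predicted prevalence equals the patient-level expectation oracle", {
  set.seed(31)
  for (rep in 1:10) {
    ref <- uniform_reference()
    st <- ref$strata
    st$prevalence <- runif(nrow(st))
    st$se <- runif(nrow(st), 0, 0.05)
    ref <- reference_table(st, buckets = ref$buckets, mode = "joint")
    pick <- sample(nrow(st), 6)
    w <- st[pick, c("sex", "race_ethnicity", "age_group", "count_bucket")]
    raw <- runif(6)
    w$weight <- raw / sum(raw)
    est <- predicted_prevalence(w, ref, n = 500)
    expect_equal(est$value, oracle_predicted(w, ref), tolerance = 1e-12)
    # boundedness in the weighted strata
    expect_gte(est$value, min(st$prevalence[pick]) - 1e-12)
    expect_lte(est$value, max(st$prevalence[pick]) + 1e-12)
  }
})

test_that("errors: mode mismatch and missing strata are reported", {
  ref <- uniform_reference()
  w_demo <- data.frame(sex = "female", race_ethnicity = "nh_white",
                       age_group = "18-44", weight = 1)
  expect_error(predicted_prevalence(w_demo, ref, n = 10), "mode mismatch")
  w_bad <- data.frame(sex = "female", race_ethnicity = "nh_white",
                      age_group = "18-44", count_bucket = "four", weight = 1)
  expect_error(predicted_prevalence(w_bad, ref, n = 10), "missing from reference table")
})

test_that("folding reference comorbidity distributions is a weighted mean", {
  ref <- uniform_reference(buckets_share = c(0.5, 0.3, 0.2))
  st <- ref$strata
  # bucket-specific prevalences 0.2/0.4/0.6 within every demographic stratum
  st$prevalence <- unname(c(zero = 0.2, one = 0.4, two_or_three = 0.6)[st$count_bucket])
  st$se <- 0
  ref <- reference_table(st, buckets = ref$buckets, mode = "joint")
  folded <- fold_reference_comorbidity(ref)
  expect_true(all(abs(folded$strata$prevalence - 0.34) < 1e-12))

  # uniform prevalence across buckets: folding changes nothing
  ref_u <- uniform_reference(p = 0.37, buckets_share = c(0.5, 0.3, 0.2))
  folded_u <- fold_reference_comorbidity(ref_u)
  expect_true(all(abs(folded_u$strata$prevalence - 0.37) < 1e-12))
  expect_error(fold_reference_comorbidity(folded_u), "already demographic")
})

test_that("folding then predicting equals predicting with reference-bucket joint weights", {
  set.seed(91)
  ref <- uniform_reference(buckets_share = c(0.45, 0.35, 0.2))
  st <- ref$strata
  st$prevalence <- runif(nrow(st))
  st$se <- runif(nrow(st), 0, 0.03)
  ref <- reference_table(st, buckets = ref$buckets, mode = "joint")
  # random demographic weights
  demo <- unique(st[c("sex", "race_ethnicity", "age_group")])
  raw <- runif(nrow(demo))
  demo$weight <- raw / sum(raw)
  est_folded <- predicted_prevalence(demo, fold_reference_comorbidity(ref), n = 100)
  joint <- tool_compatibility_weights(demo, c(zero = 0.45, one = 0.35, two_or_three = 0.2))
  est_joint <- predicted_prevalence(joint, ref, n = 100)
  expect_equal(est_folded$value, est_joint$value, tolerance = 1e-12)
})

test_that("tool-compatibility weights multiply marginals", {
  demo <- data.frame(sex = c("female", "male"), race_ethnicity = "nh_white",
                     age_group = "18-44", weight = c(0.6, 0.4))
  w <- tool_compatibility_weights(demo, c(zero = 0.5, one = 0.5, two_or_three = 0))
  expect_identical(nrow(as.data.frame(w)), 4L)
  first_zero <- w$weight[w$sex == "female" & w$count_bucket == "zero"]
  expect_equal(first_zero, 0.30, tolerance = 1e-12)
  # degenerate bucket marginal leaves demographic weights unchanged
  w1 <- tool_compatibility_weights(demo, c(zero = 1, one = 0, two_or_three = 0))
  expect_equal(sort(w1$weight), c(0.4, 0.6), tolerance = 1e-12)
  expect_true(all(w1$count_bucket == "zero"))
  expect_error(tool_compatibility_weights(demo, c(zero = 0.5, one = 0.2, two_or_three = 0.2)),
               "sum to 1")
})

test_that("patient-level joint weights approximate product weights under independence", {
  # generator assigns comorbidities independently of demographics
  sim <- generate_cohort(sim_params(n_patients = 20000, org_count = 2, seed = 17,
                                    org_effect_sd = 0))
  x <- sim$cohort
  el <- eligible_patients(x)
  asc <- ascertain_cohort(x, el)
  wj <- stratum_weights(x, el, "plus_clinical", use_comorbidity = TRUE, ascertainment = asc)
  wd <- stratum_weights(x, el, "plus_clinical", use_comorbidity = FALSE, ascertainment = asc)
  dist <- comorbidity_distribution(x, el, "plus_clinical", ascertainment = asc)
  wp <- tool_compatibility_weights(wd, dist$buckets)
  key_j <- paste(wj$sex, wj$race_ethnicity, wj$age_group, wj$count_bucket)
  key_p <- paste(wp$sex, wp$race_ethnicity, wp$age_group, wp$count_bucket)
  shared <- intersect(key_j, key_p)
  diffs <- abs(wj$weight[match(shared, key_j)] - wp$weight[match(shared, key_p)])
  # each joint cell within 3 MC SE of the product weight
  pw <- wp$weight[match(shared, key_p)]
  expect_true(all(diffs <= 3 * sqrt(pw * (1 - pw) / length(el)) + 1e-6))
})

test_that("self-consistency: reference composition returns reference overall prevalence", {
  set.seed(55)
  ref <- uniform_reference()
  st <- ref$strata
  st$prevalence <- runif(nrow(st))
  ref <- reference_table(st, buckets = ref$buckets, mode = "joint")
  raw <- runif(nrow(st))
  w <- st[c("sex", "race_ethnicity", "age_group", "count_bucket")]
  w$weight <- raw / sum(raw)
  overall <- sum(w$weight * st$prevalence)
  expect_equal(predicted_prevalence(w, ref, n = 100)$value, overall, tolerance = 1e-12)
})

test_that("reference tables round-trip through CSV", {
  p <- sim_params(n_patients = 10, seed = 4)
  ref <- generate_reference_table(p)
  dir <- withr::local_tempdir()
  f1 <- file.path(dir, "reference_table.csv")
  f2 <- file.path(dir, "reference_buckets.csv")
  write_reference_table(ref, f1, f2)
  back <- read_reference_table(f1, f2)
  expect_identical(back$mode, "joint")
  expect_equal(back$strata$prevalence, ref$strata$prevalence, tolerance = 1e-12)
  expect_equal(back$buckets$share, ref$buckets$share, tolerance = 1e-12)
  expect_error(read_reference_table(file.path(dir, "nope.csv")), "not found")
  # completeness is enforced
  expect_error(reference_table(ref$strata[-1, ], mode = "joint"), "missing")
})
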