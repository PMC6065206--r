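# Builders for small hand-made cohorts and independent brute-force oracles.
# The oracles deliberately avoid the package's vectorized code paths: they
# loop patient by patient over raw rows.

pt <- function(id, org = "org1", sex = "female", age = 50, race = "nh_white") {
  data.frame(patient_id = id, org_id = org, sex = sex, age = as.integer(age),
             race_ethnicity = race, stringsAsFactors = FALSE)
}

visit <- function(id, date = "2016-03-01", setting = "ambulatory_em") {
  data.frame(patient_id = id, date = as.Date(date), setting = setting,
             stringsAsFactors = FALSE)
}

dx <- function(id, code, source = "claim", date = "2016-03-01") {
  data.frame(patient_id = id, date = as.Date(date), code = code, source = source,
             stringsAsFactors = FALSE)
}

bp <- function(id, sys, dia, date = "2016-03-01") {
  data.frame(patient_id = id, date = as.Date(date), systolic = as.integer(sys),
             diastolic = as.integer(dia), stringsAsFactors = FALSE)
}

meas <- function(id, kind, value, date = "2016-03-01") {
  data.frame(patient_id = id, date = as.Date(date), kind = kind, value = value,
             stringsAsFactors = FALSE)
}

rbind_or_null <- function(lst) if (length(lst)) do.call(rbind, lst) else NULL

# A 10-patient fixture matching the eligibility example: 2 under-age,
# 1 with only non-E&M encounters, 1 with a prior-year visit, 6 eligible.
fixture_cohort_10 <- function() {
  patients <- rbind(
    pt("A1", age = 17), pt("A2", age = 16),                  # under-age
    pt("B1", age = 30), pt("B2", age = 44, sex = "male"),
    pt("B3", age = 65, race = "nh_black"), pt("B4", age = 85),
    pt("B5", age = 52, race = "hispanic"), pt("B6", age = 40, org = "org2"),
    pt("C1", age = 33),                                       # only 'other' encounters
    pt("D1", age = 61))                                       # visit in prior year
  encounters <- rbind(
    visit("A1"), visit("A2"), visit("B1"), visit("B2"), visit("B3"),
    visit("B4"), visit("B5"), visit("B6"),
    visit("C1", setting = "other"),
    visit("D1", date = "2015-06-01"))
  diagnoses <- rbind(
    dx("B1", "I10"), dx("B3", "I10", source = "problem_list"),
    dx("B5", "E66.9"), dx("B6", "E11.9", source = "problem_list"))
  bp_readings <- rbind(
    bp("B2", 150, 95, "2016-01-05"), bp("B2", 142, 91, "2016-02-05"),
    bp("B4", 165, 88), bp("B6", 120, 80))
  measurements <- rbind(
    meas("B5", "bmi", 31.2), meas("B6", "hba1c", 7.1), meas("B1", "egfr", 45))
  cohort(patients, encounters, diagnoses, bp_readings, measurements,
         observation_year = 2016)
}

# Random messy cohort for property tests: arbitrary codes (matching and
# non-matching), both sources, dates in and out of year, random BP readings
# and measurements. Built directly from rows, not via generate_cohort().
random_cohort <- function(seed, n = 60, orgs = 2) {
  set.seed(seed)
  ids <- sprintf("R%04d", seq_len(n))
  patients <- data.frame(
    patient_id = ids,
    org_id = sprintf("org%d", sample.int(orgs, n, replace = TRUE)),
    sex = sample(c("female", "male"), n, replace = TRUE),
    age = sample(15:90, n, replace = TRUE),
    race_ethnicity = sample(c("nh_white", "nh_black", "hispanic", "other", "missing"),
                            n, replace = TRUE, prob = c(.5, .15, .1, .15, .1)),
    stringsAsFactors = FALSE)
  codes <- c("I10", "I11.9", "I13.10", "I15.0", "I16.1", "E66.9", "E66.01",
             "E10.9", "E11.65", "N18.3", "N18.9", "J44.9", "M54.5", "Z00.00")
  rnd_date <- function(k, years = c("2015", "2016", "2017")) {
    as.Date(sprintf("%s-%02d-%02d", sample(years, k, replace = TRUE, prob = c(.15, .7, .15)),
                    sample(1:12, k, replace = TRUE), sample(1:28, k, replace = TRUE)))
  }
  who <- function(k) sample(ids, k, replace = TRUE)
  ne <- n + rpois(1, n)
  encounters <- data.frame(
    patient_id = who(ne), date = rnd_date(ne),
    setting = sample(c("ambulatory_em", "other"), ne, replace = TRUE, prob = c(.8, .2)),
    stringsAsFactors = FALSE)
  nd <- rpois(1, n * 1.2)
  diagnoses <- data.frame(
    patient_id = who(nd), date = rnd_date(nd),
    code = sample(codes, nd, replace = TRUE),
    source = sample(c("claim", "problem_list"), nd, replace = TRUE),
    stringsAsFactors = FALSE)
  nb <- rpois(1, n * 1.5)
  sys <- sample(90:200, nb, replace = TRUE)
  bp_readings <- data.frame(
    patient_id = who(nb), date = rnd_date(nb), systolic = sys,
    diastolic = pmin(sys - 10L, sample(50:130, nb, replace = TRUE)),
    stringsAsFactors = FALSE)
  nm <- rpois(1, n)
  kind <- sample(c("bmi", "hba1c", "fasting_glucose", "egfr"), nm, replace = TRUE)
  value <- ifelse(kind == "bmi", round(runif(nm, 18, 45), 1),
           ifelse(kind == "hba1c", round(runif(nm, 4.5, 10), 1),
           ifelse(kind == "fasting_glucose", sample(70:220, nm, replace = TRUE),
                  sample(20:110, nm, replace = TRUE))))
  measurements <- data.frame(patient_id = who(nm), date = rnd_date(nm),
                             kind = kind, value = value, stringsAsFactors = FALSE)
  cohort(patients, encounters, diagnoses, bp_readings, measurements,
         observation_year = 2016)
}

stratum_key_chr <- function(df) paste(df$sex, df$race_ethnicity, df$age_group)

# ---- brute-force oracles (straight re-statement of the rules) ------------

oracle_code_hit <- function(code, prefixes) {
  code <- toupper(gsub(".", "", code, fixed = TRUE))
  any(vapply(prefixes, function(p) substr(code, 1, nchar(p)) == p, logical(1)))
}

oracle_tier_one <- function(x, id, cs) {
  year <- x$observation_year
  dxp <- x$diagnoses[x$diagnoses$patient_id == id &
                       format(x$diagnoses$date, "%Y") == as.character(year), , drop = FALSE]
  claims <- FALSE; plist <- FALSE
  for (r in seq_len(nrow(dxp))) {
    if (oracle_code_hit(dxp$code[r], cs$prefixes$hypertension)) {
      if (dxp$source[r] == "claim") claims <- TRUE else plist <- TRUE
    }
  }
  if (claims) return("claims")
  if (plist) return("problem_list")
  bpp <- x$bp_readings[x$bp_readings$patient_id == id &
                         format(x$bp_readings$date, "%Y") == as.character(year), , drop = FALSE]
  hi_days <- character(0)
  for (r in seq_len(nrow(bpp))) {
    s <- bpp$systolic[r]; d <- bpp$diastolic[r]
    elev1 <- if (cs$bp_rule == "or") s >= 160 || d >= 100 else s >= 160 && d >= 100
    if (elev1) return("bp_criteria")
    elev2 <- if (cs$bp_rule == "or") s >= 140 || d >= 90 else s >= 140 && d >= 90
    if (elev2) hi_days <- union(hi_days, as.character(bpp$date[r]))
  }
  if (length(hi_days) >= 2) return("bp_criteria")
  "none"
}

oracle_flags_one <- function(x, id, cs) {
  year <- as.character(x$observation_year)
  dxp <- x$diagnoses[x$diagnoses$patient_id == id &
                       format(x$diagnoses$date, "%Y") == year, , drop = FALSE]
  msp <- x$measurements[x$measurements$patient_id == id &
                          format(x$measurements$date, "%Y") == year, , drop = FALSE]
  out <- c(obesity = "none", diabetes = "none", ckd = "none")
  for (cond in names(out)) {
    claims <- FALSE; plist <- FALSE
    for (r in seq_len(nrow(dxp))) {
      if (oracle_code_hit(dxp$code[r], cs$prefixes[[cond]])) {
        if (dxp$source[r] == "claim") claims <- TRUE else plist <- TRUE
      }
    }
    clinical <- switch(cond,
      obesity = any(msp$kind == "bmi" & msp$value >= cs$thresholds$bmi),
      diabetes = any(msp$kind == "hba1c" & msp$value >= cs$thresholds$hba1c) ||
        length(unique(msp$date[msp$kind == "fasting_glucose" &
                                 msp$value >= cs$thresholds$fasting_glucose])) >= 2,
      ckd = {
        dts <- sort(msp$date[msp$kind == "egfr" & msp$value < cs$thresholds$egfr])
        found <- FALSE
        if (length(dts) >= 2) {
          for (a in seq_along(dts)) for (b in seq_along(dts)) {
            if (b > a && as.integer(dts[b] - dts[a]) >= cs$thresholds$egfr_chronicity_days) found <- TRUE
          }
        }
        found
      })
    out[cond] <- if (claims) "claims_only" else if (plist) "plus_problem_list"
                 else if (isTRUE(clinical)) "plus_clinical" else "none"
  }
  out
}

oracle_eligible <- function(x) {
  out <- character(0)
  for (i in seq_len(nrow(x$patients))) {
    id <- x$patients$patient_id[i]
    if (x$patients$age[i] < 18 || x$patients$age[i] > 85) next
    enc <- x$encounters[x$encounters$patient_id == id, , drop = FALSE]
    ok <- FALSE
    for (r in seq_len(nrow(enc))) {
      if (enc$setting[r] == "ambulatory_em" &&
          format(enc$date[r], "%Y") == as.character(x$observation_year)) ok <- TRUE
    }
    if (ok) out <- c(out, id)
  }
  out
}

# patient-level expectation oracle for predicted prevalence: assign every
# synthetic patient the prevalence of their stratum and average
oracle_predicted <- function(weights, table, n_patients = 100000) {
  w <- as.data.frame(weights)
  joint <- "count_bucket" %in% names(w)
  key_w <- if (joint) paste(w$sex, w$race_ethnicity, w$age_group, w$count_bucket)
           else paste(w$sex, w$race_ethnicity, w$age_group)
  st <- table$strata
  key_t <- if (joint) paste(st$sex, st$race_ethnicity, st$age_group, st$count_bucket)
           else paste(st$sex, st$race_ethnicity, st$age_group)
  pis <- st$prevalence[match(key_w, key_t)]
  # exact expectation: weighted mean, accumulated naively term by term
  total <- 0
  for (i in seq_along(pis)) total <- total + w$weight[i] * pis[i]
  total
}
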