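# Per-patient pseudo-random substreams: each patient draws from a stream
# keyed by (seed, patient index), so enlarging a cohort never perturbs the
# patients already generated. The mix keeps results in 31-bit range.
derive_seed <- function(seed, i) {
  as.integer((abs(seed) * 48271 + i * 20771) %% 2147483629 + 1)
}

#' Default stratum-specific true hypertension prevalence
#'
#' A plausible prevalence surface over sex x race/ethnicity x age group:
#' a steep age gradient (roughly 16% of adults under 45 up to about 72%
#' at 75--85), men somewhat above women, and non-Hispanic Black adults
#' above the other groups -- the qualitative pattern of US survey estimates.
#' The implied overall prevalence under the default demographic mix is about
#' 39%. Values are synthetic conveniences, not survey estimates.
#'
#' @return data.frame with columns `sex`, `race_ethnicity`, `age_group`,
#'   `prevalence` covering every combination (including `missing` race,
#'   which the generator needs even though reference tables exclude it).
#' @export
default_htn_prevalence <- function() {
  grid <- expand.grid(sex = SEX_LEVELS, race_ethnicity = RACE_LEVELS,
                      age_group = AGE_GROUPS, stringsAsFactors = FALSE)
  base <- c("18-44" = 0.16, "45-64" = 0.40, "65-74" = 0.63, "75-85" = 0.72)
  sex_mult <- c(female = 0.94, male = 1.08)
  race_mult <- c(nh_white = 1.00, nh_black = 1.25, hispanic = 0.95,
                 other = 0.90, missing = 1.00)
  grid$prevalence <- pmin(0.95, pmax(0.01,
    base[grid$age_group] * sex_mult[grid$sex] * race_mult[grid$race_ethnicity]))
  rownames(grid) <- NULL
  grid
}

#' Simulation parameters for a synthetic EHR/claims cohort
#'
#' Describes a synthetic patient population with known ground truth. The
#' defaults emulate a large US multispecialty-practice population in 2016:
#' the demographic mix (57.3% female; 34.2/39.5/16.9/9.4% across the four
#' age bands; 73.9% non-Hispanic white with 5.1% missing race), 25
#' organizations, 5.9% of patients with no in-office BP reading, and
#' documentation that is deliberately incomplete -- a true hypertensive is
#' billed for hypertension with probability `claims_sensitivity`, otherwise
#' appears on the problem list with probability `problem_list_increment`,
#' and otherwise is detectable only through elevated BP readings.
#'
#' @param n_patients number of patients (default 50,000).
#' @param org_count number of organizations; patients are assigned uniformly.
#' @param observation_year calendar year the records are dated in.
#' @param demographic_mix named list of probability vectors `sex`,
#'   `race_ethnicity`, `age_group` (each summing to 1). Sampled
#'   independently across the three dimensions.
#' @param true_htn_prevalence either a single fraction (uniform across
#'   strata) or a data.frame as returned by [default_htn_prevalence()].
#' @param comorbidity_prevalence named fractions for `obesity`, `diabetes`,
#'   `ckd`; conditions are assigned independently given the stratum.
#' @param bucket_relative_risk relative risk of true hypertension by
#'   comorbidity-count bucket (`zero`, `one`, `two_or_three`); rescaled
#'   within each stratum so the stratum marginal prevalence is preserved
#'   exactly, and shrunk where needed to keep probabilities in (0, 1).
#'   Set to `c(1, 1, 1)` for independence.
#' @param claims_sensitivity named fractions (`hypertension`, `obesity`,
#'   `diabetes`, `ckd`): probability a true case carries an in-year billing
#'   code.
#' @param problem_list_increment named fractions: probability a true case
#'   *without* a billing code appears on the EHR problem list.
#' @param clinical_documentation_rate named fractions (`obesity`,
#'   `diabetes`, `ckd`): probability the clinical criterion evidence (BMI,
#'   HbA1c, paired eGFRs) is recorded for a true case.
#' @param claims_false_positive_rate named fractions: probability a non-case
#'   carries a billing code anyway (all zero by default).
#' @param visit_count_distribution named probability vector over the number
#'   of in-year ambulatory E&M visits (names are the counts).
#' @param bp_missingness fraction of patients with no BP reading at all.
#' @param bp_model list with `htn` and `normal` mean systolic/diastolic
#'   (mm Hg) and visit-level noise `sd`. Defaults 150/92 for untreated
#'   hypertensives vs 118/74 otherwise, SD 12/8 -- wide enough that some
#'   normotensives cross the office thresholds by noise alone.
#' @param bmi_measurement_rate probability a non-obese patient has a
#'   (below-threshold) BMI on record.
#' @param org_effect_sd SD of the log-normal per-organization multiplicative
#'   tilt applied to all documentation sensitivities (cross-organization
#'   documentation spread).
#' @param pseudo_survey_n per-stratum pseudo-survey size used to attach
#'   standard errors to the generated reference table.
#' @param seed integer seed for the whole simulation.
#' @return An object of class `sim_params`.
#' @seealso [generate_cohort()], [generate_reference_table()]
#' @export
sim_params <- function(n_patients = 50000L,
                       org_count = 25L,
                       observation_year = 2016L,
                       demographic_mix = list(
                         sex = c(female = 0.573, male = 0.427),
                         race_ethnicity = c(nh_white = 0.739, nh_black = 0.071,
                                            hispanic = 0.034, other = 0.105, missing = 0.051),
                         age_group = c("18-44" = 0.342, "45-64" = 0.395,
                                       "65-74" = 0.169, "75-85" = 0.094)),
                       true_htn_prevalence = default_htn_prevalence(),
                       comorbidity_prevalence = c(obesity = 0.45, diabetes = 0.165, ckd = 0.075),
                       bucket_relative_risk = c(zero = 1, one = 1.6, two_or_three = 2.4),
                       claims_sensitivity = c(hypertension = 0.75, obesity = 0.24,
                                              diabetes = 0.69, ckd = 0.46),
                       problem_list_increment = c(hypertension = 0.10, obesity = 0.07,
                                                  diabetes = 0.31, ckd = 0.25),
                       clinical_documentation_rate = c(obesity = 0.97, diabetes = 0.95, ckd = 0.92),
                       claims_false_positive_rate = c(hypertension = 0, obesity = 0,
                                                      diabetes = 0, ckd = 0),
                       visit_count_distribution = c("1" = 0.25, "2" = 0.22, "3" = 0.18,
                                                    "4" = 0.13, "5" = 0.09, "6" = 0.06,
                                                    "7" = 0.04, "8" = 0.03),
                       bp_missingness = 0.059,
                       bp_model = list(htn = c(systolic = 150, diastolic = 92),
                                       normal = c(systolic = 118, diastolic = 74),
                                       sd = c(systolic = 12, diastolic = 8)),
                       bmi_measurement_rate = 0.85,
                       org_effect_sd = 0.15,
                       pseudo_survey_n = 5000L,
                       seed = 1L) {
  if (is.numeric(true_htn_prevalence) && length(true_htn_prevalence) == 1) {
    grid <- expand.grid(sex = SEX_LEVELS, race_ethnicity = RACE_LEVELS,
                        age_group = AGE_GROUPS, stringsAsFactors = FALSE)
    grid$prevalence <- true_htn_prevalence
    true_htn_prevalence <- grid
  }
  p <- structure(list(
    n_patients = as.integer(n_patients), org_count = as.integer(org_count),
    observation_year = as.integer(observation_year),
    demographic_mix = demographic_mix,
    true_htn_prevalence = true_htn_prevalence,
    comorbidity_prevalence = comorbidity_prevalence,
    bucket_relative_risk = bucket_relative_risk,
    claims_sensitivity = claims_sensitivity,
    problem_list_increment = problem_list_increment,
    clinical_documentation_rate = clinical_documentation_rate,
    claims_false_positive_rate = claims_false_positive_rate,
    visit_count_distribution = visit_count_distribution,
    bp_missingness = bp_missingness, bp_model = bp_model,
    bmi_measurement_rate = bmi_measurement_rate,
    org_effect_sd = org_effect_sd,
    pseudo_survey_n = as.integer(pseudo_survey_n),
    seed = as.integer(seed)), class = "sim_params")
  validate_sim_params(p)
  p
}

validate_sim_params <- function(p) {
  if (p$n_patients < 1L) stop("n_patients must be >= 1")
  if (p$org_count < 1L) stop("org_count must be >= 1")
  for (nm in c("sex", "race_ethnicity", "age_group")) {
    mx <- p$demographic_mix[[nm]]
    if (is.null(mx) || abs(sum(mx) - 1) > 1e-8 || any(mx < 0)) {
      stop("demographic_mix$", nm, " must be a non-negative vector summing to 1")
    }
  }
  fracs <- c(p$comorbidity_prevalence, p$claims_sensitivity, p$problem_list_increment,
             p$clinical_documentation_rate, p$claims_false_positive_rate,
             p$bp_missingness, p$bmi_measurement_rate)
  if (any(fracs < 0 | fracs > 1)) stop("all probabilities must lie in [0, 1]")
  if (abs(sum(p$visit_count_distribution) - 1) > 1e-8 || any(p$visit_count_distribution < 0)) {
    stop("visit_count_distribution must sum to 1")
  }
  pv <- p$true_htn_prevalence
  if (!is.data.frame(pv) || !all(c("sex", "race_ethnicity", "age_group", "prevalence") %in% names(pv))) {
    stop("true_htn_prevalence must be a fraction or a data.frame with sex, race_ethnicity, age_group, prevalence")
  }
  if (any(pv$prevalence < 0 | pv$prevalence > 1)) stop("true prevalences must be in [0, 1]")
  if (any(p$bucket_relative_risk <= 0)) stop("bucket_relative_risk must be positive")
  invisible(p)
}

#' @export
print.sim_params <- function(x, ...) {
  cat(sprintf("Synthetic cohort parameters: %d patients, %d organization(s), year %d, seed %d\n",
              x$n_patients, x$org_count, x$observation_year, x$seed))
  cat(sprintf("  hypertension claims sensitivity %.2f, problem-list increment %.2f, BP missingness %.3f\n",
              x$claims_sensitivity[["hypertension"]], x$problem_list_increment[["hypertension"]],
              x$bp_missingness))
  invisible(x)
}

# lookup vector: "sex|race|age_group" -> true hypertension prevalence
htn_prev_lookup <- function(params) {
  pv <- params$true_htn_prevalence
  stats::setNames(pv$prevalence, paste(pv$sex, pv$race_ethnicity, pv$age_group, sep = "|"))
}

# Comorbidity-count bucket distribution implied by independent conditions.
bucket_distribution <- function(cp) {
  po <- cp[["obesity"]]; pd <- cp[["diabetes"]]; pk <- cp[["ckd"]]
  q0 <- (1 - po) * (1 - pd) * (1 - pk)
  q1 <- po * (1 - pd) * (1 - pk) + (1 - po) * pd * (1 - pk) + (1 - po) * (1 - pd) * pk
  c(zero = q0, one = q1, two_or_three = 1 - q0 - q1)
}

# Bucket-conditional hypertension prevalence that preserves the stratum
# marginal exactly: pi_b = p * (1 + lambda * (rel_b - 1)) with
# rel_b = r_b / sum(q_b r_b) and lambda shrunk so every pi_b stays in
# (0.005, 0.995). Since sum(q_b (rel_b - 1)) = 0, folding over the bucket
# distribution returns p for any lambda.
bucket_conditional_prev <- function(p, q, rr) {
  rel <- rr / sum(q * rr)
  lambda <- 1
  for (b in seq_along(rel)) {
    d <- rel[b] - 1
    if (d > 0) lambda <- min(lambda, (0.995 / p - 1) / d)
    if (d < 0) lambda <- min(lambda, (1 - 0.005 / p) / (-d))
  }
  lambda <- max(0, lambda)
  stats::setNames(p * (1 + lambda * (rel - 1)), names(rr))
}

# Representative ICD-10-CM codes emitted by the generator (each matches the
# default prefix for its condition).
SIM_CODES <- c(hypertension = "I10", obesity = "E66.9", diabetes = "E11.9", ckd = "N18.3")

#' Generate a synthetic cohort with known ground truth
#'
#' Simulates a patient population according to [sim_params()]: demographics,
#' true hypertension and comorbidity status per stratum, in-year ambulatory
#' visits, per-visit BP readings conditioned on true hypertension status,
#' and incomplete documentation (billing codes, problem-list entries,
#' clinical measurements) at the configured sensitivities, with per-organization
#' multiplicative documentation tilts. The generation is deterministic given
#' the seed, and each patient draws from an independent substream keyed by
#' (seed, patient index), so growing `n_patients` leaves earlier patients
#' unchanged.
#'
#' @param params a `sim_params` object.
#' @return list with elements `cohort` (a validated [cohort()]) and
#'   `ground_truth` (data.frame: `patient_id`, `org_id`, `sex`,
#'   `race_ethnicity`, `age_group`, `true_htn`, `true_obesity`,
#'   `true_diabetes`, `true_ckd`, `count_bucket`).
#' @export
generate_cohort <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  validate_sim_params(params)
  n <- params$n_patients
  mix <- params$demographic_mix
  prev <- htn_prev_lookup(params)
  q <- bucket_distribution(params$comorbidity_prevalence)
  rr <- params$bucket_relative_risk

  # per-organization documentation tilts, drawn once from substream 0
  set.seed(derive_seed(params$seed, 0L))
  org_tilt <- exp(stats::rnorm(params$org_count, 0, params$org_effect_sd))
  org_ids <- sprintf("org%02d", seq_len(params$org_count))

  # precompute bucket-conditional prevalence per stratum
  strata <- unique(names(prev))
  cond_prev <- lapply(prev, function(p) bucket_conditional_prev(p, q, rr))

  year0 <- as.Date(sprintf("%d-01-01", params$observation_year))
  year_len <- as.integer(as.Date(sprintf("%d-12-31", params$observation_year)) - year0) + 1L

  sens <- params$claims_sensitivity
  plinc <- params$problem_list_increment
  clin <- params$clinical_documentation_rate
  fp <- params$claims_false_positive_rate
  vprob <- params$visit_count_distribution
  vcounts <- as.integer(names(vprob))
  bp <- params$bp_model

  # scalar per-patient fields
  org <- sex <- race <- ageg <- character(n)
  age <- integer(n)
  t_htn <- t_ob <- t_db <- t_ck <- logical(n)
  # variable-length record accumulators (per-patient lists)
  enc_pid <- enc_day <- list()
  dx_pid <- dx_day <- dx_code <- dx_src <- list()
  bp_pid <- bp_day <- bp_sys <- bp_dia <- list()
  ms_pid <- ms_day <- ms_kind <- ms_val <- list()

  for (i in seq_len(n)) {
    set.seed(derive_seed(params$seed, i))
    pid <- sprintf("P%07d", i)
    oi <- sample.int(params$org_count, 1L)
    tilt <- org_tilt[oi]
    org[i] <- org_ids[oi]
    sex[i] <- sample(names(mix$sex), 1L, prob = mix$sex)
    race[i] <- sample(names(mix$race_ethnicity), 1L, prob = mix$race_ethnicity)
    ageg[i] <- sample(names(mix$age_group), 1L, prob = mix$age_group)
    lo <- AGE_BREAKS[match(ageg[i], AGE_GROUPS)]
    hi <- AGE_BREAKS[match(ageg[i], AGE_GROUPS) + 1L] - 1L
    age[i] <- lo + sample.int(hi - lo + 1L, 1L) - 1L

    t_ob[i] <- stats::runif(1) < params$comorbidity_prevalence[["obesity"]]
    t_db[i] <- stats::runif(1) < params$comorbidity_prevalence[["diabetes"]]
    t_ck[i] <- stats::runif(1) < params$comorbidity_prevalence[["ckd"]]
    nb <- sum(t_ob[i], t_db[i], t_ck[i])
    bname <- COUNT_BUCKETS[min(nb, 2L) + 1L]
    key <- paste(sex[i], race[i], ageg[i], sep = "|")
    t_htn[i] <- stats::runif(1) < cond_prev[[key]][[bname]]

    # visits
    k <- vcounts[sample.int(length(vcounts), 1L, prob = vprob)]
    days <- sort(sample.int(year_len, k))
    enc_pid[[i]] <- rep(pid, k); enc_day[[i]] <- days
    rand_day <- function() days[sample.int(k, 1L)]

    # documentation of each condition (claims > problem list; clinical
    # evidence recorded independently)
    p_dx_day <- integer(0); p_dx_code <- character(0); p_dx_src <- character(0)
    truth <- c(hypertension = t_htn[i], obesity = t_ob[i], diabetes = t_db[i], ckd = t_ck[i])
    for (cond in names(truth)) {
      if (truth[[cond]]) {
        if (stats::runif(1) < min(1, sens[[cond]] * tilt)) {
          p_dx_day <- c(p_dx_day, rand_day()); p_dx_code <- c(p_dx_code, SIM_CODES[[cond]])
          p_dx_src <- c(p_dx_src, "claim")
        } else if (stats::runif(1) < min(1, plinc[[cond]] * tilt)) {
          p_dx_day <- c(p_dx_day, rand_day()); p_dx_code <- c(p_dx_code, SIM_CODES[[cond]])
          p_dx_src <- c(p_dx_src, "problem_list")
        }
      } else if (fp[[cond]] > 0 && stats::runif(1) < fp[[cond]]) {
        p_dx_day <- c(p_dx_day, rand_day()); p_dx_code <- c(p_dx_code, SIM_CODES[[cond]])
        p_dx_src <- c(p_dx_src, "claim")
      }
    }
    dx_pid[[i]] <- rep(pid, length(p_dx_day))
    dx_day[[i]] <- p_dx_day; dx_code[[i]] <- p_dx_code; dx_src[[i]] <- p_dx_src

    # BP readings: one per visit unless the patient is never measured
    if (stats::runif(1) >= params$bp_missingness) {
      mu <- if (t_htn[i]) bp$htn else bp$normal
      sys <- as.integer(pmin(300, pmax(60, round(stats::rnorm(k, mu[["systolic"]], bp$sd[["systolic"]])))))
      dia <- as.integer(pmin(200, pmax(30, round(stats::rnorm(k, mu[["diastolic"]], bp$sd[["diastolic"]])))))
      dia <- pmin(dia, sys - 10L)
      bp_pid[[i]] <- rep(pid, k); bp_day[[i]] <- days; bp_sys[[i]] <- sys; bp_dia[[i]] <- dia
    }

    # clinical measurements
    m_day <- integer(0); m_kind <- character(0); m_val <- numeric(0)
    if (t_ob[i]) {
      if (stats::runif(1) < min(1, clin[["obesity"]] * tilt)) {
        m_day <- c(m_day, rand_day()); m_kind <- c(m_kind, "bmi")
        m_val <- c(m_val, round(max(30.1, stats::rnorm(1, 34, 3)), 1))
      }
    } else if (stats::runif(1) < params$bmi_measurement_rate) {
      m_day <- c(m_day, rand_day()); m_kind <- c(m_kind, "bmi")
      m_val <- c(m_val, round(min(29.4, max(15, stats::rnorm(1, 25.5, 2.5))), 1))
    }
    if (t_db[i] && stats::runif(1) < min(1, clin[["diabetes"]] * tilt)) {
      m_day <- c(m_day, rand_day()); m_kind <- c(m_kind, "hba1c")
      m_val <- c(m_val, round(max(6.6, stats::rnorm(1, 7.4, 0.8)), 1))
    }
    if (t_ck[i] && stats::runif(1) < min(1, clin[["ckd"]] * tilt)) {
      d1 <- sample.int(170L, 1L)
      d2 <- d1 + 89L + sample.int(min(105L, year_len - 89L - d1), 1L)
      vals <- round(pmin(58, pmax(8, stats::rnorm(2, 45, 8))))
      m_day <- c(m_day, d1, d2); m_kind <- c(m_kind, "egfr", "egfr"); m_val <- c(m_val, vals)
    }
    ms_pid[[i]] <- rep(pid, length(m_day))
    ms_day[[i]] <- m_day; ms_kind[[i]] <- m_kind; ms_val[[i]] <- m_val
  }

  pid_all <- sprintf("P%07d", seq_len(n))
  to_date <- function(days) year0 + (unlist(days, use.names = FALSE) - 1L)
  patients <- data.frame(patient_id = pid_all, org_id = org, sex = sex, age = age,
                         race_ethnicity = race, stringsAsFactors = FALSE)
  encounters <- data.frame(patient_id = unlist(enc_pid, use.names = FALSE),
                           date = to_date(enc_day), setting = "ambulatory_em",
                           stringsAsFactors = FALSE)
  diagnoses <- data.frame(patient_id = unlist(dx_pid, use.names = FALSE),
                          date = to_date(dx_day),
                          code = unlist(dx_code, use.names = FALSE),
                          source = unlist(dx_src, use.names = FALSE),
                          stringsAsFactors = FALSE)
  bp_readings <- data.frame(patient_id = unlist(bp_pid, use.names = FALSE),
                            date = to_date(bp_day),
                            systolic = unlist(bp_sys, use.names = FALSE),
                            diastolic = unlist(bp_dia, use.names = FALSE),
                            stringsAsFactors = FALSE)
  measurements <- data.frame(patient_id = unlist(ms_pid, use.names = FALSE),
                             date = to_date(ms_day),
                             kind = unlist(ms_kind, use.names = FALSE),
                             value = unlist(ms_val, use.names = FALSE),
                             stringsAsFactors = FALSE)
  nb_all <- t_ob + t_db + t_ck
  ground_truth <- data.frame(
    patient_id = pid_all, org_id = org, sex = sex, race_ethnicity = race,
    age_group = ageg, true_htn = t_htn, true_obesity = t_ob,
    true_diabetes = t_db, true_ckd = t_ck,
    count_bucket = COUNT_BUCKETS[pmin(nb_all, 2L) + 1L], stringsAsFactors = FALSE)

  list(cohort = cohort(patients, encounters, diagnoses, bp_readings, measurements,
                       observation_year = params$observation_year, validate = FALSE),
       ground_truth = ground_truth)
}

#' Reference prevalence table implied by simulation parameters
#'
#' Builds the stratum-prevalence table a perfectly informed reference survey
#' would provide for the simulated population: the true hypertension
#' prevalence per stratum (by comorbidity-count bucket in `"joint"` mode, or
#' the demographic marginal in `"demographic"` mode) with standard errors
#' from a pseudo-survey of size `pseudo_survey_n` per stratum
#' (`se = sqrt(p(1-p)/n)`), plus the reference comorbidity-count bucket
#' distribution per demographic stratum. Feeding this table to
#' [predicted_prevalence()] on a cohort generated from the same parameters
#' recovers the generator's true overall prevalence.
#'
#' @param params a `sim_params` object.
#' @param mode `"joint"` (stratum x count-bucket entries, the default) or
#'   `"demographic"` (demographic strata only).
#' @return A [reference_table()].
#' @export
generate_reference_table <- function(params, mode = c("joint", "demographic")) {
  stopifnot(inherits(params, "sim_params"))
  mode <- match.arg(mode)
  prev <- htn_prev_lookup(params)
  q <- bucket_distribution(params$comorbidity_prevalence)
  rr <- params$bucket_relative_risk
  n_s <- params$pseudo_survey_n

  grid <- expand.grid(sex = SEX_LEVELS, race_ethnicity = RACE_KNOWN,
                      age_group = AGE_GROUPS, stringsAsFactors = FALSE)
  buckets <- grid[rep(seq_len(nrow(grid)), each = length(COUNT_BUCKETS)), ]
  buckets$count_bucket <- rep(COUNT_BUCKETS, nrow(grid))
  buckets$share <- rep(unname(q), nrow(grid))
  rownames(buckets) <- NULL

  if (mode == "demographic") {
    grid$count_bucket <- "ALL"
    grid$prevalence <- unname(prev[paste(grid$sex, grid$race_ethnicity, grid$age_group, sep = "|")])
    grid$se <- sqrt(grid$prevalence * (1 - grid$prevalence) / n_s)
    return(reference_table(grid, buckets = buckets, mode = "demographic"))
  }
  joint <- buckets[, c("sex", "race_ethnicity", "age_group", "count_bucket")]
  key <- paste(joint$sex, joint$race_ethnicity, joint$age_group, sep = "|")
  pi_sb <- numeric(nrow(joint))
  for (k in unique(key)) {
    idx <- which(key == k)
    pi_sb[idx] <- bucket_conditional_prev(prev[[k]], q, rr)[joint$count_bucket[idx]]
  }
  joint$prevalence <- pi_sb
  joint$se <- sqrt(pi_sb * (1 - pi_sb) / n_s)
  reference_table(joint, buckets = buckets, mode = "joint")
}

#' Write generator outputs to disk
#'
#' Writes the five cohort CSVs (see [write_cohort()]) plus
#' `ground_truth.csv` and `reference_table.csv`/`reference_buckets.csv`
#' into a directory.
#'
#' @param sim result of [generate_cohort()].
#' @param params the `sim_params` used.
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_simulation <- function(sim, params, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_cohort(sim$cohort, dir)
  utils::write.csv(sim$ground_truth, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE, quote = FALSE)
  write_reference_table(generate_reference_table(params),
                        file.path(dir, "reference_table.csv"),
                        file.path(dir, "reference_buckets.csv"))
  invisible(dir)
}
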