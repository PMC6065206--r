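in_year <- function(dates, year) {
  !is.na(dates) & as.integer(format(dates, "%Y")) == year
}

# tiers that count as hypertensive at each evidence level (nested unions)
admissible_tiers <- function(level) {
  level <- match.arg(level, EVIDENCE_LEVELS)
  switch(level,
         claims_only = "claims",
         plus_problem_list = c("claims", "problem_list"),
         plus_clinical = c("claims", "problem_list", "bp_criteria"))
}

#' Office blood-pressure criterion for hypertension
#'
#' A patient's in-office readings meet the BP criterion when any single
#' reading is at or above 160/100 mm Hg, or readings on two different
#' calendar days are each at or above 140/90 mm Hg. Two readings on the
#' same day never satisfy the second arm. By default a reading crosses a
#' threshold when *either* the systolic or the diastolic component does
#' (`bp_rule = "or"` in [code_sets()]); an "and" mode is available for
#' sensitivity analysis. Thresholds are configurable.
#'
#' @param readings data.frame of one patient's readings within the
#'   observation year, with columns `date`, `systolic`, `diastolic`.
#' @param cs a [code_sets()] object (supplies thresholds and the rule).
#' @return `TRUE` or `FALSE` (an empty set of readings returns `FALSE`).
#' @export
bp_criteria_met <- function(readings, cs = code_sets()) {
  if (is.null(readings) || nrow(readings) == 0) return(FALSE)
  th <- cs$thresholds
  comb <- if (cs$bp_rule == "or") `|` else `&`
  single <- comb(readings$systolic >= th$bp_single[["systolic"]],
                 readings$diastolic >= th$bp_single[["diastolic"]])
  if (any(single)) return(TRUE)
  rep_flag <- comb(readings$systolic >= th$bp_repeat[["systolic"]],
                   readings$diastolic >= th$bp_repeat[["diastolic"]])
  length(unique(readings$date[rep_flag])) >= 2L
}

#' Hypertension case-definition tier for one patient
#'
#' Applies the three nested case definitions in order and returns the first
#' that fires: `"claims"` if any in-year billing claim carries a
#' hypertension code; otherwise `"problem_list"` if the EHR problem list
#' does; otherwise `"bp_criteria"` if [bp_criteria_met()] holds; otherwise
#' `"none"`. Patients meeting only the BP criterion are *not* considered
#' diagnosed -- they are candidates for reassessment.
#'
#' @param diagnoses data.frame of the patient's in-year diagnosis records
#'   (`date`, `code`, `source`).
#' @param bp_readings data.frame of the patient's in-year BP readings.
#' @param cs a [code_sets()] object.
#' @return One of `"none"`, `"claims"`, `"problem_list"`, `"bp_criteria"`.
#' @export
hypertension_tier <- function(diagnoses, bp_readings, cs = code_sets()) {
  if (!is.null(diagnoses) && nrow(diagnoses) > 0) {
    hit <- code_matches(diagnoses$code, cs$prefixes$hypertension)
    if (any(hit & diagnoses$source == "claim")) return("claims")
    if (any(hit & diagnoses$source == "problem_list")) return("problem_list")
  }
  if (bp_criteria_met(bp_readings, cs)) return("bp_criteria")
  "none"
}

#' Comorbidity ascertainment levels for one patient
#'
#' For each of obesity, diabetes and chronic kidney disease, returns the
#' earliest evidence level at which the condition is ascertained:
#' `"claims_only"` when an in-year billing claim carries the condition's
#' code, `"plus_problem_list"` when only the problem list does,
#' `"plus_clinical"` when only the clinical criterion is met, `"none"`
#' otherwise. Ascertainment at a level implies ascertainment at every
#' higher (more inclusive) level.
#'
#' Clinical criteria: obesity -- any BMI at or above 30 kg/m^2; diabetes --
#' any HbA1c at or above 6.5%, or fasting glucose at or above 126 mg/dL on
#' two distinct dates; CKD -- two eGFR results below 60 mL/min/1.73 m^2 on
#' dates at least 90 days apart (the chronicity requirement). All cutoffs
#' come from [code_sets()].
#'
#' @param diagnoses data.frame of the patient's in-year diagnosis records.
#' @param measurements data.frame of the patient's in-year clinical
#'   measurements (`date`, `kind`, `value`).
#' @param cs a [code_sets()] object.
#' @return Named character vector over `c("obesity", "diabetes", "ckd")`.
#' @export
condition_flags <- function(diagnoses, measurements, cs = code_sets()) {
  th <- cs$thresholds
  out <- stats::setNames(rep("none", length(CONDITIONS)), CONDITIONS)
  for (cond in CONDITIONS) {
    if (!is.null(diagnoses) && nrow(diagnoses) > 0) {
      hit <- code_matches(diagnoses$code, cs$prefixes[[cond]])
      if (any(hit & diagnoses$source == "claim")) { out[[cond]] <- "claims_only"; next }
      if (any(hit & diagnoses$source == "problem_list")) { out[[cond]] <- "plus_problem_list"; next }
    }
    if (is.null(measurements) || nrow(measurements) == 0) next
    ms <- measurements
    clinical <- switch(cond,
      obesity = any(ms$kind == "bmi" & ms$value >= th$bmi),
      diabetes = any(ms$kind == "hba1c" & ms$value >= th$hba1c) ||
        length(unique(ms$date[ms$kind == "fasting_glucose" & ms$value >= th$fasting_glucose])) >= 2L,
      ckd = {
        d <- ms$date[ms$kind == "egfr" & ms$value < th$egfr]
        length(d) >= 2L && as.integer(max(d) - min(d)) >= th$egfr_chronicity_days
      })
    if (clinical) out[[cond]] <- "plus_clinical"
  }
  out
}

#' Ascertain hypertension tier and comorbidity levels for a whole cohort
#'
#' Vectorized application of [hypertension_tier()] and [condition_flags()]
#' to every eligible patient, restricted to records dated within the
#' cohort's observation year.
#'
#' @param x a `cohort`.
#' @param eligible eligible patient ids (default [eligible_patients()]).
#' @param cs a [code_sets()] object.
#' @return data.frame with one row per eligible patient: `patient_id`,
#'   `org_id`, `htn_tier`, `obesity_level`, `diabetes_level`, `ckd_level`.
#' @export
ascertain_cohort <- function(x, eligible = eligible_patients(x), cs = code_sets()) {
  stopifnot(inherits(x, "cohort"))
  if (length(eligible) == 0) stop("eligible set is empty")
  year <- x$observation_year
  dx <- x$diagnoses[in_year(x$diagnoses$date, year) & x$diagnoses$patient_id %in% eligible, , drop = FALSE]
  bp <- x$bp_readings[in_year(x$bp_readings$date, year) & x$bp_readings$patient_id %in% eligible, , drop = FALSE]
  ms <- x$measurements[in_year(x$measurements$date, year) & x$measurements$patient_id %in% eligible, , drop = FALSE]
  th <- cs$thresholds
  comb <- if (cs$bp_rule == "or") `|` else `&`

  level_of <- function(claims_ids, pl_ids, clinical_ids) {
    lv <- rep("none", length(eligible))
    lv[eligible %in% clinical_ids] <- "plus_clinical"
    lv[eligible %in% pl_ids] <- "plus_problem_list"
    lv[eligible %in% claims_ids] <- "claims_only"
    lv
  }
  dx_ids <- function(prefixes, src) unique(dx$patient_id[dx$source == src & code_matches(dx$code, prefixes)])

  # hypertension tier
  htn_claims <- dx_ids(cs$prefixes$hypertension, "claim")
  htn_pl <- dx_ids(cs$prefixes$hypertension, "problem_list")
  single <- comb(bp$systolic >= th$bp_single[["systolic"]], bp$diastolic >= th$bp_single[["diastolic"]])
  rep_flag <- comb(bp$systolic >= th$bp_repeat[["systolic"]], bp$diastolic >= th$bp_repeat[["diastolic"]])
  rep_days <- unique(data.frame(pid = bp$patient_id[rep_flag], date = bp$date[rep_flag]))
  two_days <- names(which(table(rep_days$pid) >= 2L))
  htn_bp <- union(unique(bp$patient_id[single]), two_days)
  tier <- rep("none", length(eligible))
  tier[eligible %in% htn_bp] <- "bp_criteria"
  tier[eligible %in% htn_pl] <- "problem_list"
  tier[eligible %in% htn_claims] <- "claims"

  # clinical comorbidity evidence
  ob_clin <- unique(ms$patient_id[ms$kind == "bmi" & ms$value >= th$bmi])
  a1c <- unique(ms$patient_id[ms$kind == "hba1c" & ms$value >= th$hba1c])
  fg <- unique(data.frame(pid = ms$patient_id, date = ms$date)[
    ms$kind == "fasting_glucose" & ms$value >= th$fasting_glucose, , drop = FALSE])
  fg2 <- names(which(table(fg$pid) >= 2L))
  db_clin <- union(a1c, fg2)
  eg <- ms[ms$kind == "egfr" & ms$value < th$egfr, , drop = FALSE]
  ck_clin <- character(0)
  if (nrow(eg) > 0) {
    spread <- tapply(as.integer(eg$date), eg$patient_id, function(d) max(d) - min(d))
    ck_clin <- names(spread)[spread >= th$egfr_chronicity_days]
  }

  out <- data.frame(
    patient_id = eligible,
    org_id = x$patients$org_id[match(eligible, x$patients$patient_id)],
    htn_tier = tier,
    obesity_level = level_of(dx_ids(cs$prefixes$obesity, "claim"),
                             dx_ids(cs$prefixes$obesity, "problem_list"), ob_clin),
    diabetes_level = level_of(dx_ids(cs$prefixes$diabetes, "claim"),
                              dx_ids(cs$prefixes$diabetes, "problem_list"), db_clin),
    ckd_level = level_of(dx_ids(cs$prefixes$ckd, "claim"),
                         dx_ids(cs$prefixes$ckd, "problem_list"), ck_clin),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# is a condition ascertained at `level`, given its earliest level?
ascertained_at <- function(earliest, level) {
  rank <- match(earliest, EVIDENCE_LEVELS) # NA for "none"
  !is.na(rank) & rank <= match(level, EVIDENCE_LEVELS)
}

#' A proportion with a 95% confidence interval
#'
#' Container used for observed and predicted prevalences. For observed
#' prevalences the interval is the Wald interval
#' `p +/- 1.96 sqrt(p(1-p)/n)`; predicted prevalences carry a propagated
#' standard error instead (see [predicted_prevalence()]).
#'
#' @param value the proportion.
#' @param n denominator.
#' @param se standard error; default Wald `sqrt(value(1-value)/n)`.
#' @param count optional numerator count.
#' @return Object of class `prevalence_estimate` with fields `value`,
#'   `se`, `ci_low`, `ci_high`, `n`, `count`.
#' @export
prevalence_estimate <- function(value, n, se = sqrt(value * (1 - value) / n), count = NA_real_) {
  stopifnot(value >= 0, value <= 1, n > 0)
  structure(list(value = value, se = se,
                 ci_low = max(0, value - 1.96 * se),
                 ci_high = min(1, value + 1.96 * se),
                 n = n, count = count),
            class = "prevalence_estimate")
}

#' @export
print.prevalence_estimate <- function(x, ...) {
  cat(sprintf("%.1f%% (95%% CI %.1f-%.1f), n = %s\n",
              100 * x$value, 100 * x$ci_low, 100 * x$ci_high,
              format(x$n, big.mark = ",")))
  invisible(x)
}

#' Observed hypertension prevalence at an evidence level
#'
#' Share of eligible patients whose hypertension tier is admissible at the
#' requested evidence level: billing claims only; claims or problem list;
#' or claims, problem list and BP criteria combined.
#'
#' @param x a `cohort`.
#' @param eligible eligible patient ids.
#' @param level one of `"claims_only"`, `"plus_problem_list"`,
#'   `"plus_clinical"`.
#' @param cs a [code_sets()] object.
#' @param ascertainment optional precomputed [ascertain_cohort()] result
#'   (computed if omitted).
#' @return A [prevalence_estimate()].
#' @export
observed_prevalence <- function(x, eligible = eligible_patients(x),
                                level = "claims_only", cs = code_sets(),
                                ascertainment = NULL) {
  level <- match.arg(level, EVIDENCE_LEVELS)
  if (length(eligible) == 0) stop("eligible set is empty")
  if (is.null(ascertainment)) ascertainment <- ascertain_cohort(x, eligible, cs)
  num <- sum(ascertainment$htn_tier %in% admissible_tiers(level))
  prevalence_estimate(num / length(eligible), n = length(eligible), count = num)
}

#' Comorbidity burden at an evidence level
#'
#' Distribution of the comorbidity-count bucket (0, 1, or 2--3 of obesity,
#' diabetes, CKD ascertained at the given evidence level) plus each
#' condition's prevalence at that level.
#'
#' @inheritParams observed_prevalence
#' @return list with `buckets` (named shares over `zero`, `one`,
#'   `two_or_three`, summing to 1), `conditions` (named per-condition
#'   prevalences) and `n`.
#' @export
comorbidity_distribution <- function(x, eligible = eligible_patients(x),
                                     level = "claims_only", cs = code_sets(),
                                     ascertainment = NULL) {
  level <- match.arg(level, EVIDENCE_LEVELS)
  if (length(eligible) == 0) stop("eligible set is empty")
  if (is.null(ascertainment)) ascertainment <- ascertain_cohort(x, eligible, cs)
  flags <- cbind(obesity = ascertained_at(ascertainment$obesity_level, level),
                 diabetes = ascertained_at(ascertainment$diabetes_level, level),
                 ckd = ascertained_at(ascertainment$ckd_level, level))
  counts <- rowSums(flags)
  bucket <- factor(COUNT_BUCKETS[pmin(counts, 2L) + 1L], levels = COUNT_BUCKETS)
  list(buckets = as.vector(table(bucket) / length(counts)) |> stats::setNames(COUNT_BUCKETS),
       conditions = colMeans(flags), n = length(eligible))
}

#' Share of eligible patients with no BP reading on record
#'
#' The BP-screening gap: the fraction of the analysis denominator with zero
#' in-year blood-pressure readings, overall and per organization. Patients
#' in this gap cannot meet the BP arm of the case definition, so observed
#' prevalence understates the burden wherever screening is incomplete.
#'
#' @param x a `cohort`.
#' @param eligible eligible patient ids.
#' @return list with `overall` (fraction), `by_org` (named fractions) and
#'   `n`.
#' @export
bp_screening_gap <- function(x, eligible = eligible_patients(x)) {
  stopifnot(inherits(x, "cohort"))
  if (length(eligible) == 0) stop("eligible set is empty")
  bp <- x$bp_readings
  has_bp <- unique(bp$patient_id[in_year(bp$date, x$observation_year)])
  missing <- !(eligible %in% has_bp)
  org <- x$patients$org_id[match(eligible, x$patients$patient_id)]
  by_org <- tapply(missing, org, mean)
  list(overall = mean(missing),
       by_org = stats::setNames(as.vector(by_org), names(by_org)),
       n = length(eligible))
}

#' Write per-patient ascertainment results to CSV
#'
#' @param ascertainment result of [ascertain_cohort()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_ascertainment <- function(ascertainment, path) {
  utils::write.csv(ascertainment, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
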