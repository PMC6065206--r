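round_thousand <- function(x) 1000 * round(x / 1000)

#' Compare observed and predicted prevalence
#'
#' The headline comparison: predicted minus observed prevalence in
#' percentage points, the CI of that difference (the observed prevalence is
#' a census quantity -- it is counted, not sampled -- so only the predicted
#' CI contributes), and the implied number of additional patients who
#' potentially have undiagnosed hypertension, `n * (predicted - observed)`,
#' reported rounded to the nearest thousand. Negative gaps (observed above
#' predicted) keep their sign.
#'
#' @param observed a [prevalence_estimate()] of observed prevalence.
#' @param predicted a [prevalence_estimate()] of predicted prevalence.
#' @param n population size the patient count refers to (defaults to
#'   `observed$n`).
#' @return Object of class `gap_report`: `observed`, `predicted`, `n`,
#'   `diff_pp`, `diff_ci` (length-2, percentage points),
#'   `additional_patients_raw`, `additional_patients` (nearest thousand),
#'   `one_in_n` (see [one_in_n()]; `NA` when the gap is not positive).
#' @export
gap_compare <- function(observed, predicted, n = observed$n) {
  stopifnot(inherits(observed, "prevalence_estimate"),
            inherits(predicted, "prevalence_estimate"))
  if (is.null(n) || is.na(n) || n <= 0) stop("n must be positive")
  diff_pp <- 100 * (predicted$value - observed$value)
  diff_ci <- 100 * (c(predicted$ci_low, predicted$ci_high) - observed$value)
  raw <- n * (predicted$value - observed$value)
  structure(list(observed = observed, predicted = predicted, n = n,
                 diff_pp = diff_pp, diff_ci = diff_ci,
                 additional_patients_raw = raw,
                 additional_patients = round_thousand(raw),
                 one_in_n = one_in_n(100 * predicted$value, diff_pp)),
            class = "gap_report")
}

#' "One in N" undiagnosed ratio
#'
#' Among patients predicted to have hypertension, the share whose
#' hypertension is potentially undiagnosed is `diff_pp / predicted_pct`;
#' its reciprocal, rounded to the nearest integer, is the familiar
#' "one in N" figure. Undefined (returned as `NA`) when the gap is not
#' positive.
#'
#' @param predicted_pct predicted prevalence in percent (e.g. 33.2).
#' @param diff_pp predicted-minus-observed difference in percentage points.
#' @return Integer, or `NA_integer_` when `diff_pp <= 0`.
#' @export
one_in_n <- function(predicted_pct, diff_pp) {
  if (is.na(diff_pp) || diff_pp <= 0) return(NA_integer_)
  as.integer(round(predicted_pct / diff_pp))
}

#' @export
print.gap_report <- function(x, ...) {
  cat(sprintf("Observed %.1f%% vs predicted %.1f%% (95%% CI %.1f-%.1f), n = %s\n",
              100 * x$observed$value, 100 * x$predicted$value,
              100 * x$predicted$ci_low, 100 * x$predicted$ci_high,
              format(x$n, big.mark = ",")))
  cat(sprintf("Gap: %.1f percentage points (95%% CI %.1f-%.1f); %s additional patients",
              x$diff_pp, x$diff_ci[1], x$diff_ci[2],
              format(x$additional_patients, big.mark = ",")))
  if (!is.na(x$one_in_n)) {
    cat(sprintf("; one in %d predicted hypertensives potentially undiagnosed", x$one_in_n))
  }
  cat("\n")
  invisible(x)
}

# flatten one gap_report into a single data.frame row
gap_row <- function(g, org_id, level, comorbidity_mode) {
  data.frame(org_id = org_id, level = level, comorbidity_mode = comorbidity_mode,
             n = g$n,
             observed_pct = 100 * g$observed$value,
             predicted_pct = 100 * g$predicted$value,
             predicted_ci_low = 100 * g$predicted$ci_low,
             predicted_ci_high = 100 * g$predicted$ci_high,
             diff_pp = g$diff_pp,
             diff_ci_low = g$diff_ci[1], diff_ci_high = g$diff_ci[2],
             additional_patients = g$additional_patients,
             one_in_n = ifelse(is.na(g$one_in_n), NA_integer_, g$one_in_n),
             stringsAsFactors = FALSE)
}

#' Gap table from already-computed prevalences
#'
#' Builds per-organization gap rows directly from observed and predicted
#' prevalence columns (percentages), as published summary tables provide
#' them. Useful for re-analyzing printed results without patient-level
#' data; predicted CIs are taken as degenerate (the point estimate).
#'
#' @param org_id character vector of organization labels.
#' @param observed_pct,predicted_pct prevalences in percent.
#' @param n population sizes (recycled).
#' @param level,comorbidity_mode labels stored in the output rows.
#' @return data.frame of gap rows with attribute `extrema`
#'   (`c(min, max)` of `diff_pp`).
#' @export
gap_table <- function(org_id, observed_pct, predicted_pct, n,
                      level = "plus_clinical", comorbidity_mode = "org_specific") {
  stopifnot(length(org_id) == length(observed_pct),
            length(org_id) == length(predicted_pct))
  n <- rep_len(n, length(org_id))
  rows <- lapply(seq_along(org_id), function(i) {
    g <- gap_compare(prevalence_estimate(observed_pct[i] / 100, n = n[i], se = 0),
                     prevalence_estimate(predicted_pct[i] / 100, n = n[i], se = 0),
                     n = n[i])
    gap_row(g, org_id[i], level, comorbidity_mode)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "extrema") <- c(min = min(out$diff_pp), max = max(out$diff_pp))
  out
}

#' Per-organization observed-vs-predicted gaps
#'
#' Runs the whole estimator separately for each organization in the cohort
#' (and for the pooled cohort as `"overall"`): observed prevalence and
#' stratum weights are computed from that organization's eligible patients,
#' predicted prevalence from the shared reference table. Organizations with
#' no eligible patients are dropped with a warning.
#'
#' @param x a `cohort`.
#' @param reference a joint-mode [reference_table()] (with `buckets` when
#'   `comorbidity_modes` includes `"reference"`).
#' @param cs a [code_sets()] object.
#' @param levels evidence levels to run (default all three).
#' @param comorbidity_modes `"org_specific"` (joint weights from the
#'   organization's own ascertained comorbidities) and/or `"reference"`
#'   (demographic-only weights against the folded table).
#' @param ci_method passed to [predicted_prevalence()].
#' @return data.frame of gap rows (one per org x level x mode, with
#'   `"overall"` rows included), with attribute `extrema`: cross-organization
#'   min/max `diff_pp` per level x mode (excluding the overall rows).
#' @export
per_org_gaps <- function(x, reference, cs = code_sets(),
                         levels = EVIDENCE_LEVELS,
                         comorbidity_modes = c("org_specific", "reference"),
                         ci_method = "propagate") {
  stopifnot(inherits(x, "cohort"), inherits(reference, "reference_table"))
  levels <- match.arg(levels, EVIDENCE_LEVELS, several.ok = TRUE)
  comorbidity_modes <- match.arg(comorbidity_modes,
                                 c("org_specific", "reference"), several.ok = TRUE)
  eligible <- eligible_patients(x)
  if (length(eligible) == 0) stop("no eligible patients")
  asc <- ascertain_cohort(x, eligible, cs)
  folded <- if ("reference" %in% comorbidity_modes) fold_reference_comorbidity(reference) else NULL

  org_of <- x$patients$org_id[match(eligible, x$patients$patient_id)]
  units <- c(list(overall = eligible),
             split(eligible, org_of))
  empty_orgs <- setdiff(unique(x$patients$org_id), org_of)
  if (length(empty_orgs)) {
    warning("organization(s) with no eligible patients excluded: ",
            paste(empty_orgs, collapse = ", "))
  }
  rows <- list()
  for (u in names(units)) {
    ids <- units[[u]]
    a_u <- asc[asc$patient_id %in% ids, , drop = FALSE]
    for (lv in levels) {
      obs <- observed_prevalence(x, ids, lv, cs, ascertainment = a_u)
      for (m in comorbidity_modes) {
        if (m == "org_specific") {
          w <- stratum_weights(x, ids, lv, use_comorbidity = TRUE, cs, ascertainment = a_u)
          pred <- predicted_prevalence(w, reference, n = length(ids), ci_method = ci_method)
        } else {
          w <- stratum_weights(x, ids, lv, use_comorbidity = FALSE, cs, ascertainment = a_u)
          pred <- predicted_prevalence(w, folded, n = length(ids), ci_method = ci_method)
        }
        rows[[length(rows) + 1L]] <- gap_row(gap_compare(obs, pred, length(ids)), u, lv, m)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  orgs <- out[out$org_id != "overall", , drop = FALSE]
  if (nrow(orgs)) {
    ext <- do.call(rbind, lapply(split(orgs, paste(orgs$level, orgs$comorbidity_mode, sep = ".")),
                                 function(d) data.frame(level = d$level[1],
                                                        comorbidity_mode = d$comorbidity_mode[1],
                                                        min_diff_pp = min(d$diff_pp),
                                                        max_diff_pp = max(d$diff_pp),
                                                        stringsAsFactors = FALSE)))
    rownames(ext) <- NULL
    attr(out, "extrema") <- ext
  }
  out
}

#' Undiagnosed-hypertension gap analysis of a cohort
#'
#' The package's central fit: ascertains hypertension and comorbidities for
#' every eligible patient, computes observed prevalence under the three
#' nested case definitions, predicts expected prevalence from the reference
#' table (with organization-specific comorbidity composition and/or the
#' reference's own), and reports the gaps overall and per organization,
#' along with the demographic summary and the BP-screening gap.
#'
#' @param x a `cohort`.
#' @param reference a joint-mode [reference_table()].
#' @param cs a [code_sets()] object.
#' @param levels evidence levels to run.
#' @param comorbidity_modes `"org_specific"`, `"reference"`, or both.
#' @param ci_method passed to [predicted_prevalence()].
#' @return Object of class `htn_gap` with fields `gaps` (the
#'   [per_org_gaps()] table), `extrema`, `ascertainment`, `demographics`,
#'   `bp_gap`, `eligible_n`, `observation_year`, plus the inputs used.
#' @examples
#' params <- sim_params(n_patients = 500, org_count = 2, seed = 42)
#' sim <- generate_cohort(params)
#' fit <- htn_gap(sim$cohort, generate_reference_table(params))
#' print(fit)
#' @export
htn_gap <- function(x, reference, cs = code_sets(),
                    levels = EVIDENCE_LEVELS,
                    comorbidity_modes = c("org_specific", "reference"),
                    ci_method = "propagate") {
  stopifnot(inherits(x, "cohort"))
  eligible <- eligible_patients(x)
  if (length(eligible) == 0) stop("no eligible patients in cohort")
  asc <- ascertain_cohort(x, eligible, cs)
  gaps <- per_org_gaps(x, reference, cs, levels, comorbidity_modes, ci_method)
  structure(list(
    gaps = gaps,
    extrema = attr(gaps, "extrema"),
    ascertainment = asc,
    demographics = summarize_demographics(x, eligible),
    bp_gap = bp_screening_gap(x, eligible),
    eligible_n = length(eligible),
    observation_year = x$observation_year,
    levels = levels, comorbidity_modes = comorbidity_modes,
    code_sets = cs), class = "htn_gap")
}

#' @export
print.htn_gap <- function(x, ...) {
  ov <- x$gaps[x$gaps$org_id == "overall" & x$gaps$comorbidity_mode == x$comorbidity_modes[1], ]
  cat(sprintf("Undiagnosed-hypertension gap analysis: %s eligible patients, year %d\n",
              format(x$eligible_n, big.mark = ","), x$observation_year))
  cat(sprintf("BP-screening gap: %.1f%% of eligible patients have no BP reading\n\n",
              100 * x$bp_gap$overall))
  for (i in seq_len(nrow(ov))) {
    cat(sprintf("  %-18s observed %5.1f%%  predicted %5.1f%% (%.1f-%.1f)  gap %+.1f pp",
                ov$level[i], ov$observed_pct[i], ov$predicted_pct[i],
                ov$predicted_ci_low[i], ov$predicted_ci_high[i], ov$diff_pp[i]))
    if (!is.na(ov$one_in_n[i]) && ov$diff_pp[i] > 0) cat(sprintf("  (one in %d)", ov$one_in_n[i]))
    cat("\n")
  }
  invisible(x)
}

#' @export
summary.htn_gap <- function(object, ...) {
  structure(list(fit = object), class = "summary.htn_gap")
}

#' @export
print.summary.htn_gap <- function(x, ...) {
  fit <- x$fit
  print(fit)
  tiers <- table(factor(fit$ascertainment$htn_tier, levels = HTN_TIERS))
  cat("\nHypertension tier counts:\n")
  print(tiers)
  if (!is.null(fit$extrema)) {
    cat("\nCross-organization gap range (percentage points):\n")
    print(fit$extrema, row.names = FALSE)
  }
  invisible(x)
}

#' Write a gap table to CSV
#'
#' @param gaps the `gaps` data.frame of an `htn_gap` fit (or
#'   [per_org_gaps()] output).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_gap_report <- function(gaps, path) {
  utils::write.csv(as.data.frame(gaps), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
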