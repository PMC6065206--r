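# Enumerations shared across the package. These are closed sets: validation
# rejects anything outside them.
SEX_LEVELS <- c("female", "male")
RACE_LEVELS <- c("nh_white", "nh_black", "hispanic", "other", "missing")
RACE_KNOWN <- c("nh_white", "nh_black", "hispanic", "other")
AGE_GROUPS <- c("18-44", "45-64", "65-74", "75-85")
AGE_BREAKS <- c(18L, 45L, 65L, 75L, 86L) # left-closed bands over [18, 85]
SETTING_LEVELS <- c("ambulatory_em", "other")
SOURCE_LEVELS <- c("claim", "problem_list")
MEASUREMENT_KINDS <- c("bmi", "hba1c", "fasting_glucose", "egfr")
EVIDENCE_LEVELS <- c("claims_only", "plus_problem_list", "plus_clinical")
HTN_TIERS <- c("none", "claims", "problem_list", "bp_criteria")
COUNT_BUCKETS <- c("zero", "one", "two_or_three")
CONDITIONS <- c("obesity", "diabetes", "ckd")

#' Diagnosis code sets and clinical thresholds
#'
#' Bundles the ICD-10-CM code prefixes and the clinical cutoffs used by the
#' case definitions. Prefix matching is performed on the undotted, uppercased
#' code string, so the prefix `"I11"` matches `I11`, `I11.0` and `I11.9`.
#'
#' Default prefixes follow common claims-algorithm practice: hypertension
#' `I10`--`I13`, `I15`, `I16`; obesity `E66`; diabetes `E10`, `E11`; chronic
#' kidney disease `N18`. All of them, and every clinical threshold, can be
#' overridden -- organizations differ in the code lists they consider
#' authoritative, so nothing is hard-wired.
#'
#' @param prefixes named list of character vectors of ICD-10-CM prefixes, one
#'   entry per condition in `c("hypertension", "obesity", "diabetes", "ckd")`.
#' @param thresholds named list of clinical cutoffs:
#'   `bmi` (kg/m^2), `hba1c` (percent), `fasting_glucose` (mg/dL),
#'   `egfr` (mL/min/1.73 m^2), `egfr_chronicity_days` (days between the two
#'   qualifying eGFR results), `bp_single` (systolic/diastolic mm Hg for the
#'   single-reading blood-pressure arm), `bp_repeat` (thresholds for the
#'   two-readings-on-different-days arm).
#' @param bp_rule `"or"` (default) treats a reading as elevated when either
#'   the systolic or the diastolic component crosses its threshold; `"and"`
#'   requires both, for sensitivity analysis.
#' @return An object of class `code_sets`.
#' @examples
#' cs <- code_sets()
#' cs$prefixes$hypertension
#' @export
code_sets <- function(prefixes = NULL, thresholds = NULL, bp_rule = c("or", "and")) {
  bp_rule <- match.arg(bp_rule)
  def_prefixes <- list(
    hypertension = c("I10", "I11", "I12", "I13", "I15", "I16"),
    obesity = "E66",
    diabetes = c("E10", "E11"),
    ckd = "N18"
  )
  def_thresholds <- list(
    bmi = 30, hba1c = 6.5, fasting_glucose = 126,
    egfr = 60, egfr_chronicity_days = 90,
    bp_single = c(systolic = 160, diastolic = 100),
    bp_repeat = c(systolic = 140, diastolic = 90)
  )
  if (!is.null(prefixes)) {
    stopifnot(is.list(prefixes), all(names(prefixes) %in% names(def_prefixes)))
    def_prefixes[names(prefixes)] <- lapply(prefixes, function(p) toupper(gsub(".", "", p, fixed = TRUE)))
  }
  if (!is.null(thresholds)) {
    stopifnot(is.list(thresholds), all(names(thresholds) %in% names(def_thresholds)))
    def_thresholds[names(thresholds)] <- thresholds
  }
  if (any(lengths(def_prefixes) == 0)) stop("every condition needs at least one code prefix")
  num <- unlist(def_thresholds[c("bmi", "hba1c", "fasting_glucose", "egfr", "egfr_chronicity_days")])
  if (any(!is.finite(num)) || any(num <= 0)) stop("clinical thresholds must be positive numbers")
  structure(list(prefixes = def_prefixes, thresholds = def_thresholds, bp_rule = bp_rule),
            class = "code_sets")
}

#' @export
print.code_sets <- function(x, ...) {
  cat("Code sets (ICD-10-CM prefixes, undotted):\n")
  for (cond in names(x$prefixes)) {
    cat(sprintf("  %-12s %s\n", cond, paste(x$prefixes[[cond]], collapse = ", ")))
  }
  th <- x$thresholds
  cat(sprintf("Clinical thresholds: BMI >= %g kg/m2; HbA1c >= %g%%; fasting glucose >= %g mg/dL (x2, distinct dates);\n",
              th$bmi, th$hba1c, th$fasting_glucose))
  cat(sprintf("  eGFR < %g mL/min/1.73m2 twice >= %g days apart\n", th$egfr, th$egfr_chronicity_days))
  cat(sprintf("BP criteria: single >= %g/%g, repeat >= %g/%g mm Hg on different days (rule: %s)\n",
              th$bp_single["systolic"], th$bp_single["diastolic"],
              th$bp_repeat["systolic"], th$bp_repeat["diastolic"], x$bp_rule))
  invisible(x)
}

#' Read or write code sets as YAML
#'
#' The on-disk form mirrors the `code_sets()` arguments: a `prefixes` block,
#' a `thresholds` block and a `bp_rule` scalar.
#'
#' @param path file path of the YAML document.
#' @return `read_code_sets()` returns a `code_sets` object;
#'   `write_code_sets()` returns `path` invisibly.
#' @export
read_code_sets <- function(path) {
  if (!file.exists(path)) stop("code sets file not found: ", path)
  raw <- yaml::read_yaml(path)
  th <- raw$thresholds
  if (!is.null(th)) {
    for (nm in c("bp_single", "bp_repeat")) {
      if (!is.null(th[[nm]])) th[[nm]] <- unlist(th[[nm]])
    }
  }
  code_sets(prefixes = raw$prefixes, thresholds = th,
            bp_rule = if (is.null(raw$bp_rule)) "or" else raw$bp_rule)
}

#' @rdname read_code_sets
#' @param x a `code_sets` object.
#' @export
write_code_sets <- function(x, path) {
  stopifnot(inherits(x, "code_sets"))
  th <- x$thresholds
  th$bp_single <- as.list(th$bp_single)
  th$bp_repeat <- as.list(th$bp_repeat)
  yaml::write_yaml(list(prefixes = x$prefixes, thresholds = th, bp_rule = x$bp_rule), path)
  invisible(path)
}

# Undotted uppercase form used for all prefix matching.
strip_code <- function(code) toupper(gsub(".", "", code, fixed = TRUE))

# TRUE for each code that starts with any of the prefixes.
code_matches <- function(codes, prefixes) {
  stripped <- strip_code(codes)
  out <- rep(FALSE, length(stripped))
  for (p in prefixes) out <- out | startsWith(stripped, p)
  out
}
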