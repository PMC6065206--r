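#' Assemble a patient-level cohort
#'
#' A cohort bundles the five patient-level tables the pipeline consumes --
#' demographics, encounters, diagnosis records, blood-pressure readings and
#' clinical measurements -- together with the observation year. All analysis
#' functions take a cohort; none of them reads files directly.
#'
#' @param patients data.frame with columns `patient_id`, `org_id`, `sex`
#'   (`"female"`/`"male"`), `age` (integer years at January 1 of the
#'   observation year), `race_ethnicity` (one of `nh_white`, `nh_black`,
#'   `hispanic`, `other`, `missing`).
#' @param encounters data.frame with `patient_id`, `date`, `setting`
#'   (`"ambulatory_em"` or `"other"`).
#' @param diagnoses data.frame with `patient_id`, `date`, `code` (ICD-10-CM),
#'   `source` (`"claim"` or `"problem_list"`).
#' @param bp_readings data.frame with `patient_id`, `date`, `systolic`,
#'   `diastolic` (integer mm Hg).
#' @param measurements data.frame with `patient_id`, `date`, `kind`
#'   (`bmi`, `hba1c`, `fasting_glucose`, `egfr`), `value` (kind-specific
#'   units: kg/m^2, percent, mg/dL, mL/min/1.73 m^2).
#' @param observation_year integer calendar year the analysis refers to.
#'   Dates outside the year are allowed in the tables; in-year filtering is
#'   the job of the downstream operations.
#' @param validate if `TRUE` (default), run [validate_cohort()] and fail on
#'   the first batch of violations.
#' @return An object of class `cohort`.
#' @seealso [read_cohort()], [eligible_patients()], [generate_cohort()]
#' @export
cohort <- function(patients, encounters = NULL, diagnoses = NULL,
                   bp_readings = NULL, measurements = NULL,
                   observation_year, validate = TRUE) {
  empty <- empty_cohort_tables()
  x <- structure(list(
    patients = coerce_table(patients, "patients"),
    encounters = coerce_table(if (is.null(encounters)) empty$encounters else encounters, "encounters"),
    diagnoses = coerce_table(if (is.null(diagnoses)) empty$diagnoses else diagnoses, "diagnoses"),
    bp_readings = coerce_table(if (is.null(bp_readings)) empty$bp_readings else bp_readings, "bp_readings"),
    measurements = coerce_table(if (is.null(measurements)) empty$measurements else measurements, "measurements"),
    observation_year = as.integer(observation_year)
  ), class = "cohort")
  if (validate) {
    problems <- validate_cohort(x)
    if (length(problems)) {
      stop("invalid cohort:\n  ", paste(utils::head(problems, 20L), collapse = "\n  "),
           if (length(problems) > 20L) sprintf("\n  ... and %d more", length(problems) - 20L),
           call. = FALSE)
    }
  }
  x
}

COHORT_SCHEMAS <- list(
  patients = c(patient_id = "character", org_id = "character", sex = "character",
               age = "integer", race_ethnicity = "character"),
  encounters = c(patient_id = "character", date = "Date", setting = "character"),
  diagnoses = c(patient_id = "character", date = "Date", code = "character",
                source = "character"),
  bp_readings = c(patient_id = "character", date = "Date", systolic = "integer",
                  diastolic = "integer"),
  measurements = c(patient_id = "character", date = "Date", kind = "character",
                   value = "numeric")
)

empty_cohort_tables <- function() {
  lapply(COHORT_SCHEMAS, function(schema) {
    cols <- lapply(schema, function(type) switch(type,
      character = character(0), integer = integer(0),
      numeric = numeric(0), Date = as.Date(character(0))))
    as.data.frame(cols, stringsAsFactors = FALSE)
  })
}

coerce_table <- function(df, name) {
  schema <- COHORT_SCHEMAS[[name]]
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  missing_cols <- setdiff(names(schema), names(df))
  if (length(missing_cols)) {
    stop(sprintf("%s table is missing column(s): %s", name,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  df <- df[names(schema)]
  for (col in names(schema)) {
    df[[col]] <- switch(schema[[col]],
      character = as.character(df[[col]]),
      integer = as.integer(df[[col]]),
      numeric = as.numeric(df[[col]]),
      Date = parse_iso_date(df[[col]]))
  }
  rownames(df) <- NULL
  df
}

parse_iso_date <- function(x) {
  if (inherits(x, "Date")) return(x)
  as.Date(as.character(x), format = "%Y-%m-%d")
}

#' Validate a cohort against its type invariants
#'
#' Checks every row of the five tables: closed enumerations, physiologic
#' ranges for blood-pressure readings (systolic 40--300, diastolic 20--200,
#' diastolic below systolic), positive measurement values, ICD-10-CM code
#' shape (letter, two digits, optional dot and suffix), valid dates, unique
#' patient ids, and referential integrity (every child row's `patient_id`
#' must exist in the patients table).
#'
#' @param x a `cohort`.
#' @return Character vector of human-readable problems, one per offending
#'   row (empty when the cohort is valid). Each message names the table and
#'   the row number.
#' @export
validate_cohort <- function(x) {
  p <- character(0)
  flag <- function(table, rows, msg) {
    if (any(rows)) p <<- c(p, sprintf("%s row %d: %s", table, which(rows), msg))
    invisible(NULL)
  }
  pat <- x$patients
  flag("patients", is.na(pat$patient_id) | pat$patient_id == "", "empty patient_id")
  flag("patients", duplicated(pat$patient_id), "duplicate patient_id")
  flag("patients", is.na(pat$org_id) | pat$org_id == "", "empty org_id")
  flag("patients", !(pat$sex %in% SEX_LEVELS), "sex not in {female, male}")
  flag("patients", is.na(pat$age) | pat$age < 0, "age missing or negative")
  flag("patients", !(pat$race_ethnicity %in% RACE_LEVELS),
       paste0("race_ethnicity not in {", paste(RACE_LEVELS, collapse = ", "), "}"))
  ids <- pat$patient_id

  enc <- x$encounters
  flag("encounters", !(enc$patient_id %in% ids), "patient_id not in patients table")
  flag("encounters", is.na(enc$date), "invalid or missing date (ISO-8601 expected)")
  flag("encounters", !(enc$setting %in% SETTING_LEVELS), "setting not in {ambulatory_em, other}")

  dx <- x$diagnoses
  flag("diagnoses", !(dx$patient_id %in% ids), "patient_id not in patients table")
  flag("diagnoses", is.na(dx$date), "invalid or missing date (ISO-8601 expected)")
  bad_code <- is.na(dx$code) | !grepl("^[A-Z][0-9]{2}(\\.[A-Z0-9]{1,4})?$", dx$code)
  flag("diagnoses", bad_code, "code does not match ICD-10-CM shape (e.g. I10, E66.9)")
  flag("diagnoses", !(dx$source %in% SOURCE_LEVELS), "source not in {claim, problem_list}")

  bp <- x$bp_readings
  flag("bp_readings", !(bp$patient_id %in% ids), "patient_id not in patients table")
  flag("bp_readings", is.na(bp$date), "invalid or missing date (ISO-8601 expected)")
  flag("bp_readings", is.na(bp$systolic) | bp$systolic < 40 | bp$systolic > 300,
       "systolic outside [40, 300] mm Hg")
  flag("bp_readings", is.na(bp$diastolic) | bp$diastolic < 20 | bp$diastolic > 200,
       "diastolic outside [20, 200] mm Hg")
  ok <- !is.na(bp$systolic) & !is.na(bp$diastolic)
  flag("bp_readings", ok & bp$diastolic >= bp$systolic, "diastolic not below systolic")

  ms <- x$measurements
  flag("measurements", !(ms$patient_id %in% ids), "patient_id not in patients table")
  flag("measurements", is.na(ms$date), "invalid or missing date (ISO-8601 expected)")
  flag("measurements", !(ms$kind %in% MEASUREMENT_KINDS),
       "kind not in {bmi, hba1c, fasting_glucose, egfr}")
  flag("measurements", is.na(ms$value) | ms$value <= 0, "value must be positive")
  p
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("Cohort, observation year %d\n", x$observation_year))
  cat(sprintf("  %d patients in %d organization(s)\n",
              nrow(x$patients), length(unique(x$patients$org_id))))
  cat(sprintf("  %d encounters, %d diagnosis records, %d BP readings, %d clinical measurements\n",
              nrow(x$encounters), nrow(x$diagnoses), nrow(x$bp_readings), nrow(x$measurements)))
  invisible(x)
}

cohort_paths <- function(dir_or_paths) {
  tables <- names(COHORT_SCHEMAS)
  if (is.character(dir_or_paths) && length(dir_or_paths) == 1 && is.null(names(dir_or_paths))) {
    stats::setNames(file.path(dir_or_paths, paste0(tables, ".csv")), tables)
  } else {
    paths <- unlist(dir_or_paths)
    missing <- setdiff(tables, names(paths))
    if (length(missing)) stop("paths must name every table; missing: ", paste(missing, collapse = ", "))
    paths[tables]
  }
}

#' Read a cohort from CSV files
#'
#' Expects the five-table CSV layout written by [write_cohort()]:
#' `patients.csv`, `encounters.csv`, `diagnoses.csv`, `bp_readings.csv`,
#' `measurements.csv` (comma-separated, UTF-8, header row, ISO-8601 dates).
#' Every row is validated; violations are reported with file and row number.
#'
#' @param paths either a directory containing the five files under their
#'   standard names, or a named character vector/list with one path per
#'   table (`patients`, `encounters`, `diagnoses`, `bp_readings`,
#'   `measurements`).
#' @param observation_year integer calendar year of the analysis.
#' @return A validated `cohort`.
#' @export
read_cohort <- function(paths, observation_year) {
  paths <- cohort_paths(paths)
  for (tb in names(paths)) {
    if (!file.exists(paths[[tb]])) stop("missing file for table '", tb, "': ", paths[[tb]])
  }
  tables <- list()
  for (tb in names(paths)) {
    df <- utils::read.csv(paths[[tb]], stringsAsFactors = FALSE, colClasses = "character")
    schema <- COHORT_SCHEMAS[[tb]]
    if (!identical(sort(names(df)), sort(names(schema)))) {
      stop(sprintf("malformed header in %s: expected columns {%s}, found {%s}",
                   paths[[tb]], paste(names(schema), collapse = ", "),
                   paste(names(df), collapse = ", ")))
    }
    # numeric coercion failures become NA and are caught by validation
    suppressWarnings(tables[[tb]] <- coerce_table(df, tb))
  }
  x <- structure(c(tables, list(observation_year = as.integer(observation_year))),
                 class = "cohort")
  problems <- validate_cohort(x)
  if (length(problems)) {
    stop("invalid cohort data:\n  ", paste(utils::head(problems, 20L), collapse = "\n  "),
         if (length(problems) > 20L) sprintf("\n  ... and %d more", length(problems) - 20L),
         call. = FALSE)
  }
  x
}

#' Write a cohort to CSV files
#'
#' Inverse of [read_cohort()]: `read_cohort(write_cohort(x, dir), year)`
#' reproduces `x` exactly. An empty cohort yields five header-only files.
#'
#' @param x a `cohort`.
#' @param paths directory or named per-table paths, as in [read_cohort()].
#' @return The paths written, invisibly.
#' @export
write_cohort <- function(x, paths) {
  stopifnot(inherits(x, "cohort"))
  paths <- cohort_paths(paths)
  dirs <- unique(dirname(paths))
  for (d in dirs) if (!dir.exists(d)) dir.create(d, recursive = TRUE)
  for (tb in names(paths)) {
    df <- x[[tb]]
    for (col in names(df)) if (inherits(df[[col]], "Date")) df[[col]] <- format(df[[col]], "%Y-%m-%d")
    utils::write.csv(df, paths[[tb]], row.names = FALSE, quote = FALSE)
  }
  invisible(paths)
}

#' Analysis denominator: adults 18--85 with an in-year ambulatory E&M visit
#'
#' Returns the patients who form the denominator of every prevalence in the
#' pipeline: age 18--85 at the start of the observation year and at least
#' one ambulatory evaluation-and-management encounter dated within the
#' observation year.
#'
#' @param x a `cohort`.
#' @return Character vector of eligible `patient_id`s (in patients-table order).
#' @export
eligible_patients <- function(x) {
  stopifnot(inherits(x, "cohort"))
  enc <- x$encounters
  in_year <- !is.na(enc$date) & as.integer(format(enc$date, "%Y")) == x$observation_year
  visited <- unique(enc$patient_id[in_year & enc$setting == "ambulatory_em"])
  pat <- x$patients
  pat$patient_id[pat$age >= 18L & pat$age <= 85L & pat$patient_id %in% visited]
}

#' Age band of an adult age
#'
#' Maps an integer age in 18--85 to one of the four analysis bands
#' `18-44`, `45-64`, `65-74`, `75-85`. The bands partition the interval:
#' every integer age maps to exactly one band.
#'
#' @param age integer vector of ages in years.
#' @return Character vector of band labels.
#' @export
age_group <- function(age) {
  age <- as.integer(age)
  if (any(is.na(age) | age < 18L | age > 85L)) {
    stop("age_group is defined for integer ages in [18, 85]")
  }
  AGE_GROUPS[findInterval(age, AGE_BREAKS)]
}

#' Demographic composition of the eligible population
#'
#' Percentage breakdown by age group, sex and race/ethnicity, overall and
#' per organization. Within each characteristic the percentages sum to 100
#' (up to rounding in display; the returned values are unrounded).
#'
#' @param x a `cohort`.
#' @param eligible character vector of eligible patient ids (see
#'   [eligible_patients()]); must be a subset of the patients table.
#' @return data.frame with columns `org_id` (`"overall"` plus each
#'   organization), `characteristic` (`n_patients`, `age_group`, `sex`,
#'   `race_ethnicity`), `level`, `count`, `percent`.
#' @export
summarize_demographics <- function(x, eligible = eligible_patients(x)) {
  stopifnot(inherits(x, "cohort"))
  if (length(eligible) == 0) stop("eligible set is empty")
  pat <- x$patients[x$patients$patient_id %in% eligible, , drop = FALSE]
  if (nrow(pat) < length(unique(eligible))) stop("eligible contains ids not present in the cohort")
  pat$age_band <- age_group(pat$age)

  one_block <- function(df, org) {
    blocks <- list(data.frame(org_id = org, characteristic = "n_patients", level = "total",
                              count = nrow(df), percent = 100, stringsAsFactors = FALSE))
    specs <- list(age_group = list(col = "age_band", levels = AGE_GROUPS),
                  sex = list(col = "sex", levels = SEX_LEVELS),
                  race_ethnicity = list(col = "race_ethnicity", levels = RACE_LEVELS))
    for (ch in names(specs)) {
      tab <- table(factor(df[[specs[[ch]]$col]], levels = specs[[ch]]$levels))
      blocks[[length(blocks) + 1L]] <- data.frame(
        org_id = org, characteristic = ch, level = names(tab),
        count = as.integer(tab), percent = 100 * as.integer(tab) / nrow(df),
        stringsAsFactors = FALSE)
    }
    do.call(rbind, blocks)
  }
  out <- one_block(pat, "overall")
  for (org in sort(unique(pat$org_id))) {
    out <- rbind(out, one_block(pat[pat$org_id == org, , drop = FALSE], org))
  }
  rownames(out) <- NULL
  out
}
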