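demographic_grid <- function() {
  expand.grid(sex = SEX_LEVELS, race_ethnicity = RACE_KNOWN, age_group = AGE_GROUPS,
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
}

stratum_key <- function(df, joint) {
  base <- paste(df$sex, df$race_ethnicity, df$age_group, sep = "|")
  if (joint) paste(base, df$count_bucket, sep = "|") else base
}

#' Stratum-specific reference prevalence table
#'
#' The estimator's knowledge base: for every stratum of the reference
#' population, the hypertension prevalence and its standard error. In
#' `"joint"` mode a stratum is sex x race/ethnicity x age group x
#' comorbidity-count bucket; in `"demographic"` mode the bucket dimension is
#' absent (`count_bucket` is `"ALL"`). The optional `buckets` table carries
#' the reference population's own comorbidity-count distribution per
#' demographic stratum, which [fold_reference_comorbidity()] uses when an
#' organization cannot supply its own comorbidity data.
#'
#' Every possible stratum must be present. Race/ethnicity `missing` is not a
#' reference stratum; [stratum_weights()] redistributes such patients.
#'
#' @param strata data.frame with columns `sex`, `race_ethnicity`,
#'   `age_group`, `count_bucket` (`"ALL"` in demographic mode),
#'   `prevalence`, `se`.
#' @param buckets optional data.frame with `sex`, `race_ethnicity`,
#'   `age_group`, `count_bucket`, `share` (shares sum to 1 within each
#'   demographic stratum).
#' @param mode `"joint"` or `"demographic"`.
#' @return Object of class `reference_table` with fields `strata`,
#'   `buckets`, `mode`.
#' @export
reference_table <- function(strata, buckets = NULL, mode = c("joint", "demographic")) {
  mode <- match.arg(mode)
  strata <- as.data.frame(strata, stringsAsFactors = FALSE)
  need <- c("sex", "race_ethnicity", "age_group", "prevalence", "se")
  if (!all(need %in% names(strata))) {
    stop("reference table needs columns: ", paste(need, collapse = ", "))
  }
  if (mode == "demographic" && !("count_bucket" %in% names(strata))) strata$count_bucket <- "ALL"
  if (any(strata$prevalence < 0 | strata$prevalence > 1)) stop("prevalences must be in [0, 1]")
  if (any(strata$se < 0 | strata$se > 1)) stop("standard errors must be in [0, 1]")

  grid <- demographic_grid()
  expected <- if (mode == "joint") {
    g <- grid[rep(seq_len(nrow(grid)), each = length(COUNT_BUCKETS)), ]
    g$count_bucket <- rep(COUNT_BUCKETS, nrow(grid))
    g
  } else {
    grid$count_bucket <- "ALL"
    grid
  }
  have <- stratum_key(strata, joint = TRUE)
  want <- stratum_key(expected, joint = TRUE)
  absent <- setdiff(want, have)
  if (length(absent)) {
    stop("reference table is missing ", length(absent), " stratum/strata, e.g. ", absent[1])
  }
  if (anyDuplicated(have)) stop("reference table has duplicate strata")
  if (!is.null(buckets)) {
    buckets <- as.data.frame(buckets, stringsAsFactors = FALSE)
    sums <- tapply(buckets$share, stratum_key(buckets, joint = FALSE), sum)
    if (any(abs(sums - 1) > 1e-8)) stop("reference bucket shares must sum to 1 per demographic stratum")
  }
  rownames(strata) <- NULL
  structure(list(strata = strata, buckets = buckets, mode = mode), class = "reference_table")
}

#' @export
print.reference_table <- function(x, ...) {
  cat(sprintf("Reference prevalence table (%s mode): %d strata, prevalence %.3f-%.3f\n",
              x$mode, nrow(x$strata), min(x$strata$prevalence), max(x$strata$prevalence)))
  if (!is.null(x$buckets)) cat("  includes reference comorbidity-count distributions\n")
  invisible(x)
}

#' Read or write a reference table as CSV
#'
#' `reference_table.csv` holds `sex`, `race_ethnicity`, `age_group`,
#' `count_bucket` (`"ALL"` for demographic-only tables), `prevalence`, `se`;
#' the companion `reference_buckets.csv` holds the per-demographic-stratum
#' count-bucket shares.
#'
#' @param path path of the strata CSV.
#' @param buckets_path optional path of the bucket-distribution CSV.
#' @return `read_reference_table()` returns a [reference_table()];
#'   `write_reference_table()` returns `path` invisibly.
#' @export
read_reference_table <- function(path, buckets_path = NULL) {
  if (!file.exists(path)) stop("reference table file not found: ", path)
  strata <- utils::read.csv(path, stringsAsFactors = FALSE)
  buckets <- NULL
  if (!is.null(buckets_path)) {
    if (!file.exists(buckets_path)) stop("reference buckets file not found: ", buckets_path)
    buckets <- utils::read.csv(buckets_path, stringsAsFactors = FALSE)
  }
  mode <- if (all(strata$count_bucket == "ALL")) "demographic" else "joint"
  reference_table(strata, buckets = buckets, mode = mode)
}

#' @rdname read_reference_table
#' @param x a `reference_table`.
#' @export
write_reference_table <- function(x, path, buckets_path = NULL) {
  stopifnot(inherits(x, "reference_table"))
  utils::write.csv(x$strata, path, row.names = FALSE, quote = FALSE)
  if (!is.null(buckets_path) && !is.null(x$buckets)) {
    utils::write.csv(x$buckets, buckets_path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

new_stratum_weights <- function(df, mode, n) {
  rownames(df) <- NULL
  structure(df, class = c("stratum_weights", "data.frame"), mode = mode, n = n)
}

#' Stratum composition of an analyzed population
#'
#' Computes the fraction of the eligible population in each stratum, the
#' quantity the expected-prevalence estimator weights the reference table
#' by. With `use_comorbidity = TRUE` the strata are the full joint
#' sex x race/ethnicity x age group x comorbidity-count bucket (the bucket
#' ascertained at `level`); otherwise demographics only.
#'
#' Patients with missing race/ethnicity are redistributed proportionally
#' over the known race categories within their cell (sex x age group, plus
#' bucket in joint mode); a cell with no known-race patients falls back to
#' the cohort-wide known-race distribution. Weights are non-negative and
#' sum to 1.
#'
#' @param x a `cohort`.
#' @param eligible eligible patient ids.
#' @param level evidence level used to ascertain comorbidities.
#' @param use_comorbidity include the comorbidity-count bucket dimension?
#' @param cs a [code_sets()] object.
#' @param ascertainment optional precomputed [ascertain_cohort()] result.
#' @return A `stratum_weights` data.frame (`sex`, `race_ethnicity`,
#'   `age_group`, optionally `count_bucket`, `weight`) with attributes
#'   `mode` and `n`.
#' @export
stratum_weights <- function(x, eligible = eligible_patients(x),
                            level = "claims_only", use_comorbidity = TRUE,
                            cs = code_sets(), ascertainment = NULL) {
  stopifnot(inherits(x, "cohort"))
  level <- match.arg(level, EVIDENCE_LEVELS)
  if (length(eligible) == 0) stop("eligible set is empty")
  pat <- x$patients[match(eligible, x$patients$patient_id), , drop = FALSE]
  if (anyNA(pat$patient_id)) stop("eligible contains ids not present in the cohort")
  df <- data.frame(sex = pat$sex, race_ethnicity = pat$race_ethnicity,
                   age_group = age_group(pat$age), stringsAsFactors = FALSE)
  if (use_comorbidity) {
    if (is.null(ascertainment)) ascertainment <- ascertain_cohort(x, eligible, cs)
    a <- ascertainment[match(eligible, ascertainment$patient_id), , drop = FALSE]
    counts <- ascertained_at(a$obesity_level, level) +
      ascertained_at(a$diabetes_level, level) + ascertained_at(a$ckd_level, level)
    df$count_bucket <- COUNT_BUCKETS[pmin(counts, 2L) + 1L]
  }
  cell_cols <- setdiff(names(df), "race_ethnicity")
  cell <- do.call(paste, c(df[cell_cols], sep = "|"))

  # counts per (cell, race), then redistribute the missing-race mass
  tab <- table(cell = cell, race = factor(df$race_ethnicity, levels = RACE_LEVELS))
  counts <- matrix(as.numeric(tab), nrow = nrow(tab),
                   dimnames = list(rownames(tab), colnames(tab)))
  known <- counts[, RACE_KNOWN, drop = FALSE]
  miss <- counts[, "missing"]
  overall_known <- colSums(known)
  if (sum(overall_known) == 0 && sum(miss) > 0) {
    stop("all patients have missing race/ethnicity; cannot form reference strata")
  }
  for (r in which(miss > 0)) {
    base <- known[r, ]
    if (sum(base) > 0) {
      known[r, ] <- base + miss[r] * base / sum(base)
    } else {
      known[r, ] <- miss[r] * overall_known / sum(overall_known)
    }
  }
  long <- data.frame(cell = rep(rownames(known), times = ncol(known)),
                     race_ethnicity = rep(colnames(known), each = nrow(known)),
                     weight = as.vector(known) / length(eligible),
                     stringsAsFactors = FALSE)
  long <- long[long$weight > 0, , drop = FALSE]
  parts <- do.call(rbind, strsplit(long$cell, "|", fixed = TRUE))
  out <- data.frame(sex = parts[, 1], race_ethnicity = long$race_ethnicity,
                    age_group = parts[, 2], stringsAsFactors = FALSE)
  if (use_comorbidity) out$count_bucket <- parts[, 3]
  out$weight <- long$weight
  out <- out[order(stratum_key(out, joint = use_comorbidity)), , drop = FALSE]
  new_stratum_weights(out, mode = if (use_comorbidity) "joint" else "demographic",
                      n = length(eligible))
}

#' Expected hypertension prevalence for a population composition
#'
#' Indirect standardization: the prevalence a reference population model
#' implies for a population with the given stratum composition,
#' `value = sum_s w_s * pi_s`, with standard error propagated from the
#' reference table, `se = sqrt(sum_s w_s^2 * se_s^2)`, and a 95% Wald
#' interval clipped to `[0, 1]`. The result always lies between the
#' smallest and largest reference stratum prevalence, and a population
#' whose composition equals the reference population's own returns the
#' reference overall prevalence.
#'
#' @param weights a [stratum_weights()] object (or data.frame with the key
#'   columns and a `weight` column summing to 1).
#' @param table a [reference_table()] in the same mode as `weights`.
#' @param n size of the analyzed population (used for reporting and for
#'   additional-patient counts downstream).
#' @param ci_method `"propagate"` (default: reference-table SE propagation)
#'   or `"wald"` (binomial SE at the point estimate,
#'   `sqrt(v(1-v)/n)`).
#' @return A [prevalence_estimate()].
#' @export
predicted_prevalence <- function(weights, table, n, ci_method = c("propagate", "wald")) {
  ci_method <- match.arg(ci_method)
  stopifnot(inherits(table, "reference_table"))
  w_mode <- attr(weights, "mode")
  if (is.null(w_mode)) w_mode <- if ("count_bucket" %in% names(weights)) "joint" else "demographic"
  if (w_mode != table$mode) {
    stop(sprintf("mode mismatch: weights are %s, reference table is %s", w_mode, table$mode))
  }
  w <- as.data.frame(weights)
  if (abs(sum(w$weight) - 1) > 1e-9) stop("weights must sum to 1")
  joint <- table$mode == "joint"
  idx <- match(stratum_key(w, joint), stratum_key(table$strata, joint))
  if (anyNA(idx)) {
    stop("stratum missing from reference table: ", stratum_key(w, joint)[which(is.na(idx))[1]])
  }
  value <- sum(w$weight * table$strata$prevalence[idx])
  se <- if (ci_method == "propagate") {
    sqrt(sum(w$weight^2 * table$strata$se[idx]^2))
  } else {
    sqrt(value * (1 - value) / n)
  }
  prevalence_estimate(value, n = n, se = se)
}

#' Fold reference comorbidity distributions into a demographic-only table
#'
#' Converts a joint-mode reference table to demographic-only mode using the
#' reference population's own comorbidity-count distribution: for each
#' demographic stratum, `pi_demo = sum_b q_b * pi_(demo,b)` and
#' `se_demo = sqrt(sum_b q_b^2 * se_(demo,b)^2)`. This is the
#' "no organization-specific comorbidity data" mode: predictions then rely
#' entirely on the reference comorbidity mix.
#'
#' @param table a joint-mode [reference_table()] with `buckets`.
#' @return A demographic-mode [reference_table()] (buckets retained).
#' @export
fold_reference_comorbidity <- function(table) {
  stopifnot(inherits(table, "reference_table"))
  if (table$mode != "joint") stop("table is already demographic-only")
  if (is.null(table$buckets)) stop("table has no reference bucket distributions to fold over")
  st <- table$strata
  bk <- table$buckets
  key_st <- stratum_key(st, joint = FALSE)
  idx <- match(paste(key_st, st$count_bucket, sep = "|"), stratum_key(bk, joint = TRUE))
  if (anyNA(idx)) stop("bucket distribution missing for stratum ", key_st[which(is.na(idx))[1]])
  q <- bk$share[idx]
  folded_p <- tapply(q * st$prevalence, key_st, sum)
  folded_v <- tapply(q^2 * st$se^2, key_st, sum)
  grid <- demographic_grid()
  key_g <- stratum_key(grid, joint = FALSE)
  grid$count_bucket <- "ALL"
  grid$prevalence <- as.vector(folded_p[key_g])
  grid$se <- sqrt(as.vector(folded_v[key_g]))
  reference_table(grid, buckets = table$buckets, mode = "demographic")
}

#' Joint weights from marginal summaries (tool-compatibility mode)
#'
#' The published estimator tool takes summary marginals -- a demographic
#' distribution and a comorbidity-count distribution -- rather than
#' patient-level data. This helper reproduces that interface: joint weights
#' are the product of the demographic weight and the bucket marginal
#' (independence assumption).
#'
#' @param demographic_weights demographic-mode [stratum_weights()] (or a
#'   data.frame with `sex`, `race_ethnicity`, `age_group`, `weight`).
#' @param bucket_marginal named fractions over
#'   `c("zero", "one", "two_or_three")`, summing to 1.
#' @return Joint-mode `stratum_weights`.
#' @export
tool_compatibility_weights <- function(demographic_weights, bucket_marginal) {
  w <- as.data.frame(demographic_weights)
  if (!all(COUNT_BUCKETS %in% names(bucket_marginal))) {
    stop("bucket_marginal must be named over: ", paste(COUNT_BUCKETS, collapse = ", "))
  }
  bucket_marginal <- bucket_marginal[COUNT_BUCKETS]
  if (abs(sum(bucket_marginal) - 1) > 1e-9 || any(bucket_marginal < 0)) {
    stop("bucket_marginal must be non-negative and sum to 1")
  }
  if (abs(sum(w$weight) - 1) > 1e-9) stop("demographic weights must sum to 1")
  out <- w[rep(seq_len(nrow(w)), each = length(COUNT_BUCKETS)),
           c("sex", "race_ethnicity", "age_group"), drop = FALSE]
  out$count_bucket <- rep(COUNT_BUCKETS, nrow(w))
  out$weight <- rep(w$weight, each = length(COUNT_BUCKETS)) * rep(unname(bucket_marginal), nrow(w))
  out <- out[out$weight > 0, , drop = FALSE]
  n <- attr(demographic_weights, "n")
  new_stratum_weights(out, mode = "joint", n = if (is.null(n)) NA_integer_ else n)
}
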