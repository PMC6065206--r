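#' Run configuration
#'
#' Describes one end-to-end run: where the cohort comes from (CSV directory
#' or simulation parameters -- exactly one of the two), which code sets and
#' reference table to use, which evidence levels and comorbidity modes to
#' run, and where outputs go. Serializable to YAML (JSON accepted too).
#'
#' @param input_dir directory of cohort CSVs (see [read_cohort()]), or
#'   `NULL` when simulating.
#' @param simulation named list of [sim_params()] arguments, or `NULL` when
#'   reading files. When set, the reference table defaults to the
#'   generator's own truth unless `reference_table` is given.
#' @param observation_year calendar year (required with `input_dir`).
#' @param code_sets_path optional YAML of code sets ([read_code_sets()]);
#'   defaults to the built-in [code_sets()].
#' @param reference_table_path,reference_buckets_path reference-table CSVs
#'   ([read_reference_table()]); required with `input_dir`.
#' @param levels evidence levels to run.
#' @param comorbidity_modes `"org_specific"`, `"reference"`, or both.
#' @param ci_method `"propagate"` or `"wald"`.
#' @param output_dir where [run_pipeline()] writes its artifacts.
#' @param seed integer seed (overrides `simulation$seed` when both given).
#' @return Object of class `run_config`.
#' @export
run_config <- function(input_dir = NULL, simulation = NULL,
                       observation_year = NULL, code_sets_path = NULL,
                       reference_table_path = NULL, reference_buckets_path = NULL,
                       levels = EVIDENCE_LEVELS,
                       comorbidity_modes = c("org_specific", "reference"),
                       ci_method = "propagate",
                       output_dir = "htngap_output", seed = 1L) {
  if (is.null(input_dir) == is.null(simulation)) {
    stop("exactly one of input_dir and simulation must be set")
  }
  if (!is.null(input_dir) && is.null(observation_year)) {
    stop("observation_year is required when reading cohort files")
  }
  if (!is.null(input_dir) && is.null(reference_table_path)) {
    stop("reference_table_path is required when reading cohort files")
  }
  structure(list(input_dir = input_dir, simulation = simulation,
                 observation_year = observation_year,
                 code_sets_path = code_sets_path,
                 reference_table_path = reference_table_path,
                 reference_buckets_path = reference_buckets_path,
                 levels = match.arg(levels, EVIDENCE_LEVELS, several.ok = TRUE),
                 comorbidity_modes = match.arg(comorbidity_modes,
                                               c("org_specific", "reference"),
                                               several.ok = TRUE),
                 ci_method = match.arg(ci_method, c("propagate", "wald")),
                 output_dir = output_dir, seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from YAML (or JSON)
#'
#' @param path configuration file; parsed with [yaml::read_yaml()], which
#'   also accepts JSON.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw[intersect(names(raw), names(formals(run_config)))])
}

#' Write a documented template configuration
#'
#' The `config init` starting point: a simulation-driven run with every
#' default spelled out.
#'
#' @param path file to write.
#' @return `path`, invisibly.
#' @export
write_config_template <- function(path = "htngap_config.yaml") {
  template <- list(
    simulation = list(n_patients = 20000L, org_count = 25L, seed = 1L),
    observation_year = 2016L,
    levels = EVIDENCE_LEVELS,
    comorbidity_modes = c("org_specific", "reference"),
    ci_method = "propagate",
    output_dir = "htngap_output",
    seed = 1L)
  yaml::write_yaml(template, path)
  invisible(path)
}

stage <- function(fmt, ...) message(sprintf(paste0("[htngap] ", fmt), ...))

#' Run the full pipeline from a configuration
#'
#' Generate-or-load cohort, ascertain, estimate, compare, render: writes
#' `ascertainment.csv`, `gap_report.csv`, `table_overall.md`,
#' `table_by_org.md`, `demographics.csv`, `bp_screening.csv` and
#' `manifest.json` (resolved configuration, seed, package version) into the
#' output directory. Deterministic given configuration and seed: two runs
#' produce byte-identical files.
#'
#' @param config a [run_config()] or the path of a YAML/JSON configuration.
#' @return The fitted [htn_gap()] object, invisibly, with attribute
#'   `paths` naming the files written.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  cs <- if (is.null(config$code_sets_path)) code_sets() else read_code_sets(config$code_sets_path)

  if (!is.null(config$simulation)) {
    sim_args <- config$simulation
    sim_args$seed <- config$seed
    if (!is.null(config$observation_year)) sim_args$observation_year <- config$observation_year
    params <- do.call(sim_params, sim_args)
    stage("simulating cohort: %d patients, %d organization(s), seed %d",
          params$n_patients, params$org_count, params$seed)
    sim <- generate_cohort(params)
    x <- sim$cohort
    reference <- if (is.null(config$reference_table_path)) {
      generate_reference_table(params)
    } else {
      read_reference_table(config$reference_table_path, config$reference_buckets_path)
    }
  } else {
    stage("reading cohort from %s", config$input_dir)
    x <- read_cohort(config$input_dir, config$observation_year)
    reference <- read_reference_table(config$reference_table_path,
                                      config$reference_buckets_path)
  }
  eligible <- eligible_patients(x)
  stage("eligibility: %d of %d patients (18-85, in-year ambulatory E&M visit)",
        length(eligible), nrow(x$patients))

  fit <- htn_gap(x, reference, cs, config$levels, config$comorbidity_modes,
                 config$ci_method)
  stage("ascertained %d patients; observed prevalence %s",
        nrow(fit$ascertainment),
        paste(sprintf("%s %.1f%%",
                      fit$gaps$level[fit$gaps$org_id == "overall" &
                                       fit$gaps$comorbidity_mode == config$comorbidity_modes[1]],
                      fit$gaps$observed_pct[fit$gaps$org_id == "overall" &
                                              fit$gaps$comorbidity_mode == config$comorbidity_modes[1]]),
              collapse = ", "))

  out <- config$output_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  paths <- c(
    ascertainment = write_ascertainment(fit$ascertainment, file.path(out, "ascertainment.csv")),
    gap_report = write_gap_report(fit$gaps, file.path(out, "gap_report.csv")),
    table_overall = {
      writeLines(render_overall_table(fit$gaps), file.path(out, "table_overall.md"))
      file.path(out, "table_overall.md")
    },
    table_by_org = {
      writeLines(render_org_table(fit$gaps), file.path(out, "table_by_org.md"))
      file.path(out, "table_by_org.md")
    },
    demographics = {
      utils::write.csv(fit$demographics, file.path(out, "demographics.csv"),
                       row.names = FALSE, quote = FALSE)
      file.path(out, "demographics.csv")
    },
    bp_screening = {
      bp <- data.frame(org_id = c("overall", names(fit$bp_gap$by_org)),
                       no_bp_fraction = c(fit$bp_gap$overall, unname(fit$bp_gap$by_org)),
                       stringsAsFactors = FALSE)
      utils::write.csv(bp, file.path(out, "bp_screening.csv"), row.names = FALSE, quote = FALSE)
      file.path(out, "bp_screening.csv")
    },
    manifest = {
      manifest <- list(package = "htngap",
                       version = as.character(utils::packageVersion("htngap")),
                       seed = config$seed,
                       config = unclass(config))
      jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                           auto_unbox = TRUE, pretty = TRUE, null = "null")
      file.path(out, "manifest.json")
    })
  stage("wrote %d artifact(s) to %s", length(paths), out)
  attr(fit, "paths") <- paths
  invisible(fit)
}

md_row <- function(cells) paste0("| ", paste(cells, collapse = " | "), " |")

level_label <- c(claims_only = "Claims",
                 plus_problem_list = "Claims or problem list",
                 plus_clinical = "Claims + problem list + clinical")

#' Render gap results as Markdown tables
#'
#' `render_overall_table()` lays the overall rows out with one column per
#' evidence level (claims, then claims-or-problem-list, then all data) and
#' one block per comorbidity mode; `render_org_table()` gives one row per
#' organization with observed/predicted pairs per level. Percentages are
#' printed to one decimal, patient counts to the nearest thousand.
#'
#' @param gaps gap table from [htn_gap()] or [per_org_gaps()].
#' @return Character vector of Markdown lines.
#' @export
render_overall_table <- function(gaps) {
  g <- gaps[gaps$org_id == "overall", , drop = FALSE]
  if (nrow(g) == 0) stop("no overall rows to render")
  lvls <- intersect(EVIDENCE_LEVELS, unique(g$level))
  lines <- c(md_row(c("Prevalence", level_label[lvls])),
             md_row(rep("---", length(lvls) + 1L)))
  pick <- function(mode, col, fmt) {
    vapply(lvls, function(lv) {
      r <- g[g$level == lv & g$comorbidity_mode == mode, , drop = FALSE]
      if (nrow(r) == 0) "" else sprintf(fmt, r[[col]][1])
    }, character(1))
  }
  obs_mode <- unique(g$comorbidity_mode)[1]
  lines <- c(lines, md_row(c("Observed, %", pick(obs_mode, "observed_pct", "%.1f"))))
  for (mode in intersect(c("org_specific", "reference"), unique(g$comorbidity_mode))) {
    tag <- if (mode == "org_specific") "organization-specific comorbidity data"
           else "reference comorbidity estimates"
    pred <- vapply(lvls, function(lv) {
      r <- g[g$level == lv & g$comorbidity_mode == mode, , drop = FALSE]
      if (nrow(r) == 0) "" else sprintf("%.1f (%.1f-%.1f)", r$predicted_pct[1],
                                        r$predicted_ci_low[1], r$predicted_ci_high[1])
    }, character(1))
    diff <- vapply(lvls, function(lv) {
      r <- g[g$level == lv & g$comorbidity_mode == mode, , drop = FALSE]
      if (nrow(r) == 0) "" else sprintf("%.1f (%.1f-%.1f)", r$diff_pp[1],
                                        r$diff_ci_low[1], r$diff_ci_high[1])
    }, character(1))
    lines <- c(lines,
               md_row(c(sprintf("Predicted using %s, %% (95%% CI)", tag), pred)),
               md_row(c("Percentage point difference (95% CI)", diff)),
               md_row(c("No. of additional patients identified",
                        pick(mode, "additional_patients", "%d"))))
  }
  lines
}

#' @rdname render_overall_table
#' @export
render_org_table <- function(gaps) {
  g <- gaps[gaps$org_id != "overall" & gaps$comorbidity_mode == gaps$comorbidity_mode[1], ,
            drop = FALSE]
  if (nrow(g) == 0) return(character(0))
  lvls <- intersect(EVIDENCE_LEVELS, unique(g$level))
  header <- c("Organization",
              as.vector(rbind(paste(level_label[lvls], "observed"),
                              paste(level_label[lvls], "predicted"))))
  lines <- c(md_row(header), md_row(rep("---", length(header))))
  # organizations ordered by descending claims-level observed prevalence
  first <- lvls[1]
  ord <- g[g$level == first, c("org_id", "observed_pct")]
  ord <- ord$org_id[order(-ord$observed_pct)]
  for (org in ord) {
    cells <- org
    for (lv in lvls) {
      r <- g[g$org_id == org & g$level == lv, , drop = FALSE]
      cells <- c(cells, sprintf("%.1f%%", r$observed_pct[1]), sprintf("%.1f%%", r$predicted_pct[1]))
    }
    lines <- c(lines, md_row(cells))
  }
  lines
}
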