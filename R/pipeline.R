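#' Configuration for an end-to-end pipeline run
#'
#' Exactly one input source must be given: `input_dir` (a directory of
#' claims CSVs, see [read_bundle()]) or `simulation` (a [sim_config()]; its
#' seed is overridden by the pipeline `seed` so one seed drives the run).
#'
#' @param input_dir Directory with an existing claims bundle, or `NULL`.
#' @param simulation A [sim_config()], or `NULL`.
#' @param cohort A [cohort_criteria()].
#' @param prevalence_window_days Baseline window in days.
#' @param conditions Condition labels for prevalence (`NULL` = vocabulary
#'   default).
#' @param gap_days Persistence gap for era construction.
#' @param session_persistence_days Per-visit persistence for procedures.
#' @param default_days_supply Imputation for missing days' supply.
#' @param capture_lead_days,followup_days,overlap_days,max_lines Pathway
#'   parameters; see [assign_lines()] and [aggregate_pathways()].
#' @param out_dir Output directory for report files.
#' @param seed Integer seed driving all randomness of the run.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(input_dir = NULL, simulation = NULL,
                            cohort = cohort_criteria(),
                            prevalence_window_days = 180L,
                            conditions = NULL,
                            gap_days = 30L,
                            session_persistence_days = 30L,
                            default_days_supply = 30L,
                            capture_lead_days = 30L,
                            followup_days = 1095L,
                            overlap_days = 30L,
                            max_lines = 4L,
                            out_dir = tempfile("txp_out_"),
                            seed = 1L) {
  if (is.null(input_dir) == is.null(simulation)) {
    abort_config("exactly one of `input_dir` or `simulation` must be supplied",
                 field = "input_dir")
  }
  if (!is.null(simulation)) validate_sim_config(simulation)
  if (!inherits(cohort, "cohort_criteria")) {
    abort_config("`cohort` must be a cohort_criteria() object", field = "cohort")
  }
  if (!is_count(seed)) abort_config("`seed` must be a single integer", field = "seed")
  structure(list(
    input_dir = input_dir, simulation = simulation, cohort = cohort,
    prevalence_window_days = as.integer(prevalence_window_days),
    conditions = conditions,
    gap_days = as.integer(gap_days),
    session_persistence_days = as.integer(session_persistence_days),
    default_days_supply = as.integer(default_days_supply),
    capture_lead_days = as.integer(capture_lead_days),
    followup_days = as.integer(followup_days),
    overlap_days = as.integer(overlap_days),
    max_lines = as.integer(max_lines),
    out_dir = out_dir, seed = as.integer(seed)),
    class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the [pipeline_config()] arguments; the `simulation:`
#' and `cohort:` sections take the [sim_config()] / [cohort_criteria()]
#' argument names. Unknown keys raise a configuration error.
#'
#' @param path YAML file path.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort_parse(sprintf("missing config file: %s", path),
                                      file = path)
  y <- yaml::read_yaml(path)
  known <- c("input_dir", "simulation", "cohort", "prevalence_window_days",
             "conditions", "gap_days", "session_persistence_days",
             "default_days_supply", "capture_lead_days", "followup_days",
             "overlap_days", "max_lines", "out_dir", "seed")
  unknown <- setdiff(names(y), known)
  if (length(unknown)) {
    abort_config(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  if (!is.null(y$simulation)) {
    y$simulation <- do.call(sim_config, y$simulation)
  }
  if (!is.null(y$cohort)) {
    y$cohort <- do.call(cohort_criteria, y$cohort)
  }
  do.call(pipeline_config, y)
}

#' Run the full claims pathway pipeline
#'
#' Generates or reads the claims bundle, builds the incident cohort,
#' computes demographics and baseline prevalence, constructs treatment eras
#' and lines, aggregates the pathway tree, and writes all report files to
#' `config$out_dir`: `cohort.csv`, `demographics.csv`, `prevalence.csv`,
#' `eras.csv`, `lines.csv`, `pathway_tree.json`, `line_marginals.csv`,
#' `regimen_table.csv`, `utilization.csv`, `run_log.txt`. Percentages are
#' rounded to 2 decimals in CSVs; the JSON keeps full precision. Given the
#' same configuration and seed the output files are byte-identical across
#' runs.
#'
#' An empty cohort is not an error at the R level: the function writes a
#' log, warns, and returns with `ok = FALSE` so script wrappers can exit
#' nonzero.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with `ok`, `bundle`, `cohort`, `demographics`,
#'   `prevalence`, `eras`, `lines`, `tree`, `marginals`, `regimens`,
#'   `utilization`, `out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  bundle <- if (!is.null(config$simulation)) {
    sim <- config$simulation
    sim$seed <- config$seed
    generate_claims(sim)
  } else {
    read_bundle(config$input_dir)
  }

  cohort <- build_cohort(bundle, config$cohort)
  attrition <- attr(cohort, "attrition")
  log_lines <- c(
    "txpathways run log",
    sprintf("seed: %d", config$seed),
    sprintf("input: %s",
            if (is.null(config$simulation)) config$input_dir
            else sprintf("simulated (n_patients=%d)", config$simulation$n_patients)),
    sprintf("parameters: gap_days=%d session_persistence_days=%d overlap_days=%d",
            config$gap_days, config$session_persistence_days, config$overlap_days),
    sprintf("            capture_lead_days=%d followup_days=%d max_lines=%d",
            config$capture_lead_days, config$followup_days, config$max_lines),
    sprintf("            prevalence_window_days=%d", config$prevalence_window_days),
    "exclusions:",
    sprintf("  %-28s %d", names(attrition), attrition),
    sprintf("cohort size: %d", nrow(cohort)))

  if (nrow(cohort) == 0) {
    writeLines(c(log_lines, "status: EMPTY COHORT"),
               file.path(config$out_dir, "run_log.txt"))
    warning("pipeline produced an empty cohort; no reports written")
    return(invisible(list(ok = FALSE, reason = "empty cohort", bundle = bundle,
                          cohort = cohort, out_dir = config$out_dir)))
  }

  demographics <- demographic_summary(cohort)
  prevalence <- baseline_prevalence(bundle, cohort,
                                    window_days = config$prevalence_window_days,
                                    conditions = config$conditions)
  eras <- build_all_eras(bundle, gap_days = config$gap_days,
                         session_persistence_days = config$session_persistence_days,
                         default_days_supply = config$default_days_supply)
  lines <- build_treatment_lines(eras, cohort,
                                 capture_lead_days = config$capture_lead_days,
                                 followup_days = config$followup_days,
                                 overlap_days = config$overlap_days,
                                 max_lines = Inf)
  tree <- aggregate_pathways(lines, cohort, max_lines = config$max_lines)
  marginals <- line_marginals(lines, max_lines = config$max_lines)
  regimens <- regimen_summary(lines, max_lines = config$max_lines)
  util <- treated_fraction(lines, cohort)

  out <- config$out_dir
  readr::write_csv(cohort, file.path(out, "cohort.csv"), na = "")
  readr::write_csv(round_pct(demographics, "pct"),
                   file.path(out, "demographics.csv"), na = "")
  prev_out <- prevalence
  prev_out$pct <- round(100 * prev_out$proportion, 2)
  readr::write_csv(prev_out[c("condition", "stratum_type", "stratum",
                              "n_patients", "denominator", "pct")],
                   file.path(out, "prevalence.csv"), na = "")
  readr::write_csv(eras, file.path(out, "eras.csv"), na = "")
  lines_out <- lines[c("person_id", "line_number", "regimen", "line_start",
                       "line_end")]
  readr::write_csv(lines_out, file.path(out, "lines.csv"), na = "")
  write_pathway_json(tree, file.path(out, "pathway_tree.json"))
  readr::write_csv(round_pct(marginals, "pct_of_treated"),
                   file.path(out, "line_marginals.csv"), na = "")
  readr::write_csv(round_pct(regimens, "pct_of_line"),
                   file.path(out, "regimen_table.csv"), na = "")
  readr::write_csv(round_pct(util$utilization, "pct"),
                   file.path(out, "utilization.csv"), na = "")
  comb <- attr(regimens, "combination_summary")
  comb1 <- comb$pct_combination[comb$line == 1]
  log_lines <- c(
    log_lines,
    sprintf("treated patients: %d (%.2f%%)", util$n_treated,
            100 * util$treated_fraction),
    sprintf("combination therapy, line 1: %.2f%%",
            if (length(comb1)) comb1 else NA_real_),
    "status: OK")
  writeLines(log_lines, file.path(out, "run_log.txt"))

  invisible(list(ok = TRUE, bundle = bundle, cohort = cohort,
                 demographics = demographics, prevalence = prevalence,
                 eras = eras, lines = lines, tree = tree,
                 marginals = marginals, regimens = regimens,
                 utilization = util, out_dir = out))
}

round_pct <- function(df, col) {
  df[[col]] <- round(df[[col]], 2)
  df
}
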