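#' Write a procedure log to delimited text
#'
#' Comma-separated UTF-8 with a header row; one row per monitored procedure.
#'
#' @param procedures A procedure data frame (e.g. `cohort$procedures`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_procedure_log <- function(procedures, path) {
  if (!is.data.frame(procedures))
    abort_validation("procedures", "must be a data frame")
  utils::write.csv(procedures, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

LOG_MANDATORY <- c("learner_id", "procedure_index", "competency_level", "passed")

#' Read and validate a procedure log
#'
#' Validates the mandatory schema (`learner_id`, `procedure_index`,
#' `competency_level` in 0/1/2, `passed` in 0/1); optional metric columns are
#' passed through. Row-level problems are collected and reported together
#' with their file line numbers (header = line 1).
#'
#' @param path Path to a comma-separated log with a header row.
#' @return A validated data frame.
#' @export
read_procedure_log <- function(path) {
  if (!file.exists(path)) abort_validation("path", sprintf("file not found: %s", path))
  df <- utils::read.csv(path, fileEncoding = "UTF-8")
  missing_cols <- setdiff(LOG_MANDATORY, names(df))
  if (length(missing_cols))
    abort_validation("path", paste("missing mandatory column(s):",
                                   paste(missing_cols, collapse = ", ")))
  if (!nrow(df)) return(df)

  problems <- character(0)
  line <- function(i) i + 1L  # header occupies line 1
  bad_level <- which(!(df$competency_level %in% c(0L, 1L, 2L)))
  for (i in bad_level)
    problems <- c(problems, sprintf("line %d: competency_level must be 0, 1 or 2 (got %s)",
                                    line(i), df$competency_level[i]))
  bad_pass <- which(!(df$passed %in% c(0L, 1L)))
  for (i in bad_pass)
    problems <- c(problems, sprintf("line %d: passed must be 0 or 1 (got %s)",
                                    line(i), df$passed[i]))
  bad_idx <- which(is.na(df$procedure_index) | df$procedure_index < 1 |
                     df$procedure_index != round(df$procedure_index))
  for (i in bad_idx)
    problems <- c(problems, sprintf("line %d: procedure_index must be a positive integer",
                                    line(i)))
  if (length(problems))
    abort_validation("path", paste(c("invalid rows:", problems), collapse = "\n  "))
  df
}

#' Export chart trajectories for replotting
#'
#' One row per (learner, procedure) with the absolute program score (0 to
#' the program target, e.g. 39), sufficient to redraw the learning-curve
#' charts.
#'
#' @param x An `lc_cohort`, a procedure data frame with a `score` column, or
#'   a single `lc_program_result`.
#' @param path Output file path (comma-separated, header row).
#' @return `path`, invisibly.
#' @export
export_trajectories <- function(x, path) {
  if (inherits(x, "lc_cohort")) x <- x$procedures
  if (inherits(x, "lc_program_result")) {
    lvls <- rep(seq_along(x$per_level_traces) - 1L,
                lengths(x$per_level_traces))
    x <- data.frame(learner_id = 1L,
                    competency_level = lvls,
                    procedure_index = seq_along(lvls),
                    score = unlist(x$per_level_traces))
  }
  if (!is.data.frame(x) ||
      !all(c("learner_id", "competency_level", "procedure_index", "score") %in% names(x)))
    abort_validation("x", "needs columns learner_id, competency_level, procedure_index, score")
  if (!nrow(x)) abort_validation("x", "no trajectories to export")
  out <- x[c("learner_id", "competency_level", "procedure_index", "score")]
  names(out)[2] <- "level"
  utils::write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Configure an end-to-end pipeline run
#'
#' @param output_dir Directory for all artifacts (created if absent).
#' @param seed Integer seed; mandatory.
#' @param cohort A [cohort_config()]; its seed is taken from `seed`.
#'   Defaults to the standard 32-learner mixture.
#' @param monitoring An [lc_design()] recorded alongside the integer program
#'   design in the manifest.
#' @param ruleset_path Optional path to a YAML rule set; default rules
#'   otherwise.
#' @param include_metrics Generate per-procedure metrics (default `TRUE`).
#' @param verbose Log stage-level progress with counts (default `TRUE`).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(output_dir, seed,
                            cohort = NULL,
                            monitoring = lc_design(),
                            ruleset_path = NULL,
                            include_metrics = TRUE,
                            verbose = TRUE) {
  if (!is.character(output_dir) || length(output_dir) != 1L)
    abort_validation("output_dir", "must be a single path")
  if (missing(seed) || !is_number(seed)) abort_validation("seed", "an integer seed is required")
  if (is.null(cohort)) cohort <- cohort_config(seed = seed)
  if (!inherits(cohort, "cohort_config"))
    abort_validation("cohort", "must be a cohort_config")
  cohort$seed <- as.integer(seed)
  if (!inherits(monitoring, "lc_design"))
    abort_validation("monitoring", "must be an lc_design")
  if (!is.null(ruleset_path) && !file.exists(ruleset_path))
    abort_validation("ruleset_path", sprintf("file not found: %s", ruleset_path))
  structure(list(output_dir = output_dir, seed = as.integer(seed),
                 cohort = cohort, monitoring = monitoring,
                 ruleset_path = ruleset_path,
                 include_metrics = check_flag(include_metrics, "include_metrics"),
                 verbose = check_flag(verbose, "verbose")),
            class = "pipeline_config")
}

pipeline_stage <- function(name, verbose, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage `%s` failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full simulate -> assess -> chart -> diagnostics pipeline
#'
#' Simulates a cohort, writes the procedure log, the trajectory export, the
#' learner summary, the diagnostic analysis of the pass/fail-by-career table
#' (skipped with a note when a margin is empty, e.g. a flawless cohort), and
#' a run manifest recording the configuration, its MD5 hash and the seed.
#'
#' @param config A [pipeline_config()].
#' @return A result bundle (list) with the cohort, the contingency table
#'   (or `NULL`), the diagnostic summary (or `NULL`), test p-values, and the
#'   paths of all written files.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config"))
    abort_validation("config", "must be a pipeline_config")
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (config$verbose) message(sprintf(...))
  ruleset <- if (is.null(config$ruleset_path)) default_ruleset()
             else pipeline_stage("load_ruleset", config$verbose,
                                 load_ruleset(config$ruleset_path))

  cohort <- pipeline_stage("simulate_cohort", config$verbose,
                           simulate_cohort(config$cohort,
                                           include_metrics = config$include_metrics,
                                           ruleset = ruleset))
  say("simulate_cohort: %d learners, %d procedures, %d program passes",
      nrow(cohort$learners), nrow(cohort$procedures),
      sum(cohort$learners$passed_program))

  paths <- list(
    procedure_log = file.path(config$output_dir, "procedure_log.csv"),
    trajectories = file.path(config$output_dir, "trajectories.csv"),
    learners = file.path(config$output_dir, "learners.csv"),
    diagnostics = file.path(config$output_dir, "diagnostics.csv"),
    manifest = file.path(config$output_dir, "manifest.yaml"),
    config = file.path(config$output_dir, "config.yaml")
  )

  pipeline_stage("write_outputs", config$verbose, {
    write_procedure_log(cohort$procedures, paths$procedure_log)
    export_trajectories(cohort, paths$trajectories)
    utils::write.csv(cohort$learners, paths$learners, row.names = FALSE,
                     fileEncoding = "UTF-8")
    # self-consistency: the log must re-validate through the same reader
    invisible(read_procedure_log(paths$procedure_log))
  })
  say("write_outputs: %s", config$output_dir)

  tab <- contingency_from_cohort(cohort)
  diag <- NULL
  fisher_p <- NA_real_
  chisq <- list(statistic = NA_real_, p_value = NA_real_)
  diag_note <- "ok"
  d <- tryCatch(diagnostic_measures(tab), error = function(e) e)
  if (inherits(d, "lccusum_undefined_measure_error")) {
    diag_note <- conditionMessage(d)
    say("diagnostics: skipped (%s)", diag_note)
  } else if (inherits(d, "error")) {
    stop(sprintf("pipeline stage `diagnostics` failed: %s", conditionMessage(d)),
         call. = FALSE)
  } else {
    diag <- d
    m <- as.matrix(tab)
    if (all(rowSums(m) > 0) && all(colSums(m) > 0)) {
      fisher_p <- fisher_exact(tab)
      chisq <- chi_square(tab)
    } else {
      diag_note <- "degenerate margins: association tests skipped"
    }
    utils::write.csv(as.data.frame(diag), paths$diagnostics, row.names = FALSE,
                     fileEncoding = "UTF-8")
    say("diagnostics: ppv %.3f, fisher p %.4f", diag$estimate[1], fisher_p)
  }

  cfg_record <- list(
    seed = config$seed,
    n_learners = config$cohort$n_learners,
    profiles = lapply(config$cohort$profiles, function(p) p[names(p) != "label"]),
    weights = config$cohort$weights,
    program_design = unclass(config$cohort$design),
    monitoring_design = unclass(config$monitoring),
    ruleset = if (is.null(config$ruleset_path)) "default" else config$ruleset_path,
    include_metrics = config$include_metrics
  )
  yaml::write_yaml(cfg_record, paths$config)
  manifest <- list(
    package = "lccusum",
    version = as.character(utils::packageVersion("lccusum")),
    seed = config$seed,
    config_md5 = unname(tools::md5sum(paths$config)),
    counts = list(
      learners = nrow(cohort$learners),
      procedures = nrow(cohort$procedures),
      program_passes = sum(cohort$learners$passed_program),
      program_minimum_procedures = config$cohort$design$program_target
    ),
    diagnostics_note = diag_note,
    outputs = lapply(paths[c("procedure_log", "trajectories", "learners", "diagnostics")],
                     basename)
  )
  yaml::write_yaml(manifest, paths$manifest)
  say("manifest: %s", paths$manifest)

  invisible(list(cohort = cohort, table = tab, diagnostics = diag,
                 fisher_p = fisher_p, chi_square = chisq,
                 manifest = manifest, paths = paths))
}
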