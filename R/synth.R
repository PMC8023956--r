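#' @name learner-synthesis
#' @title Synthetic learner cohorts
#'
#' @description
#' Generates learner cohorts with the statistical structure the downstream
#' analysis assumes, so charts, operating characteristics and cohort
#' diagnostics can all be exercised without real training data. A learner's
#' per-procedure failure probability follows an exponential-decay learning
#' curve `p(t) = asymptotic + (initial - asymptotic) * exp(-t / tau)` over
#' cumulative procedure count `t`; outcomes are independent Bernoulli draws.
#' Procedure metrics are sampled constructively so that re-assessing them
#' with the rule engine reproduces the drawn verdict exactly. A binary
#' career outcome (still in the specialty at follow-up) is drawn conditional
#' only on the program pass/fail verdict.
NULL

#' Define a learner archetype
#'
#' @param label Short name for the archetype.
#' @param initial_failure_prob Failure probability on the first procedure.
#' @param asymptotic_failure_prob Long-run failure probability (must not
#'   exceed the initial probability).
#' @param learning_time_constant Decay constant `tau` in procedures (> 0).
#' @param persistence Maximum procedures the learner will attempt across the
#'   whole program before quitting.
#' @param career_stay_prob_if_pass,career_stay_prob_if_fail Probability of
#'   still working in the specialty at follow-up, conditional on the program
#'   verdict. Defaults 13/14 and 9/18, the structure of the observed cohort.
#' @return A list of class `learner_profile`.
#' @export
learner_profile <- function(label,
                            initial_failure_prob,
                            asymptotic_failure_prob,
                            learning_time_constant,
                            persistence = 150L,
                            career_stay_prob_if_pass = 13 / 14,
                            career_stay_prob_if_fail = 9 / 18) {
  if (!is.character(label) || length(label) != 1L)
    abort_validation("label", "must be a single string")
  check_prob(initial_failure_prob, "initial_failure_prob")
  check_prob(asymptotic_failure_prob, "asymptotic_failure_prob")
  if (asymptotic_failure_prob > initial_failure_prob)
    abort_validation("asymptotic_failure_prob", "must not exceed initial_failure_prob")
  if (!is_number(learning_time_constant) || learning_time_constant <= 0)
    abort_validation("learning_time_constant", "must be > 0 procedures")
  persistence <- check_count(persistence, "persistence")
  check_prob(career_stay_prob_if_pass, "career_stay_prob_if_pass")
  check_prob(career_stay_prob_if_fail, "career_stay_prob_if_fail")

  structure(list(
    label = label,
    initial_failure_prob = initial_failure_prob,
    asymptotic_failure_prob = asymptotic_failure_prob,
    learning_time_constant = learning_time_constant,
    persistence = persistence,
    career_stay_prob_if_pass = career_stay_prob_if_pass,
    career_stay_prob_if_fail = career_stay_prob_if_fail
  ), class = "learner_profile")
}

failure_curve <- function(profile, t) {
  profile$asymptotic_failure_prob +
    (profile$initial_failure_prob - profile$asymptotic_failure_prob) *
    exp(-t / profile$learning_time_constant)
}

#' Default cohort archetypes
#'
#' Two archetypes in equal proportion: a `persistent` learner who improves
#' quickly to a low asymptotic failure rate and keeps training, and a
#' `non_persistent` learner who improves slowly toward a failure rate above
#' the unacceptable level and stops training early (not returning for later
#' sessions is modelled as a hard procedure budget).
#'
#' @return A list of two [learner_profile()] objects.
#' @export
default_cohort_profiles <- function() {
  list(
    persistent = learner_profile("persistent",
                                 initial_failure_prob = 0.45,
                                 asymptotic_failure_prob = 0.04,
                                 learning_time_constant = 12,
                                 persistence = 150L),
    non_persistent = learner_profile("non_persistent",
                                     initial_failure_prob = 0.65,
                                     asymptotic_failure_prob = 0.20,
                                     learning_time_constant = 35,
                                     persistence = 60L)
  )
}

#' Cohort generation configuration
#'
#' @param n_learners Number of learners (default 32).
#' @param profiles List of [learner_profile()] objects.
#' @param weights Mixture weights (positive, summing to 1).
#' @param design An [lc_program_design()] governing the monitored program.
#' @param seed Integer seed; mandatory.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_learners = 32L,
                          profiles = default_cohort_profiles(),
                          weights = rep(1 / length(profiles), length(profiles)),
                          design = lc_program_design(),
                          seed) {
  n_learners <- check_count(n_learners, "n_learners")
  if (!is.list(profiles) || !length(profiles) ||
      !all(vapply(profiles, inherits, logical(1), "learner_profile")))
    abort_validation("profiles", "must be a non-empty list of learner_profile objects")
  if (!is.numeric(weights) || length(weights) != length(profiles) ||
      any(weights <= 0) || abs(sum(weights) - 1) > 1e-8)
    abort_validation("weights", "must be positive and sum to 1, one per profile")
  if (!inherits(design, "lc_program_design"))
    abort_validation("design", "must be an lc_program_design")
  if (missing(seed) || !is_number(seed)) abort_validation("seed", "an integer seed is required")

  structure(list(n_learners = n_learners, profiles = profiles,
                 weights = weights, design = design, seed = as.integer(seed)),
            class = "cohort_config")
}

#' Simulate a pass/fail outcome sequence for one learner
#'
#' Draws `n` independent Bernoulli outcomes whose failure probability follows
#' the profile's exponential-decay learning curve over procedure index
#' `t = 1..n`.
#'
#' @param profile A [learner_profile()].
#' @param n Number of procedures.
#' @param seed Integer seed; mandatory.
#' @return A logical vector (`TRUE` = passed).
#' @examples
#' p <- learner_profile("demo", 0.5, 0.05, 10)
#' simulate_outcomes(p, 20, seed = 1)
#' @export
simulate_outcomes <- function(profile, n, seed) {
  if (!inherits(profile, "learner_profile"))
    abort_validation("profile", "must be a learner_profile")
  n <- check_count(n, "n")
  if (!is_number(seed)) abort_validation("seed", "an integer seed is required")
  withr::with_seed(seed, {
    p_fail <- failure_curve(profile, seq_len(n))
    stats::runif(n) >= p_fail
  })
}

# Default metric-generation parameters, loosely matched to observed
# performance summaries (per-level times / fluoroscopy / radiographs; TAD
# centred near 13 mm among passing procedures).
metric_gen_params <- function() {
  list(
    tad_mean = 13, tad_sd = 2,
    time_mean = c(66, 77, 206), time_sd = c(15, 15, 35),
    fluoro_mean = c(9, 13, 31), fluoro_sd = c(4, 6, 12),
    radio_mean = c(21, 22, 36),
    drill_mean = 6.5, drill_sd = 1.5
  )
}

draw_common <- function(level, gp) {
  lv <- level + 1L
  list(
    fluoroscopy_time = max(0, stats::rnorm(1, gp$fluoro_mean[lv], gp$fluoro_sd[lv])),
    radiograph_count = stats::rpois(1, gp$radio_mean[lv]),
    total_time = max(1, stats::rnorm(1, gp$time_mean[lv], gp$time_sd[lv]))
  )
}

draw_passing <- function(level, gp) {
  tad <- stats::rnorm(1, gp$tad_mean, gp$tad_sd)
  tad <- min(max(tad, 2), 20)
  zone <- sample(PASSING_ZONES, 1L, prob = c(0.7, 0.3))
  attempts <- sample(1:3, 1L, prob = c(0.7, 0.25, 0.05))
  com <- draw_common(level, gp)
  if (level == 2L) {
    dhs_metrics(tad, zone, FALSE, attempts,
                reamer_breach = FALSE, plate_angle_appropriate = TRUE,
                shaft_screw_bicortical = TRUE,
                cortical_drill_outside_mm = max(0, stats::rnorm(1, gp$drill_mean, gp$drill_sd)),
                fluoroscopy_time = com$fluoroscopy_time,
                radiograph_count = com$radiograph_count,
                total_time = com$total_time)
  } else {
    wire_metrics(tad, zone, FALSE, attempts,
                 fluoroscopy_time = com$fluoroscopy_time,
                 radiograph_count = com$radiograph_count,
                 total_time = com$total_time)
  }
}

draw_failing <- function(level, gp) {
  n_viol_pool <- if (level == 2L) 7L else 4L
  viol <- which(stats::runif(n_viol_pool) < 0.35)
  if (!length(viol)) viol <- sample.int(n_viol_pool, 1L)
  # pool order: tad, zone, breach, attempts, (reamer, plate, bicortical)
  tad <- if (1L %in% viol) stats::runif(1, 20.5, 35) else
    min(max(stats::rnorm(1, gp$tad_mean, gp$tad_sd), 2), 20)
  zone <- if (2L %in% viol)
    sample(setdiff(PLACEMENT_ZONES, PASSING_ZONES), 1L)
  else sample(PASSING_ZONES, 1L, prob = c(0.7, 0.3))
  breach <- 3L %in% viol
  attempts <- if (4L %in% viol) sample(4:7, 1L) else sample(1:3, 1L, prob = c(0.7, 0.25, 0.05))
  com <- draw_common(level, gp)
  if (level == 2L) {
    dhs_metrics(tad, zone, breach, attempts,
                reamer_breach = 5L %in% viol,
                plate_angle_appropriate = !(6L %in% viol),
                shaft_screw_bicortical = !(7L %in% viol),
                cortical_drill_outside_mm = max(0, stats::rnorm(1, gp$drill_mean, gp$drill_sd)),
                fluoroscopy_time = com$fluoroscopy_time,
                radiograph_count = com$radiograph_count,
                total_time = com$total_time)
  } else {
    wire_metrics(tad, zone, breach, attempts,
                 fluoroscopy_time = com$fluoroscopy_time,
                 radiograph_count = com$radiograph_count,
                 total_time = com$total_time)
  }
}

#' Simulate procedure metrics consistent with a given verdict
#'
#' Samples metrics and re-assesses them with the rule engine until the
#' requested verdict is reproduced (constructive sampling with bounded
#' retries). With the default rule set the first draw almost always agrees;
#' the retry bound exists to surface inconsistent custom rule sets.
#'
#' @param passed Requested verdict.
#' @param level Competency level 0, 1 or 2.
#' @param seed Optional integer seed; if `NULL` the current RNG stream is
#'   used (for calls nested inside an already-seeded simulation).
#' @param ruleset Rule set the metrics must satisfy (or violate).
#' @param max_retries Draw budget before giving up (default 100).
#' @return A [wire_metrics()] (levels 0/1) or [dhs_metrics()] (level 2)
#'   object whose re-assessment equals `passed`.
#' @examples
#' m <- simulate_metrics(TRUE, level = 0, seed = 1)
#' assess_wire(m)$passed  # TRUE
#' @export
simulate_metrics <- function(passed, level, seed = NULL,
                             ruleset = default_ruleset(), max_retries = 100L) {
  passed <- check_flag(passed, "passed")
  level <- check_count(level, "level", min = 0L)
  if (level > 2L) abort_validation("level", "must be 0, 1 or 2")
  draw <- function() {
    gp <- metric_gen_params()
    for (i in seq_len(max_retries)) {
      m <- if (passed) draw_passing(level, gp) else draw_failing(level, gp)
      if (assess_at_level(m, level, ruleset)$passed == passed) return(m)
    }
    abort_generation(sprintf(
      "could not generate metrics with verdict %s at level %d in %d draws; the rule set may be inconsistent with the generator",
      passed, level, max_retries))
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Simulate a full learner cohort through the monitored program
#'
#' Each learner is assigned an archetype by the mixture weights, then works
#' through the competency levels adaptively: within a level, outcomes are
#' drawn from the learning curve (over cumulative procedure count) until the
#' integer chart signals or the per-level cap -- or the learner's persistence
#' budget -- is exhausted. A learner failing a level stops. The career
#' outcome is a Bernoulli draw conditional on the program verdict.
#'
#' @param config A [cohort_config()].
#' @param include_metrics Also draw per-procedure metrics consistent with
#'   each outcome (default `TRUE`; disable for large operating-characteristic
#'   simulations where only the outcomes matter).
#' @param ruleset Rule set used when generating metrics.
#' @return A list of class `lc_cohort`:
#' \describe{
#'   \item{procedures}{data frame with one row per procedure: `learner_id`,
#'     `procedure_index` (cumulative, 1-based), `competency_level`, `passed`
#'     (0/1), `score` (absolute program score after the procedure) and, if
#'     requested, the metric columns.}
#'   \item{learners}{data frame with one row per learner: `learner_id`,
#'     `profile`, `passed_program`, `total_procedures`, `career_stayed`.}
#'   \item{config}{the generating configuration.}
#' }
#' @examples
#' cfg <- cohort_config(n_learners = 4, seed = 42)
#' coh <- simulate_cohort(cfg, include_metrics = FALSE)
#' coh$learners
#' @export
simulate_cohort <- function(config, include_metrics = TRUE,
                            ruleset = default_ruleset()) {
  if (!inherits(config, "cohort_config"))
    abort_validation("config", "must be a cohort_config")
  include_metrics <- check_flag(include_metrics, "include_metrics")
  design <- config$design

  withr::with_seed(config$seed, {
    profile_idx <- sample.int(length(config$profiles), config$n_learners,
                              replace = TRUE, prob = config$weights)
    proc_rows <- vector("list", config$n_learners)
    learner_rows <- vector("list", config$n_learners)

    for (i in seq_len(config$n_learners)) {
      prof <- config$profiles[[profile_idx[i]]]
      t <- 0L
      lvl_v <- integer(0); pass_v <- logical(0); score_v <- numeric(0)
      program_passed <- TRUE
      for (k in seq_len(design$n_levels) - 1L) {
        budget <- min(design$per_level_cap, prof$persistence - t)
        if (budget <= 0L) {
          program_passed <- FALSE
          break
        }
        p_fail <- failure_curve(prof, t + seq_len(budget))
        outs <- stats::runif(budget) >= p_fail
        pars <- chart_params(design, k)
        r <- run_scores(outs, pars$up, pars$down, pars$floor, pars$limit)
        used <- length(r$trajectory)
        lvl_v <- c(lvl_v, rep(k, used))
        pass_v <- c(pass_v, outs[seq_len(used)])
        score_v <- c(score_v, r$trajectory)
        t <- t + used
        if (is.null(r$signal_index)) {
          program_passed <- FALSE
          break
        }
      }
      career <- stats::runif(1) < (if (program_passed) prof$career_stay_prob_if_pass
                                   else prof$career_stay_prob_if_fail)
      proc_rows[[i]] <- data.frame(
        learner_id = rep(i, length(lvl_v)),
        procedure_index = seq_along(lvl_v),
        competency_level = lvl_v,
        passed = as.integer(pass_v),
        score = score_v
      )
      learner_rows[[i]] <- data.frame(
        learner_id = i,
        profile = prof$label,
        passed_program = program_passed,
        total_procedures = length(lvl_v),
        career_stayed = career
      )
    }

    procedures <- do.call(rbind, proc_rows)
    rownames(procedures) <- NULL
    if (include_metrics && nrow(procedures)) {
      mlist <- lapply(seq_len(nrow(procedures)), function(j)
        simulate_metrics(procedures$passed[j] == 1L,
                         procedures$competency_level[j],
                         seed = NULL, ruleset = ruleset))
      for (cn in KNOWN_METRICS) {
        if (cn == "placement_zone") {
          procedures[[cn]] <- vapply(mlist, function(m)
            if (is.null(m[[cn]])) NA_character_ else m[[cn]], character(1))
        } else {
          procedures[[cn]] <- vapply(mlist, function(m)
            if (is.null(m[[cn]])) NA_real_ else as.numeric(m[[cn]]), numeric(1))
        }
      }
    }
    learners <- do.call(rbind, learner_rows)
    rownames(learners) <- NULL

    structure(list(procedures = procedures, learners = learners, config = config),
              class = "lc_cohort")
  })
}

#' @export
print.lc_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d learners, %d procedures; %d/%d passed the program\n",
              nrow(x$learners), nrow(x$procedures),
              sum(x$learners$passed_program), nrow(x$learners)))
  invisible(x)
}
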