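#' Build a continuous LC-CUSUM monitoring design
#'
#' The LC-CUSUM test assumes inadequate performance (the null hypothesis) and
#' signals competency once the accumulated log-likelihood-ratio evidence
#' crosses the in-control limit `h`. The per-procedure score increments are
#' the Bernoulli log-likelihood ratios comparing the acceptable failure rate
#' `p1` against the unacceptable rate `p0 = p1 + delta`:
#' a success adds `log((1 - p1) / (1 - p0))` and a failure adds
#' `log(p1 / p0)` (negative). The running score has a holding barrier at 0.
#'
#' With the defaults (`p1 = 0.10`, `delta = 0.05`, `h = 0.74`) the increments
#' are +0.0572 and -0.4055, so 13 consecutive successful procedures -- and no
#' fewer -- reach the limit.
#'
#' @param acceptable_failure_rate Adequate-performance failure probability
#'   `p1`, strictly in (0, 1). Default 0.10.
#' @param equivalence_delta Width of the equivalence zone `delta` (> 0); the
#'   unacceptable rate is `p1 + delta`. Default 0.05.
#' @param signal_limit In-control limit `h` (> 0) the score must reach to
#'   declare competency. Default 0.74.
#' @param horizon Maximum number of procedures monitored. Default 50.
#' @return An object of class `lc_design`: a list with the two rates, the
#'   derived unacceptable rate, `success_increment`, `failure_increment`
#'   (stored at full floating precision), `signal_limit` and `horizon`.
#' @examples
#' d <- lc_design()
#' round(d$success_increment, 3)   # 0.057
#' round(d$failure_increment, 3)   # -0.405
#' @seealso [lc_program_design()] for the integer-scored multi-level variant,
#'   [run_chart()], [signal_probability_exact()].
#' @export
lc_design <- function(acceptable_failure_rate = 0.10,
                      equivalence_delta = 0.05,
                      signal_limit = 0.74,
                      horizon = 50L) {
  p1 <- check_prob(acceptable_failure_rate, "acceptable_failure_rate", open = TRUE)
  if (!is_number(equivalence_delta) || equivalence_delta <= 0)
    abort_validation("equivalence_delta",
                     "must be > 0 (a zero-width equivalence zone makes both increments log(1) = 0)")
  p0 <- p1 + equivalence_delta
  if (p0 >= 1)
    abort_validation("equivalence_delta",
                     "acceptable_failure_rate + equivalence_delta must be < 1")
  if (!is_number(signal_limit) || signal_limit <= 0)
    abort_validation("signal_limit", "must be a positive number")
  horizon <- check_count(horizon, "horizon")

  ws <- log((1 - p1) / (1 - p0))
  wf <- log(p1 / p0)
  if (signal_limit / ws > horizon)
    abort_validation("signal_limit",
                     sprintf("unreachable: %d procedures are needed to signal but the horizon is %d",
                             ceiling(signal_limit / ws), horizon))

  structure(list(
    acceptable_failure_rate = p1,
    equivalence_delta = equivalence_delta,
    unacceptable_failure_rate = p0,
    success_increment = ws,
    failure_increment = wf,
    signal_limit = signal_limit,
    horizon = horizon
  ), class = "lc_design")
}

#' @export
print.lc_design <- function(x, ...) {
  cat("LC-CUSUM monitoring design\n")
  cat(sprintf("  acceptable failure rate p1 = %.3f, unacceptable p0 = %.3f (delta = %.3f)\n",
              x$acceptable_failure_rate, x$unacceptable_failure_rate, x$equivalence_delta))
  cat(sprintf("  increments: success %+.3f, failure %+.3f\n",
              x$success_increment, x$failure_increment))
  cat(sprintf("  signal limit h = %g over a horizon of %d procedures\n",
              x$signal_limit, x$horizon))
  cat(sprintf("  consecutive successes to signal: %d\n",
              ceiling(x$signal_limit / x$success_increment)))
  invisible(x)
}

#' Build the integer-scored multi-level LC-CUSUM program design
#'
#' A didactic simplification of the continuous chart: a success scores +1, a
#' failure -7, and a competency level is cleared when the score climbs
#' `level_width` points above the level floor. Level k (0-based) is bound to
#' scores in `[k * level_width, (k + 1) * level_width]`, so with 3 levels of
#' width 13 the program score runs 0-39 and a learner needs at least
#' `n_levels * level_width` = 39 consecutive successful procedures to pass the
#' whole program. Each level allows at most `per_level_cap` procedures.
#'
#' @param success_step Integer score gain per passed procedure (default +1).
#' @param failure_step Integer score loss per failed procedure (default -7).
#' @param level_width Points needed to clear one level (default 13).
#' @param n_levels Number of competency levels (default 3).
#' @param per_level_cap Maximum procedures allowed per level (default 50).
#' @return An object of class `lc_program_design`; `program_target` is the
#'   derived `n_levels * level_width`.
#' @examples
#' lc_program_design()
#' @export
lc_program_design <- function(success_step = 1L,
                              failure_step = -7L,
                              level_width = 13L,
                              n_levels = 3L,
                              per_level_cap = 50L) {
  success_step <- check_count(success_step, "success_step")
  if (!is_number(failure_step) || failure_step != round(failure_step) || failure_step >= 0)
    abort_validation("failure_step", "must be a negative integer")
  failure_step <- as.integer(failure_step)
  level_width <- check_count(level_width, "level_width")
  n_levels <- check_count(n_levels, "n_levels")
  per_level_cap <- check_count(per_level_cap, "per_level_cap")
  if (per_level_cap < level_width)
    abort_validation("per_level_cap",
                     "must be at least level_width (otherwise no level can ever signal)")

  structure(list(
    success_step = success_step,
    failure_step = failure_step,
    level_width = level_width,
    n_levels = n_levels,
    per_level_cap = per_level_cap,
    program_target = n_levels * level_width
  ), class = "lc_program_design")
}

#' @export
print.lc_program_design <- function(x, ...) {
  cat("Integer LC-CUSUM program design\n")
  cat(sprintf("  steps: success %+d, failure %+d; level width h = %d\n",
              x$success_step, x$failure_step, x$level_width))
  cat(sprintf("  %d levels, cap %d procedures each; program target score %d\n",
              x$n_levels, x$per_level_cap, x$program_target))
  invisible(x)
}

# Chart parameters (floor, limit, increments) for level k (0-based) of either
# design variant. The continuous chart has a single level with floor 0.
chart_params <- function(design, level = 0L) {
  if (inherits(design, "lc_design")) {
    if (level != 0L) abort_validation("level", "a continuous design has a single level (0)")
    list(up = design$success_increment, down = design$failure_increment,
         floor = 0, limit = design$signal_limit)
  } else if (inherits(design, "lc_program_design")) {
    if (level < 0L || level >= design$n_levels)
      abort_validation("level", sprintf("must be in 0..%d", design$n_levels - 1L))
    list(up = design$success_step, down = design$failure_step,
         floor = level * design$level_width,
         limit = (level + 1L) * design$level_width)
  } else {
    abort_validation("design", "must be an lc_design or lc_program_design")
  }
}
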