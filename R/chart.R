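#' Create a fresh LC-CUSUM chart state
#'
#' @param floor Holding barrier for the score (0 for the continuous chart; a
#'   level floor such as 13 or 26 in the integer program).
#' @return An object of class `lc_chart_state` with fields `score`, `floor`,
#'   `procedures_observed`, `signalled` and `signal_index` (1-based procedure
#'   count at the first signal, `NULL` until then).
#' @export
new_chart_state <- function(floor = 0) {
  if (!is_number(floor)) abort_validation("floor", "must be a single finite number")
  structure(list(
    score = floor,
    floor = floor,
    procedures_observed = 0L,
    signalled = FALSE,
    signal_index = NULL
  ), class = "lc_chart_state")
}

#' @export
print.lc_chart_state <- function(x, ...) {
  cat(sprintf("LC-CUSUM chart state: score %.4g after %d procedures%s\n",
              x$score, x$procedures_observed,
              if (x$signalled) sprintf(" (signalled at procedure %d)", x$signal_index) else ""))
  invisible(x)
}

#' Update an LC-CUSUM chart with one procedure outcome
#'
#' Applies the CUSUM recursion `S_t = max(floor, S_{t-1} + W)` where `W` is
#' the design's success or failure increment, and signals when the new score
#' reaches the in-control limit. A signalled state is absorbing: the test is
#' over and further updates are a contract violation.
#'
#' @param state An `lc_chart_state` (not yet signalled).
#' @param passed `TRUE` if the procedure was passed.
#' @param design An [lc_design()].
#' @return The updated `lc_chart_state`.
#' @examples
#' d <- lc_design()
#' s <- new_chart_state()
#' s <- update_chart(s, passed = FALSE, d)  # clamped at the floor
#' s$score  # 0
#' @export
update_chart <- function(state, passed, design) {
  if (!inherits(state, "lc_chart_state"))
    abort_validation("state", "must be an lc_chart_state")
  if (state$signalled)
    abort_contract("chart has already signalled; the state is absorbing")
  passed <- check_flag(passed, "passed")
  if (!inherits(design, "lc_design"))
    abort_validation("design", "must be an lc_design")

  inc <- if (passed) design$success_increment else design$failure_increment
  state$score <- max(state$floor, state$score + inc)
  state$procedures_observed <- state$procedures_observed + 1L
  if (state$score >= design$signal_limit) {
    state$signalled <- TRUE
    state$signal_index <- state$procedures_observed
  }
  state
}

# Low-level chart runner shared by the continuous and integer variants.
# Stops consuming outcomes at the first signal (>= limit).
run_scores <- function(outcomes, up, down, floor, limit) {
  n <- length(outcomes)
  traj <- numeric(n)
  s <- floor
  sig <- NA_integer_
  for (i in seq_len(n)) {
    s <- max(floor, s + if (outcomes[i]) up else down)
    traj[i] <- s
    if (s >= limit) {
      sig <- i
      break
    }
  }
  if (is.na(sig)) list(trajectory = traj, signal_index = NULL)
  else list(trajectory = traj[seq_len(sig)], signal_index = sig)
}

#' Run a continuous LC-CUSUM chart over an outcome sequence
#'
#' Folds [update_chart()] over the sequence, stopping at the first signal.
#' Sequences longer than the design horizon are truncated with a warning.
#'
#' @param outcomes Ordered pass/fail sequence (logical, or 0/1 with 1 = pass).
#' @param design An [lc_design()].
#' @return A list of class `lc_chart_run`: `trajectory` (one score per
#'   consumed outcome), `signal_index` (1-based, `NULL` if no signal) and
#'   `signalled`.
#' @examples
#' run_chart(rep(TRUE, 13), lc_design())$signal_index  # 13
#' run_chart(rep(TRUE, 12), lc_design())$signalled     # FALSE
#' @export
run_chart <- function(outcomes, design) {
  if (!inherits(design, "lc_design"))
    abort_validation("design", "must be an lc_design")
  outcomes <- as_outcomes(outcomes)
  if (length(outcomes) > design$horizon) {
    warning(sprintf("outcome sequence (%d) exceeds the monitoring horizon (%d); truncating",
                    length(outcomes), design$horizon))
    outcomes <- outcomes[seq_len(design$horizon)]
  }
  r <- run_scores(outcomes, design$success_increment, design$failure_increment,
                  0, design$signal_limit)
  structure(list(
    trajectory = r$trajectory,
    signal_index = r$signal_index,
    signalled = !is.null(r$signal_index)
  ), class = "lc_chart_run")
}

#' @export
print.lc_chart_run <- function(x, ...) {
  cat(sprintf("LC-CUSUM run: %d procedures, %s\n", length(x$trajectory),
              if (x$signalled) sprintf("competency signalled at procedure %d", x$signal_index)
              else "no signal"))
  invisible(x)
}

#' Run the integer-scored multi-level LC-CUSUM program
#'
#' Evaluates one outcome sequence per competency level. Within level k
#' (0-based) the score starts at the level floor `k * level_width`, moves by
#' the success/failure steps, is clamped at the level floor, and the level is
#' cleared when the score reaches `(k + 1) * level_width`. A level that does
#' not signal within `per_level_cap` procedures fails the level and the
#' program; by default evaluation stops there. With `allow_overrun = TRUE`
#' the full supplied sequence of a failed level is still consumed (recording
#' the extended trace -- learners may be allowed to keep training past the
#' cap) and later levels are evaluated, but the program verdict remains
#' failed whenever any level needed more than the cap.
#'
#' @param outcomes_by_level A list of exactly `n_levels` pass/fail sequences.
#' @param design An [lc_program_design()].
#' @param allow_overrun Continue past the per-level cap and into later levels
#'   (default `FALSE`).
#' @return A list of class `lc_program_result`: `per_level_traces` (absolute
#'   program scores), `per_level_signalled`, `per_level_signal_index`,
#'   `per_level_within_cap`, `per_level_procedure_counts`,
#'   `total_procedures`, `program_passed` and the `design`.
#' @examples
#' res <- run_integer_program(rep(list(rep(1, 13)), 3), lc_program_design())
#' res$program_passed     # TRUE
#' res$total_procedures   # 39
#' @export
run_integer_program <- function(outcomes_by_level, design = lc_program_design(),
                                allow_overrun = FALSE) {
  if (!inherits(design, "lc_program_design"))
    abort_validation("design", "must be an lc_program_design")
  if (!is.list(outcomes_by_level) || length(outcomes_by_level) != design$n_levels)
    abort_validation("outcomes_by_level",
                     sprintf("must be a list of exactly %d outcome sequences (got %d)",
                             design$n_levels, length(outcomes_by_level)))
  allow_overrun <- check_flag(allow_overrun, "allow_overrun")

  n <- design$n_levels
  traces <- vector("list", n)
  signalled <- logical(n)
  signal_index <- rep(NA_integer_, n)
  within_cap <- logical(n)
  counts <- integer(n)

  for (k in seq_len(n) - 1L) {
    outs <- as_outcomes(outcomes_by_level[[k + 1L]],
                        sprintf("outcomes_by_level[[%d]]", k + 1L))
    if (!allow_overrun && length(outs) > design$per_level_cap) {
      warning(sprintf("level %d sequence (%d) exceeds the per-level cap (%d); truncating",
                      k, length(outs), design$per_level_cap))
      outs <- outs[seq_len(design$per_level_cap)]
    }
    p <- chart_params(design, k)
    r <- run_scores(outs, p$up, p$down, p$floor, p$limit)
    traces[[k + 1L]] <- r$trajectory
    counts[k + 1L] <- length(r$trajectory)
    signalled[k + 1L] <- !is.null(r$signal_index)
    if (signalled[k + 1L]) {
      signal_index[k + 1L] <- r$signal_index
      within_cap[k + 1L] <- r$signal_index <= design$per_level_cap
    }
    if (!within_cap[k + 1L] && !allow_overrun) break
  }

  structure(list(
    per_level_traces = traces,
    per_level_signalled = signalled,
    per_level_signal_index = signal_index,
    per_level_within_cap = within_cap,
    per_level_procedure_counts = counts,
    total_procedures = sum(counts),
    program_passed = all(within_cap),
    design = design
  ), class = "lc_program_result")
}

#' @export
print.lc_program_result <- function(x, ...) {
  cat(sprintf("LC-CUSUM program: %s after %d procedures\n",
              if (x$program_passed) "PASSED" else "FAILED", x$total_procedures))
  for (k in seq_along(x$per_level_signalled)) {
    cat(sprintf("  level %d: %s (%d procedures)\n", k - 1L,
                if (x$per_level_within_cap[k]) sprintf("cleared at procedure %d", x$per_level_signal_index[k])
                else if (x$per_level_signalled[k]) sprintf("cleared only at procedure %d (beyond cap)", x$per_level_signal_index[k])
                else "not cleared",
                x$per_level_procedure_counts[k]))
  }
  invisible(x)
}
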