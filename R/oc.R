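#' @name operating-characteristics
#' @title Operating characteristics of an LC-CUSUM chart
#'
#' @description
#' The probability that a chart signals competency within a finite horizon,
#' and the distribution of the signal time, when each procedure fails
#' independently with a fixed true failure rate. Computed two ways: exactly,
#' by forward dynamic programming over the reachable set of clamped scores,
#' and by seeded Monte Carlo simulation. Because the success and failure
#' increments are incommensurable in the continuous design, the DP tracks
#' probability mass per distinct reachable score (each a clamped lattice
#' combination of the two increments) rather than on a rounded score grid;
#' scores are coalesced only when equal to within 1e-9.
NULL

# Forward DP over reachable clamped scores. Returns the run-length pmf over
# 1..horizon plus the surviving (no-signal) mass.
oc_dp <- function(up, down, floor, limit, p_fail, horizon) {
  scores <- floor
  probs <- 1
  pmf <- numeric(horizon)
  p_pass <- 1 - p_fail
  for (t in seq_len(horizon)) {
    ns <- c(pmax(floor, scores + up), pmax(floor, scores + down))
    np <- c(probs * p_pass, probs * p_fail)
    keep <- np > 0
    ns <- ns[keep]
    np <- np[keep]
    sig <- ns >= limit
    pmf[t] <- sum(np[sig])
    ns <- ns[!sig]
    np <- np[!sig]
    if (!length(ns)) break
    key <- sprintf("%.9f", ns)
    ukey <- unique(key)
    idx <- match(key, ukey)
    probs <- vapply(seq_along(ukey), function(i) sum(np[idx == i]), numeric(1))
    scores <- ns[match(ukey, key)]
  }
  list(pmf = pmf, no_signal = max(0, 1 - sum(pmf)))
}

oc_result <- function(pmf, no_signal, rate, horizon, method, se = NULL) {
  structure(list(
    signal_probability = sum(pmf),
    run_length_pmf = pmf,
    no_signal_probability = no_signal,
    true_failure_rate = rate,
    horizon = horizon,
    method = method,
    standard_error = se
  ), class = "lc_oc")
}

#' @export
print.lc_oc <- function(x, ...) {
  cat(sprintf("LC-CUSUM operating characteristic (%s)\n", x$method))
  cat(sprintf("  true failure rate %.3f, horizon %d procedures\n",
              x$true_failure_rate, x$horizon))
  cat(sprintf("  P(signal) = %.4f%s, P(no signal) = %.4f\n",
              x$signal_probability,
              if (!is.null(x$standard_error)) sprintf(" (SE %.4f)", x$standard_error) else "",
              x$no_signal_probability))
  erl <- sum(seq_along(x$run_length_pmf) * x$run_length_pmf)
  if (x$signal_probability > 0)
    cat(sprintf("  E[run length | signal] = %.2f\n", erl / x$signal_probability))
  invisible(x)
}

#' Exact signal probability and run-length distribution
#'
#' @rdname operating-characteristics
#' @param design An [lc_design()], or an [lc_program_design()] (in which case
#'   a single level of the integer chart is analysed: floor 0, limit
#'   `level_width`, steps `success_step`/`failure_step`).
#' @param true_failure_rate Hypothesised per-procedure failure probability in
#'   \eqn{[0, 1]}.
#' @param horizon Number of procedures monitored; defaults to the design's
#'   horizon (continuous) or `per_level_cap` (integer).
#' @return An object of class `lc_oc` with `signal_probability`,
#'   `run_length_pmf` (probability of first signal at each procedure
#'   1..horizon), `no_signal_probability` and, for the Monte Carlo variant,
#'   `standard_error`.
#' @examples
#' d <- lc_design()
#' signal_probability_exact(d, 0)$signal_probability   # 1: all passes signal at 13
#' signal_probability_exact(d, 1)$signal_probability   # 0: failures never climb
#' @export
signal_probability_exact <- function(design, true_failure_rate, horizon = NULL) {
  check_prob(true_failure_rate, "true_failure_rate")
  p <- chart_params(design, 0L)
  if (is.null(horizon))
    horizon <- if (inherits(design, "lc_design")) design$horizon else design$per_level_cap
  horizon <- check_count(horizon, "horizon")
  r <- oc_dp(p$up, p$down, p$floor, p$limit, true_failure_rate, horizon)
  oc_result(r$pmf, r$no_signal, true_failure_rate, horizon, "exact")
}

#' Monte Carlo signal probability
#'
#' @rdname operating-characteristics
#' @param replicates Number of simulated charts (>= 1).
#' @param seed Integer seed; mandatory (no hidden RNG state).
#' @export
signal_probability_mc <- function(design, true_failure_rate, replicates, seed,
                                  horizon = NULL) {
  check_prob(true_failure_rate, "true_failure_rate")
  replicates <- check_count(replicates, "replicates")
  if (!is_number(seed)) abort_validation("seed", "an integer seed is required")
  p <- chart_params(design, 0L)
  if (is.null(horizon))
    horizon <- if (inherits(design, "lc_design")) design$horizon else design$per_level_cap
  horizon <- check_count(horizon, "horizon")

  sig_t <- withr::with_seed(seed, {
    s <- rep(p$floor, replicates)
    alive <- rep(TRUE, replicates)
    when <- rep(NA_integer_, replicates)
    for (t in seq_len(horizon)) {
      ia <- which(alive)
      if (!length(ia)) break
      fail <- stats::runif(length(ia)) < true_failure_rate
      s[ia] <- pmax(p$floor, s[ia] + ifelse(fail, p$down, p$up))
      newly <- ia[s[ia] >= p$limit]
      when[newly] <- t
      alive[newly] <- FALSE
    }
    when
  })
  pmf <- tabulate(sig_t[!is.na(sig_t)], nbins = horizon) / replicates
  p_hat <- sum(pmf)
  oc_result(pmf, 1 - p_hat, true_failure_rate, horizon, "monte-carlo",
            se = sqrt(p_hat * (1 - p_hat) / replicates))
}

#' Probability of passing the whole integer-scored program
#'
#' After shifting out each level's floor, every level of the integer program
#' is the same chart (limit `level_width`, steps `success_step` and
#' `failure_step`, holding barrier). With independent procedures the program
#' pass probability is therefore the product of the per-level single-chart
#' signal probabilities within `per_level_cap` procedures.
#'
#' @param design An [lc_program_design()].
#' @param true_failure_rate A single failure rate applied at every level, or
#'   a vector of one rate per level.
#' @param per_level_cap Procedures allowed per level; defaults to the
#'   design's cap.
#' @return The program pass probability.
#' @examples
#' program_pass_probability(lc_program_design(), 0)          # 1
#' program_pass_probability(lc_program_design(), c(0, 0, 1)) # 0
#' @export
program_pass_probability <- function(design, true_failure_rate,
                                     per_level_cap = design$per_level_cap) {
  if (!inherits(design, "lc_program_design"))
    abort_validation("design", "must be an lc_program_design")
  per_level_cap <- check_count(per_level_cap, "per_level_cap")
  rates <- true_failure_rate
  if (length(rates) == 1L) rates <- rep(rates, design$n_levels)
  if (length(rates) != design$n_levels)
    abort_validation("true_failure_rate",
                     sprintf("supply one rate or %d per-level rates", design$n_levels))
  for (r in rates) check_prob(r, "true_failure_rate")

  prod(vapply(rates, function(r)
    signal_probability_exact(design, r, horizon = per_level_cap)$signal_probability,
    numeric(1)))
}

#' Calibrate the in-control limit h for a target signal probability
#'
#' Searches a grid of candidate limits (the operating characteristic is a
#' step function of `h`, so a grid matching the precision at which `h` is
#' quoted is the natural search space) and returns the largest grid multiple
#' of `grid_step` whose exact signal probability at `rate_for_target` still
#' meets `target_signal_probability` -- the most conservative limit that
#' retains the requested power. The achieved probabilities at both the
#' acceptable and the unacceptable failure rate are reported.
#'
#' @param acceptable_failure_rate,equivalence_delta As in [lc_design()].
#' @param horizon Monitoring horizon (procedures).
#' @param target_signal_probability Required signal probability in (0, 1].
#' @param rate_for_target True failure rate at which the target must be met.
#' @param grid_step Grid resolution for `h` (default 0.01, i.e. limits quoted
#'   to two decimals).
#' @return A list of class `lc_calibration`: `signal_limit`, `achieved`
#'   (probability at `rate_for_target`), `at_acceptable_rate`,
#'   `at_unacceptable_rate`, and the inputs.
#' @examples
#' cal <- calibrate_limit(0.10, 0.05, 50,
#'                        target_signal_probability = 0.85,
#'                        rate_for_target = 0.10)
#' cal$signal_limit
#' @export
calibrate_limit <- function(acceptable_failure_rate, equivalence_delta, horizon,
                            target_signal_probability, rate_for_target,
                            grid_step = 0.01) {
  p1 <- check_prob(acceptable_failure_rate, "acceptable_failure_rate", open = TRUE)
  if (!is_number(equivalence_delta) || equivalence_delta <= 0 || p1 + equivalence_delta >= 1)
    abort_validation("equivalence_delta", "must satisfy 0 < p1 + delta < 1")
  horizon <- check_count(horizon, "horizon")
  if (!is_number(target_signal_probability) ||
      target_signal_probability <= 0 || target_signal_probability > 1)
    abort_validation("target_signal_probability", "must lie in (0, 1]")
  check_prob(rate_for_target, "rate_for_target")
  if (!is_number(grid_step) || grid_step <= 0)
    abort_validation("grid_step", "must be a positive number")

  p0 <- p1 + equivalence_delta
  ws <- log((1 - p1) / (1 - p0))
  wf <- log(p1 / p0)
  h_max <- horizon * ws
  grid <- seq(grid_step, by = grid_step,
              length.out = floor(h_max / grid_step + 1e-9))
  if (!length(grid))
    abort_unattainable(sprintf(
      "no grid multiple of %g is reachable within %d procedures (max limit %.4f)",
      grid_step, horizon, h_max))

  # P(signal) is non-increasing in h: scan from the largest candidate down,
  # so the first qualifying h is the largest one. If none qualifies, the last
  # value scanned (smallest h) is the best achievable probability.
  best <- NA_real_
  chosen <- NA_real_
  for (h in rev(grid)) {
    p_sig <- sum(oc_dp(ws, wf, 0, h, rate_for_target, horizon)$pmf)
    best <- p_sig
    if (p_sig >= target_signal_probability) {
      chosen <- h
      break
    }
  }
  if (is.na(chosen))
    abort_unattainable(sprintf(
      "target %.4f unattainable at failure rate %.3f over %d procedures; best achievable %.4f",
      target_signal_probability, rate_for_target, horizon, best))

  structure(list(
    signal_limit = chosen,
    achieved = best,
    at_acceptable_rate = sum(oc_dp(ws, wf, 0, chosen, p1, horizon)$pmf),
    at_unacceptable_rate = sum(oc_dp(ws, wf, 0, chosen, p0, horizon)$pmf),
    target_signal_probability = target_signal_probability,
    rate_for_target = rate_for_target,
    horizon = horizon,
    grid_step = grid_step
  ), class = "lc_calibration")
}

#' @export
print.lc_calibration <- function(x, ...) {
  cat(sprintf("Calibrated LC-CUSUM limit h = %g (grid step %g, horizon %d)\n",
              x$signal_limit, x$grid_step, x$horizon))
  cat(sprintf("  P(signal) = %.4f at rate %.3f (target %.4f)\n",
              x$achieved, x$rate_for_target, x$target_signal_probability))
  cat(sprintf("  achieved OC: %.4f at the acceptable rate, %.4f at the unacceptable rate\n",
              x$at_acceptable_rate, x$at_unacceptable_rate))
  invisible(x)
}
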