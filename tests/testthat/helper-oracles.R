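# Independent oracles used to check the analytic implementations.

# Two-sided Fisher p-value by brute-force enumeration of every table with the
# observed margins, probability-mass ordering.
fisher_bruteforce <- function(a, b, c, d) {
  m <- a + c   # stayed column total
  n2 <- b + d  # left column total
  k <- a + b   # passed row total
  ks <- max(0, k - n2):min(k, m)
  probs <- stats::dhyper(ks, m, n2, k)
  p_obs <- stats::dhyper(a, m, n2, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Exact signal probability by exhaustive enumeration of all 2^horizon outcome
# sequences, folding the public chart runner over each. Only usable for tiny
# horizons; independent of the dynamic-programming recursion.
enumerate_signal_probability <- function(design, rate, horizon) {
  stopifnot(horizon <= 12)
  pmf <- numeric(horizon)
  for (bits in 0:(2^horizon - 1)) {
    outs <- as.logical(bitwAnd(bits, 2^(0:(horizon - 1))) > 0)  # TRUE = pass
    seq_prob <- prod(ifelse(outs, 1 - rate, rate))
    if (seq_prob == 0) next
    r <- if (inherits(design, "lc_design")) {
      run_chart(outs, design)
    } else {
      pr <- run_integer_program(list(outs), design)
      list(signal_index = if (pr$per_level_signalled[1]) pr$per_level_signal_index[1] else NULL)
    }
    if (!is.null(r$signal_index)) pmf[r$signal_index] <- pmf[r$signal_index] + seq_prob
  }
  list(signal_probability = sum(pmf), pmf = pmf)
}

# A fixed bank of randomised metrics spanning passes and failures, used to
# compare rule-set representations.
random_metrics_bank <- function(n, seed) {
  withr::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      level <- sample(0:2, 1)
      tad <- stats::runif(1, 0, 40)
      zone <- sample(c("center-center", "center-inferior", "center-superior",
                       "inferior", "superior", "anterior", "posterior", "other"), 1)
      breach <- stats::runif(1) < 0.3
      attempts <- sample(1:6, 1)
      m <- if (level == 2) {
        dhs_metrics(tad, zone, breach, attempts,
                    reamer_breach = stats::runif(1) < 0.3,
                    plate_angle_appropriate = stats::runif(1) < 0.7,
                    shaft_screw_bicortical = stats::runif(1) < 0.7,
                    cortical_drill_outside_mm = stats::runif(1, 0, 15),
                    fluoroscopy_time = stats::runif(1, 0, 60),
                    radiograph_count = sample(0:60, 1),
                    total_time = stats::runif(1, 30, 400))
      } else {
        wire_metrics(tad, zone, breach, attempts,
                     fluoroscopy_time = stats::runif(1, 0, 60),
                     radiograph_count = sample(0:60, 1),
                     total_time = stats::runif(1, 30, 400))
      }
      list(level = level, metrics = m)
    })
  })
}

# A small program design whose single level is exhaustively enumerable.
tiny_program_design <- function() {
  lc_program_design(success_step = 1L, failure_step = -2L,
                    level_width = 3L, n_levels = 1L, per_level_cap = 10L)
}

# Dispatch assessment by competency level through the public API.
assess_at_level_public <- function(metrics, level, ruleset = default_ruleset()) {
  if (level == 2) assess_dhs(metrics, ruleset) else assess_wire(metrics, ruleset)
}
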