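design <- lc_design()
pdesign <- lc_program_design()

test_that("degenerate failure rates give certain outcomes", {
  oc0 <- signal_probability_exact(design, 0)
  expect_equal(oc0$signal_probability, 1)
  expect_equal(oc0$run_length_pmf[13], 1)
  expect_equal(sum(oc0$run_length_pmf[-13]), 0)

  oc1 <- signal_probability_exact(design, 1)
  expect_equal(oc1$signal_probability, 0)
  expect_equal(oc1$no_signal_probability, 1)

  mc0 <- signal_probability_mc(design, 0, replicates = 500, seed = 3)
  expect_identical(mc0$signal_probability, 1)
  expect_identical(mc0$standard_error, 0)
})

test_that("probability mass is conserved and starts at the minimum signal time", {
  for (rate in c(0, 0.05, 0.10, 0.15, 0.30, 1)) {
    oc <- signal_probability_exact(design, rate)
    expect_equal(sum(oc$run_length_pmf) + oc$no_signal_probability, 1,
                 tolerance = 1e-9)
    expect_equal(sum(oc$run_length_pmf[1:12]), 0)  # 13 passes are the fastest signal
  }
})

test_that("the DP matches exhaustive enumeration on a tiny continuous design", {
  tiny <- lc_design(0.2, 0.2, signal_limit = 0.8, horizon = 10)
  for (rate in c(0.3, 0.5, 0.85)) {
    oracle <- enumerate_signal_probability(tiny, rate, 10)
    oc <- signal_probability_exact(tiny, rate, horizon = 10)
    expect_equal(oc$signal_probability, oracle$signal_probability, tolerance = 1e-12)
    expect_equal(oc$run_length_pmf, oracle$pmf, tolerance = 1e-12)
  }
})

test_that("the DP matches exhaustive enumeration on a tiny integer design", {
  tiny <- tiny_program_design()
  for (rate in c(0.25, 0.5)) {
    oracle <- enumerate_signal_probability(tiny, rate, tiny$per_level_cap)
    oc <- signal_probability_exact(tiny, rate)
    expect_equal(oc$signal_probability, oracle$signal_probability, tolerance = 1e-12)
    expect_equal(oc$run_length_pmf, oracle$pmf, tolerance = 1e-12)
  }
})

test_that("Monte Carlo agrees with the DP and is seed-reproducible", {
  for (rate in c(0.10, 0.30)) {
    dp <- signal_probability_exact(design, rate)$signal_probability
    mc <- signal_probability_mc(design, rate, replicates = 20000, seed = 17)
    expect_lt(abs(mc$signal_probability - dp), 3 * mc$standard_error + 1e-12)
  }
  a <- signal_probability_mc(design, 0.10, 5000, seed = 5)
  b <- signal_probability_mc(design, 0.10, 5000, seed = 5)
  expect_identical(a$signal_probability, b$signal_probability)
  c2 <- signal_probability_mc(design, 0.10, 20000, seed = 6)
  d2 <- signal_probability_mc(design, 0.10, 20000, seed = 7)
  expect_lt(abs(c2$signal_probability - d2$signal_probability),
            6 * sqrt(c2$standard_error^2 + d2$standard_error^2))
})

test_that("signal probability is monotone in rate, horizon and limit", {
  rates <- c(0, 0.05, 0.10, 0.15, 0.30, 0.6, 1)
  p_rate <- vapply(rates, function(r)
    signal_probability_exact(design, r)$signal_probability, numeric(1))
  expect_true(all(diff(p_rate) <= 1e-12))

  horizons <- c(13, 20, 30, 50)
  p_hor <- vapply(horizons, function(h)
    signal_probability_exact(design, 0.10, horizon = h)$signal_probability, numeric(1))
  expect_true(all(diff(p_hor) >= -1e-12))

  limits <- c(0.3, 0.5, 0.74, 1.5, 2.5)
  p_lim <- vapply(limits, function(h)
    signal_probability_exact(lc_design(signal_limit = h), 0.10)$signal_probability,
    numeric(1))
  expect_true(all(diff(p_lim) <= 1e-12))
})

test_that("integer single-level DP equals a continuous chart with the same unit increments", {
  # one level of the +1/-7/13 scheme, expressed through the generic DP
  for (rate in c(0.10, 0.15, 0.30)) {
    int_dp <- signal_probability_exact(pdesign, rate)
    cont_dp <- lccusum:::oc_dp(1, -7, 0, 13, rate, pdesign$per_level_cap)
    expect_equal(int_dp$run_length_pmf, cont_dp$pmf, tolerance = 1e-12)
  }
})

test_that("program pass probability composes per-level signal probabilities", {
  expect_equal(program_pass_probability(pdesign, 0), 1)
  expect_equal(program_pass_probability(pdesign, c(0, 0, 1)), 0)
  for (r in c(0.05, 0.15)) {
    single <- signal_probability_exact(pdesign, r)$signal_probability
    expect_equal(program_pass_probability(pdesign, r), single^3, tolerance = 1e-12)
  }
  expect_error(program_pass_probability(pdesign, c(0.1, 0.1)),
               "true_failure_rate", class = "lccusum_validation_error")
})

test_that("limit calibration recovers the published limit and reports both rates", {
  target <- signal_probability_exact(design, 0.10)$signal_probability
  cal <- calibrate_limit(0.10, 0.05, 50,
                         target_signal_probability = target,
                         rate_for_target = 0.10, grid_step = 0.01)
  expect_equal(cal$signal_limit, 0.74)
  expect_equal(cal$achieved, target, tolerance = 1e-12)
  expect_equal(cal$at_acceptable_rate, target, tolerance = 1e-12)
  expect_lt(cal$at_unacceptable_rate, cal$at_acceptable_rate)
})

test_that("calibration returns the largest reachable limit for a sure target", {
  d <- lc_design()
  cal <- calibrate_limit(0.10, 0.05, 50, target_signal_probability = 1,
                         rate_for_target = 0, grid_step = 0.01)
  h_max <- 50 * d$success_increment
  expect_lte(cal$signal_limit, h_max)
  expect_gt(cal$signal_limit + 0.01, h_max)  # the next grid step would be unreachable
  expect_equal(cal$achieved, 1)
})

test_that("an impossible calibration target raises an unattainable error", {
  expect_error(
    calibrate_limit(0.10, 0.05, 50, target_signal_probability = 0.5,
                    rate_for_target = 1),
    "unattainable", class = "lccusum_unattainable_error")
})
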