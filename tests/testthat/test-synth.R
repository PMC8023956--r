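test_that("outcome simulation is seed-deterministic", {
  p <- learner_profile("demo", 0.5, 0.05, 10)
  a <- simulate_outcomes(p, 200, seed = 42)
  b <- simulate_outcomes(p, 200, seed = 42)
  expect_identical(a, b)
  c2 <- simulate_outcomes(p, 200, seed = 43)
  expect_false(identical(a, c2))
})

test_that("flat learning curves give i.i.d. Bernoulli failures at the set rate", {
  p0 <- learner_profile("flawless", 0, 0, 1)
  expect_true(all(simulate_outcomes(p0, 100, seed = 1)))

  r <- 0.3
  pr <- learner_profile("const", r, r, 1)
  outs <- simulate_outcomes(pr, 1e4, seed = 12)
  expect_lt(abs(mean(!outs) - r), 4 * sqrt(r * (1 - r) / 1e4))
})

test_that("the learning curve lowers the failure rate over experience", {
  p <- learner_profile("learner", 0.6, 0.05, 10)
  outs <- simulate_outcomes(p, 1e4, seed = 31)
  early <- mean(!outs[1:10])
  late <- mean(!outs[9901:10000])
  expect_gt(early, late)
})

test_that("profile invariants are enforced", {
  expect_error(learner_profile("x", 0.1, 0.5, 10),
               "asymptotic_failure_prob", class = "lccusum_validation_error")
  expect_error(learner_profile("x", 0.5, 0.1, 0),
               "learning_time_constant", class = "lccusum_validation_error")
})

test_that("generated metrics reproduce their requested verdict and ranges", {
  n <- 1000
  withr::with_seed(77, {
    lv <- sample(0:2, n, replace = TRUE)
    want <- sample(c(TRUE, FALSE), n, replace = TRUE)
    tads <- numeric(0)
    for (i in seq_len(n)) {
      m <- simulate_metrics(want[i], lv[i])
      v <- assess_at_level_public(m, lv[i])
      expect_identical(v$passed, want[i])
      if (!want[i]) expect_gt(length(v$failed_criteria), 0)
      if (want[i] && lv[i] == 2) tads <- c(tads, m$tip_apex_distance)
    }
    # passing draws centre near the generator's configured TAD
    expect_gt(length(tads), 50)
    expect_gt(mean(tads), 10)
    expect_lt(mean(tads), 17)
  })
})

test_that("an inconsistent rule set exhausts the metric generator's retries", {
  f <- withr::local_tempfile(fileext = ".yaml")
  # impossible requirement: TAD must be both <= 20 and >= 100
  writeLines(c(
    "wire:",
    "  - {metric: tip_apex_distance, comparator: le, threshold: 20}",
    "  - {metric: tip_apex_distance, comparator: ge, threshold: 100}",
    "dhs: []"), f)
  rs <- load_ruleset(f)
  expect_error(simulate_metrics(TRUE, 0, seed = 1, ruleset = rs, max_retries = 20),
               "rule set", class = "lccusum_generation_error")
})

test_that("a flawless cohort passes the whole program in exactly 39 procedures", {
  flawless <- learner_profile("flawless", 0, 0, 1)
  cfg <- cohort_config(n_learners = 6, profiles = list(flawless), weights = 1,
                       seed = 5)
  coh <- simulate_cohort(cfg, include_metrics = FALSE)
  expect_true(all(coh$learners$passed_program))
  expect_true(all(coh$learners$total_procedures == 39L))
  expect_equal(max(coh$procedures$score), 39)
})

test_that("cohort simulation is byte-deterministic under its seed", {
  cfg <- cohort_config(n_learners = 8, seed = 9)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$procedures, b$procedures)
  expect_identical(a$learners, b$learners)

  c2 <- simulate_cohort(cohort_config(n_learners = 8, seed = 10))
  expect_false(identical(a$procedures, c2$procedures))
  expect_identical(names(a$procedures), names(c2$procedures))
  expect_identical(names(a$learners), names(c2$learners))
})

test_that("cohort metric rows re-assess to their logged verdicts", {
  cfg <- cohort_config(n_learners = 5, seed = 14)
  coh <- simulate_cohort(cfg, include_metrics = TRUE)
  df <- coh$procedures
  for (i in seq_len(nrow(df))) {
    lvl <- df$competency_level[i]
    m <- if (lvl == 2) {
      dhs_metrics(df$tip_apex_distance[i], df$placement_zone[i],
                  df$cortical_breach[i] == 1, df$kwire_attempts[i],
                  reamer_breach = df$reamer_breach[i] == 1,
                  plate_angle_appropriate = df$plate_angle_appropriate[i] == 1,
                  shaft_screw_bicortical = df$shaft_screw_bicortical[i] == 1,
                  cortical_drill_outside_mm = df$cortical_drill_outside_mm[i])
    } else {
      wire_metrics(df$tip_apex_distance[i], df$placement_zone[i],
                   df$cortical_breach[i] == 1, df$kwire_attempts[i])
    }
    expect_identical(assess_at_level_public(m, lvl)$passed, df$passed[i] == 1L)
  }
})

test_that("career outcomes converge to the configured conditional probabilities", {
  # mixture with both verdicts well represented
  cfg <- cohort_config(n_learners = 4000, seed = 123)
  coh <- simulate_cohort(cfg, include_metrics = FALSE)
  l <- coh$learners
  n_pass <- sum(l$passed_program)
  n_fail <- sum(!l$passed_program)
  expect_gt(n_pass, 200)
  expect_gt(n_fail, 200)
  ppv <- mean(l$career_stayed[l$passed_program])
  npv <- mean(!l$career_stayed[!l$passed_program])
  expect_lt(abs(ppv - 13 / 14), 4 * sqrt((13 / 14) * (1 / 14) / n_pass))
  expect_lt(abs(npv - 0.5), 4 * sqrt(0.25 / n_fail))
})

test_that("empirical program-pass fraction matches the exact composition rule", {
  r <- 0.10
  prof <- learner_profile("const", r, r, 1, persistence = 150L)
  cfg <- cohort_config(n_learners = 2000, profiles = list(prof), weights = 1,
                       seed = 2024)
  coh <- simulate_cohort(cfg, include_metrics = FALSE)
  p_hat <- mean(coh$learners$passed_program)
  p_exact <- program_pass_probability(lc_program_design(), r)
  expect_lt(abs(p_hat - p_exact), 3 * sqrt(p_exact * (1 - p_exact) / 2000))
})
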