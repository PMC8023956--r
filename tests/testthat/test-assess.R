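test_that("the default K-wire criteria reproduce the pass/fail rules", {
  expect_true(assess_wire(wire_metrics(13, "center-center", FALSE, 1))$passed)

  v <- assess_wire(wire_metrics(21, "center-center", FALSE, 1))
  expect_false(v$passed)
  expect_identical(v$failed_criteria, "tad")

  # failure is strictly beyond the thresholds: boundary values pass
  expect_true(assess_wire(wire_metrics(20, "center-inferior", FALSE, 3))$passed)

  v4 <- assess_wire(wire_metrics(25, "superior", TRUE, 4))
  expect_false(v4$passed)
  expect_setequal(v4$failed_criteria,
                  c("tad", "placement_zone", "cortical_breach", "kwire_attempts"))
})

test_that("the full-procedure criteria extend the K-wire rules conjunctively", {
  ok <- dhs_metrics(13, "center-center", FALSE, 1,
                    reamer_breach = FALSE, plate_angle_appropriate = TRUE,
                    shaft_screw_bicortical = TRUE)
  expect_true(assess_dhs(ok)$passed)
  expect_identical(assess_dhs(ok)$failed_criteria, character(0))

  ream <- dhs_metrics(13, "center-center", FALSE, 1,
                      reamer_breach = TRUE, plate_angle_appropriate = TRUE,
                      shaft_screw_bicortical = TRUE)
  expect_identical(assess_dhs(ream)$failed_criteria, "reamer_breach")

  tad_bad <- dhs_metrics(22, "center-center", FALSE, 1,
                         reamer_breach = FALSE, plate_angle_appropriate = TRUE,
                         shaft_screw_bicortical = TRUE)
  expect_identical(assess_dhs(tad_bad)$failed_criteria, "tad")
})

test_that("unknown placement zones are rejected at construction", {
  expect_error(wire_metrics(13, "middle", FALSE, 1),
               "placement_zone", class = "lccusum_validation_error")
  expect_error(wire_metrics(13, "center-center", FALSE, 0),
               "kwire_attempts", class = "lccusum_validation_error")
})

test_that("worsening any single metric never flips a failed verdict to passed", {
  bank <- random_metrics_bank(60, seed = 21)
  worsen <- list(
    function(m) { m$tip_apex_distance <- m$tip_apex_distance + 5; m },
    function(m) { m$kwire_attempts <- m$kwire_attempts + 1L; m },
    function(m) { m$cortical_breach <- TRUE; m },
    function(m) { m$placement_zone <- "other"; m }
  )
  for (case in bank) {
    before <- assess_at_level_public(case$metrics, case$level)
    for (w in worsen) {
      after <- assess_at_level_public(w(case$metrics), case$level)
      if (!before$passed) expect_false(after$passed)
    }
  }
})

test_that("fluoroscopy, radiograph and time metrics never influence the verdict", {
  bank <- random_metrics_bank(40, seed = 8)
  for (case in bank) {
    base <- assess_at_level_public(case$metrics, case$level)
    m <- case$metrics
    m$fluoroscopy_time <- 1e6
    m$radiograph_count <- 999L
    m$total_time <- 1e6
    expect_identical(assess_at_level_public(m, case$level)$passed, base$passed)
    expect_identical(assess_at_level_public(m, case$level)$failed_criteria,
                     base$failed_criteria)
  }
})

test_that("the shipped YAML rule set is equivalent to the built-in default", {
  path <- system.file("extdata", "default_ruleset.yaml", package = "lccusum")
  expect_true(nzchar(path))
  rs <- load_ruleset(path)
  bank <- random_metrics_bank(100, seed = 99)
  for (case in bank) {
    a <- assess_at_level_public(case$metrics, case$level, default_ruleset())
    b <- assess_at_level_public(case$metrics, case$level, rs)
    expect_identical(a$passed, b$passed)
    expect_identical(sort(a$failed_criteria), sort(b$failed_criteria))
  }
})

test_that("an empty criterion list is a vacuous conjunction", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("wire: []", "dhs: []"), f)
  rs <- load_ruleset(f)
  bank <- random_metrics_bank(20, seed = 4)
  for (case in bank)
    expect_true(assess_at_level_public(case$metrics, case$level, rs)$passed)
})

test_that("duplicate metric entries are both applied", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "wire:",
    "  - {id: tad_loose, metric: tip_apex_distance, comparator: le, threshold: 20}",
    "  - {id: tad_strict, metric: tip_apex_distance, comparator: le, threshold: 15}",
    "dhs: []"), f)
  rs <- load_ruleset(f)
  v <- assess_wire(wire_metrics(17, "center-center", FALSE, 1), rs)
  expect_false(v$passed)
  expect_identical(v$failed_criteria, "tad_strict")
})

test_that("malformed rule entries are rejected with their index", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "wire:",
    "  - {metric: tip_apex_distance, comparator: le, threshold: 20}",
    "  - {metric: made_up_metric, comparator: le, threshold: 1}"), f)
  expect_error(load_ruleset(f), "wire\\[2\\]", class = "lccusum_validation_error")

  f2 <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("wire:", "  - {metric: tip_apex_distance, comparator: between}"), f2)
  expect_error(load_ruleset(f2), "wire\\[1\\]", class = "lccusum_validation_error")
})

test_that("verdicts are pure functions of metrics and rule set", {
  m <- wire_metrics(19.5, "center-inferior", FALSE, 3)
  expect_identical(assess_wire(m), assess_wire(m))
})
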