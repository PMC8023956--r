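#' @name procedure-assessment
#' @title Pass/fail classification of a simulated procedure
#'
#' @description
#' Every monitored procedure must be classified as passed or failed before it
#' can feed an LC-CUSUM chart. The classification is a conjunction of
#' criteria over the procedure metrics: the K-wire levels (CL0 and CL1 share
#' one rule set) require a tip-apex distance (TAD) of at most 20 mm, a
#' center-center or center-inferior placement, no breach of cortical bone,
#' and at most 3 attempts to place the K-wire; the full-procedure level (CL2)
#' additionally requires no reamer breach, an appropriate plate angle and a
#' bicortical shaft screw. Failure is strictly above the thresholds ("more
#' than 20 mm", "more than 3 attempts"), so boundary values pass.
#' Fluoroscopy time, radiograph count and total time are recorded but never
#' influence the verdict under the default rules. Criteria are data, not
#' code: [load_ruleset()] reads an alternative rule set from a YAML file.
NULL

PLACEMENT_ZONES <- c("center-center", "center-inferior", "center-superior",
                     "inferior", "superior", "anterior", "posterior", "other")
PASSING_ZONES <- c("center-center", "center-inferior")

#' Construct validated K-wire procedure metrics
#'
#' @param tip_apex_distance TAD in mm (>= 0, finite).
#' @param placement_zone One of `"center-center"`, `"center-inferior"`,
#'   `"center-superior"`, `"inferior"`, `"superior"`, `"anterior"`,
#'   `"posterior"`, `"other"`.
#' @param cortical_breach Did the K-wire breach cortical bone?
#' @param kwire_attempts Attempts to place the K-wire (>= 1).
#' @param fluoroscopy_time Fluoroscopy time in seconds (informational only).
#' @param radiograph_count Number of radiographs (informational only).
#' @param total_time Total procedure time in seconds (informational only).
#' @return A named list of class `wire_metrics`.
#' @examples
#' m <- wire_metrics(13, "center-center", FALSE, 1)
#' assess_wire(m)$passed
#' @export
wire_metrics <- function(tip_apex_distance, placement_zone, cortical_breach,
                         kwire_attempts, fluoroscopy_time = 0,
                         radiograph_count = 0L, total_time = 0) {
  if (!is_number(tip_apex_distance) || tip_apex_distance < 0)
    abort_validation("tip_apex_distance", "must be a finite length in mm, >= 0")
  if (!is.character(placement_zone) || length(placement_zone) != 1L ||
      !(placement_zone %in% PLACEMENT_ZONES))
    abort_validation("placement_zone",
                     paste("must be one of:", paste(PLACEMENT_ZONES, collapse = ", ")))
  cortical_breach <- check_flag(cortical_breach, "cortical_breach")
  kwire_attempts <- check_count(kwire_attempts, "kwire_attempts")
  if (!is_number(fluoroscopy_time) || fluoroscopy_time < 0)
    abort_validation("fluoroscopy_time", "must be >= 0 seconds")
  radiograph_count <- check_count(radiograph_count, "radiograph_count", min = 0L)
  if (!is_number(total_time) || total_time < 0)
    abort_validation("total_time", "must be >= 0 seconds")

  structure(list(
    tip_apex_distance = tip_apex_distance,
    placement_zone = placement_zone,
    cortical_breach = cortical_breach,
    kwire_attempts = kwire_attempts,
    fluoroscopy_time = fluoroscopy_time,
    radiograph_count = radiograph_count,
    total_time = total_time
  ), class = "wire_metrics")
}

#' Construct validated full-procedure (DHS) metrics
#'
#' Extends [wire_metrics()] with the steps added at the full-procedure level:
#' reaming, plate angle selection and fixation with a single bicortical shaft
#' screw.
#'
#' @inheritParams wire_metrics
#' @param reamer_breach Did the reamer breach cortical bone?
#' @param plate_angle_appropriate Was the chosen DHS plate angle appropriate
#'   for the patient?
#' @param cortical_drill_outside_mm Drill length outside the femoral shaft in
#'   mm (informational only).
#' @param shaft_screw_bicortical Was the shaft screw bicortical?
#' @return A named list of class `c("dhs_metrics", "wire_metrics")`.
#' @export
dhs_metrics <- function(tip_apex_distance, placement_zone, cortical_breach,
                        kwire_attempts, reamer_breach, plate_angle_appropriate,
                        shaft_screw_bicortical, cortical_drill_outside_mm = 0,
                        fluoroscopy_time = 0, radiograph_count = 0L,
                        total_time = 0) {
  m <- wire_metrics(tip_apex_distance, placement_zone, cortical_breach,
                    kwire_attempts, fluoroscopy_time, radiograph_count, total_time)
  reamer_breach <- check_flag(reamer_breach, "reamer_breach")
  plate_angle_appropriate <- check_flag(plate_angle_appropriate, "plate_angle_appropriate")
  shaft_screw_bicortical <- check_flag(shaft_screw_bicortical, "shaft_screw_bicortical")
  if (!is_number(cortical_drill_outside_mm) || cortical_drill_outside_mm < 0)
    abort_validation("cortical_drill_outside_mm", "must be a length in mm, >= 0")
  m$reamer_breach <- reamer_breach
  m$plate_angle_appropriate <- plate_angle_appropriate
  m$cortical_drill_outside_mm <- cortical_drill_outside_mm
  m$shaft_screw_bicortical <- shaft_screw_bicortical
  class(m) <- c("dhs_metrics", "wire_metrics")
  m
}

# One criterion: id, metric, comparator in {le, ge, lt, gt, eq, in}, value.
new_criterion <- function(id, metric, comparator, value) {
  list(id = id, metric = metric, comparator = comparator, value = value)
}

KNOWN_METRICS <- c("tip_apex_distance", "placement_zone", "cortical_breach",
                   "kwire_attempts", "fluoroscopy_time", "radiograph_count",
                   "total_time", "reamer_breach", "plate_angle_appropriate",
                   "cortical_drill_outside_mm", "shaft_screw_bicortical")

#' The default pass/fail rule set
#'
#' CL0 and CL1 (`wire`): TAD <= 20 mm, placement in \{center-center,
#' center-inferior\}, no cortical breach, at most 3 K-wire attempts.
#' CL2 (`dhs`) extends these with: no reamer breach, appropriate plate angle,
#' bicortical shaft screw.
#'
#' @return A list of class `lc_ruleset` with criterion lists `wire` and `dhs`.
#' @export
default_ruleset <- function() {
  wire <- list(
    new_criterion("tad", "tip_apex_distance", "le", 20),
    new_criterion("placement_zone", "placement_zone", "in", PASSING_ZONES),
    new_criterion("cortical_breach", "cortical_breach", "eq", FALSE),
    new_criterion("kwire_attempts", "kwire_attempts", "le", 3)
  )
  dhs <- c(wire, list(
    new_criterion("reamer_breach", "reamer_breach", "eq", FALSE),
    new_criterion("plate_angle", "plate_angle_appropriate", "eq", TRUE),
    new_criterion("shaft_screw_bicortical", "shaft_screw_bicortical", "eq", TRUE)
  ))
  structure(list(wire = wire, dhs = dhs), class = "lc_ruleset")
}

#' Load a pass/fail rule set from a YAML configuration
#'
#' The file declares, per level group (`wire` for CL0/CL1, `dhs` for CL2), a
#' list of criterion entries with fields `id` (optional, defaults to the
#' metric name), `metric`, `comparator` (`le`, `ge`, `lt`, `gt`, `eq`, `in`)
#' and `threshold` (or `allowed` for `in`). Duplicate entries for one metric
#' are all applied (conjunction). The shipped default file
#' `system.file("extdata", "default_ruleset.yaml", package = "lccusum")`
#' reproduces [default_ruleset()] exactly.
#'
#' @param path Path to the YAML file.
#' @return An `lc_ruleset`.
#' @export
load_ruleset <- function(path) {
  if (!file.exists(path)) abort_validation("path", sprintf("file not found: %s", path))
  cfg <- yaml::read_yaml(path)
  parse_group <- function(entries, group) {
    if (is.null(entries)) return(list())
    lapply(seq_along(entries), function(i) {
      e <- entries[[i]]
      bad <- function(msg) abort_validation(
        sprintf("%s[%d]", group, i), msg)
      if (!is.list(e) || is.null(e$metric) || is.null(e$comparator))
        bad("each entry needs `metric` and `comparator` fields")
      if (!(e$metric %in% KNOWN_METRICS))
        bad(sprintf("unknown metric `%s`", e$metric))
      if (!(e$comparator %in% c("le", "ge", "lt", "gt", "eq", "in")))
        bad(sprintf("unknown comparator `%s`", e$comparator))
      value <- if (identical(e$comparator, "in")) {
        if (is.null(e$allowed)) bad("comparator `in` needs an `allowed` list")
        unlist(e$allowed)
      } else {
        if (is.null(e$threshold)) bad("needs a `threshold` field")
        e$threshold
      }
      new_criterion(if (is.null(e$id)) e$metric else e$id,
                    e$metric, e$comparator, value)
    })
  }
  structure(list(wire = parse_group(cfg$wire, "wire"),
                 dhs = parse_group(cfg$dhs, "dhs")),
            class = "lc_ruleset")
}

# Evaluate one criterion list against a metrics list; returns failed ids.
apply_criteria <- function(metrics, criteria) {
  failed <- character(0)
  for (crit in criteria) {
    val <- metrics[[crit$metric]]
    if (is.null(val))
      abort_validation(crit$metric,
                       sprintf("metric required by criterion `%s` is missing", crit$id))
    ok <- switch(crit$comparator,
                 le = val <= crit$value,
                 ge = val >= crit$value,
                 lt = val < crit$value,
                 gt = val > crit$value,
                 eq = identical(as.vector(val), as.vector(crit$value)) ||
                   isTRUE(val == crit$value),
                 `in` = val %in% crit$value)
    if (!isTRUE(ok)) failed <- c(failed, crit$id)
  }
  failed
}

verdict <- function(failed) {
  structure(list(passed = length(failed) == 0L, failed_criteria = failed),
            class = "lc_verdict")
}

#' @export
print.lc_verdict <- function(x, ...) {
  if (x$passed) cat("procedure PASSED\n")
  else cat("procedure FAILED:", paste(x$failed_criteria, collapse = ", "), "\n")
  invisible(x)
}

#' Assess a K-wire procedure (CL0/CL1)
#'
#' @param metrics A [wire_metrics()] object.
#' @param ruleset An `lc_ruleset`; defaults to [default_ruleset()].
#' @return A list of class `lc_verdict` with `passed` and `failed_criteria`
#'   (empty iff passed; every violated criterion is listed).
#' @examples
#' assess_wire(wire_metrics(21, "center-center", FALSE, 1))$failed_criteria  # "tad"
#' @export
assess_wire <- function(metrics, ruleset = default_ruleset()) {
  if (!inherits(metrics, "wire_metrics"))
    abort_validation("metrics", "must be a wire_metrics object")
  verdict(apply_criteria(metrics, ruleset$wire))
}

#' Assess a full DHS procedure (CL2)
#'
#' @param metrics A [dhs_metrics()] object.
#' @inheritParams assess_wire
#' @return An `lc_verdict`.
#' @export
assess_dhs <- function(metrics, ruleset = default_ruleset()) {
  if (!inherits(metrics, "dhs_metrics"))
    abort_validation("metrics", "must be a dhs_metrics object")
  verdict(apply_criteria(metrics, ruleset$dhs))
}

# Assess by competency level: 0/1 -> wire rules, 2 -> dhs rules.
assess_at_level <- function(metrics, level, ruleset = default_ruleset()) {
  if (level %in% c(0L, 1L)) verdict(apply_criteria(metrics, ruleset$wire))
  else if (level == 2L) verdict(apply_criteria(metrics, ruleset$dhs))
  else abort_validation("level", "must be 0, 1 or 2")
}
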