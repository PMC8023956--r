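#' Build a pass/fail-by-career 2x2 contingency table
#'
#' Cross-classifies the program verdict (passed/failed) against the binary
#' career outcome (still in the specialty at follow-up, or left). The
#' observed cohort gives (13, 1, 9, 9): of 14 passing learners 13 stayed, of
#' 18 failing learners 9 left.
#'
#' @param passed_stayed,passed_left,failed_stayed,failed_left Non-negative
#'   counts.
#' @return A list of class `lc_ctable`; `as.matrix()` gives the 2x2 matrix
#'   with rows passed/failed and columns stayed/left.
#' @examples
#' tab <- contingency_table(13, 1, 9, 9)
#' as.matrix(tab)
#' @export
contingency_table <- function(passed_stayed, passed_left, failed_stayed, failed_left) {
  counts <- c(passed_stayed = passed_stayed, passed_left = passed_left,
              failed_stayed = failed_stayed, failed_left = failed_left)
  for (nm in names(counts)) check_count(counts[[nm]], nm, min = 0L)
  if (sum(counts) == 0L) abort_validation("counts", "table total must be > 0")
  structure(stats::setNames(as.list(as.integer(counts)), names(counts)),
            class = "lc_ctable")
}

#' @export
as.matrix.lc_ctable <- function(x, ...) {
  matrix(c(x$passed_stayed, x$passed_left, x$failed_stayed, x$failed_left),
         nrow = 2, byrow = TRUE,
         dimnames = list(verdict = c("passed", "failed"),
                         career = c("stayed", "left")))
}

#' @export
print.lc_ctable <- function(x, ...) {
  print(as.matrix(x))
  invisible(x)
}

#' Tabulate a simulated cohort into the 2x2 table
#'
#' @param cohort An `lc_cohort` from [simulate_cohort()], or its `learners`
#'   data frame.
#' @return An [contingency_table()] object.
#' @export
contingency_from_cohort <- function(cohort) {
  learners <- if (inherits(cohort, "lc_cohort")) cohort$learners else cohort
  if (!is.data.frame(learners) ||
      !all(c("passed_program", "career_stayed") %in% names(learners)))
    abort_validation("cohort", "needs learner columns passed_program and career_stayed")
  p <- learners$passed_program
  s <- learners$career_stayed
  contingency_table(sum(p & s), sum(p & !s), sum(!p & s), sum(!p & !s))
}

wilson_ci <- function(x, n, conf_level = 0.95) {
  # prop.test's warning concerns its chi-square test, not the score interval
  as.numeric(suppressWarnings(
    stats::prop.test(x, n, correct = FALSE, conf.level = conf_level)$conf.int))
}

clopper_pearson_ci <- function(x, n, conf_level = 0.95) {
  as.numeric(stats::binom.test(x, n, conf.level = conf_level)$conf.int)
}

#' Diagnostic accuracy of the program verdict for the career outcome
#'
#' Treats program pass as the positive test and staying in the specialty as
#' the positive outcome: PPV = passed_stayed / all passed, NPV =
#' failed_left / all failed, sensitivity = passed_stayed / all stayed,
#' specificity = failed_left / all left. Confidence intervals default to the
#' Wilson score interval (which reproduces published whole-percent intervals
#' such as NPV 29-71 and sensitivity 39-77 for the (13, 1, 9, 9) table);
#' Clopper-Pearson is available as an option. Note that interval conventions
#' differ between software near the boundary: for proportions close to 1 the
#' Wilson upper bound can sit a percentage point below intervals computed by
#' other methods.
#'
#' @param table An [contingency_table()].
#' @param ci_method `"wilson"` (default) or `"clopper-pearson"`.
#' @param conf_level Confidence level (default 0.95).
#' @return A data frame of class `lc_diagnostics` with columns `measure`,
#'   `numerator`, `denominator`, `estimate`, `lower`, `upper`; the CI method
#'   is attached as attribute `ci_method`.
#' @examples
#' diagnostic_measures(contingency_table(13, 1, 9, 9))
#' @export
diagnostic_measures <- function(table, ci_method = c("wilson", "clopper-pearson"),
                                conf_level = 0.95) {
  if (!inherits(table, "lc_ctable"))
    abort_validation("table", "must be an lc_ctable")
  ci_method <- match.arg(ci_method)
  ci_fun <- switch(ci_method, wilson = wilson_ci, `clopper-pearson` = clopper_pearson_ci)

  defs <- list(
    ppv         = c(table$passed_stayed, table$passed_stayed + table$passed_left),
    npv         = c(table$failed_left,   table$failed_stayed + table$failed_left),
    sensitivity = c(table$passed_stayed, table$passed_stayed + table$failed_stayed),
    specificity = c(table$failed_left,   table$passed_left + table$failed_left)
  )
  for (nm in names(defs)) {
    if (defs[[nm]][2] == 0L)
      stop(structure(
        class = c("lccusum_undefined_measure_error", "error", "condition"),
        list(message = sprintf("`%s` is undefined: its denominator is zero", nm),
             call = NULL)))
  }
  rows <- lapply(names(defs), function(nm) {
    x <- defs[[nm]][1]; n <- defs[[nm]][2]
    ci <- ci_fun(x, n, conf_level)
    data.frame(measure = nm, numerator = x, denominator = n,
               estimate = x / n, lower = ci[1], upper = ci[2])
  })
  out <- do.call(rbind, rows)
  attr(out, "ci_method") <- ci_method
  attr(out, "conf_level") <- conf_level
  class(out) <- c("lc_diagnostics", "data.frame")
  out
}

#' @export
print.lc_diagnostics <- function(x, digits = NULL, ...) {
  cat(sprintf("Diagnostic accuracy (%s %g%% CI)\n",
              attr(x, "ci_method"), 100 * attr(x, "conf_level")))
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-11s %2d/%2d = %3.0f%% (CI %.0f-%.0f)\n",
                x$measure[i], x$numerator[i], x$denominator[i],
                100 * x$estimate[i], 100 * x$lower[i], 100 * x$upper[i]))
  }
  invisible(x)
}

#' Fisher's exact test on the 2x2 table
#'
#' Two-sided p-value by exact hypergeometric enumeration with the
#' probability-mass ordering (the sum of the probabilities of all tables
#' with the observed margins no more probable than the observed one).
#'
#' @param table An [contingency_table()].
#' @return The two-sided p-value.
#' @examples
#' fisher_exact(contingency_table(13, 1, 9, 9))  # ~0.019
#' @export
fisher_exact <- function(table) {
  if (!inherits(table, "lc_ctable"))
    abort_validation("table", "must be an lc_ctable")
  m <- as.matrix(table)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    abort_validation("table", "all margins must be positive")
  stats::fisher.test(m)$p.value
}

#' Pearson chi-square test on the 2x2 table
#'
#' @param table An [contingency_table()].
#' @param correct Apply the Yates continuity correction (default `FALSE`).
#' @return A list with `statistic`, `p_value` and `df` (= 1).
#' @export
chi_square <- function(table, correct = FALSE) {
  if (!inherits(table, "lc_ctable"))
    abort_validation("table", "must be an lc_ctable")
  correct <- check_flag(correct, "correct")
  m <- as.matrix(table)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    abort_validation("table", "all margins must be positive")
  ct <- suppressWarnings(stats::chisq.test(m, correct = correct))
  list(statistic = unname(ct$statistic), p_value = ct$p.value,
       df = unname(ct$parameter))
}

#' Group summaries of cohort measures
#'
#' Summarises numeric cohort columns within the pass/fail-by-career groups:
#' mean with a t-based confidence interval, and median with range. A group
#' of one learner gets its mean with an undefined (NA) interval; an empty
#' group yields a row of missing values.
#'
#' @param learners A cohort `learners` data frame (or any data frame with
#'   the grouping columns).
#' @param value_cols Names of numeric columns to summarise (default: every
#'   numeric column other than ids and the grouping columns).
#' @param by Grouping column names (default pass/fail and career).
#' @param conf_level Confidence level for the mean (default 0.95).
#' @return A data frame with one row per group x variable: `n`, `mean`,
#'   `lower`, `upper`, `median`, `min`, `max`.
#' @export
group_summary <- function(learners,
                          value_cols = NULL,
                          by = c("passed_program", "career_stayed"),
                          conf_level = 0.95) {
  if (inherits(learners, "lc_cohort")) learners <- learners$learners
  if (!is.data.frame(learners)) abort_validation("learners", "must be a data frame")
  missing_by <- setdiff(by, names(learners))
  if (length(missing_by))
    abort_validation("by", paste("columns not found:", paste(missing_by, collapse = ", ")))
  if (is.null(value_cols)) {
    value_cols <- names(learners)[vapply(learners, is.numeric, logical(1))]
    value_cols <- setdiff(value_cols, c(by, "learner_id"))
  }
  bad <- setdiff(value_cols, names(learners))
  if (length(bad))
    abort_validation("value_cols", paste("columns not found:", paste(bad, collapse = ", ")))

  groups <- split(learners, learners[by], drop = FALSE)
  rows <- list()
  for (g in names(groups)) {
    df <- groups[[g]]
    for (v in value_cols) {
      x <- df[[v]]
      n <- length(x)
      if (n == 0L) {
        rows[[length(rows) + 1L]] <- data.frame(
          group = g, variable = v, n = 0L, mean = NA_real_,
          lower = NA_real_, upper = NA_real_,
          median = NA_real_, min = NA_real_, max = NA_real_)
        next
      }
      m <- mean(x)
      if (n >= 2L && stats::sd(x) > 0) {
        half <- stats::qt(1 - (1 - conf_level) / 2, n - 1L) * stats::sd(x) / sqrt(n)
        lo <- m - half; hi <- m + half
      } else if (n >= 2L) {
        lo <- m; hi <- m   # constant column: degenerate interval
      } else {
        lo <- NA_real_; hi <- NA_real_  # no variance estimate from one learner
      }
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, variable = v, n = n, mean = m, lower = lo, upper = hi,
        median = stats::median(x), min = min(x), max = max(x))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
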