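# Internal condition helpers. Validation errors carry the offending field name;
# contract errors mark misuse of an API invariant (e.g. updating an absorbed chart).

abort_validation <- function(field, msg) {
  stop(structure(
    class = c("lccusum_validation_error", "error", "condition"),
    list(message = sprintf("invalid `%s`: %s", field, msg), call = NULL)
  ))
}

abort_contract <- function(msg) {
  stop(structure(
    class = c("lccusum_contract_error", "error", "condition"),
    list(message = msg, call = NULL)
  ))
}

abort_unattainable <- function(msg) {
  stop(structure(
    class = c("lccusum_unattainable_error", "error", "condition"),
    list(message = msg, call = NULL)
  ))
}

abort_generation <- function(msg) {
  stop(structure(
    class = c("lccusum_generation_error", "error", "condition"),
    list(message = msg, call = NULL)
  ))
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

check_prob <- function(x, field, open = FALSE) {
  if (!is_number(x)) abort_validation(field, "must be a single finite number")
  if (open && (x <= 0 || x >= 1)) abort_validation(field, "must lie strictly in (0, 1)")
  if (!open && (x < 0 || x > 1)) abort_validation(field, "must lie in [0, 1]")
  x
}

check_count <- function(x, field, min = 1L) {
  if (!is_number(x) || x != round(x) || x < min)
    abort_validation(field, sprintf("must be an integer >= %d", min))
  as.integer(x)
}

check_flag <- function(x, field) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    abort_validation(field, "must be TRUE or FALSE")
  x
}

# Coerce a pass/fail stream to logical (TRUE = passed). Accepts logical or 0/1.
as_outcomes <- function(x, field = "outcomes") {
  if (length(x) == 0L) return(logical(0))
  if (is.logical(x)) {
    if (anyNA(x)) abort_validation(field, "contains missing values")
    return(x)
  }
  if (is.numeric(x)) {
    if (anyNA(x) || !all(x %in% c(0, 1)))
      abort_validation(field, "numeric outcomes must be 0 (fail) or 1 (pass)")
    return(x == 1)
  }
  abort_validation(field, "must be logical or 0/1")
}
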