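# Shared internal helpers: classed conditions, rounding, small utilities.

`%||%` <- function(x, y) if (is.null(x)) y else x

cig_abort <- function(message, class, ...) {
  stop(errorCondition(message, ..., class = c(class, "cig_error")))
}

#' Round half away from zero
#'
#' Ties at the last kept digit round away from zero (so 12.25 -> 12.3 at one
#' decimal), matching how percentages are conventionally printed in study
#' tables, rather than R's round-half-even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places kept.
#' @return rounded numeric vector.
#' @keywords internal
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

# One issue row; validators accumulate these into a data frame.
issue_row <- function(code, location, message) {
  data.frame(code = code, location = location, message = message,
             stringsAsFactors = FALSE)
}

no_issues <- function() {
  data.frame(code = character(), location = character(), message = character(),
             stringsAsFactors = FALSE)
}

bind_issues <- function(...) {
  do.call(rbind, Filter(Negate(is.null), list(...))) %||% no_issues()
}

# Deterministic scoped RNG: evaluates expr under `seed` without disturbing
# the caller's RNG state.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

# Render a parameter value for messages / narratives.
fmt_value <- function(v) {
  if (is.numeric(v)) format(v, trim = TRUE) else as.character(v)
}
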