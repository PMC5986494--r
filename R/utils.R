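# Internal validation helpers. All user-facing errors are rlang conditions with
# a class so callers (and tests) can distinguish invalid input from model
# inconsistencies discovered mid-run.

stop_invalid <- function(msg, ...) {
  abort(msg, class = "foplcea_invalid_input", ...)
}

stop_model <- function(msg, ...) {
  abort(msg, class = "foplcea_model_error", ...)
}

check_number <- function(x, name, lower = -Inf, upper = Inf, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      (finite && !is.finite(x)) || x < lower || x > upper) {
    stop_invalid(sprintf(
      "`%s` must be a single number in [%s, %s], got %s",
      name, format(lower), format(upper), paste(format(x), collapse = ", ")
    ))
  }
  invisible(x)
}

check_count <- function(x, name, lower = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower ||
      x != as.integer(x)) {
    stop_invalid(sprintf("`%s` must be an integer >= %d", name, lower))
  }
  invisible(as.integer(x))
}

# discount factor for amounts accruing at integer year t, base year 0
discount_factor <- function(t, rate) {
  (1 + rate)^(-t)
}
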