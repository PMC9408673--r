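# Internal helpers shared across modules.

sigmoid <- function(x) 1 / (1 + exp(-x))

logit <- function(p) log(p / (1 - p))

#' @noRd
stop_epiwatch <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "epiwatch_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

assert_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop_epiwatch(sprintf("`%s` must be a probability in [0, 1]", name),
                  "epiwatch_parameter_error")
  }
  invisible(x)
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 open_lower = FALSE, open_upper = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (if (open_lower) x > lower else x >= lower) &&
    (if (open_upper) x < upper else x <= upper)
  if (!ok) {
    stop_epiwatch(sprintf("`%s` must be a number in %s%s, %s%s", name,
                          if (open_lower) "(" else "[", lower, upper,
                          if (open_upper) ")" else "]"),
                  "epiwatch_parameter_error")
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
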