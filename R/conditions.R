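# Classed conditions so callers (and the CLI) can map failures to exit codes:
# validation errors -> 2, format errors -> 3, everything else -> 1.

stop_validation <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("volprec_validation_error", "volprec_error")))
}

stop_format <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("volprec_format_error", "volprec_error")))
}

stop_domain <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("volprec_domain_error", "volprec_error")))
}

stop_io <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("volprec_io_error", "volprec_error")))
}

# scalar argument checks ------------------------------------------------------

check_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop_domain("`%s` must be a single positive finite number", name)
  invisible(x)
}

check_nonnegative_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0)
    stop_domain("`%s` must be a single non-negative finite number", name)
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x < min || x != round(x))
    stop_domain("`%s` must be an integer >= %d", name, min)
  invisible(as.integer(x))
}
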