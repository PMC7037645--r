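# internal helpers: argument checking and error signalling

stop_config <- function(msg, field = NULL) {
  stop(structure(
    class = c("kidfit_config_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), field = field)
  ))
}

stop_input <- function(msg) {
  stop(structure(
    class = c("kidfit_input_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                config = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    x >= lower && x <= upper
  if (!ok) {
    msg <- sprintf("`%s` must be a single finite number in [%s, %s], got %s",
                   name, format(lower), format(upper),
                   paste(format(x), collapse = ", "))
    if (config) stop_config(msg, field = name) else stop_input(msg)
  }
  invisible(x)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a
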