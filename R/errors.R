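# Typed conditions so callers (and the CLI) can distinguish bad parameters,
# malformed inputs, degenerate data and numerical failures.

stop_dffocm <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "dffocm_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

stop_parameter <- function(msg, ...) stop_dffocm("dffocm_parameter_error", msg, ...)
stop_structural <- function(msg, ...) stop_dffocm("dffocm_structural_error", msg, ...)
stop_degenerate <- function(msg, ...) stop_dffocm("dffocm_degenerate_input_error", msg, ...)
stop_io <- function(msg, ...) stop_dffocm("dffocm_io_error", msg, ...)
stop_numerical <- function(msg, ...) stop_dffocm("dffocm_numerical_error", msg, ...)

warn_dffocm <- function(msg, ...) {
  warning(structure(
    class = c("dffocm_warning", "warning", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}
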