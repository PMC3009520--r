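# Classed conditions so callers (and the CLI exit-code mapping) can
# distinguish bad parameters from bad data from external-tool failures.

stop_fadpred <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "fadpred_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

stop_format      <- function(msg, ...) stop_fadpred("fadpred_format_error", msg, ...)
stop_parameter   <- function(msg, ...) stop_fadpred("fadpred_parameter_error", msg, ...)
stop_data        <- function(msg, ...) stop_fadpred("fadpred_data_error", msg, ...)
stop_consistency <- function(msg, ...) stop_fadpred("fadpred_consistency_error", msg, ...)
stop_tool        <- function(msg, ...) stop_fadpred("fadpred_tool_error", msg, ...)

warn_fadpred <- function(msg, ...) {
  warning(sprintf(msg, ...), call. = FALSE)
}
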