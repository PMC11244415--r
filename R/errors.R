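# Typed conditions used across the package. Every user-facing failure mode
# carries a class so callers (and tests) can distinguish malformed files,
# invalid data, bad configuration, and domain violations.

tt_abort <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "tapmetrics_error"), ...)
}

abort_format <- function(message, ...) tt_abort(message, "tapmetrics_format_error", ...)
abort_data <- function(message, ...) tt_abort(message, "tapmetrics_data_error", ...)
abort_config <- function(message, ...) tt_abort(message, "tapmetrics_config_error", ...)
abort_domain <- function(message, ...) tt_abort(message, "tapmetrics_domain_error", ...)
abort_insufficient <- function(message, ...) {
  tt_abort(message, "tapmetrics_insufficient_events_error", ...)
}
abort_degenerate <- function(message, ...) tt_abort(message, "tapmetrics_degenerate_error", ...)
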