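# Condition helpers. Every user-facing failure carries a class so callers
# (and the CLI exit-code mapping) can distinguish bad usage, bad data, and
# runtime faults without string-matching messages.

ax_stop <- function(msg, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "ataxic_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

err_validate <- function(msg) ax_stop(msg, "ataxic_validation_error")
err_parse    <- function(msg) ax_stop(msg, "ataxic_parse_error")
err_usage    <- function(msg) ax_stop(msg, "ataxic_usage_error")
err_state    <- function(msg) ax_stop(msg, "ataxic_state_error")
err_empty    <- function(msg) ax_stop(msg, "ataxic_empty_result_error")
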