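# Structured error conditions. Input/format/config errors are distinguished so
# the CLI can map them to exit code 2 while internal failures stay exit 1.

abort_input <- function(msg, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c("fireveg_input_error", "fireveg_error"),
                      call = call))
}

abort_format <- function(msg, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c("fireveg_format_error", "fireveg_input_error",
                                     "fireveg_error"), call = call))
}

abort_config <- function(msg, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c("fireveg_config_error", "fireveg_input_error",
                                     "fireveg_error"), call = call))
}

abort_training <- function(msg, diagnostics = NULL, call = sys.call(-1)) {
  cond <- errorCondition(msg, class = c("fireveg_training_error", "fireveg_error"),
                         call = call)
  cond$diagnostics <- diagnostics
  stop(cond)
}
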