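# Classed conditions used across the package so callers (and the CLI) can map
# failures to exit codes without string-matching messages.

stop_synbeats <- function(message, class) {
  stop(structure(
    list(message = message, call = sys.call(-1)),
    class = c(class, "synbeats_error", "error", "condition")
  ))
}

stop_schema <- function(message) stop_synbeats(message, "synbeats_schema_error")
stop_data <- function(message) stop_synbeats(message, "synbeats_data_error")
stop_insufficient <- function(message) stop_synbeats(message, "synbeats_insufficient_data_error")
stop_domain <- function(message) stop_synbeats(message, "synbeats_domain_error")
stop_contract <- function(message) stop_synbeats(message, "synbeats_contract_error")
stop_state <- function(message) stop_synbeats(message, "synbeats_state_error")
stop_metric <- function(message) stop_synbeats(message, "synbeats_undefined_metric_error")
stop_numeric <- function(message) stop_synbeats(message, "synbeats_numeric_error")

signal_empty_batch <- function(message) {
  warning(structure(
    list(message = message, call = NULL),
    class = c("synbeats_empty_batch", "warning", "condition")
  ))
}
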