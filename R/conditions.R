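# Classed error helpers so callers (and the CLI wrapper) can distinguish
# malformed files, bad configuration, and numerical failures.

stop_invalid <- function(msg, call. = FALSE) {
  stop(errorCondition(msg, class = c("vmdcal_invalid_input", "vmdcal_error", "error", "condition")))
}

stop_config <- function(msg) {
  stop(errorCondition(msg, class = c("vmdcal_config_error", "vmdcal_error", "error", "condition")))
}

stop_format <- function(msg) {
  stop(errorCondition(msg, class = c("vmdcal_format_error", "vmdcal_error", "error", "condition")))
}

stop_numerical <- function(msg) {
  stop(errorCondition(msg, class = c("vmdcal_numerical_error", "vmdcal_error", "error", "condition")))
}

check_matrix <- function(X, name = "X") {
  X <- as.matrix(X)
  if (!is.numeric(X) || !all(is.finite(X)))
    stop_invalid(sprintf("'%s' must be a finite numeric matrix", name))
  X
}
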