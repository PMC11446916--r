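# Classed conditions so callers (and the CLI) can distinguish failure modes.

stop_emdmn <- function(class, message, ...) {
  stop(errorCondition(message, ..., class = c(class, "emdmn_error")))
}

stop_degenerate <- function(message) stop_emdmn("emdmn_degenerate_image", message)
stop_config     <- function(message) stop_emdmn("emdmn_config_error", message)
stop_input      <- function(message) stop_emdmn("emdmn_input_error", message)
stop_placement  <- function(message) stop_emdmn("emdmn_placement_error", message)
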