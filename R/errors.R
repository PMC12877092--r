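# Classed conditions so callers (and tests) can distinguish failure modes.

mb_error <- function(msg, class) {
  stop(structure(
    class = c(class, "mbstage_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

stop_format     <- function(msg) mb_error(msg, "mbstage_format_error")
stop_validation <- function(msg) mb_error(msg, "mbstage_validation_error")
stop_param      <- function(msg) mb_error(msg, "mbstage_parameter_error")
stop_geometry   <- function(msg) mb_error(msg, "mbstage_geometry_error")
stop_degenerate <- function(msg) mb_error(msg, "mbstage_degenerate_error")

mb_warn <- function(msg) warning(msg, call. = FALSE)
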