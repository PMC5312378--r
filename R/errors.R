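# Classed error conditions so callers and tests can distinguish failure
# modes (configuration vs alignment vs inference vs degenerate input).

stop_mirsurv <- function(class, message, call. = FALSE) {
  stop(errorCondition(message, class = c(class, "mirsurv_error")))
}

config_error    <- function(msg) stop_mirsurv("mirsurv_config_error", msg)
alignment_error <- function(msg) stop_mirsurv("mirsurv_alignment_error", msg)
input_error     <- function(msg) stop_mirsurv("mirsurv_input_error", msg)
state_error     <- function(msg) stop_mirsurv("mirsurv_state_error", msg)
inference_error <- function(msg) stop_mirsurv("mirsurv_inference_error", msg)
rank_error      <- function(msg) stop_mirsurv("mirsurv_rank_error", msg)
floor_error     <- function(msg) stop_mirsurv("mirsurv_floor_error", msg)
degenerate_sample_error <- function(msg)
  stop_mirsurv("mirsurv_degenerate_sample_error", msg)
imputation_error <- function(msg) stop_mirsurv("mirsurv_imputation_error", msg)
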