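# Classed conditions so callers can distinguish structural file problems,
# unfittable spectra, and domain errors programmatically.

amk_stop <- function(subclass, msg, ..., call = sys.call(-1)) {
  stop(errorCondition(msg, ..., class = c(subclass, "amorphkit_error"),
                      call = call))
}

amk_format_error <- function(msg, ...) amk_stop("amorphkit_format_error", msg, ...)
amk_domain_error <- function(msg, ...) amk_stop("amorphkit_domain_error", msg, ...)
amk_not_fittable <- function(msg, ...) amk_stop("amorphkit_not_fittable", msg, ...)
amk_fit_failure  <- function(msg, ...) amk_stop("amorphkit_fit_failure", msg, ...)
amk_insufficient_data <- function(msg, ...) {
  amk_stop("amorphkit_insufficient_data", msg, ...)
}
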