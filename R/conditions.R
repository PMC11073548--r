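# Classed conditions so callers can branch on failure mode rather than
# matching message text.

abort_topofilt <- function(message, class) {
  stop(errorCondition(message, class = c(class, "topofilt_error")))
}

warn_topofilt <- function(message, class = "topofilt_warning") {
  warning(warningCondition(message, class = c(class, "topofilt_warning")))
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

is_count <- function(x, min = 1L) {
  is_scalar_number(x) && x >= min && x == round(x)
}
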