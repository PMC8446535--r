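#' Uniformly sampled signal container
#'
#' Light S3 container for a uniformly sampled voltage or current trace.
#' Most analysis functions accept either a `voltage_trace` or a plain
#' numeric vector plus a sampling rate.
#'
#' @param values Numeric vector of samples.
#' @param fs Sampling rate in Hz.
#' @param units Unit label, e.g. `"mV"`, `"pA"` or `"uV"`.
#' @param t0 Time of the first sample in seconds.
#' @return An object of class `voltage_trace` with fields `values`, `fs`,
#'   `units`, `t0`.
#' @export
voltage_trace <- function(values, fs, units = "mV", t0 = 0) {
  if (!is.numeric(values)) invalid_argument("`values` must be numeric")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    invalid_argument("`fs` must be a positive scalar")
  structure(list(values = as.numeric(values), fs = fs, units = units, t0 = t0),
            class = "voltage_trace")
}

#' @export
print.voltage_trace <- function(x, ...) {
  cat(sprintf("<voltage_trace> %d samples @ %g Hz (%.3f s), units %s\n",
              length(x$values), x$fs, length(x$values) / x$fs, x$units))
  invisible(x)
}

#' @export
length.voltage_trace <- function(x) length(x$values)

# Resolve (x, fs) from either a voltage_trace/current_stimulus or a numeric
# vector plus explicit fs.
trace_values <- function(x, fs = NULL) {
  if (inherits(x, c("voltage_trace", "current_stimulus"))) {
    list(values = x$values, fs = x$fs)
  } else {
    if (is.null(fs)) invalid_argument("`fs` must be supplied for a plain vector")
    list(values = as.numeric(x), fs = fs)
  }
}

#' Sorted spike time container
#'
#' @param times Numeric vector of event times in seconds.
#' @return A numeric vector of class `spike_train`, sorted increasingly.
#' @export
spike_train <- function(times) {
  if (length(times) && (!is.numeric(times) || any(!is.finite(times))))
    invalid_argument("spike times must be finite numbers")
  if (any(times < 0)) invalid_argument("spike times must be non-negative")
  structure(sort(as.numeric(times)), class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %d spikes", length(unclass(x))))
  if (length(x)) cat(sprintf(" over %.3f s", max(unclass(x)) - min(unclass(x))))
  cat("\n")
  invisible(x)
}
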