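#' Zero-phase elliptic band-pass filter
#'
#' Second-order elliptic band-pass (default 0.3-3 kHz) applied
#' forward-backward for zero phase, as used to condition extracellular
#' field recordings before spike detection. Ripple and attenuation
#' default to 0.1 dB passband / 40 dB stopband.
#'
#' @param x Numeric trace or `voltage_trace`.
#' @param fs Sampling rate, Hz (for plain vectors). Must exceed twice the
#'   upper band edge.
#' @param band Passband edges, Hz.
#' @param order Filter order per design (default 2).
#' @param rp,rs Passband ripple and stopband attenuation, dB.
#' @return Filtered numeric vector.
#' @export
bandpass_elliptic <- function(x, fs = NULL, band = c(300, 3000), order = 2,
                              rp = 0.1, rs = 40) {
  tr <- trace_values(x, fs)
  if (tr$fs <= 2 * band[2])
    invalid_argument("sampling rate must exceed twice the upper band edge")
  if (band[1] <= 0 || band[1] >= band[2])
    invalid_argument("band edges must satisfy 0 < low < high")
  flt <- signal::ellip(order, rp, rs, band / (tr$fs / 2), type = "pass")
  as.numeric(signal::filtfilt(flt, tr$values))
}

#' Robust noise threshold from the median absolute deviation
#'
#' Computes `Thr = k * median(|x|) / 0.6745`. The scaled median absolute
#' deviation `H = median(|x|)/0.6745` is a consistent estimator of the
#' noise SD for Gaussian noise, insensitive to the spikes themselves.
#'
#' @param x Filtered trace (numeric or `voltage_trace`).
#' @param k Threshold multiplier (default 5; 4 is the conventional
#'   fallback when visual inspection shows missed events).
#' @return Threshold in the units of `x`, with attribute `H`.
#' @export
mad_threshold <- function(x, k = 5) {
  v <- if (inherits(x, "voltage_trace")) x$values else as.numeric(x)
  if (length(v) == 0L) invalid_argument("empty trace")
  if (k <= 0) invalid_argument("`k` must be positive")
  H <- stats::median(abs(v)) / 0.6745
  structure(k * H, H = H)
}

#' Extracellular spike detection by MAD thresholding
#'
#' Band-passes the trace ([bandpass_elliptic()]), derives a threshold
#' `k * H` from the median absolute deviation, and returns the times of
#' local extrema exceeding it in the chosen polarity, thinned to a
#' refractory minimum separation (larger peaks win).
#'
#' @param x Raw extracellular trace (numeric or `voltage_trace`).
#' @param fs Sampling rate, Hz.
#' @param k Threshold multiplier (default 5).
#' @param band Band-pass edges, Hz.
#' @param polarity `"negative"` (default for extracellular spikes),
#'   `"positive"` or `"absolute"`.
#' @param refractory Minimum peak separation, s (default 1 ms).
#' @param filter_order Elliptic filter order.
#' @return `spike_train` of peak times (s), with attributes `threshold`
#'   and `H`.
#' @export
detect_spikes <- function(x, fs = NULL, k = 5, band = c(300, 3000),
                          polarity = c("negative", "positive", "absolute"),
                          refractory = 1e-3, filter_order = 2) {
  polarity <- match.arg(polarity)
  tr <- trace_values(x, fs)
  fx <- bandpass_elliptic(tr$values, tr$fs, band = band, order = filter_order)
  thr <- mad_threshold(fx, k)
  sig <- switch(polarity, negative = -fx, positive = fx, absolute = abs(fx))
  idx <- find_peaks(sig, as.numeric(thr), refractory * tr$fs)
  out <- spike_train((idx - 1L) / tr$fs)
  attr(out, "threshold") <- as.numeric(thr)
  attr(out, "H") <- attr(thr, "H")
  out
}

#' Detect spontaneous synaptic potentials
#'
#' Band-passes a membrane-potential recording (default 2-100 Hz,
#' second-order Butterworth, zero phase) and detects positive deflections
#' exceeding `pos_thr` as EPSPs and negative deflections exceeding
#' `neg_thr` in magnitude as IPSPs. Peaks closer than `min_sep` are
#' merged, keeping the larger. When thresholds are not supplied they
#' default to `k * H` of the filtered trace (a programmatic stand-in for
#' manual threshold adjustment).
#'
#' @param x Numeric trace or `voltage_trace` (mV).
#' @param fs Sampling rate, Hz.
#' @param pos_thr,neg_thr Positive/negative thresholds, mV (magnitudes,
#'   both > 0). `NULL` uses `k * H`.
#' @param band Pre-filter edges, Hz.
#' @param min_sep Minimum event separation, s.
#' @param k MAD multiplier for automatic thresholds (default 3).
#' @param edge_guard Time excluded at each end of the trace, s; the
#'   zero-phase high-pass leaves settling transients there (scale
#'   `1/(2*pi*band[1])`).
#' @return List with `epsp_times` and `ipsp_times` (`spike_train`s, s).
#' @export
detect_psps <- function(x, fs = NULL, pos_thr = NULL, neg_thr = NULL,
                        band = c(2, 100), min_sep = 0.005, k = 3,
                        edge_guard = 0.25) {
  tr <- trace_values(x, fs)
  bf <- signal::butter(2, band / (tr$fs / 2), type = "pass")
  # demean first: the resting-potential offset would otherwise drive large
  # high-pass settling transients at the trace edges
  fx <- as.numeric(signal::filtfilt(bf, tr$values - mean(tr$values)))
  if (is.null(pos_thr) || is.null(neg_thr)) {
    auto <- as.numeric(mad_threshold(fx, k))
    pos_thr <- pos_thr %||% auto
    neg_thr <- neg_thr %||% auto
  }
  if (pos_thr <= 0 || neg_thr <= 0)
    invalid_argument("thresholds must be positive in magnitude")
  ei <- find_peaks(fx, pos_thr, min_sep * tr$fs)
  ii <- find_peaks(-fx, neg_thr, min_sep * tr$fs)
  lo <- edge_guard * tr$fs
  hi <- length(fx) - edge_guard * tr$fs
  ei <- ei[ei > lo & ei < hi]
  ii <- ii[ii > lo & ii < hi]
  list(epsp_times = spike_train((ei - 1L) / tr$fs),
       ipsp_times = spike_train((ii - 1L) / tr$fs))
}

#' Remove target spikes coincident with reference spikes
#'
#' Deletes target timestamps falling within `window` (closed interval,
#' default +/- 200 microseconds) of any reference timestamp, preventing a
#' reference unit from contaminating a nearby multi-unit recording.
#' Idempotent; order preserved.
#'
#' @param target,reference Sorted spike time vectors, s.
#' @param window Half-width of the deletion interval, s.
#' @return `spike_train` of surviving target times.
#' @export
dedup_timestamps <- function(target, reference, window = 2e-4) {
  target <- as.numeric(target)
  reference <- as.numeric(reference)
  if (length(target) == 0L || length(reference) == 0L)
    return(spike_train(target))
  i <- findInterval(target, reference)
  n <- length(reference)
  d_lo <- ifelse(i >= 1L, target - reference[pmax(i, 1L)], Inf)
  d_hi <- ifelse(i < n, reference[pmin(i + 1L, n)] - target, Inf)
  # closed interval; the epsilon absorbs floating-point representation of
  # boundary-coincident timestamps
  keep <- pmin(d_lo, d_hi) > window + 1e-12
  spike_train(target[keep])
}

#' Spike-triggered average of an injected current
#'
#' Reverse correlation: averages current segments aligned to spike times
#' over a pre/post window, and extracts waveform features from the
#' unfiltered average — the pre-spike peak, the latency from the peak to
#' the spike, and the maximum rising slope (first derivative) of the
#' pre-spike limb.
#'
#' @param current Injected current (numeric, `current_stimulus` or
#'   `voltage_trace`), pA.
#' @param spikes Spike times, s.
#' @param fs Sampling rate, Hz.
#' @param window Window around each spike in ms, e.g. `c(-10, 5)`.
#' @return An object of class `sta_result`: `t_ms`, `sta`, `peak` (pA),
#'   `latency_to_peak` (ms), `max_rising_slope` (pA/ms), `n_spikes`.
#' @export
spike_triggered_average <- function(current, spikes, fs = NULL,
                                    window = c(-10, 5)) {
  tr <- trace_values(current, fs)
  v <- tr$values
  i0 <- round(window[1] / 1000 * tr$fs)
  i1 <- round(window[2] / 1000 * tr$fs)
  idx <- round(as.numeric(spikes) * tr$fs) + 1L
  usable <- idx + i0 >= 1L & idx + i1 <= length(v)
  if (!any(usable))
    undefined_result("no spike with a full averaging window inside the trace")
  idx <- idx[usable]
  mat <- t(vapply(idx, function(i) v[(i + i0):(i + i1)],
                  numeric(i1 - i0 + 1L)))
  sta <- colMeans(mat)
  t_ms <- (i0:i1) / tr$fs * 1000
  pre <- which(t_ms < 0)
  pk_i <- pre[which.max(sta[pre])]
  dt_ms <- 1000 / tr$fs
  slopes <- diff(sta) / dt_ms
  pre_sl <- which(t_ms[-1] <= t_ms[pk_i])
  structure(list(t_ms = t_ms, sta = sta,
                 peak = sta[pk_i],
                 latency_to_peak = -t_ms[pk_i],
                 max_rising_slope = max(slopes[pre_sl]),
                 n_spikes = length(idx)),
            class = "sta_result")
}

#' @export
print.sta_result <- function(x, ...) {
  cat(sprintf(
    "<sta_result> n = %d spikes; peak %.2f pA at %.2f ms before spike; max slope %.2f pA/ms\n",
    x$n_spikes, x$peak, x$latency_to_peak, x$max_rising_slope))
  invisible(x)
}
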