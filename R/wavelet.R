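#' Construct a Morlet filtering wavelet
#'
#' Builds a sampled Morlet wavelet — a sine carrier multiplied by a
#' Gaussian envelope — whose power spectrum has a prescribed full width at
#' half maximum (the frequency-domain bandwidth). The envelope standard
#' deviation follows from the bandwidth as
#' \eqn{\sigma = \sqrt{\ln 2} / (\pi \cdot \mathrm{FWHM})}, and the
#' amplitude is normalized so that a unit sinusoid at the center frequency
#' passes a single convolution with gain 1.
#'
#' @param f Center (carrier) frequency, Hz.
#' @param dt Sampling interval, s. Must satisfy `dt < 1/(10*f)`.
#' @param bandwidth Frequency-domain FWHM of the kernel power spectrum, Hz.
#'   Default 0.75 Hz, the value used for membrane-noise band decomposition.
#' @param n_sigma Half support of the kernel in envelope SDs (>= 4).
#' @return An object of class `morlet_kernel` with fields `kernel`, `t`,
#'   `f`, `sigma`, `bandwidth`, `dt` and the normalization `amplitude`.
#' @export
make_morlet <- function(f, dt, bandwidth = 0.75, n_sigma = 4) {
  if (!is.numeric(f) || f <= 0) invalid_argument("`f` must be positive")
  if (!is.numeric(dt) || dt <= 0) invalid_argument("`dt` must be positive")
  if (bandwidth <= 0) invalid_argument("`bandwidth` must be positive")
  if (dt >= 1 / (10 * f))
    invalid_argument("`dt` too coarse for carrier frequency: need dt < 1/(10 f)")
  if (f <= bandwidth)
    invalid_argument("bandwidth unreachable: center frequency must exceed the bandwidth")
  if (n_sigma < 4) invalid_argument("`n_sigma` must be at least 4")

  sigma <- sqrt(log(2)) / (pi * bandwidth)
  L <- ceiling(n_sigma * sigma / dt)
  t <- (-L:L) * dt
  k0 <- sin(2 * pi * f * t) * exp(-t^2 / (2 * sigma^2))
  # single-pass gain for a sinusoid at f under discrete convolution
  gain <- Mod(sum(k0 * exp(-2i * pi * f * t)))
  a <- 1 / gain
  structure(list(kernel = a * k0, t = t, f = f, sigma = sigma,
                 bandwidth = bandwidth, dt = dt, amplitude = a),
            class = "morlet_kernel")
}

#' @export
print.morlet_kernel <- function(x, ...) {
  cat(sprintf("<morlet_kernel> f = %g Hz, bandwidth = %g Hz, sigma = %.4f s, %d samples\n",
              x$f, x$bandwidth, x$sigma, length(x$kernel)))
  invisible(x)
}

#' Measured frequency-domain FWHM of a Morlet kernel
#'
#' Computes the kernel power spectrum on a zero-padded grid and measures
#' its full width at half maximum by linear interpolation of the
#' half-power crossings.
#'
#' @param mw A `morlet_kernel`.
#' @param resolution Frequency grid spacing, Hz (default 0.01).
#' @return FWHM in Hz.
#' @export
morlet_fwhm <- function(mw, resolution = 0.01) {
  stopifnot(inherits(mw, "morlet_kernel"))
  n <- length(mw$kernel)
  N <- stats::nextn(max(n, ceiling(1 / (resolution * mw$dt))), 2)
  P <- Mod(stats::fft(c(mw$kernel, rep(0, N - n))))^2
  fr <- (0:(N - 1)) / (N * mw$dt)
  keep <- fr <= 1 / (2 * mw$dt)
  P <- P[keep]; fr <- fr[keep]
  i0 <- which.max(P)
  half <- P[i0] / 2
  # walk left and right to the half-power crossings
  il <- i0
  while (il > 1L && P[il] > half) il <- il - 1L
  ir <- i0
  while (ir < length(P) && P[ir] > half) ir <- ir + 1L
  fl <- fr[il] + (half - P[il]) / (P[il + 1L] - P[il]) * (fr[il + 1L] - fr[il])
  fu <- fr[ir - 1L] + (half - P[ir - 1L]) / (P[ir] - P[ir - 1L]) * (fr[ir] - fr[ir - 1L])
  fu - fl
}

#' Zero-phase Morlet band filtering
#'
#' Band-limits a trace around `f` by forward-backward convolution with a
#' Morlet wavelet. The two passes cancel the 90-degree phase of the
#' odd-symmetric kernel, giving a zero-phase output of the same length
#' with unit gain at the center frequency. Edges are reflection-padded;
#' the first and last kernel half-lengths are edge-contaminated and their
#' extent is reported in the `edge_samples` attribute.
#'
#' @param x Numeric trace or `voltage_trace`.
#' @param f Band center frequency, Hz.
#' @param fs Sampling rate, Hz (ignored if `x` is a `voltage_trace`).
#' @param bandwidth Frequency-domain FWHM, Hz (default 0.75).
#' @return Filtered numeric vector, same length as the input.
#' @export
wavelet_filter <- function(x, f, fs = NULL, bandwidth = 0.75) {
  tr <- trace_values(x, fs)
  v <- tr$values
  mw <- make_morlet(f, 1 / tr$fs, bandwidth)
  k <- mw$kernel
  L <- (length(k) - 1L) %/% 2L
  n <- length(v)
  if (n < length(k))
    invalid_argument("trace shorter than the wavelet kernel")
  left <- v[(L + 1L):2L]
  right <- v[(n - 1L):(n - L)]
  xp <- c(left, v, right)
  y <- conv_same(xp, k)
  y <- rev(conv_same(rev(y), k))
  out <- y[(L + 1L):(L + n)]
  attr(out, "edge_samples") <- L
  out
}

#' Per-epoch band amplitude (6 x SD)
#'
#' Divides a recording into fixed-length epochs, band-filters it at each
#' requested center frequency, and quantifies the band's peak-to-peak
#' amplitude in each full epoch as six standard deviations of the filtered
#' signal. Trailing samples not filling a complete epoch are dropped.
#'
#' @param x Numeric trace or `voltage_trace` (mV).
#' @param freqs Vector of band center frequencies, Hz.
#' @param fs Sampling rate, Hz (ignored for a `voltage_trace`).
#' @param epoch Epoch length in seconds (default 30).
#' @param bandwidth Frequency-domain FWHM of each band, Hz.
#' @return A data frame with columns `center_freq`, `epoch_index`, `p2p`.
#' @export
band_amplitude <- function(x, freqs, fs = NULL, epoch = 30, bandwidth = 0.75) {
  tr <- trace_values(x, fs)
  n_per <- floor(epoch * tr$fs)
  n_ep <- floor(length(tr$values) / n_per)
  if (n_ep < 1L)
    invalid_argument("trace shorter than one epoch")
  out <- lapply(freqs, function(f) {
    filt <- wavelet_filter(tr$values, f, tr$fs, bandwidth)
    p2p <- vapply(seq_len(n_ep), function(i) {
      seg <- filt[((i - 1L) * n_per + 1L):(i * n_per)]
      6 * stats::sd(seg)
    }, numeric(1))
    data.frame(center_freq = f, epoch_index = seq_len(n_ep), p2p = p2p)
  })
  do.call(rbind, out)
}

#' Discrete-time Ornstein-Uhlenbeck series
#'
#' First-order autoregressive recursion
#' \eqn{X_{n+1} = \lambda_1 X_n + \lambda_2 \xi_{n+1}} with standard
#' Gaussian innovations and \eqn{X_0 = 0}.
#'
#' @param n Number of samples to return (\eqn{X_1, \dots, X_n}).
#' @param lambda1 Autocorrelation parameter, `0 <= lambda1 < 1`.
#' @param lambda2 Innovation amplitude, `>= 0`.
#' @param seed Optional integer seed for reproducibility.
#' @return Numeric vector of length `n`.
#' @export
ou_series <- function(n, lambda1, lambda2, seed = NULL) {
  if (!is.numeric(n) || n < 1) invalid_argument("`n` must be positive")
  if (lambda1 >= 1) invalid_argument("`lambda1` >= 1 is non-stationary")
  if (lambda1 < 0) invalid_argument("`lambda1` must be in [0, 1)")
  if (lambda2 < 0) invalid_argument("`lambda2` must be non-negative")
  with_seed(seed, {
    xi <- stats::rnorm(n)
    as.numeric(stats::filter(lambda2 * xi, lambda1, method = "recursive"))
  })
}

#' Wavelet-filtered noise current stimulus
#'
#' Convolves a Morlet wavelet with a discrete-time Ornstein-Uhlenbeck
#' process and rescales the result so that its 6 x SD peak-to-peak
#' amplitude equals `target_p2p`. The stimulus power spectrum peaks at
#' the wavelet center frequency.
#'
#' @param f Stimulus center frequency, Hz.
#' @param duration Duration, s.
#' @param dt Sampling interval, s.
#' @param target_p2p Target peak-to-peak amplitude (6 x SD), pA.
#' @param lambda1,lambda2 OU parameters (see [ou_series()]); the wavelet
#'   convolution dominates the spectrum so `lambda1` mainly shapes
#'   realization-to-realization variability.
#' @param bandwidth Wavelet frequency-domain FWHM, Hz.
#' @param seed Optional integer seed.
#' @return A `current_stimulus` object with fields `values` (pA), `fs`,
#'   `f`, `target_p2p`.
#' @export
make_noise_stimulus <- function(f, duration, dt, target_p2p,
                                lambda1 = 0.8, lambda2 = 1,
                                bandwidth = 0.75, seed = NULL) {
  if (duration <= 0 || dt <= 0) invalid_argument("duration and dt must be positive")
  n <- round(duration / dt)
  ou <- ou_series(n, lambda1, lambda2, seed = seed)
  mw <- make_morlet(f, dt, bandwidth)
  stim <- conv_same(ou, mw$kernel)
  s <- stats::sd(stim)
  if (s > 0) stim <- stim * target_p2p / (6 * s)
  structure(list(values = stim, fs = 1 / dt, f = f, target_p2p = target_p2p,
                 units = "pA"),
            class = "current_stimulus")
}

#' @export
print.current_stimulus <- function(x, ...) {
  cat(sprintf("<current_stimulus> %d samples @ %g Hz, center %g Hz, p2p %g %s\n",
              length(x$values), x$fs, x$f %||% NA, x$target_p2p %||% NA,
              x$units %||% ""))
  invisible(x)
}

#' Spike-stimulus phase coherence
#'
#' Phase-locking (vector-strength) measure of coherence between spike
#' times and a narrow-band stimulus: the modulus of the mean unit phase
#' vector of the stimulus analytic-signal phase sampled at spike times.
#' Bounded in \[0, 1\]; 1 means all spikes fall at an identical stimulus
#' phase.
#'
#' @param spikes Spike times, s.
#' @param stimulus `current_stimulus` or numeric vector.
#' @param fs Sampling rate, Hz (for plain vectors).
#' @param f Optional center frequency; if given, the stimulus is wavelet
#'   band-filtered at `f` before phase extraction.
#' @return Coherence in \[0, 1\].
#' @export
spike_field_coherence <- function(spikes, stimulus, fs = NULL, f = NULL) {
  tr <- trace_values(stimulus, fs)
  if (length(spikes) == 0L)
    undefined_result("coherence is undefined without spikes")
  v <- tr$values
  if (!is.null(f)) v <- wavelet_filter(v, f, tr$fs)
  idx <- round(as.numeric(spikes) * tr$fs) + 1L
  if (any(idx < 1L | idx > length(v)))
    invalid_argument("spike times fall outside the stimulus")
  phase <- Arg(analytic_signal(v))
  Mod(mean(exp(1i * phase[idx])))
}

#' Spectral center of a mean synaptic-potential waveform
#'
#' Fits a Gaussian to the positive-frequency power spectrum of a
#' baseline-subtracted mean waveform and returns the fitted center
#' frequency. Spontaneous synaptic potentials analysed through a
#' band-passed recording chain have band-limited spectra that are well
#' summarized this way.
#'
#' @param w Baseline-subtracted mean waveform (e.g. from
#'   [mean_event_waveform()]).
#' @param dt Sampling interval, s.
#' @param fmax Upper frequency bound of the fit, Hz.
#' @param resolution Spectral grid resolution, Hz.
#' @return A list with `center_hz`, `sigma_hz`, `r2` and `ok`. When the
#'   spectrum is DC-dominated or the fit fails, `ok` is `FALSE` and the
#'   center is `NA`; a non-unimodal spectrum triggers a warning and the
#'   best local fit is returned.
#' @export
psp_spectrum_center <- function(w, dt, fmax = 100, resolution = 0.25) {
  w <- as.numeric(w)
  if (length(w) < 8L) invalid_argument("waveform too short")
  n <- length(w)
  dc <- mean(w)
  if (stats::sd(w) > 0 && abs(dc) > 2 * stats::sd(w)) {
    warning("waveform is DC-dominated; Gaussian center fit failed")
    return(list(center_hz = NA_real_, sigma_hz = NA_real_, r2 = NA_real_,
                ok = FALSE))
  }
  # remove the window mean: truncation would otherwise leak the snippet's
  # DC component into the low-frequency bins
  w <- w - dc
  N <- stats::nextn(max(n, ceiling(1 / (resolution * dt))), 2)
  P <- Mod(stats::fft(c(w, rep(0, N - n))))^2
  fr <- (0:(N - 1)) / (N * dt)
  keep <- fr > 0 & fr <= fmax
  P <- P[keep]; fr <- fr[keep]
  i0 <- which.max(P)
  if (i0 <= 2L) {
    warning("spectrum is DC-dominated; Gaussian center fit failed")
    return(list(center_hz = NA_real_, sigma_hz = NA_real_, r2 = NA_real_,
                ok = FALSE))
  }
  # unimodality check on a lightly smoothed spectrum
  sm <- stats::filter(P, rep(1 / 5, 5), sides = 2)
  sm[is.na(sm)] <- 0
  pk <- which(diff(sign(diff(sm))) == -2) + 1L
  pk <- pk[sm[pk] > 0.2 * max(sm)]
  if (length(pk) > 1L)
    warning("power spectrum is not unimodal; returning best local Gaussian fit")
  centroid <- sum(fr * P) / sum(P)
  spread <- sqrt(sum((fr - centroid)^2 * P) / sum(P))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      P ~ A * exp(-(fr - c0)^2 / (2 * s0^2)),
      start = list(A = max(P), c0 = centroid, s0 = spread),
      lower = c(0, 0, 1e-3),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    warning("Gaussian spectrum fit did not converge")
    return(list(center_hz = NA_real_, sigma_hz = NA_real_, r2 = NA_real_,
                ok = FALSE))
  }
  cf <- coef(fit)
  # a center below ~two Rayleigh widths of the analysis window cannot be
  # told apart from a DC/step component
  f_resolve <- 2 / (n * dt)
  ok <- cf[["c0"]] >= f_resolve
  if (!ok)
    warning(sprintf(
      "fitted center %.2f Hz is below the %.2f Hz spectral resolution of the window; fit failure flagged",
      cf[["c0"]], f_resolve))
  list(center_hz = unname(cf["c0"]), sigma_hz = unname(cf["s0"]),
       r2 = r_squared(P, fitted(fit)), ok = ok)
}

#' Mean event-aligned waveform from a recording
#'
#' Band-passes a trace (default 2-100 Hz, second-order Butterworth applied
#' forward-backward), extracts snippets around each event time, averages
#' them, and subtracts the mean of the pre-event baseline portion. This
#' mirrors the analysis chain used for spontaneous synaptic potentials,
#' whose detection operates on the 2-100 Hz band.
#'
#' @param x Numeric trace or `voltage_trace`.
#' @param times Event times, s.
#' @param fs Sampling rate, Hz (for plain vectors).
#' @param window Snippet window around each event, s (default -50 ms to
#'   +100 ms).
#' @param band Band-pass edges in Hz, or `NULL` to skip filtering.
#' @param baseline Pre-event window used for baseline subtraction, s.
#' @return Mean waveform vector with a `t` attribute (s, event at 0).
#' @export
mean_event_waveform <- function(x, times, fs = NULL, window = c(-0.05, 0.1),
                                band = c(2, 100), baseline = c(-0.05, -0.02)) {
  tr <- trace_values(x, fs)
  v <- tr$values
  if (!is.null(band)) {
    bf <- signal::butter(2, band / (tr$fs / 2), type = "pass")
    v <- signal::filtfilt(bf, v)
  }
  i0 <- round(window[1] * tr$fs)
  i1 <- round(window[2] * tr$fs)
  idx <- round(as.numeric(times) * tr$fs) + 1L
  usable <- idx + i0 >= 1L & idx + i1 <= length(v)
  if (!any(usable)) undefined_result("no event with a full window inside the trace")
  mat <- t(vapply(idx[usable], function(i) v[(i + i0):(i + i1)],
                  numeric(i1 - i0 + 1L)))
  w <- colMeans(mat)
  t <- (i0:i1) / tr$fs
  base <- t >= baseline[1] & t <= baseline[2]
  if (any(base)) w <- w - mean(w[base])
  attr(w, "t") <- t
  w
}
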