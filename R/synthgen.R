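#' Synaptic-potential kernel specification
#'
#' Difference-of-exponentials kernel
#' `k(t) = amp_norm * (exp(-t/decay_tau) - exp(-t/rise_tau))`, scaled so
#' its extremum equals `amplitude` (positive for EPSP-like, negative for
#' IPSP-like events).
#'
#' @param amplitude Peak amplitude, mV (nonzero).
#' @param rise_tau Rise time constant, ms (> 0).
#' @param decay_tau Decay time constant, ms (> rise_tau).
#' @return An object of class `psp_kernel_spec`.
#' @export
psp_kernel_spec <- function(amplitude, rise_tau, decay_tau) {
  if (amplitude == 0) invalid_argument("`amplitude` must be nonzero")
  if (rise_tau <= 0) invalid_argument("`rise_tau` must be positive")
  if (decay_tau <= rise_tau)
    invalid_argument("`decay_tau` must exceed `rise_tau`")
  structure(list(amplitude = amplitude, rise_tau = rise_tau,
                 decay_tau = decay_tau),
            class = "psp_kernel_spec")
}

#' Default EPSP/IPSP kernels
#'
#' Kernel time constants chosen so that mean event waveforms extracted
#' through the 2-100 Hz analysis band have power spectra whose fitted
#' Gaussian centers match the observed spontaneous EPSP/IPSP spectral
#' centers (about 23 and 33 Hz respectively); see the methods vignette.
#'
#' @return A `psp_kernel_spec`.
#' @export
default_epsp_kernel <- function() psp_kernel_spec(1.0, 0.8, 3.0)

#' @rdname default_epsp_kernel
#' @export
default_ipsp_kernel <- function() psp_kernel_spec(-1.0, 0.4, 1.0)

# Sampled kernel (unit events), t in seconds.
sample_psp_kernel <- function(kern, dt) {
  tau_r <- kern$rise_tau / 1000
  tau_d <- kern$decay_tau / 1000
  t <- seq(0, 8 * tau_d, by = dt)
  k <- exp(-t / tau_d) - exp(-t / tau_r)
  k * kern$amplitude / max(abs(k))
}

#' Synthetic membrane-potential trace with Poisson synaptic events
#'
#' Generates a resting-potential trace carrying Poisson trains of
#' EPSP-like and IPSP-like events (difference-of-exponentials kernels)
#' plus white Gaussian membrane noise, together with the ground-truth
#' event times. Default rates are the spontaneous EPSC/IPSC control
#' rates (4.1 and 6.8 Hz).
#'
#' @param duration Trace duration, s.
#' @param dt Sampling interval, s (default 1 ms).
#' @param epsp_rate,ipsp_rate Poisson event rates, Hz.
#' @param epsp_kernel,ipsp_kernel [psp_kernel_spec()] objects.
#' @param v_rest Baseline potential, mV (default -65, the holding
#'   potential).
#' @param noise_sd Membrane noise SD, mV (a free parameter of the
#'   emulation).
#' @param seed Optional integer seed; identical seeds give identical
#'   output.
#' @return List with `trace` (a [voltage_trace()]) and `truth` (fields
#'   `epsp_times`, `ipsp_times`, `spike_times`, `seed`).
#' @export
generate_psp_trace <- function(duration, dt = 1e-3,
                               epsp_rate = 4.1, ipsp_rate = 6.8,
                               epsp_kernel = default_epsp_kernel(),
                               ipsp_kernel = default_ipsp_kernel(),
                               v_rest = -65, noise_sd = 0.05, seed = NULL) {
  if (duration <= 0 || dt <= 0)
    invalid_argument("`duration` and `dt` must be positive")
  if (epsp_rate < 0 || ipsp_rate < 0)
    invalid_argument("event rates must be non-negative")
  n <- round(duration / dt)
  with_seed(seed, {
    draw_times <- function(rate) {
      m <- stats::rpois(1, rate * duration)
      sort(stats::runif(m, 0, duration))
    }
    et <- draw_times(epsp_rate)
    it <- draw_times(ipsp_rate)
    v <- rep(0, n)
    add_events <- function(v, times, kern) {
      if (length(times) == 0L) return(v)
      k <- sample_psp_kernel(kern, dt)
      for (t0 in times) {
        i0 <- floor(t0 / dt) + 1L
        i1 <- min(n, i0 + length(k) - 1L)
        v[i0:i1] <- v[i0:i1] + k[seq_len(i1 - i0 + 1L)]
      }
      v
    }
    v <- add_events(v, et, epsp_kernel)
    v <- add_events(v, it, ipsp_kernel)
    if (noise_sd > 0) v <- v + stats::rnorm(n, 0, noise_sd)
    list(trace = voltage_trace(v_rest + v, fs = 1 / dt, units = "mV"),
         truth = list(epsp_times = et, ipsp_times = it,
                      spike_times = numeric(0), seed = seed))
  })
}

#' Reference/target spike-train pair with controlled synchrony
#'
#' Builds an evenly spaced reference train (default 300 spikes at 10 Hz,
#' the simulated regular train used for synchrony benchmarking) and a
#' target train in which `n_ref - n_async` spikes sit within
#' `+/- sync_halfwidth` of distinct reference spikes (Gaussian jitter
#' truncated to the window) and `n_async` spikes are placed uniformly
#' outside every such window.
#'
#' @param n_ref Number of reference spikes.
#' @param ref_rate Reference rate, Hz.
#' @param n_async Number of asynchronous target spikes (0..n_ref).
#' @param sync_halfwidth Half-width of the synchrony window, ms
#'   (default 10).
#' @param jitter_sd Jitter SD of synchronous spikes, ms (0 = coincident).
#' @param seed Optional integer seed.
#' @return List with `ref` and `target` ([spike_train()]s, s) and
#'   `sync_index` (reference indices paired with synchronous target
#'   spikes).
#' @export
generate_sync_pair <- function(n_ref = 300, ref_rate = 10, n_async = 0,
                               sync_halfwidth = 10, jitter_sd = 0,
                               seed = NULL) {
  if (n_ref <= 0) invalid_argument("`n_ref` must be positive")
  if (n_async < 0 || n_async > n_ref)
    invalid_argument("`n_async` must lie in [0, n_ref]")
  if (sync_halfwidth <= 0) invalid_argument("`sync_halfwidth` must be positive")
  hw <- sync_halfwidth / 1000
  T_end <- n_ref / ref_rate
  if (2 * hw * ref_rate >= 0.95)
    invalid_argument("synchrony windows cover the recording; no room for asynchronous spikes")
  ref <- (seq_len(n_ref) - 1) / ref_rate
  n_sync <- n_ref - n_async
  with_seed(seed, {
    sync_idx <- if (n_sync == n_ref) seq_len(n_ref) else
      sort(sample.int(n_ref, n_sync))
    jit <- if (jitter_sd > 0 && n_sync > 0) {
      j <- stats::rnorm(n_sync, 0, jitter_sd / 1000)
      while (any(bad <- abs(j) > hw))  # truncate by resampling
        j[bad] <- stats::rnorm(sum(bad), 0, jitter_sd / 1000)
      j
    } else rep(0, n_sync)
    sync_times <- pmax(ref[sync_idx] + jit, 0)  # first ref spike sits at t = 0
    async_times <- numeric(0)
    while (length(async_times) < n_async) {
      cand <- stats::runif(2 * (n_async - length(async_times)) + 10, 0, T_end)
      d <- vapply(cand, function(x) min(abs(x - ref)), numeric(1))
      async_times <- c(async_times, cand[d > hw])
    }
    async_times <- async_times[seq_len(n_async)]
    list(ref = spike_train(ref),
         target = spike_train(c(sync_times, async_times)),
         sync_index = sync_idx)
  })
}

#' Biphasic extracellular spike template
#'
#' Derivative-of-Gaussian waveform with a dominant negative phase, the
#' canonical extracellular action potential shape.
#'
#' @param fs Sampling rate, Hz.
#' @param amp Peak (negative) amplitude magnitude, uV.
#' @param dur_ms Template duration, ms.
#' @return Numeric template vector (uV).
#' @export
spike_template <- function(fs = 25000, amp = 60, dur_ms = 1.2) {
  n <- max(8L, round(dur_ms / 1000 * fs))
  x <- seq(-3, 3, length.out = n)
  w <- -x * exp(-x^2 / 2)
  w * amp / max(abs(w))
}

#' Synthetic extracellular trace with embedded spikes
#'
#' White Gaussian noise with a spike template inserted at each supplied
#' spike time, for scoring spike-detection sensitivity against ground
#' truth.
#'
#' @param spike_times Spike times, s.
#' @param template Spike waveform (e.g. [spike_template()]), uV.
#' @param fs Sampling rate, Hz (10 kHz or more recommended).
#' @param noise_sd Noise SD, uV.
#' @param duration Trace duration, s; defaults to the last spike plus
#'   50 ms.
#' @param seed Optional integer seed.
#' @return A [voltage_trace()] in uV.
#' @export
generate_extracellular_trace <- function(spike_times, template, fs = 25000,
                                         noise_sd = 6, duration = NULL,
                                         seed = NULL) {
  spike_times <- as.numeric(spike_times)
  duration <- duration %||%
    (if (length(spike_times)) max(spike_times) + 0.05 else 1)
  n <- round(duration * fs)
  idx <- round(spike_times * fs) + 1L
  if (any(idx < 1L) || any(idx + length(template) - 1L > n))
    invalid_argument("spike (plus template) extends beyond the trace end")
  with_seed(seed, {
    v <- if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else numeric(n)
    for (i in idx) {
      span <- i:(i + length(template) - 1L)
      v[span] <- v[span] + template
    }
    voltage_trace(v, fs = fs, units = "uV")
  })
}

#' Synthetic calcium-imaging stack of presynaptic puncta
#'
#' Image stack of Gaussian puncta on a dim background. Responding puncta
#' show a stimulus-locked transient (exponential rise during the
#' stimulus, exponential decay after); every pixel shares a global
#' double-exponential bleaching envelope; noise is Gaussian with variance
#' proportional to the local mean (a shot-noise surrogate). The default
#' stimulus window emulates a 2 s, 50 Hz train imaged at 10 frames/s.
#'
#' @param dims Stack dimensions `c(x, y, frames)`.
#' @param frame_dt Frame interval, s (default 0.1).
#' @param n_respond,n_nonrespond Punctum counts.
#' @param punctum_sigma Punctum Gaussian SD, pixels.
#' @param amp Transient amplitude, delta F/F0.
#' @param stim_onset,stim_dur Stimulus onset and duration, s.
#' @param bleach_taus Double-exponential bleach time constants, s.
#' @param bleach_weights Mixture weights of the two bleach components
#'   (sum 1; `c(1, 0)` for single-exponential bleaching).
#' @param noise_sd Noise SD at baseline punctum brightness (fluorescence
#'   units; 0 for a noiseless stack).
#' @param baseline Punctum peak brightness over background.
#' @param background Background level.
#' @param rise_tau,decay_tau Transient kinetics, s.
#' @param min_sep Minimum center separation, pixels; if unplaceable after
#'   many attempts a warning (not an error) is raised and remaining
#'   puncta may overlap.
#' @param seed Optional integer seed.
#' @return List with `stack` (array) and `truth` (fields `centers`
#'   (matrix), `responding` (logical), `bleach_taus`, `noise_sd`,
#'   `stim_frames`).
#' @export
generate_calcium_stack <- function(dims = c(48, 48, 60), frame_dt = 0.1,
                                   n_respond = 5, n_nonrespond = 5,
                                   punctum_sigma = 1.5, amp = 0.5,
                                   stim_onset = 2, stim_dur = 2,
                                   bleach_taus = c(5, 50),
                                   bleach_weights = c(0.2, 0.8),
                                   noise_sd = 2, baseline = 100,
                                   background = 10,
                                   rise_tau = 0.3, decay_tau = 1,
                                   min_sep = NULL, seed = NULL) {
  if (n_respond < 0 || n_nonrespond < 0)
    invalid_argument("punctum counts must be non-negative")
  if (punctum_sigma <= 0) invalid_argument("`punctum_sigma` must be positive")
  if (any(bleach_taus <= 0)) invalid_argument("bleach taus must be positive")
  n_frames <- dims[3]
  t <- (seq_len(n_frames) - 1) * frame_dt
  if (stim_onset < 0 || stim_onset + stim_dur > max(t))
    invalid_argument("stimulus window must lie inside the stack")
  n_p <- n_respond + n_nonrespond
  min_sep <- min_sep %||% (4 * punctum_sigma)
  with_seed(seed, {
    margin <- ceiling(3 * punctum_sigma)
    centers <- matrix(NA_real_, n_p, 2)
    placed <- 0
    attempts <- 0
    while (placed < n_p && attempts < 200 * max(n_p, 1)) {
      attempts <- attempts + 1
      cand <- c(stats::runif(1, margin + 1, dims[1] - margin),
                stats::runif(1, margin + 1, dims[2] - margin))
      if (placed == 0 ||
          min(sqrt(rowSums((centers[seq_len(placed), , drop = FALSE] -
                              matrix(cand, placed, 2, byrow = TRUE))^2))) >= min_sep) {
        placed <- placed + 1
        centers[placed, ] <- cand
      }
    }
    if (placed < n_p) {
      warning("could not respect the punctum packing limit; placing remaining puncta at random")
      while (placed < n_p) {
        placed <- placed + 1
        centers[placed, ] <- c(stats::runif(1, margin + 1, dims[1] - margin),
                               stats::runif(1, margin + 1, dims[2] - margin))
      }
    }
    responding <- c(rep(TRUE, n_respond), rep(FALSE, n_nonrespond))
    bleach <- bleach_weights[1] * exp(-t / bleach_taus[1]) +
      bleach_weights[2] * exp(-t / bleach_taus[2])
    transient <- numeric(n_frames)
    during <- t >= stim_onset & t < stim_onset + stim_dur
    after <- t >= stim_onset + stim_dur
    transient[during] <- amp * (1 - exp(-(t[during] - stim_onset) / rise_tau))
    end_val <- amp * (1 - exp(-stim_dur / rise_tau))
    transient[after] <- end_val * exp(-(t[after] - stim_onset - stim_dur) / decay_tau)
    xs <- seq_len(dims[1])
    ys <- seq_len(dims[2])
    base_img <- matrix(background, dims[1], dims[2])
    spots <- vector("list", n_p)
    for (p in seq_len(n_p)) {
      gx <- exp(-(xs - centers[p, 1])^2 / (2 * punctum_sigma^2))
      gy <- exp(-(ys - centers[p, 2])^2 / (2 * punctum_sigma^2))
      spots[[p]] <- baseline * outer(gx, gy)
    }
    stack <- array(0, dims)
    for (k in seq_len(n_frames)) {
      frame <- base_img
      for (p in seq_len(n_p)) {
        gain <- if (responding[p]) 1 + transient[k] else 1
        frame <- frame + spots[[p]] * gain
      }
      frame <- frame * bleach[k]
      if (noise_sd > 0)
        frame <- frame + stats::rnorm(length(frame),
                                      0, noise_sd * sqrt(pmax(frame, 0) / baseline))
      stack[, , k] <- frame
    }
    list(stack = stack,
         truth = list(centers = centers, responding = responding,
                      bleach_taus = bleach_taus, noise_sd = noise_sd,
                      stim_frames = which(during | after & transient > 0.05 * amp)))
  })
}

#' Synthetic conductance-voltage (I-V) dataset
#'
#' Currents follow `I(V) = gmax * B(V) * (V - erev)` with a Boltzmann
#' activation curve `B` (half-activation `v50`, slope factor `slope`)
#' and multiplicative Gaussian noise, emulating voltage-step recordings
#' of Kv3 currents.
#'
#' @param v_steps Step potentials, mV (excluding `erev`).
#' @param v50 Half-activation voltage, mV (default -11.4, a control
#'   Kv3.1b value).
#' @param slope Slope factor, mV (> 0).
#' @param gmax Maximal conductance, nS.
#' @param erev Reversal potential, mV.
#' @param noise_sd Multiplicative noise SD (fraction of each current).
#' @param seed Optional integer seed.
#' @return List of class `iv_dataset`: `v_steps`, `currents` (pA, with
#'   gmax in nS and V in mV), `erev`, plus the generating parameters.
#' @export
generate_iv_dataset <- function(v_steps = seq(-70, 40, by = 10), v50 = -11.4,
                                slope = 8, gmax = 10, erev = -85,
                                noise_sd = 0, seed = NULL) {
  if (slope <= 0) invalid_argument("`slope` must be positive")
  if (any(v_steps == erev))
    invalid_argument("`v_steps` must exclude the reversal potential")
  b <- 1 / (1 + exp((v50 - v_steps) / slope))
  i <- gmax * b * (v_steps - erev)
  with_seed(seed, {
    if (noise_sd > 0) i <- i * (1 + stats::rnorm(length(i), 0, noise_sd))
    structure(list(v_steps = v_steps, currents = i, erev = erev,
                   v50 = v50, slope = slope, gmax = gmax),
              class = "iv_dataset")
  })
}
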