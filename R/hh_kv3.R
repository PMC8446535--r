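#' Hodgkin-Huxley model parameters with a Kv3 conductance
#'
#' Parameter set for a point-membrane model carrying the classical Na+,
#' delayed-rectifier K+ and leak currents plus a fast, high-voltage
#' activated Kv3 K+ current. The Kv3 gate uses
#' \deqn{\alpha = a\,(-(V+b)) / (e^{-(V+b)/c} - 1), \qquad
#'       \beta = d\, e^{(V - V_{rest})/80}}
#' with `a = 0.3` per ms, `b = -4.18` mV, `c = 6.43` mV and `d = 0.011`
#' per ms. Referencing the beta exponent to the resting potential makes
#' the n^4 conductance decay at rest with time constant
#' `1/(4 d) ~ 22.7 ms`, which underlies the roughly 20 ms post-spike
#' activation of the conductance; `kv3_beta_ref = "absolute"` switches to
#' an absolute-voltage exponent.
#'
#' Leak reversal sits `e_l_offset` above rest (original HH convention).
#' All conductances are in mS/cm^2, capacitance in uF/cm^2, voltages in
#' mV, rates in 1/ms.
#'
#' @param cm Membrane capacitance.
#' @param g_na,g_k,g_l Canonical HH conductances.
#' @param g_kv3 Kv3 maximal conductance (0-35 covers the range studied).
#' @param e_na,e_k,e_kv3 Reversal potentials.
#' @param e_l_offset Leak reversal offset above rest.
#' @param v_rest Resting potential.
#' @param kv3_a,kv3_b,kv3_c,kv3_d Kv3 gate rate parameters.
#' @param kv3_beta_vscale Voltage scale of the Kv3 beta exponent, mV.
#' @param kv3_beta_ref `"rest"` (default) or `"absolute"` exponent
#'   reference.
#' @return An object of class `hh_params`.
#' @export
hh_params <- function(cm = 1, g_na = 120, g_k = 36, g_l = 0.3, g_kv3 = 35,
                      e_na = 50, e_k = -77, e_kv3 = -81, e_l_offset = 10.6,
                      v_rest = -65,
                      kv3_a = 0.3, kv3_b = -4.18, kv3_c = 6.43, kv3_d = 0.011,
                      kv3_beta_vscale = 80,
                      kv3_beta_ref = c("rest", "absolute")) {
  kv3_beta_ref <- match.arg(kv3_beta_ref)
  if (cm <= 0) invalid_argument("`cm` must be positive")
  if (any(c(g_na, g_k, g_l, g_kv3) < 0))
    invalid_argument("conductances must be non-negative")
  structure(list(cm = cm, g_na = g_na, g_k = g_k, g_l = g_l, g_kv3 = g_kv3,
                 e_na = e_na, e_k = e_k, e_kv3 = e_kv3,
                 e_l = v_rest + e_l_offset, e_l_offset = e_l_offset,
                 v_rest = v_rest,
                 kv3_a = kv3_a, kv3_b = kv3_b, kv3_c = kv3_c, kv3_d = kv3_d,
                 kv3_beta_vscale = kv3_beta_vscale,
                 kv3_beta_ref = kv3_beta_ref),
            class = "hh_params")
}

# R copies of the gate rate functions (used for initialization and for
# steady-state inspection; the integrator itself runs in C++).
hh_rates <- function(v) {
  am <- if (abs(v + 40) < 1e-7) 1 else 0.1 * (v + 40) / (1 - exp(-(v + 40) / 10))
  an <- if (abs(v + 55) < 1e-7) 0.1 else 0.01 * (v + 55) / (1 - exp(-(v + 55) / 10))
  list(am = am,
       bm = 4 * exp(-(v + 65) / 18),
       ah = 0.07 * exp(-(v + 65) / 20),
       bh = 1 / (1 + exp(-(v + 35) / 10)),
       an = an,
       bn = 0.125 * exp(-(v + 65) / 80))
}

#' Kv3 gate rate constants and steady-state activation
#'
#' @param v Membrane potential, mV (vectorized).
#' @param params An [hh_params()] object.
#' @return `kv3_rates()`: list with `alpha` and `beta` (1/ms);
#'   `kv3_steady_state()`: steady-state activation `alpha/(alpha+beta)`.
#' @export
kv3_rates <- function(v, params = hh_params()) {
  x <- v + params$kv3_b
  alpha <- ifelse(abs(x) < 1e-7, params$kv3_a * params$kv3_c,
                  params$kv3_a * (-x) / (exp(-x / params$kv3_c) - 1))
  vref <- if (params$kv3_beta_ref == "rest") params$v_rest else 0
  beta <- params$kv3_d * exp((v - vref) / params$kv3_beta_vscale)
  list(alpha = alpha, beta = beta)
}

#' @rdname kv3_rates
#' @export
kv3_steady_state <- function(v, params = hh_params()) {
  r <- kv3_rates(v, params)
  r$alpha / (r$alpha + r$beta)
}

#' Simulate the HH-type membrane with Kv3 conductance
#'
#' Forward-Euler integration of the point-membrane model under an
#' injected current density. Gates start at their steady state for the
#' initial voltage and are clamped to \[0, 1\]. A numerical blow-up
#' (|V| > 200 mV) raises an integration-failure error naming the step.
#'
#' @param params An [hh_params()] object.
#' @param stim Injected current density (uA/cm^2): numeric vector sampled
#'   at `dt`, or a [make_pulse_train()] object (its `dt` wins).
#' @param dt Time step, ms (must be <= 0.025).
#' @param v0 Initial voltage, mV (defaults to `params$v_rest`).
#' @return An object of class `hh_sim`: `t_ms`, `v`, gate trajectories
#'   `m`, `h`, `n`, `n_kv3`, the Kv3 conductance trace `g_kv3_trace`
#'   (mS/cm^2), `stim`, `dt`, `params`.
#' @export
hh_simulate <- function(params, stim, dt = 0.01, v0 = params$v_rest) {
  stopifnot(inherits(params, "hh_params"))
  if (inherits(stim, "pulse_train")) {
    dt <- stim$dt
    stim_v <- stim$values
  } else {
    stim_v <- as.numeric(stim)
  }
  if (dt > 0.025) invalid_argument("`dt` must be <= 0.025 ms")
  r <- hh_rates(v0)
  kr <- kv3_rates(v0, params)
  vref <- if (params$kv3_beta_ref == "rest") params$v_rest else 0
  res <- hh_integrate(stim_v, dt,
                      params$cm, params$g_na, params$g_k, params$g_l,
                      params$g_kv3,
                      params$e_na, params$e_k, params$e_l, params$e_kv3,
                      params$kv3_a, params$kv3_b, params$kv3_c, params$kv3_d,
                      vref, params$kv3_beta_vscale,
                      v0,
                      r$am / (r$am + r$bm),
                      r$ah / (r$ah + r$bh),
                      r$an / (r$an + r$bn),
                      kr$alpha / (kr$alpha + kr$beta))
  if (res$err_step >= 0)
    stop_kv3(sprintf("integration failure: |V| exceeded 200 mV at step %d (t = %.3f ms)",
                     res$err_step, (res$err_step - 1) * dt),
             "kv3noise_integration_failure")
  structure(list(t_ms = (seq_along(stim_v) - 1) * dt,
                 v = res$v, m = res$m, h = res$h, n = res$n,
                 n_kv3 = res$n_kv3,
                 g_kv3_trace = params$g_kv3 * res$n_kv3^4,
                 stim = stim_v, dt = dt, params = params),
            class = "hh_sim")
}

#' @export
print.hh_sim <- function(x, ...) {
  cat(sprintf("<hh_sim> %.1f ms at dt = %g ms; %d action potential(s)\n",
              max(x$t_ms), x$dt, length(ap_times(x))))
  invisible(x)
}

#' Action potential times of a simulation
#'
#' Upward 0 mV crossings of the voltage trajectory.
#'
#' @param sim An `hh_sim`.
#' @param v_thr Crossing threshold, mV.
#' @return Crossing times, ms.
#' @export
ap_times <- function(sim, v_thr = 0) {
  v <- sim$v
  idx <- which(v[-length(v)] < v_thr & v[-1] >= v_thr)
  idx * sim$dt
}

#' Duration of post-spike Kv3 conductance activation
#'
#' Measures how long the Kv3 conductance remains active after an action
#' potential: from the post-peak conductance maximum until the
#' conductance first decays below 1/e of that maximum.
#'
#' @param x An `hh_sim` containing a single action potential, or a plain
#'   conductance trace.
#' @param dt Time step, ms (for a plain trace).
#' @param ap_peak_time Time of the action potential peak, ms (for a plain
#'   trace).
#' @return Active duration, ms.
#' @export
kv3_active_duration <- function(x, dt = NULL, ap_peak_time = NULL) {
  if (inherits(x, "hh_sim")) {
    if (x$params$g_kv3 <= 0)
      undefined_result("Kv3 conductance is zero in this simulation")
    if (max(x$v) <= 0)
      undefined_result("no action potential in the simulation")
    g <- x$g_kv3_trace
    dt <- x$dt
    peak_i <- which.max(x$v)
  } else {
    g <- as.numeric(x)
    if (is.null(dt) || is.null(ap_peak_time))
      invalid_argument("`dt` and `ap_peak_time` required for a plain trace")
    if (max(g) <= 0) undefined_result("conductance trace is identically zero")
    peak_i <- max(1L, round(ap_peak_time / dt) + 1L)
  }
  post <- g[peak_i:length(g)]
  gi <- which.max(post)
  gmax <- post[gi]
  if (gmax <= 0) undefined_result("no post-spike conductance activation")
  below <- which(post[gi:length(post)] < gmax / exp(1))
  if (length(below) == 0L)
    undefined_result("conductance did not decay below 1/e within the trace")
  (below[1L] - 1L) * dt
}

#' Pulse-train current stimulus with amplitude noise
#'
#' Rectangular pulse train (default 50 Hz, 100 pulses) whose per-pulse
#' amplitudes are drawn from a normal distribution with SD
#' `noise_frac * amplitude`, reproducing trial-to-trial stimulus
#' variability; `n_omit` pulses are zeroed at seeded random positions.
#'
#' @param amplitude Mean pulse amplitude, uA/cm^2.
#' @param rate Pulse rate, Hz.
#' @param n_pulses Number of pulses.
#' @param pulse_width Pulse width, ms.
#' @param noise_frac Amplitude SD as a fraction of the mean (default 0.05).
#' @param n_omit Number of randomly omitted pulses.
#' @param dt Sampling step, ms.
#' @param onset Delay before the first pulse, ms.
#' @param tail Silent time after the last inter-pulse interval, ms.
#' @param seed Optional integer seed.
#' @return An object of class `pulse_train`: `values` (uA/cm^2), `dt`,
#'   `onsets_ms`, per-pulse `amps`, and the generating spec fields.
#' @export
make_pulse_train <- function(amplitude, rate = 50, n_pulses = 100,
                             pulse_width = 1, noise_frac = 0.05, n_omit = 0,
                             dt = 0.01, onset = 10, tail = 50, seed = NULL) {
  if (n_omit > n_pulses) invalid_argument("`n_omit` cannot exceed `n_pulses`")
  if (noise_frac < 0) invalid_argument("`noise_frac` must be non-negative")
  period <- 1000 / rate
  if (pulse_width >= period)
    invalid_argument("pulse width must be shorter than the inter-pulse interval")
  total_ms <- onset + n_pulses * period + tail
  n <- round(total_ms / dt)
  values <- numeric(n)
  res <- with_seed(seed, {
    amps <- stats::rnorm(n_pulses, amplitude, noise_frac * amplitude)
    omit <- if (n_omit > 0) sample.int(n_pulses, n_omit) else integer(0)
    list(amps = amps, omit = omit)
  })
  amps <- res$amps
  amps[res$omit] <- 0
  onsets_ms <- onset + (seq_len(n_pulses) - 1) * period
  wid <- max(1L, round(pulse_width / dt))
  for (p in seq_len(n_pulses)) {
    i0 <- round(onsets_ms[p] / dt) + 1L
    values[i0:(i0 + wid - 1L)] <- amps[p]
  }
  structure(list(values = values, dt = dt, onsets_ms = onsets_ms,
                 amps = amps, rate = rate, n_pulses = n_pulses,
                 pulse_width = pulse_width, noise_frac = noise_frac,
                 n_omit = n_omit, amplitude = amplitude),
            class = "pulse_train")
}

#' Per-pulse action potential successes and failures
#'
#' A pulse succeeds if the voltage crosses 0 mV upward within one
#' inter-pulse interval of the pulse onset. Every pulse slot (including
#' omitted pulses) is scored, so `n_ap + n_fail = n_pulses`.
#'
#' @param sim An `hh_sim` driven by `train`.
#' @param train The [make_pulse_train()] stimulus used.
#' @return List with `n_ap`, `n_fail` and the logical per-pulse `outcome`.
#' @export
count_ap_failures <- function(sim, train) {
  stopifnot(inherits(sim, "hh_sim"), inherits(train, "pulse_train"))
  cr <- ap_times(sim)
  period <- 1000 / train$rate
  outcome <- vapply(train$onsets_ms, function(o)
    any(cr > o & cr <= o + period), logical(1))
  list(n_ap = sum(outcome), n_fail = sum(!outcome), outcome = outcome)
}

#' Calibrate pulse amplitude to a target firing probability
#'
#' Bisection over the pulse-train amplitude until the mean per-pulse
#' action potential probability across training seeds is within `tol` of
#' `target_rate` (default 0.95, the per-stimulus success rate the noisy
#' 50 Hz train is tuned to). Amplitude noise makes the success
#' probability a smooth, monotone function of the mean amplitude, which
#' the bisection exploits; with `noise_frac = 0` success is a step
#' function and the routine returns a bracketing amplitude with a
#' warning.
#'
#' @param params An [hh_params()] object.
#' @param target_rate Target per-pulse success probability, strictly
#'   inside (0, 1).
#' @param seeds Integer seeds of the training pulse trains.
#' @param rate,n_pulses,pulse_width,noise_frac Pulse-train spec
#'   (see [make_pulse_train()]).
#' @param dt Integration step, ms.
#' @param tol Convergence tolerance on the success probability.
#' @param max_iter Maximum bisection iterations.
#' @param amp_init Starting amplitude for bracketing, uA/cm^2.
#' @return List with `amplitude`, `achieved` (training success
#'   probability), and `iterations`.
#' @export
calibrate_stimulus <- function(params, target_rate = 0.95, seeds = 1:5,
                               rate = 50, n_pulses = 100, pulse_width = 1,
                               noise_frac = 0.05, dt = 0.01, tol = 0.02,
                               max_iter = 40, amp_init = 10) {
  if (target_rate <= 0 || target_rate >= 1)
    invalid_argument("`target_rate` must lie strictly inside (0, 1)")
  success <- function(amp) {
    mean(vapply(seeds, function(s) {
      train <- make_pulse_train(amp, rate = rate, n_pulses = n_pulses,
                                pulse_width = pulse_width,
                                noise_frac = noise_frac, dt = dt, seed = s)
      sim <- hh_simulate(params, train, dt = dt)
      count_ap_failures(sim, train)$n_ap / n_pulses
    }, numeric(1)))
  }
  lo <- amp_init
  f_lo <- success(lo)
  k <- 0
  while (f_lo >= target_rate && k < 20) {
    lo <- lo / 2
    f_lo <- success(lo)
    k <- k + 1
  }
  if (f_lo >= target_rate)
    stop_kv3("could not bracket from below: success never falls under the target",
             "kv3noise_calibration_failure")
  hi <- max(lo * 2, amp_init)
  f_hi <- success(hi)
  k <- 0
  while (f_hi < target_rate && k < 20) {
    hi <- hi * 2
    f_hi <- success(hi)
    k <- k + 1
  }
  if (f_hi < target_rate)
    stop_kv3("calibration failure: target success unreachable (asymptotic)",
             "kv3noise_calibration_failure")
  # bisect to bracket convergence, keeping the amplitude whose training
  # success lies closest to the target: stopping at the first amplitude
  # merely inside the tolerance would leave a systematic offset that the
  # held-out evaluation inherits
  iter <- 0
  best_amp <- hi
  best_f <- f_hi
  while (iter < max_iter && (hi - lo) / hi > 0.001) {
    iter <- iter + 1
    mid <- (lo + hi) / 2
    f_mid <- success(mid)
    if (abs(f_mid - target_rate) < abs(best_f - target_rate)) {
      best_amp <- mid
      best_f <- f_mid
    }
    if (f_mid < target_rate) lo <- mid else hi <- mid
  }
  if (noise_frac == 0) {
    warning("success is a step function of amplitude without noise; returning a bracketing amplitude")
    return(list(amplitude = hi, achieved = success(hi), iterations = iter))
  }
  if (abs(best_f - target_rate) <= tol)
    return(list(amplitude = best_amp, achieved = best_f, iterations = iter))
  stop_kv3("calibration did not converge within `max_iter` iterations",
           "kv3noise_calibration_failure")
}
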