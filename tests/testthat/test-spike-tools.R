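test_that("elliptic band-pass preserves the passband and rejects out-of-band tones", {
  fs <- 25000
  t <- (0:(fs - 1)) / fs
  pass <- bandpass_elliptic(sin(2 * pi * 1000 * t), fs)
  mid <- 5000:20000
  expect_lt(abs((max(pass[mid]) - min(pass[mid])) / 2 - 1), 0.05)
  low <- bandpass_elliptic(sin(2 * pi * 10 * t), fs)
  expect_lt(max(abs(low[mid])), 0.1)  # > 20 dB down
  expect_equal(bandpass_elliptic(rep(0, 1000), fs), rep(0, 1000))
  expect_invalid_argument(bandpass_elliptic(rnorm(100), fs = 5000))
})

test_that("the MAD threshold matches its definition and the Gaussian SD", {
  x <- rep(c(0.6745, -0.6745), 500)
  thr <- mad_threshold(x, k = 5)
  expect_equal(as.numeric(thr), 5)
  expect_equal(attr(thr, "H"), 1)
  set.seed(1)
  g <- rnorm(1e6, sd = 2.5)
  expect_lt(abs(attr(mad_threshold(g, 5), "H") / 2.5 - 1), 0.01)
  expect_equal(as.numeric(mad_threshold(rep(0, 100), 5)), 0)
})

test_that("spike detection recovers embedded spikes and stays quiet on noise", {
  fs <- 25000
  set.seed(20)
  truth <- seq(0.05, 9.95, by = 0.1) + runif(100, -0.02, 0.02)
  tmpl <- spike_template(fs, amp = 60)
  peak_off <- which.min(tmpl) / fs
  hits <- fps <- numeric(0)
  for (s in 1:5) {
    tr <- generate_extracellular_trace(truth, tmpl, fs, noise_sd = 6,
                                       duration = 10, seed = s)
    det <- detect_spikes(tr, k = 5)
    hit <- vapply(truth + peak_off, function(t0) any(abs(det - t0) < 5e-4),
                  logical(1))
    hits <- c(hits, mean(hit))
    fps <- c(fps, sum(!vapply(det, function(d)
      any(abs(truth + peak_off - d) < 5e-4), logical(1))))
  }
  expect_gte(mean(hits), 0.99)
  expect_lte(mean(fps), 1)  # false positives per 10 s
  # pure noise: Gaussian exceedance at 5 SD predicts < 1 event per 10 s
  noise <- generate_extracellular_trace(numeric(0), tmpl, fs, noise_sd = 6,
                                        duration = 10, seed = 99)
  expect_lte(length(detect_spikes(noise, k = 5)), 1)
})

test_that("detection is monotone in the threshold multiplier and scale-equivariant", {
  fs <- 25000
  truth <- seq(0.1, 4.9, by = 0.1)
  tmpl <- spike_template(fs, amp = 40)
  tr <- generate_extracellular_trace(truth, tmpl, fs, noise_sd = 6,
                                     duration = 5, seed = 8)
  d5 <- detect_spikes(tr, k = 5)
  d4 <- detect_spikes(tr, k = 4)
  expect_true(all(d5 %in% d4))
  # scaling the trace scales the threshold and preserves detections
  tr10 <- voltage_trace(tr$values * 10, tr$fs)
  d5s <- detect_spikes(tr10, k = 5)
  expect_equal(as.numeric(d5s), as.numeric(d5))
  expect_equal(attr(d5s, "threshold"), 10 * attr(d5, "threshold"),
               tolerance = 1e-10)
})

test_that("synaptic potential detection recovers Poisson event counts", {
  gen <- generate_psp_trace(60, epsp_rate = 2, ipsp_rate = 2,
                            epsp_kernel = psp_kernel_spec(1.0, 0.8, 3.0),
                            ipsp_kernel = psp_kernel_spec(-1.0, 0.4, 1.0),
                            noise_sd = 0.05, seed = 31)
  # thresholds sit below the band-limited event amplitudes (the 100 Hz
  # low-pass attenuates the fast IPSP kernel more than the EPSP kernel)
  ev <- detect_psps(gen$trace, pos_thr = 0.4, neg_thr = 0.25, min_sep = 0.01)
  inside <- function(tt) sum(tt > 0.25 & tt < 59.75)  # detector edge guard
  n_e <- inside(gen$truth$epsp_times)
  n_i <- inside(gen$truth$ipsp_times)
  expect_lt(abs(length(ev$epsp_times) - n_e) / n_e, 0.05)
  expect_lt(abs(length(ev$ipsp_times) - n_i) / n_i, 0.10)
  expect_invalid_argument(detect_psps(gen$trace, pos_thr = 0, neg_thr = 0.3))
  # EPSP-only trace leaves the IPSP list empty
  gen_e <- generate_psp_trace(30, epsp_rate = 2, ipsp_rate = 0,
                              noise_sd = 0.02, seed = 5)
  ev_e <- detect_psps(gen_e$trace, pos_thr = 0.3, neg_thr = 0.3)
  expect_length(ev_e$ipsp_times, 0)
})

test_that("timestamp de-duplication removes coincidences with a closed window and is idempotent", {
  r <- c(0.1, 0.2, 0.3)
  expect_length(dedup_timestamps(r, r), 0)
  # boundary exactly at the window is removed
  expect_length(dedup_timestamps(0.1 + 2e-4, 0.1), 0)
  expect_length(dedup_timestamps(0.1 + 2.0001e-4, 0.1), 1)
  t2 <- c(0.05, 0.1001, 0.25, 0.4)
  once <- dedup_timestamps(t2, r)
  twice <- dedup_timestamps(once, r)
  expect_equal(as.numeric(once), as.numeric(twice))
  far <- c(1, 2, 3)
  expect_equal(as.numeric(dedup_timestamps(far, r)), far)
})

test_that("the spike-triggered average reproduces a pulse fixture and its features", {
  fx <- pulse_sta_fixture()
  sta <- spike_triggered_average(fx$current, fx$spikes, fx$fs,
                                 window = c(-10, 5))
  expect_equal(sta$peak, 100)
  expect_lt(abs(sta$latency_to_peak - fx$lag_ms), 1000 / fx$fs * 2 + 1e-9)
  expect_gt(sta$max_rising_slope, 0)
  expect_equal(sta$n_spikes, length(fx$spikes))
  # single spike: STA is that segment exactly
  one <- spike_triggered_average(fx$current, fx$spikes[1], fx$fs,
                                 window = c(-10, 5))
  i0 <- round(fx$spikes[1] * fx$fs) + 1 + round(-10 / 1000 * fx$fs)
  seg <- fx$current[i0:(i0 + length(one$sta) - 1)]
  expect_equal(one$sta, seg)
  expect_undefined_result(
    spike_triggered_average(fx$current, numeric(0), fx$fs))
})

test_that("a white-noise STA with random spikes stays within sampling error and shifts with spike times", {
  fs <- 10000
  set.seed(3)
  cur <- rnorm(fs * 20)
  spikes <- sort(runif(5000, 0.05, 19.9))
  sta <- spike_triggered_average(cur, spikes, fs, window = c(-10, 5))
  se <- 1 / sqrt(sta$n_spikes)
  expect_lt(max(abs(sta$sta)), 5 * se)
  # shifting all spikes by one sample shifts the STA by one sample
  sta2 <- spike_triggered_average(cur, spikes + 1 / fs, fs, window = c(-10, 5))
  n <- length(sta$sta)
  expect_equal(sta2$sta[1:(n - 1)], sta$sta[2:n], tolerance = 1e-12)
})
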