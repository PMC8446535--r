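test_that("Morlet kernels carry the requested center frequency and bandwidth", {
  for (f in c(3, 10, 40)) {
    mw <- make_morlet(f, 1e-3)
    # odd symmetry: samples sum to zero
    expect_lt(abs(sum(mw$kernel)) / max(abs(mw$kernel)), 1e-10)
    fwhm <- morlet_fwhm(mw)
    expect_lt(abs(fwhm - 0.75) / 0.75, 0.10)
    # power spectrum peaks at the carrier
    n <- length(mw$kernel)
    N <- stats::nextn(max(n, 2^16), 2)
    P <- Mod(fft(c(mw$kernel, rep(0, N - n))))^2
    fr <- (0:(N - 1)) / (N * mw$dt)
    half <- fr <= 1 / (2 * mw$dt)
    expect_lt(abs(fr[half][which.max(P[half])] - f), 0.05)
  }
  expect_invalid_argument(make_morlet(10, dt = 0.05))
  expect_invalid_argument(make_morlet(0.5, dt = 1e-3, bandwidth = 0.75))
})

test_that("wavelet filtering is zero-phase with unit passband gain and strong stopband rejection", {
  fs <- 1000
  t <- (0:59999) / fs
  f <- 10
  x <- sin(2 * pi * f * t)
  y <- wavelet_filter(x, f, fs)
  mid <- 20000:40000
  expect_lt(abs((max(y[mid]) - min(y[mid])) / 2 - 1), 0.02)
  # zero phase: filtered sine aligned with the input
  expect_gt(cor(x[mid], y[mid]), 0.9999)
  # tone at 4f is essentially removed
  y4 <- wavelet_filter(sin(2 * pi * 4 * f * t), f, fs)
  expect_lt(max(abs(y4[mid])), 0.05)
  expect_equal(wavelet_filter(rep(0, 10000), f, fs), rep(0, 10000),
               ignore_attr = TRUE)
})

test_that("wavelet filtering is linear and never amplifies variance", {
  fs <- 500
  set.seed(42)
  x <- rnorm(8000)
  y <- rnorm(8000)
  lhs <- wavelet_filter(2 * x - 3 * y, 6, fs)
  rhs <- 2 * wavelet_filter(x, 6, fs) - 3 * wavelet_filter(y, 6, fs)
  expect_lt(max(abs(lhs - rhs)) / max(abs(lhs)), 1e-10)
  for (f in c(3, 10, 40)) {
    expect_lte(var(wavelet_filter(x, f, fs)), var(x))
  }
})

test_that("epoch band amplitude equals six standard deviations of the filtered signal", {
  fs <- 500
  t <- (0:(90 * fs - 1)) / fs
  A <- 2.5
  x <- A * sin(2 * pi * 10 * t)
  ba <- band_amplitude(x, 10, fs, epoch = 30)
  expect_equal(nrow(ba), 3)
  expect_true(all(abs(ba$p2p - 6 * A / sqrt(2)) / (6 * A / sqrt(2)) < 0.02))
  # definitional check on Gaussian noise
  set.seed(7)
  g <- rnorm(30 * fs, sd = 1.3)
  ba2 <- band_amplitude(g, 10, fs, epoch = 30)
  filt <- wavelet_filter(g, 10, fs)
  expect_equal(ba2$p2p, 6 * sd(filt[1:(30 * fs)]), tolerance = 1e-10)
  expect_equal(band_amplitude(rep(0, 40 * fs), 10, fs)$p2p, 0)
  expect_invalid_argument(band_amplitude(rnorm(100), 10, fs, epoch = 30))
})

test_that("the OU recursion matches its AR(1) identities", {
  expect_equal(ou_series(100, 0.5, 0, seed = 1), rep(0, 100))
  x <- ou_series(1e6, 0.9, 1, seed = 2)
  expect_lt(abs(cor(x[-1], x[-length(x)]) - 0.9), 0.01)
  expect_lt(abs(var(x) / (1 / (1 - 0.81)) - 1), 0.02)
  w <- ou_series(1e5, 0, 1, seed = 3)
  expect_lt(abs(cor(w[-1], w[-length(w)])), 0.02)
  expect_invalid_argument(ou_series(10, 1, 1))
})

test_that("wavelet-filtered noise stimuli hit the requested spectral peak and amplitude", {
  stim <- make_noise_stimulus(40, 10, 1e-4, target_p2p = 300, seed = 5)
  expect_equal(6 * sd(stim$values), 300, tolerance = 1e-6)
  n <- length(stim$values)
  P <- Mod(fft(stim$values))^2
  fr <- (0:(n - 1)) * stim$fs / n
  half <- fr <= stim$fs / 2
  expect_lt(abs(fr[half][which.max(P[half])] - 40), 1)
  # distinct seeds give distinct realizations with comparable band power
  s2 <- make_noise_stimulus(40, 10, 1e-4, target_p2p = 300, seed = 6)
  expect_gt(max(abs(stim$values - s2$values)), 1)
  expect_equal(sd(s2$values), sd(stim$values), tolerance = 1e-6)
})

test_that("phase coherence is 1 for locked spikes and near the null for random spikes", {
  stim <- make_noise_stimulus(40, 10, 1e-4, target_p2p = 300, seed = 5)
  ph <- Arg(kv3noise:::analytic_signal(stim$values))
  locked <- which(diff(ph) < -5) / stim$fs  # phase-wrap instants
  expect_gt(spike_field_coherence(locked, stim), 0.99)
  set.seed(6)
  null_c <- replicate(30, spike_field_coherence(sort(runif(1000, 0, 10)), stim))
  expect_lt(mean(null_c), 0.05)  # null expectation ~ sqrt(pi/(4N)) = 0.028
  expect_undefined_result(spike_field_coherence(numeric(0), stim))
})

test_that("spectral center fitting recovers a Gabor atom and flags degenerate input", {
  dt <- 1e-3
  t <- seq(-1, 1, by = dt)
  gab <- sin(2 * pi * 23 * t) * exp(-t^2 / (2 * 0.1^2))
  res <- psp_spectrum_center(gab, dt)
  expect_true(res$ok)
  expect_lt(abs(res$center_hz - 23), 0.5)
  step <- c(rep(0, 100), rep(1, 400))
  res2 <- suppressWarnings(psp_spectrum_center(step, dt))
  expect_false(res2$ok)
})

test_that("synthetic mean EPSP/IPSP spectra sit at the observed spectral centers", {
  gen <- generate_psp_trace(120, epsp_rate = 4, ipsp_rate = 0,
                            noise_sd = 0.05, seed = 42)
  w <- mean_event_waveform(gen$trace$values + 65, gen$truth$epsp_times,
                           fs = gen$trace$fs)
  res <- suppressWarnings(psp_spectrum_center(w, 1e-3))
  expect_true(res$ok)
  expect_gt(res$center_hz, 20)
  expect_lt(res$center_hz, 26)
  gen_i <- generate_psp_trace(120, epsp_rate = 0, ipsp_rate = 4,
                              noise_sd = 0.05, seed = 42)
  wi <- mean_event_waveform(-(gen_i$trace$values + 65), gen_i$truth$ipsp_times,
                            fs = gen_i$trace$fs)
  res_i <- suppressWarnings(psp_spectrum_center(wi, 1e-3))
  expect_true(res_i$ok)
  expect_gt(res_i$center_hz, 29)
  expect_lt(res_i$center_hz, 37)
})
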