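# Shared fixtures, built in code at test time.

# Two-disc image, optionally bridged into a dumbbell.
disc_image <- function(n = 60, centers = list(c(20, 30), c(40, 30)), r = 8,
                       bridge = FALSE) {
  img <- matrix(0, n, n)
  xy <- expand.grid(x = seq_len(n), y = seq_len(n))
  for (cc in centers) {
    d <- sqrt((xy$x - cc[1])^2 + (xy$y - cc[2])^2)
    img[d < r] <- 1
  }
  if (bridge) img[(centers[[1]][1]):(centers[[2]][1]),
                  (centers[[1]][2] - 1):(centers[[1]][2] + 1)] <- 1
  img
}

# Current trace with identical rectangular pulses and spikes at a fixed lag.
pulse_sta_fixture <- function(fs = 20000, lag_s = 0.002, amp = 100) {
  cur <- rep(0, fs)
  onsets <- seq(0.1, 0.9, by = 0.05)
  for (t0 in onsets) {
    i <- round(t0 * fs)
    cur[i:(i + round(0.001 * fs))] <- amp
  }
  list(current = cur, fs = fs, spikes = onsets + lag_s, lag_ms = lag_s * 1000)
}

expect_invalid_argument <- function(expr) {
  expect_error(expr, class = "kv3noise_invalid_argument")
}

expect_undefined_result <- function(expr) {
  expect_error(expr, class = "kv3noise_undefined_result")
}
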