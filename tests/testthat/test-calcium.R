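test_that("bleach correction removes a pure double exponential and preserves transients", {
  t <- (0:79) * 0.1
  pure <- 100 * (0.2 * exp(-t / 5) + 0.8 * exp(-t / 50))
  bc <- bleach_correct(pure, stim_window = 30:45, frame_dt = 0.1)
  expect_lt(sd(bc - mean(bc)), 0.01 * pure[1])
  # transient integral survives correction within 2%
  transient <- numeric(80)
  transient[21:40] <- 30 * sin(seq(0, pi, length.out = 20))
  bc2 <- bleach_correct(pure + transient, stim_window = 18:45, frame_dt = 0.1)
  base2 <- mean(bc2[c(1:17, 46:80)])
  expect_lt(abs(sum(bc2[21:40] - base2) - sum(transient)) / sum(transient),
            0.02)
  # constant trace passes through
  flat <- bleach_correct(rep(42, 60), stim_window = 25:35)
  expect_equal(as.numeric(flat), rep(42, 60))
  expect_invalid_argument(bleach_correct(rep(1, 20), stim_window = 3:18))
})

test_that("F/F0 normalization follows its definition", {
  expect_equal(dff(rep(50, 40), 1:10), rep(1, 40))
  f <- c(rep(50, 20), rep(55, 10), rep(50, 10))
  expect_equal(max(dff(f, 1:20)), 1.10)
  expect_invalid_argument(dff(rep(0, 40), 1:10))
  # scaling the whole trace leaves F/F0 unchanged
  t <- (0:79) * 0.1
  tr <- 100 * (0.3 * exp(-t / 4) + 0.7 * exp(-t / 60))
  tr[21:35] <- tr[21:35] * 1.3
  expect_equal(dff(5 * tr, 1:18, stim_window = 19:40),
               dff(tr, 1:18, stim_window = 19:40), tolerance = 1e-3)
})

test_that("segmentation finds well-separated puncta, merges close pairs and ignores blanks", {
  gen <- generate_calcium_stack(dims = c(48, 48, 50), n_respond = 3,
                                n_nonrespond = 3, amp = 1, noise_sd = 0.5,
                                seed = 9)
  pl <- segment_puncta(gen$stack)
  expect_length(pl, 6)
  found <- t(vapply(pl, function(p) p$centroid, numeric(2)))
  d <- vapply(seq_len(nrow(found)), function(i)
    sqrt(min(colSums((t(gen$truth$centers) - found[i, ])^2))), numeric(1))
  expect_lt(max(d), 2)
  blank <- array(10, c(24, 24, 20))
  expect_length(segment_puncta(blank), 0)
  # two puncta closer than 2 sigma collapse into one flagged component
  sigma <- 1.5
  close <- generate_calcium_stack(dims = c(32, 32, 20), n_respond = 0,
                                  n_nonrespond = 1, punctum_sigma = sigma,
                                  stim_onset = 0.5, stim_dur = 1,
                                  noise_sd = 0, seed = 1)
  xs <- seq_len(32)
  cen <- close$truth$centers[1, ]
  spot <- 100 * outer(exp(-(xs - cen[1] - 2.5)^2 / (2 * sigma^2)),
                      exp(-(xs - cen[2])^2 / (2 * sigma^2)))
  stack2 <- close$stack + array(rep(spot, 20), c(32, 32, 20))
  pl2 <- suppressWarnings(segment_puncta(stack2))
  expect_true(length(pl2) <= 2)
  if (length(pl2) == 1) expect_true(pl2[[1]]$merged)
})

test_that("responding classification behaves at strong signal and under the null", {
  set.seed(5)
  mk <- function(delta) punctum_trace(c(rnorm(20, 100, 2),
                                        rnorm(20, 100 + delta, 2),
                                        rnorm(20, 100, 2)))
  strong <- mk(20)
  for (m in c("wilcoxon", "sd4")) {
    cl <- classify_puncta(strong, baseline_window = 1:20,
                          evoked_window = 21:40, method = m, bleach = FALSE)
    expect_true(cl$responding)
  }
  # null false-positive rate of the rank test near its level
  set.seed(6)
  fp <- mean(vapply(1:400, function(i) {
    classify_puncta(mk(0), baseline_window = 1:20, evoked_window = 21:40,
                    bleach = FALSE)$responding
  }, logical(1)))
  expect_lt(abs(fp - 0.05), 0.03)
  # the 4 SD rule fires less often than the rank test under matched null noise
  set.seed(7)
  both <- vapply(1:400, function(i) {
    p <- mk(0)
    c(classify_puncta(p, baseline_window = 1:20, evoked_window = 21:40,
                      bleach = FALSE)$responding,
      classify_puncta(p, baseline_window = 1:20, evoked_window = 21:40,
                      method = "sd4", bleach = FALSE)$responding)
  }, logical(2))
  expect_lte(mean(both[2, ]), mean(both[1, ]))
  expect_invalid_argument(
    classify_puncta(mk(0), baseline_window = 1:3, evoked_window = 21:40))
  expect_invalid_argument(
    classify_puncta(mk(0), baseline_window = 1:20, evoked_window = 20:30))
})

test_that("Hill fits recover exact parameters, obey the identities and reject poor fits", {
  x <- c(50, 100, 150, 250, 400, 600, 800)
  y <- 1 + 0.04 * x^2 / (120^2 + x^2)
  hf <- fit_hill(x, y)
  expect_lt(abs(hf$y0 - 1) / 1, 0.01)
  expect_lt(abs(hf$a - 0.04) / 0.04, 0.01)
  expect_lt(abs(hf$c - 120) / 120, 0.01)
  expect_lt(abs(hf$b - 2) / 2, 0.01)
  expect_gt(hf$r2, 0.999)
  # half-activation identity at x = c
  y_at_c <- hf$y0 + hf$a * hf$c^hf$b / (hf$c^hf$b + hf$c^hf$b)
  expect_equal(y_at_c - hf$y0, hf$a / 2)
  # scale equivariance in the covariate
  hf2 <- fit_hill(3 * x, y)
  expect_equal(hf2$c / hf$c, 3, tolerance = 1e-4)
  # heavy noise drops r^2 below the acceptance gate
  set.seed(8)
  ybad <- y + rnorm(length(y), 0, 0.05)
  expect_error(fit_hill(x, ybad), class = "kv3noise_fit_rejected")
  expect_invalid_argument(fit_hill(x[1:4], y[1:4]))
})

test_that("ensemble fluorescence correlates with responding bouton counts", {
  counts <- c(2, 5, 9, 14, 18, 21)
  expect_equal(ensemble_bouton_correlation(0.01 * counts, counts), 1)
  set.seed(10)
  rs <- replicate(100, ensemble_bouton_correlation(rnorm(6), sample(1:20, 6)))
  expect_lt(abs(mean(rs)), 0.1)
  expect_undefined_result(ensemble_bouton_correlation(rep(1, 5), 1:5))
  # a sweep where responding count drives the ensemble signal
  set.seed(11)
  counts2 <- c(3, 6, 10, 15, 19, 22, 24)
  peaks <- 0.005 * counts2 * (1 + rnorm(7, 0, 0.05))
  expect_gt(ensemble_bouton_correlation(peaks, counts2), 0.9)
})
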