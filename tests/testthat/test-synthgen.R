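test_that("generators are bit-reproducible under a fixed seed", {
  a <- generate_psp_trace(5, seed = 77)
  b <- generate_psp_trace(5, seed = 77)
  expect_identical(a$trace$values, b$trace$values)
  expect_identical(a$truth$epsp_times, b$truth$epsp_times)
  p1 <- generate_sync_pair(n_ref = 50, n_async = 10, jitter_sd = 2, seed = 3)
  p2 <- generate_sync_pair(n_ref = 50, n_async = 10, jitter_sd = 2, seed = 3)
  expect_identical(as.numeric(p1$target), as.numeric(p2$target))
  # the dense default layout cannot honour the packing limit on a small
  # field, which warns rather than errors
  expect_warning(s1 <- generate_calcium_stack(dims = c(24, 24, 50), seed = 5),
                 "packing")
  expect_warning(s2 <- generate_calcium_stack(dims = c(24, 24, 50), seed = 5),
                 "packing")
  expect_identical(s1$stack, s2$stack)
  # the global RNG stream is untouched
  set.seed(1); x1 <- runif(1)
  set.seed(1); invisible(generate_psp_trace(1, seed = 9)); x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("Poisson event counts track rate times duration", {
  counts <- vapply(1:100, function(s)
    length(generate_psp_trace(20, epsp_rate = 4.1, ipsp_rate = 0,
                              noise_sd = 0, seed = s)$truth$epsp_times),
    numeric(1))
  expected <- 4.1 * 20
  se <- sqrt(expected / 100)
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("a silent noiseless trace is flat at rest and events obey their invariants", {
  g <- generate_psp_trace(2, epsp_rate = 0, ipsp_rate = 0, noise_sd = 0,
                          seed = 1)
  expect_true(all(g$trace$values == -65))
  g2 <- generate_psp_trace(10, seed = 2)
  for (tt in list(g2$truth$epsp_times, g2$truth$ipsp_times)) {
    expect_true(!is.unsorted(tt))
    expect_true(all(tt >= 0 & tt < 10))
  }
  expect_invalid_argument(generate_psp_trace(-1))
  expect_invalid_argument(psp_kernel_spec(1, 2, 1))
  expect_invalid_argument(psp_kernel_spec(0, 1, 2))
})

test_that("synchrony pairs honour the window geometry at both limits", {
  p <- generate_sync_pair(n_ref = 300, ref_rate = 10, n_async = 0,
                          jitter_sd = 0, seed = 1)
  expect_equal(as.numeric(p$ref), seq(0, 29.9, by = 0.1))
  expect_equal(as.numeric(p$target), as.numeric(p$ref))
  pa <- generate_sync_pair(n_ref = 100, n_async = 100, seed = 2)
  d <- vapply(as.numeric(pa$target),
              function(x) min(abs(x - as.numeric(pa$ref))), numeric(1))
  expect_true(all(d > 0.010))
  pj <- generate_sync_pair(n_ref = 100, n_async = 20, sync_halfwidth = 10,
                           jitter_sd = 4, seed = 3)
  expect_length(pj$target, 100)
  sync <- as.numeric(pj$target)[vapply(as.numeric(pj$target), function(x)
    min(abs(x - as.numeric(pj$ref))) <= 0.010, logical(1))]
  expect_length(sync, 80)
  expect_invalid_argument(generate_sync_pair(n_ref = 10, n_async = 11))
})

test_that("extracellular traces embed the template exactly and respect bounds", {
  fs <- 25000
  tmpl <- spike_template(fs, amp = 50)
  tr <- generate_extracellular_trace(0.01, tmpl, fs, noise_sd = 0,
                                     duration = 0.1, seed = 1)
  i0 <- round(0.01 * fs) + 1
  expect_equal(tr$values[i0:(i0 + length(tmpl) - 1)], tmpl)
  expect_true(all(tr$values[-(i0:(i0 + length(tmpl) - 1))] == 0))
  noise <- generate_extracellular_trace(numeric(0), tmpl, fs, noise_sd = 4,
                                        duration = 2, seed = 2)
  expect_lt(abs(sd(noise$values) - 4) / 4, 0.05)
  expect_invalid_argument(
    generate_extracellular_trace(0.2, tmpl, fs, duration = 0.1))
})

test_that("calcium stacks carry recoverable bleaching and responding labels", {
  # noiseless, stimulus-free stack: every punctum pixel is double-exponential
  g <- generate_calcium_stack(dims = c(24, 24, 60), n_respond = 0,
                              n_nonrespond = 2, noise_sd = 0, amp = 0,
                              bleach_taus = c(0.5, 5), seed = 4)
  px <- g$truth$centers[1, ]
  f <- g$stack[round(px[1]), round(px[2]), ]
  t <- (seq_along(f) - 1) * 0.1
  fit <- minpack.lm::nlsLM(f ~ A1 * exp(-t / t1) + A2 * exp(-t / t2),
                           start = list(A1 = f[1] / 2, t1 = 0.4,
                                        A2 = f[1] / 2, t2 = 4))
  r2 <- 1 - sum(resid(fit)^2) / sum((f - mean(f))^2)
  expect_gt(r2, 0.99)
  # strong transients, small noise: labels recovered across seeds
  for (s in 1:5) {
    gen <- generate_calcium_stack(dims = c(48, 48, 60), n_respond = 4,
                                  n_nonrespond = 4, amp = 1.5, noise_sd = 0.5,
                                  seed = s)
    pl <- segment_puncta(gen$stack)
    expect_length(pl, 8)
    cl <- classify_puncta(pl, baseline_window = 1:18, evoked_window = 22:40,
                          method = "sd4")
    cent <- t(vapply(cl, function(p) p$centroid, numeric(2)))
    truth_id <- apply(cent, 1, function(cc)
      which.min(colSums((t(gen$truth$centers) - cc)^2)))
    expect_equal(vapply(cl, function(p) p$responding, logical(1)),
                 gen$truth$responding[truth_id])
  }
  # no responders at zero amplitude: nothing exceeds baseline + 4 SD
  g0 <- generate_calcium_stack(dims = c(32, 32, 60), n_respond = 0,
                               n_nonrespond = 4, amp = 0, noise_sd = 1,
                               seed = 6)
  pl0 <- segment_puncta(g0$stack)
  cl0 <- classify_puncta(pl0, baseline_window = 1:18, evoked_window = 22:40,
                         method = "sd4")
  expect_true(!any(vapply(cl0, function(p) p$responding, logical(1))))
})

test_that("synthetic I-V data recover their Boltzmann parameters", {
  iv <- generate_iv_dataset(v50 = -11.4, noise_sd = 0)
  fit <- fit_boltzmann(iv$v_steps, conductance_from_iv(iv$v_steps, iv$currents))
  expect_lt(abs(fit$v50 - (-11.4)), 0.1)
  iv0 <- generate_iv_dataset(gmax = 0)
  expect_true(all(iv0$currents == 0))
  expect_warning(g0 <- conductance_from_iv(iv0$v_steps, iv0$currents))
  expect_error(fit_boltzmann(iv0$v_steps, g0), class = "kv3noise_error")
  # 5% noise: median half-activation error stays below half the slope factor
  errs <- vapply(1:50, function(s) {
    ivn <- generate_iv_dataset(noise_sd = 0.05, seed = s)
    fit_boltzmann(ivn$v_steps,
                  conductance_from_iv(ivn$v_steps, ivn$currents))$v50 + 11.4
  }, numeric(1))
  expect_lt(median(abs(errs)), 8 / 2)
})
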