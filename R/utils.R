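# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG seed, restoring global RNG state.
# Generators are bit-reproducible for a fixed seed because of this.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  force(code)
}

# Classed error conditions so callers can distinguish failure modes.
stop_kv3 <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "kv3noise_error"), call = call))
}

invalid_argument <- function(msg) stop_kv3(msg, "kv3noise_invalid_argument")
undefined_result <- function(msg) stop_kv3(msg, "kv3noise_undefined_result")
fit_rejected     <- function(msg) stop_kv3(msg, "kv3noise_fit_rejected")

`%||%` <- function(a, b) if (is.null(a)) b else a

# Linear convolution via FFT, 'same' alignment on the centre of an
# odd-length kernel.
conv_same <- function(x, k) {
  n <- length(x)
  m <- length(k)
  stopifnot(m %% 2L == 1L)
  N <- stats::nextn(n + m - 1L, 2)
  X <- stats::fft(c(x, rep(0, N - n)))
  K <- stats::fft(c(k, rep(0, N - m)))
  full <- Re(stats::fft(X * K, inverse = TRUE))[seq_len(n + m - 1L)] / N
  half <- (m - 1L) %/% 2L
  full[(half + 1L):(half + n)]
}

# Discrete analytic signal (one-sided spectrum doubling).
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1L] <- 1
    h[n / 2L + 1L] <- 1
    h[2L:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2L:((n + 1L) / 2L)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# Strict local maxima of y exceeding thr, thinned to a minimum separation
# (larger peaks win).
find_peaks <- function(y, thr, min_sep) {
  cand <- which(diff(sign(diff(y))) == -2) + 1L
  cand <- cand[y[cand] > thr]
  if (length(cand) == 0L) return(integer(0))
  ord <- cand[order(y[cand], decreasing = TRUE)]
  taken <- integer(0)
  for (i in ord) {
    if (length(taken) == 0L || all(abs(i - taken) >= min_sep)) {
      taken <- c(taken, i)
    }
  }
  sort(taken)
}

# Levenberg-Marquardt least squares on a residual function. Returns the
# nls.lm object, or NULL when the input is improper or the result is not
# finite; fit quality is judged downstream (r-squared gates), not here.
nls_lm_fit <- function(par, fn, lower = NULL, upper = NULL, maxiter = 500) {
  args <- list(par = par, fn = fn,
               control = minpack.lm::nls.lm.control(maxiter = maxiter))
  if (!is.null(lower)) args$lower <- lower
  if (!is.null(upper)) args$upper <- upper
  out <- tryCatch(do.call(minpack.lm::nls.lm, args), error = function(e) NULL)
  if (is.null(out) || out$info == 0 || any(!is.finite(out$par))) return(NULL)
  out
}

r_squared <- function(obs, fit) {
  ss_tot <- sum((obs - mean(obs))^2)
  if (ss_tot == 0) return(NA_real_)
  1 - sum((obs - fit)^2) / ss_tot
}
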