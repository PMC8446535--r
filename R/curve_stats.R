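#' Normalized conductance from an I-V dataset
#'
#' Converts currents to conductance, `G = I / (V - E_rev)` with a
#' theoretical K+ reversal of -85 mV, and normalizes by the maximum.
#'
#' @param v Step potentials, mV (must exclude `erev`).
#' @param i Currents, pA (steady-state or peak, per protocol).
#' @param erev Reversal potential, mV.
#' @return Normalized conductance `G/Gmax` per step. All-zero currents
#'   return zeros with a warning (normalization undefined).
#' @export
conductance_from_iv <- function(v, i, erev = -85) {
  if (length(v) != length(i)) invalid_argument("`v` and `i` must match")
  if (any(v == erev))
    invalid_argument("step potentials must exclude the reversal potential")
  g <- i / (v - erev)
  gmax <- max(g)
  if (gmax <= 0) {
    warning("maximal conductance is not positive; normalization skipped")
    return(g * 0)
  }
  g / gmax
}

#' Boltzmann fit of a conductance-voltage curve
#'
#' Fits \deqn{B(V) = a + (b - a) / (1 + e^{(V_{50} - V)/c})} to
#' normalized conductance, where `a` and `b` are the minimal and maximal
#' conductances, `V50` the half-activation voltage and `c` the slope
#' factor. Non-sigmoidal data (r^2 < `r2_min`) are rejected.
#'
#' @param v Step potentials, mV (>= 6 points spanning the transition).
#' @param g Normalized conductance `G/Gmax`.
#' @param r2_min Acceptance gate (default 0.8).
#' @return An object of class `boltzmann_fit`: `a`, `b`, `v50` (mV),
#'   `c` (mV), `r2`.
#' @export
fit_boltzmann <- function(v, g, r2_min = 0.8) {
  v <- as.numeric(v)
  g <- as.numeric(g)
  if (length(v) < 6) invalid_argument("need at least 6 voltage steps")
  mid <- (max(g) + min(g)) / 2
  v50_0 <- v[which.min(abs(g - mid))]
  model <- function(p) p[1] + (p[2] - p[1]) / (1 + exp((p[3] - v) / p[4]))
  fit <- nls_lm_fit(c(min(g), max(g), v50_0, diff(range(v)) / 6),
                    function(p) g - model(p))
  if (is.null(fit)) fit_rejected("Boltzmann fit did not converge")
  p <- fit$par
  if (p[4] <= 0)
    fit_rejected("Boltzmann fit rejected: non-positive slope factor")
  r2 <- r_squared(g, model(p))
  if (!is.finite(r2) || r2 < r2_min)
    fit_rejected(sprintf("Boltzmann fit rejected: r^2 = %.3f < %.2f",
                         r2, r2_min))
  structure(list(a = p[1], b = p[2], v50 = p[3], c = p[4], r2 = r2),
            class = "boltzmann_fit")
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  cat(sprintf("<boltzmann_fit> V50 = %.2f mV, slope = %.2f mV, range [%.3f, %.3f] (r2 = %.3f)\n",
              x$v50, x$c, x$a, x$b, x$r2))
  invisible(x)
}

#' Average correlation coefficients via Fisher's z transformation
#'
#' Averages correlations on the variance-stabilized scale:
#' `tanh(mean(atanh(r)))`.
#'
#' @param rs Correlation coefficients, all strictly inside (-1, 1).
#' @return The back-transformed mean correlation.
#' @export
fisher_mean_r <- function(rs) {
  rs <- as.numeric(rs)
  if (length(rs) == 0L) invalid_argument("no correlations supplied")
  if (any(abs(rs) >= 1))
    invalid_argument("Fisher z is undefined at |r| = 1")
  tanh(mean(atanh(rs)))
}

#' Holm (step-down Bonferroni) correction
#'
#' Adjusts a family of P-values with the Bonferroni-Holm step-down
#' procedure (monotone, capped at 1). Plain Bonferroni multiplication is
#' available via `method = "bonferroni"`.
#'
#' @param pvals P-values in \[0, 1\].
#' @param method `"holm"` (default) or `"bonferroni"`.
#' @return Adjusted P-values in the original order.
#' @export
holm_correct <- function(pvals, method = c("holm", "bonferroni")) {
  method <- match.arg(method)
  if (any(pvals < 0 | pvals > 1)) invalid_argument("P-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = method)
}

#' Paired equivalence test (TOST)
#'
#' Two one-sided paired t-tests of the mean difference `test - ref`
#' against a lower and an upper equivalence bound; the groups are
#' declared equivalent iff both one-sided tests reject at level `alpha`.
#' With `scale = "mean"` the bounds are interpreted on the test-group
#' mean instead of the difference.
#'
#' @param ref,test Paired observation vectors of equal length (n >= 3).
#' @param bounds Ordered equivalence bounds `c(lower, upper)`.
#' @param alpha Level of each one-sided test (default 0.05).
#' @param scale `"difference"` (bounds on mean(test - ref)) or `"mean"`
#'   (bounds on mean(test)).
#' @return List with `equivalent`, the `1 - 2*alpha` confidence interval
#'   `ci`, `p_lower`, `p_upper` and `mean_value`.
#' @export
tost_equivalence <- function(ref, test, bounds, alpha = 0.05,
                             scale = c("difference", "mean")) {
  scale <- match.arg(scale)
  if (length(ref) != length(test)) invalid_argument("paired samples must match")
  if (length(test) < 3) invalid_argument("need at least 3 pairs")
  if (bounds[1] >= bounds[2]) invalid_argument("bounds must be ordered")
  d <- if (scale == "difference") test - ref else test
  m <- mean(d)
  s <- stats::sd(d)
  n <- length(d)
  if (s <= 1e-12 * max(abs(m), 1)) {  # degenerate: constant differences
    equivalent <- m > bounds[1] && m < bounds[2]
    return(list(equivalent = equivalent, ci = c(m, m),
                p_lower = as.numeric(!(m > bounds[1])),
                p_upper = as.numeric(!(m < bounds[2])),
                mean_value = m))
  }
  p_lower <- stats::t.test(d, mu = bounds[1], alternative = "greater")$p.value
  p_upper <- stats::t.test(d, mu = bounds[2], alternative = "less")$p.value
  se <- s / sqrt(n)
  tcrit <- stats::qt(1 - alpha, df = n - 1)
  list(equivalent = p_lower < alpha && p_upper < alpha,
       ci = c(m - tcrit * se, m + tcrit * se),
       p_lower = p_lower, p_upper = p_upper, mean_value = m)
}
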