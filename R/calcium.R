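#' Photobleaching correction by double-exponential subtraction
#'
#' Fits a double exponential `A1 exp(-t/tau1) + A2 exp(-t/tau2) + C` to
#' the frames outside the evoked window (pre- and post-stimulation) and
#' subtracts the fitted decay terms from the whole trace, preserving the
#' constant offset so that F/F0 normalization remains meaningful. When
#' the two fitted time constants are degenerate (ratio < 2) or the
#' double-exponential fit fails, a single exponential is used instead; a
#' constant trace is passed through unchanged.
#'
#' @param f Raw fluorescence series (one value per frame).
#' @param stim_window Frame indices covering the evoked response
#'   (excluded from the fit).
#' @param frame_dt Frame interval, s (only scales the reported taus).
#' @param keep_offset Keep the fitted constant offset in the corrected
#'   trace (default `TRUE`); `FALSE` subtracts the full fit.
#' @return Corrected series with attributes `fit` (fitted bleach curve
#'   over all frames) and `taus` (s).
#' @export
bleach_correct <- function(f, stim_window, frame_dt = 1, keep_offset = TRUE) {
  f <- as.numeric(f)
  n <- length(f)
  idx <- setdiff(seq_len(n), stim_window)
  if (sum(idx < min(stim_window)) < 10 || sum(idx > max(stim_window)) < 10)
    invalid_argument("need at least 10 non-evoked frames on each side of the stimulus")
  t_all <- (seq_len(n) - 1) * frame_dt
  tt <- t_all[idx]
  ff <- f[idx]
  if (stats::sd(ff) < 1e-12 * max(abs(ff), 1)) {
    out <- if (keep_offset) f else f - mean(ff)
    attr(out, "fit") <- rep(mean(ff), n)
    attr(out, "taus") <- numeric(0)
    return(out)
  }
  span <- max(tt) - min(tt)
  a0 <- ff[1] - ff[length(ff)]
  m2 <- function(p, t) p[1] * exp(-t / p[2]) + p[3] * exp(-t / p[4]) + p[5]
  fit2 <- nls_lm_fit(c(0.3 * a0, span / 10, 0.7 * a0, span, ff[length(ff)]),
                     function(p) ff - m2(p, tt),
                     lower = c(-Inf, span / 1e4, -Inf, span / 1e4, -Inf))
  # a component with tau far beyond the recording is an offset in disguise
  fold_flat <- function(amps, taus, C) {
    flat <- taus > 10 * span
    list(amps = amps[!flat], taus = taus[!flat], C = C + sum(amps[flat]))
  }
  comp <- NULL
  if (!is.null(fit2)) {
    comp <- fold_flat(fit2$par[c(1, 3)], fit2$par[c(2, 4)], fit2$par[5])
    if (length(comp$taus) == 2 &&
        max(comp$taus) / min(comp$taus) < 2) comp <- NULL  # degenerate pair
  }
  if (is.null(comp)) {
    m1 <- function(p, t) p[1] * exp(-t / p[2]) + p[3]
    fit1 <- nls_lm_fit(c(a0, span / 3, ff[length(ff)]),
                       function(p) ff - m1(p, tt),
                       lower = c(-Inf, span / 1e4, -Inf))
    if (is.null(fit1))
      fit_rejected("bleach fit diverged for both double and single exponential models")
    comp <- fold_flat(fit1$par[1], fit1$par[2], fit1$par[3])
  }
  decay <- rep(0, n)
  for (i in seq_along(comp$taus))
    decay <- decay + comp$amps[i] * exp(-t_all / comp$taus[i])
  C <- comp$C
  taus <- sort(comp$taus)
  out <- if (keep_offset) f - decay else f - decay - C
  attr(out, "fit") <- as.numeric(decay + C)
  attr(out, "taus") <- taus
  out
}

#' Fluorescence normalization F/F0
#'
#' Divides a (bleach-corrected) fluorescence series by F0, the mean raw
#' pre-stimulation fluorescence computed before bleach subtraction.
#'
#' @param f Raw fluorescence series.
#' @param pre_window Frame indices of the pre-stimulation baseline.
#' @param stim_window Optional evoked frame indices; when supplied the
#'   numerator is bleach-corrected with [bleach_correct()] first.
#' @param frame_dt Frame interval, s (passed to the bleach fit).
#' @return F/F0 series.
#' @export
dff <- function(f, pre_window, stim_window = NULL, frame_dt = 1) {
  f <- as.numeric(f)
  if (length(pre_window) == 0L) invalid_argument("`pre_window` must be nonempty")
  f0 <- mean(f[pre_window])
  if (!is.finite(f0) || f0 <= 0)
    invalid_argument("F0 (mean raw pre-stimulation fluorescence) must be positive")
  num <- if (is.null(stim_window)) f else
    as.numeric(bleach_correct(f, stim_window, frame_dt = frame_dt))
  num / f0
}

#' Single-punctum trace container
#'
#' @param f Raw fluorescence per frame.
#' @param centroid Punctum centroid, pixels `c(x, y)`.
#' @param id Identifier.
#' @param baseline_window,evoked_window Frame index ranges.
#' @param merged Flag set by segmentation when two puncta could not be
#'   separated.
#' @return An object of class `punctum_trace`.
#' @export
punctum_trace <- function(f, centroid = c(NA, NA), id = NA_integer_,
                          baseline_window = NULL, evoked_window = NULL,
                          merged = FALSE) {
  structure(list(f = as.numeric(f), centroid = centroid, id = id,
                 baseline_window = baseline_window,
                 evoked_window = evoked_window,
                 dff = NULL, peak_dff = NA_real_,
                 responding = NA, method = NA_character_, merged = merged),
            class = "punctum_trace")
}

# 3x3x3 median filter with edge replication; stacks are modest so the
# 27-shift construction is adequate.
median_filter_3d <- function(a) {
  d <- dim(a)
  pad <- a[c(1, seq_len(d[1]), d[1]),
           c(1, seq_len(d[2]), d[2]),
           c(1, seq_len(d[3]), d[3])]
  vals <- matrix(0, prod(d), 27L)
  k <- 0L
  for (i in 0:2) for (j in 0:2) for (l in 0:2) {
    k <- k + 1L
    vals[, k] <- as.vector(pad[i + seq_len(d[1]), j + seq_len(d[2]),
                               l + seq_len(d[3])])
  }
  array(apply(vals, 1L, stats::median), d)
}

#' Segment fluorescent puncta in an image stack
#'
#' Median-filters the stack in x, y and time (3 x 3 x 3), forms a mean
#' time projection, background-subtracts it, thresholds at a robust SD
#' multiple, and labels connected components as puncta. Each punctum's
#' trace is the per-frame mean of the raw stack over its mask. A
#' component containing more than one well-separated local maximum is
#' flagged as `merged`.
#'
#' @param stack Numeric array `x * y * frames`.
#' @param thr Threshold in robust SD multiples of the projection.
#' @param min_pixels Minimum component size, pixels.
#' @param background_subtract Subtract the projection median first.
#' @return List of [punctum_trace()] objects (empty when nothing is
#'   found), with the projection and label matrix as attributes.
#' @export
segment_puncta <- function(stack, thr = 4, min_pixels = 3,
                           background_subtract = TRUE) {
  stopifnot(length(dim(stack)) == 3L)
  sm <- median_filter_3d(stack)
  proj <- apply(sm, c(1, 2), mean)
  if (background_subtract) proj <- proj - stats::median(proj)
  s_rob <- stats::mad(proj)
  if (s_rob == 0) s_rob <- stats::sd(proj)
  if (is.na(s_rob) || s_rob == 0) return(list())
  mask <- proj > thr * s_rob
  # watershed on the masked intensity so touching puncta split at saddles
  relief <- pmax(proj, 0) * mask
  mx <- max(relief)
  lab <- if (mx > 0) {
    EBImage::watershed(EBImage::Image(relief / mx), tolerance = 0.2)
  } else {
    EBImage::bwlabel(EBImage::Image(mask * 1))
  }
  lab <- EBImage::imageData(lab)
  nlab <- max(lab)
  if (nlab == 0) return(structure(list(), projection = proj, labels = lab))
  out <- list()
  for (id in seq_len(nlab)) {
    sel <- lab == id
    if (sum(sel) < min_pixels) next
    px <- which(sel, arr.ind = TRUE)
    centroid <- colMeans(px)
    # local maxima of the projection inside the mask
    is_max <- vapply(seq_len(nrow(px)), function(r) {
      i <- px[r, 1]; j <- px[r, 2]
      ii <- max(1, i - 1):min(nrow(proj), i + 1)
      jj <- max(1, j - 1):min(ncol(proj), j + 1)
      proj[i, j] >= max(proj[ii, jj])
    }, logical(1))
    maxima <- px[is_max, , drop = FALSE]
    merged <- FALSE
    if (nrow(maxima) > 1) {
      dd <- stats::dist(maxima)
      merged <- max(dd) > 2
    }
    # a strongly elongated component is a fused pair even when the saddle
    # between the two maxima has been smoothed away
    if (!merged && nrow(px) >= 6) {
      w <- pmax(proj[sel], 0)
      if (sum(w) > 0) {
        mu <- colSums(px * w) / sum(w)
        cc <- sweep(px, 2, mu)
        cov_w <- crossprod(cc * sqrt(w / sum(w)))
        ev <- eigen(cov_w, symmetric = TRUE, only.values = TRUE)$values
        # single puncta measure ~1.0-1.1 even with noise; sub-resolution
        # fused pairs exceed ~1.25
        if (ev[2] > 0 && sqrt(ev[1] / ev[2]) > 1.15) merged <- TRUE
      }
    }
    if (merged)
      warning(sprintf("punctum %d contains multiple maxima; flagged as merged",
                      id))
    f <- vapply(seq_len(dim(stack)[3]), function(k) mean(stack[, , k][sel]),
                numeric(1))
    out[[length(out) + 1L]] <- punctum_trace(
      f, centroid = c(centroid[[1]], centroid[[2]]),
      id = length(out) + 1L, merged = merged)
  }
  structure(out, projection = proj, labels = lab)
}

#' Classify puncta as responding or non-responding
#'
#' Two classification rules for stimulus-evoked fluorescence increases:
#' `"wilcoxon"` — a one-sided Wilcoxon rank-sum test of evoked versus
#' baseline frames at level `alpha` (exact for small samples without
#' ties, normal approximation with tie correction otherwise);
#' `"sd4"` — responding if the maximum evoked fluorescence exceeds the
#' baseline mean by more than 4 baseline SDs. Both rules operate on the
#' bleach-corrected trace.
#'
#' @param puncta List of [punctum_trace()] objects (or a single one).
#' @param baseline_window,evoked_window Frame index ranges (each >= 5
#'   frames for the rank test). Per-punctum windows take precedence.
#' @param alpha Test level for the rank-sum rule.
#' @param method `"wilcoxon"` (default) or `"sd4"`.
#' @param bleach Apply [bleach_correct()] with the evoked window before
#'   testing (default `TRUE`).
#' @return The input list with `responding`, `peak_dff` and `method`
#'   fields filled in.
#' @export
classify_puncta <- function(puncta, baseline_window = NULL,
                            evoked_window = NULL, alpha = 0.05,
                            method = c("wilcoxon", "sd4"), bleach = TRUE) {
  method <- match.arg(method)
  single <- inherits(puncta, "punctum_trace")
  if (single) puncta <- list(puncta)
  out <- lapply(puncta, function(p) {
    bw <- p$baseline_window %||% baseline_window
    ew <- p$evoked_window %||% evoked_window
    if (is.null(bw) || is.null(ew))
      invalid_argument("baseline and evoked windows must be supplied")
    if (length(intersect(bw, ew)))
      invalid_argument("baseline and evoked windows must be disjoint")
    if (method == "wilcoxon" && (length(bw) < 5 || length(ew) < 5))
      invalid_argument("rank test needs at least 5 frames in each window")
    fc <- if (bleach) {
      tryCatch(as.numeric(bleach_correct(p$f, stim_window = ew)),
               error = function(e) {
                 warning("bleach fit failed for a punctum; classifying the raw trace")
                 p$f
               })
    } else p$f
    base <- fc[bw]
    ev <- fc[ew]
    p$responding <- if (method == "wilcoxon") {
      pv <- suppressWarnings(
        stats::wilcox.test(ev, base, alternative = "greater")$p.value)
      pv < alpha
    } else {
      max(ev) > mean(base) + 4 * stats::sd(base)
    }
    p$method <- method
    p$baseline_window <- bw
    p$evoked_window <- ew
    f0 <- mean(p$f[bw])
    if (f0 > 0) {
      p$dff <- fc / f0
      p$peak_dff <- max(p$dff[ew])
    }
    p
  })
  if (single) out[[1]] else out
}

#' Four-parameter Hill fit of intensity-response data
#'
#' Fits `y = y0 + a x^b / (c^b + x^b)` to peak evoked fluorescence versus
#' stimulus intensity, where `c` is the half-activation intensity (I50)
#' and `b` the Hill coefficient. Fits with r^2 <= `r2_min` are rejected.
#' The rising slope is a linear regression over the points whose
#' intensity lies where the fitted curve is between 20% and 80% of its
#' dynamic range `a` (falling back to the fitted curve itself when fewer
#' than two observations lie there).
#'
#' @param intensities Stimulus intensities, uA (>= 5 levels spanning
#'   initiation to plateau).
#' @param peaks Peak evoked F/F0 per intensity.
#' @param r2_min Acceptance gate on the Hill fit r^2 (default 0.85).
#' @return An object of class `hill_fit`: `y0`, `a`, `c`, `b`, `r2`,
#'   `rising_slope` (F/F0 per uA), `slope_r2`.
#' @export
fit_hill <- function(intensities, peaks, r2_min = 0.85) {
  x <- as.numeric(intensities)
  y <- as.numeric(peaks)
  if (length(x) < 5) invalid_argument("need at least 5 intensity levels")
  if (any(x < 0)) invalid_argument("intensities must be non-negative")
  model <- function(p) p[1] + p[2] * x^p[4] / (p[3]^p[4] + x^p[4])
  fit <- nls_lm_fit(c(min(y), max(y) - min(y), stats::median(x), 2),
                    function(p) y - model(p),
                    lower = c(-Inf, 1e-12, 1e-9, 0.1),
                    upper = c(Inf, Inf, Inf, 20))
  if (is.null(fit)) fit_rejected("Hill fit did not converge")
  if (fit$par[3] <= 0 || fit$par[4] <= 0 || fit$par[2] <= 0)
    fit_rejected("Hill fit rejected: non-physical parameters")
  cf <- list(y0 = fit$par[1], a = fit$par[2], c = fit$par[3], b = fit$par[4])
  r2 <- r_squared(y, model(fit$par))
  if (!is.finite(r2) || r2 <= r2_min)
    fit_rejected(sprintf("Hill fit rejected: r^2 = %.3f <= %.2f", r2, r2_min))
  x20 <- cf$c * (0.2 / 0.8)^(1 / cf$b)
  x80 <- cf$c * (0.8 / 0.2)^(1 / cf$b)
  sel <- x >= x20 & x <= x80
  if (sum(sel) >= 2) {
    lf <- stats::lm(y[sel] ~ x[sel])
    slope <- unname(coef(lf)[2])
    slope_r2 <- r_squared(y[sel], fitted(lf))
  } else {
    xg <- seq(x20, x80, length.out = 20)
    yg <- cf$y0 + cf$a * xg^cf$b / (cf$c^cf$b + xg^cf$b)
    lf <- stats::lm(yg ~ xg)
    slope <- unname(coef(lf)[2])
    slope_r2 <- r_squared(yg, fitted(lf))
  }
  structure(list(y0 = cf$y0, a = cf$a, c = cf$c, b = cf$b, r2 = r2,
                 rising_slope = slope, slope_r2 = slope_r2),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf(
    "<hill_fit> y0 = %.3g, a = %.3g, I50 = %.3g, b = %.2f (r2 = %.3f); rising slope %.3g (r2 = %.3f)\n",
    x$y0, x$a, x$c, x$b, x$r2, x$rising_slope, x$slope_r2))
  invisible(x)
}

#' Ensemble fluorescence versus responding-bouton-count correlation
#'
#' Pearson correlation between the peak ensemble F/F0 at each stimulus
#' intensity and the number of responding boutons at that intensity.
#' Correlations from multiple recordings are combined with
#' [fisher_mean_r()].
#'
#' @param peaks Peak ensemble F/F0 per intensity.
#' @param counts Responding bouton counts per intensity.
#' @return Pearson r.
#' @export
ensemble_bouton_correlation <- function(peaks, counts) {
  if (length(peaks) != length(counts) || length(peaks) < 3)
    invalid_argument("need at least 3 paired intensity points")
  if (stats::sd(peaks) == 0 || stats::sd(counts) == 0)
    undefined_result("correlation undefined with zero variance")
  stats::cor(peaks, counts)
}
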