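# Model-based SNR of oscillatory peaks: a 1/f noise baseline curve plus
# Gaussian peak bumps fitted to the PSD in decibels; SNR is the maximal
# height of the fitted peak curve above the fitted noise curve.

# Linear least squares for the noise curve k + a * f^(-b) at fixed b.
noise_ls <- function(psd, freqs, b, mask = NULL) {
  if (is.null(mask)) mask <- rep(TRUE, length(psd))
  X <- cbind(1, freqs[mask]^(-b))
  cf <- tryCatch(qr.solve(X, psd[mask]), error = function(e) c(NA, NA))
  if (any(!is.finite(cf))) return(list(rss = Inf))
  fit <- cbind(1, freqs^(-b)) %*% cf
  list(k = cf[1L], a = cf[2L], b = b, curve = as.numeric(fit),
       rss = sum((psd[mask] - X %*% cf)^2))
}

# Fit the noise baseline over a deterministic exponent grid, then mask bins
# more than one residual SD above the curve (presumed peaks) and refit once;
# optionally polish (k, a, b) with bounded Levenberg-Marquardt.
fit_noise_curve <- function(psd, freqs, b_grid = seq(0.25, 3, by = 0.25),
                            polish = TRUE) {
  pick <- function(mask) {
    fits <- lapply(b_grid, function(b) noise_ls(psd, freqs, b, mask))
    fits[[which.min(vapply(fits, `[[`, 0, "rss"))]]
  }
  f0 <- pick(NULL)
  resid <- psd - f0$curve
  mask <- resid <= stats::sd(resid)
  if (sum(mask) < 5L) mask <- rep(TRUE, length(psd))
  f1 <- pick(mask)
  if (polish) {
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nlsLM(
        p ~ k + a * f^(-b),
        data = list(p = psd[mask], f = freqs[mask]),
        start = list(k = f1$k, a = f1$a, b = f1$b),
        lower = c(-Inf, -Inf, 0), upper = c(Inf, Inf, 6),
        control = minpack.lm::nls.lm.control(maxiter = 40))),
      error = function(e) NULL)
    if (!is.null(fit)) {
      cf <- stats::coef(fit)
      f1 <- list(k = unname(cf["k"]), a = unname(cf["a"]), b = unname(cf["b"]),
                 curve = as.numeric(cf["k"] + cf["a"] * freqs^(-cf["b"])),
                 rss = sum(stats::resid(fit)^2))
    }
  }
  f1
}

gauss_bump <- function(freqs, center, width, height)
  height * exp(-(freqs - center)^2 / (2 * width^2))

# Fit one Gaussian bump to a residual spectrum: deterministic (center, width)
# grid with linear height, then a bounded Levenberg-Marquardt polish.
fit_one_peak <- function(resid, freqs, polish = TRUE) {
  c0 <- freqs[which.max(resid)]
  h0 <- max(resid)
  if (h0 <= 0) return(NULL)
  best <- NULL
  for (w in c(0.75, 1.5, 3)) {
    g <- exp(-(freqs - c0)^2 / (2 * w^2))
    h <- max(0, sum(g * resid) / sum(g^2))
    rss <- sum((resid - h * g)^2)
    if (is.null(best) || rss < best$rss)
      best <- list(center = c0, width = w, height = h, rss = rss)
  }
  if (polish) {
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nlsLM(
        r ~ h * exp(-(f - c)^2 / (2 * w^2)),
        data = list(r = resid, f = freqs),
        start = list(h = max(best$height, 1e-3), c = best$center,
                     w = best$width),
        lower = c(0, min(freqs), 0.3), upper = c(Inf, max(freqs), 8),
        control = minpack.lm::nls.lm.control(maxiter = 30))),
      error = function(e) NULL)
    if (!is.null(fit)) {
      cf <- stats::coef(fit)
      best <- list(center = unname(cf["c"]), width = unname(cf["w"]),
                   height = unname(cf["h"]),
                   rss = sum(stats::resid(fit)^2))
    }
  }
  best
}

#' Parametric PSD model fit (noise baseline + peaks)
#'
#' Fits, in decibel units, a decaying noise baseline `k + a * f^(-b)` (linear
#' least squares over a deterministic exponent grid, with one peak-masked
#' refit) and up to `n_peaks_max` Gaussian bumps on the residual (grid
#' initialization plus a bounded Levenberg-Marquardt polish). The objective
#' throughout is the L2 norm of the difference between the PSD and the model
#' curves.
#'
#' @param psd per-frequency power in dB.
#' @param freqs frequencies, Hz (positive).
#' @param n_peaks_max maximal number of peak bumps.
#' @param min_height bumps lower than this (dB) are not retained.
#' @param polish run the Levenberg-Marquardt polish after grid init.
#' @return object of class `PSDModelFit`: `noise_params` `(offset, scale,
#'   exponent)`, `peak_params` (list of `(center, width, height)`),
#'   `residual` (L2 norm), `fitted_noise`, `fitted_total`, `freqs`,
#'   `degenerate` flag (exponent at the grid bound).
#' @export
fit_psd_model <- function(psd, freqs, n_peaks_max = 2L, min_height = 0.5,
                          polish = TRUE) {
  psd <- as.numeric(psd); freqs <- as.numeric(freqs)
  if (any(!is.finite(psd)) || any(!is.finite(freqs)))
    stop("non-finite PSD or frequency values")
  if (length(psd) < 20L)
    stop("need >= 20 frequency points for a stable fit")
  nf <- fit_noise_curve(psd, freqs, polish = polish)
  degenerate <- nf$b >= 6 || nf$b <= 0.01
  if (nf$b <= 0.01 || abs(nf$a) < 1e-8) {
    ## near-flat spectra: prefer the explicit constant baseline when it fits
    ## at least as well
    k0 <- mean(psd)
    if (sum((psd - k0)^2) <= sum((psd - nf$curve)^2) * 1.001)
      nf <- list(k = k0, a = 0, b = 0, curve = rep(k0, length(psd)))
  }
  resid <- psd - nf$curve
  peaks <- list()
  for (p in seq_len(n_peaks_max)) {
    pk <- fit_one_peak(resid, freqs, polish = polish)
    if (is.null(pk) || pk$height < min_height) break
    peaks[[length(peaks) + 1L]] <-
      c(center = pk$center, width = pk$width, height = pk$height)
    resid <- resid - gauss_bump(freqs, pk$center, pk$width, pk$height)
  }
  total <- nf$curve
  for (pk in peaks)
    total <- total + gauss_bump(freqs, pk["center"], pk["width"], pk["height"])
  structure(list(noise_params = c(offset = unname(nf$k), scale = unname(nf$a),
                                  exponent = unname(nf$b)),
                 peak_params = peaks,
                 residual = sqrt(sum((psd - total)^2)),
                 fitted_noise = nf$curve, fitted_total = total,
                 freqs = freqs, degenerate = degenerate),
            class = "PSDModelFit")
}

#' SNR from a fitted PSD model
#'
#' Evaluates the fitted peak curve (sum of bumps) on a fine frequency grid
#' and returns its maximal height above the fitted noise curve — zero when no
#' peak was retained.
#'
#' @param fit a [fit_psd_model()].
#' @return object of class `SNREstimate`: `snr` (dB), `peak_freq` (Hz, `NA`
#'   without peaks).
#' @export
snr_from_fit <- function(fit) {
  stopifnot(inherits(fit, "PSDModelFit"))
  if (length(fit$peak_params) == 0L)
    return(structure(list(snr = 0, peak_freq = NA_real_),
                     class = "SNREstimate"))
  f <- seq(min(fit$freqs), max(fit$freqs), by = 0.05)
  peak_total <- rep(0, length(f))
  for (pk in fit$peak_params)
    peak_total <- peak_total + gauss_bump(f, pk["center"], pk["width"],
                                          pk["height"])
  i <- which.max(peak_total)
  structure(list(snr = max(0, peak_total[i]), peak_freq = f[i]),
            class = "SNREstimate")
}

# Auto-spectra (dB) of component series: same cross-trial Hann/zero-padded
# estimator as the connectivity layer. x: n_series x samples x trials.
component_psd_db <- function(x, fs, nfft = 128L, fmin = 3, fmax = 40) {
  cs <- cross_spectrum(x, fs, nfft)
  keep <- which(cs$freqs >= fmin & cs$freqs <= fmax)
  n <- dim(cs$S)[2L]
  psd <- matrix(0, length(keep), n)
  for (j in seq_len(n))
    psd[, j] <- 10 * log10(pmax(Re(cs$S[keep, j, j]), .Machine$double.xmin))
  list(psd = psd, freqs = cs$freqs[keep])
}

#' Subject-level SNR for one analysis interval
#'
#' Fits the PSD model to every SVD component of every ROI, separately per
#' class, and averages the resulting SNR values. Components whose fit fails
#' are skipped with a warning; more than 50% failures is an error.
#'
#' @param rc an [extract_roi_components()] result for the interval.
#' @param nfft FFT length for the PSD estimate.
#' @param per_class fit separately per class (as in the reference analysis)
#'   or once on all trials pooled (faster, used at cohort scale).
#' @param polish see [fit_psd_model()].
#' @return scalar mean SNR (dB).
#' @export
subject_snr <- function(rc, nfft = 128L, per_class = TRUE, polish = TRUE) {
  stopifnot(inherits(rc, "ROIComponents"))
  groups <- if (per_class) unique(rc$labels) else list(unique(rc$labels))
  vals <- c(); fails <- 0L
  for (roi in names(rc$comps)) {
    for (g in groups) {
      x <- rc$comps[[roi]][, , rc$labels %in% g, drop = FALSE]
      pd <- component_psd_db(x, rc$fs, nfft)
      for (j in seq_len(ncol(pd$psd))) {
        s <- tryCatch({
          fit <- fit_psd_model(pd$psd[, j], pd$freqs, polish = polish)
          snr_from_fit(fit)$snr
        }, error = function(e) NA_real_)
        if (is.na(s)) fails <- fails + 1L else vals <- c(vals, s)
      }
    }
  }
  if (fails > 0L)
    warning(sprintf("%d component fit(s) failed and were skipped", fails))
  if (fails > length(vals)) stop("more than 50% of component fits failed")
  mean(vals)
}
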