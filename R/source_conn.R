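# eLORETA source reconstruction, ROI component extraction, cross-trial
# spectral estimation, imaginary coherency and its band/scheme aggregates.

# Symmetric PSD matrix square root / inverse square root via eigen.
sym_sqrt <- function(S, inverse = FALSE, eps = 1e-12) {
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  v <- pmax(e$values, eps * max(e$values, eps))
  d <- if (inverse) 1 / sqrt(v) else sqrt(v)
  e$vectors %*% (d * t(e$vectors))
}

#' eLORETA inverse operator
#'
#' Iterates the eLORETA weight equations to their fixed point: with per-source
#' 3x3 weight blocks `W_s`, the sensor-space model covariance is
#' `C = sum_s L_s W_s^{-1} L_s'`, and each block is updated to
#' `W_s = (L_s' (C + alpha I)^+ L_s)^{1/2}` until the relative change of the
#' weights falls below `tol`. The kernel is
#' `K = W^{-1} L' (L W^{-1} L' + alpha I)^+`, which for a noiseless point
#' source localizes the source exactly (the defining property of eLORETA).
#'
#' @param lf a [make_lead_field()] object.
#' @param reg Tikhonov regularization as a fraction of the mean sensor-space
#'   model power (`trace(C)/channels`); `0` uses a pseudoinverse.
#' @param tol convergence tolerance on the relative Frobenius change of the
#'   weight blocks.
#' @param max_iter iteration cap; exceeding it is an error that reports the
#'   last change.
#' @return object of class `InverseOperator` with `kernel`
#'   (`(3*sources) x channels`), `regularization`, `n_iter`, `delta`.
#' @export
eloreta_inverse <- function(lf, reg = 0.05, tol = 1e-6, max_iter = 200L) {
  stopifnot(inherits(lf, "LeadField"))
  L <- lf$gain
  if (!all(is.finite(L))) stop("lead field must be finite")
  C <- nrow(L)
  if (C < 2L) stop("need >= 2 channels")
  S <- length(lf$roi_labels)
  Winv <- replicate(S, diag(3), simplify = FALSE)
  delta <- Inf
  iter <- 0L
  alpha <- 0
  repeat {
    iter <- iter + 1L
    ## Cmat = L W^-1 L'
    LW <- L
    for (s in seq_len(S)) {
      cols <- (s - 1L) * 3L + (1:3)
      LW[, cols] <- L[, cols] %*% Winv[[s]]
    }
    Cmat <- LW %*% t(L)
    alpha <- reg * sum(diag(Cmat)) / C
    M <- if (alpha > 0) solve(Cmat + alpha * diag(C)) else MASS::ginv(Cmat)
    delta <- 0
    for (s in seq_len(S)) {
      cols <- (s - 1L) * 3L + (1:3)
      ## W_s = (L_s' M L_s)^(1/2); store its inverse for the kernel
      Wold_inv <- Winv[[s]]
      Winv[[s]] <- sym_sqrt(t(L[, cols]) %*% M %*% L[, cols], inverse = TRUE)
      delta <- max(delta, norm(Winv[[s]] - Wold_inv, "F") /
                     max(norm(Wold_inv, "F"), .Machine$double.eps))
    }
    if (delta < tol) break
    if (iter >= max_iter)
      stop(sprintf("eLORETA did not converge in %d iterations (last delta %g)",
                   max_iter, delta))
  }
  LW <- L
  for (s in seq_len(S)) {
    cols <- (s - 1L) * 3L + (1:3)
    LW[, cols] <- L[, cols] %*% Winv[[s]]
  }
  Cmat <- LW %*% t(L)
  M <- if (alpha > 0) solve(Cmat + alpha * diag(C)) else MASS::ginv(Cmat)
  K <- t(LW) %*% M    # = W^-1 L' M
  structure(list(kernel = K, regularization = reg, n_iter = iter,
                 delta = delta, n_sources = S, roi_labels = lf$roi_labels,
                 winv = Winv, alpha = alpha),
            class = "InverseOperator")
}

#' @export
print.InverseOperator <- function(x, ...) {
  cat(sprintf("<InverseOperator> eLORETA, %d sources, reg %.3g, %d iterations\n",
              x$n_sources, x$regularization, x$n_iter))
  invisible(x)
}

#' Source power map of a sensor topography
#'
#' Applies the inverse kernel to a sensor vector and returns the per-source
#' power (squared norm over the three orientations) — the localizer used in
#' the exact point-source localization property.
#'
#' @param inv an [eloreta_inverse()] operator.
#' @param topo sensor vector (channels).
#' @return numeric vector of per-source power.
#' @export
source_power_map <- function(inv, topo) {
  s <- inv$kernel %*% as.numeric(topo)
  colSums(matrix(s^2, 3L))
}

#' ROI component time series via source projection and SVD
#'
#' Crops the epochs to `interval`, projects sensors to sources with the
#' inverse kernel, normalizes every source-orientation series to unit
#' variance over the concatenated trials, and reduces each ROI to the three
#' leading SVD components of its standardized activity. Component signs are
#' fixed by making the largest-magnitude loading positive.
#'
#' @param epochs an `EpochSet`.
#' @param inv an [eloreta_inverse()] operator.
#' @param lf the matching lead field.
#' @param interval `(start, end)` s (e.g. pre `(-1, 0)` or post `(1.5, 3)`).
#' @param rois ROI labels to extract.
#' @return object of class `ROIComponents`: list with `comps` (named list of
#'   `3 x samples x trials` arrays), `svd_gains`, `labels`, `fs`,
#'   `interval`.
#' @export
extract_roi_components <- function(epochs, inv, lf,
                                   interval = c(1.5, 3.0),
                                   rois = c("precentral_L", "precentral_R",
                                            "postcentral_L", "postcentral_R")) {
  stopifnot(inherits(epochs, "EpochSet"), inherits(inv, "InverseOperator"))
  missing_roi <- setdiff(rois, unique(lf$roi_labels))
  if (length(missing_roi) > 0L)
    stop("ROI(s) absent from lead field: ", paste(missing_roi, collapse = ", "))
  ep <- crop_epochs(epochs, interval[1L], interval[2L])
  d <- dim(ep$data)
  X <- matrix(ep$data, d[1L], d[2L] * d[3L])
  comps <- list(); gains <- list()
  for (roi in rois) {
    src <- which(lf$roi_labels == roi)
    rows <- as.vector(vapply(src, function(s) (s - 1L) * 3L + (1:3),
                             integer(3L)))
    A <- inv$kernel[rows, , drop = FALSE] %*% X     # (3*roi) x (samples*trials)
    A <- A - rowMeans(A)
    sdv <- sqrt(rowMeans(A^2))
    sdv[sdv == 0] <- 1
    A <- A / sdv
    ## top-3 left singular vectors via the small Gram matrix
    G <- tcrossprod(A)
    eg <- eigen((G + t(G)) / 2, symmetric = TRUE)
    U <- eg$vectors[, 1:3, drop = FALSE]
    sv <- sqrt(pmax(eg$values[1:3], 0))
    ## sign convention: largest |loading| positive
    for (j in 1:3) {
      i0 <- which.max(abs(U[, j]))
      if (U[i0, j] < 0) U[, j] <- -U[, j]
    }
    Z <- crossprod(U, A)                            # 3 x (samples*trials)
    comps[[roi]] <- array(Z, dim = c(3L, d[2L], d[3L]))
    gains[[roi]] <- sv
  }
  structure(list(comps = comps, svd_gains = gains, labels = ep$labels,
                 fs = ep$fs, interval = interval),
            class = "ROIComponents")
}

#' Cross-trial cross-spectrum
#'
#' Treats trials as independent realizations: each series segment is
#' demeaned, Hann-tapered, zero-padded to `nfft` and Fourier transformed; the
#' cross-spectral matrix at each frequency is the average over trials of the
#' outer products. No within-trial segmentation is performed (the 1 s
#' pre-stimulus segment leaves no room for Welch splitting).
#'
#' @param x `n_series x samples x trials` array (e.g. stacked ROI
#'   components).
#' @param fs sampling rate, Hz.
#' @param nfft FFT length (zero-padded).
#' @return object of class `CrossSpectrum` with `S` (`nfreq x n x n` complex
#'   array, Hermitian in the series indices), `freqs`, `n_trials`.
#' @export
cross_spectrum <- function(x, fs, nfft = 128L) {
  d <- dim(x)
  if (is.na(d[3L]) || d[3L] < 2L) stop("need >= 2 trials")
  n_ser <- d[1L]; n_samp <- d[2L]; n_tr <- d[3L]
  ## segments longer than nfft (e.g. the 1.5 s post-stimulus interval) raise
  ## nfft to the next power of two so zero-padding stays well defined
  while (n_samp > nfft) nfft <- 2L * nfft
  win <- hann_window(n_samp)
  flat <- matrix(aperm(x, c(2L, 1L, 3L)), n_samp, n_ser * n_tr)
  flat <- (flat - rep(colMeans(flat), each = n_samp)) * win
  padded <- rbind(flat, matrix(0, nfft - n_samp, ncol(flat)))
  Xf <- stats::mvfft(padded)
  nfreq <- nfft %/% 2L + 1L
  Xf <- Xf[seq_len(nfreq), , drop = FALSE]
  S <- array(0i, dim = c(nfreq, n_ser, n_ser))
  Xarr <- array(Xf, dim = c(nfreq, n_ser, n_tr))
  for (f in seq_len(nfreq)) {
    Xi <- matrix(Xarr[f, , ], n_ser, n_tr)
    S[f, , ] <- Xi %*% Conj(t(Xi)) / n_tr
  }
  structure(list(S = S, freqs = (seq_len(nfreq) - 1L) * fs / nfft,
                 n_trials = n_tr),
            class = "CrossSpectrum")
}

#' Absolute imaginary coherency
#'
#' `|Im( S_ij / sqrt(S_ii S_jj) )|` per frequency bin and series pair —
#' nonzero only for stable non-zero phase lags, insensitive to instantaneous
#' (zero-lag) mixing, bounded by 1.
#'
#' @param cs a [cross_spectrum()].
#' @return numeric `nfreq x n x n` array in `[0, 1]`.
#' @export
icoh <- function(cs) {
  stopifnot(inherits(cs, "CrossSpectrum"))
  d <- dim(cs$S)
  out <- array(0, dim = d)
  for (f in seq_len(d[1L])) {
    auto <- Re(diag(matrix(cs$S[f, , ], d[2L], d[2L])))
    if (any(auto <= 0)) stop("zero auto-spectrum at bin ", f)
    norm <- sqrt(outer(auto, auto))
    out[f, , ] <- abs(Im(matrix(cs$S[f, , ], d[2L], d[2L]) / norm))
  }
  out
}

# The four ROI labels in canonical order and the region pairs entering each
# aggregation scheme. "within" joins motor and sensory cortex of the same
# hemisphere; "across" joins the four inter-hemispheric region pairs
# (sensory-motor both ways, motor-motor, sensory-sensory).
roi_order <- c("precentral_L", "precentral_R", "postcentral_L", "postcentral_R")

scheme_pairs <- function(scheme) {
  switch(scheme,
         within = list(c("precentral_L", "postcentral_L"),
                       c("precentral_R", "postcentral_R")),
         across = list(c("postcentral_L", "precentral_R"),
                       c("postcentral_R", "precentral_L"),
                       c("precentral_L", "precentral_R"),
                       c("postcentral_L", "postcentral_R")),
         stop("unknown scheme"))
}

#' Per-class iCOH spectra between all ROI components
#'
#' Stacks the 3 SVD components of all four ROIs (12 series), computes one
#' cross-trial cross-spectrum per class, and returns the absolute imaginary
#' coherency arrays.
#'
#' @param rc an [extract_roi_components()] result.
#' @param nfft FFT length.
#' @return list with `icoh` (list per class of `nfreq x 12 x 12` arrays),
#'   `freqs`, `series_roi` (ROI label of each series).
#' @export
roi_icoh <- function(rc, nfft = 128L) {
  stopifnot(inherits(rc, "ROIComponents"))
  rois <- roi_order[roi_order %in% names(rc$comps)]
  d <- dim(rc$comps[[1L]])
  stacked <- array(0, dim = c(3L * length(rois), d[2L], d[3L]))
  for (i in seq_along(rois))
    stacked[(i - 1L) * 3L + (1:3), , ] <- rc$comps[[rois[i]]]
  series_roi <- rep(rois, each = 3L)
  classes <- unique(rc$labels)
  ic <- list(); freqs <- NULL
  for (cl in classes) {
    cs <- cross_spectrum(stacked[, , rc$labels == cl, drop = FALSE],
                         rc$fs, nfft)
    ic[[cl]] <- icoh(cs)
    freqs <- cs$freqs
  }
  list(icoh = ic, freqs = freqs, series_roi = series_roi)
}

#' Band- and scheme-aggregated connectivity
#'
#' Averages `|iCOH|` over the 3 x 3 component pairs of each region pair, over
#' classes and over the frequency bins whose center lies inside the band;
#' region pairs are then averaged within the scheme (`within`: the two
#' intra-hemispheric motor-sensory pairs; `across`: the four
#' inter-hemispheric pairs).
#'
#' @param ric a [roi_icoh()] result.
#' @param band `(low, high)` Hz.
#' @param scheme `"within"` or `"across"`.
#' @return scalar aggregate in `[0, 1]`.
#' @export
aggregate_icoh <- function(ric, band, scheme = c("within", "across")) {
  scheme <- match.arg(scheme)
  bins <- which(ric$freqs >= band[1L] & ric$freqs <= band[2L])
  if (length(bins) == 0L) stop("no frequency bins inside the band")
  pairs <- scheme_pairs(scheme)
  vals <- c()
  for (pr in pairs) {
    i <- which(ric$series_roi == pr[1L])
    j <- which(ric$series_roi == pr[2L])
    for (cl in names(ric$icoh))
      vals <- c(vals, as.vector(ric$icoh[[cl]][bins, i, j]))
  }
  mean(vals)
}

#' Connectivity aggregates for one subject and interval
#'
#' Convenience wrapper returning the four scalars of one analysis interval:
#' `within`/`across` scheme in the canonical mu band and the subject's
#' feedback band.
#'
#' @param epochs calibration `EpochSet`.
#' @param inv inverse operator.
#' @param lf lead field.
#' @param interval analysis interval, s.
#' @param mu_band canonical mu band, Hz.
#' @param feedback_band the subject's selected feedback band, Hz.
#' @param nfft FFT length.
#' @return named numeric vector `within_mu`, `within_fb`, `across_mu`,
#'   `across_fb`.
#' @export
connectivity_aggregates <- function(epochs, inv, lf, interval,
                                    mu_band = c(9, 14), feedback_band,
                                    nfft = 128L) {
  rc <- extract_roi_components(epochs, inv, lf, interval)
  ric <- roi_icoh(rc, nfft)
  c(within_mu = aggregate_icoh(ric, mu_band, "within"),
    within_fb = aggregate_icoh(ric, feedback_band, "within"),
    across_mu = aggregate_icoh(ric, mu_band, "across"),
    across_fb = aggregate_icoh(ric, feedback_band, "across"))
}
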