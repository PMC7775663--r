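# Temporal filtering, discriminability spectra, band and interval selection,
# and ERD/ERS envelope curves.

# FFT bin frequencies for n samples at rate fs (two-sided, R fft order).
fft_freqs <- function(n, fs) {
  k <- 0:(n - 1L)
  k[k > n %/% 2L] <- k[k > n %/% 2L] - n
  k * fs / n
}

# Squared magnitude response of an order-`ord` Butterworth band-pass at
# frequencies f (Hz). Zero response at DC.
butter_bp_mag2 <- function(f, band, ord = 4L) {
  fl <- band[1L]; fh <- band[2L]
  fa <- abs(f)
  out <- numeric(length(f))
  nz <- fa > 0
  x <- (fa[nz]^2 - fl * fh) / (fa[nz] * (fh - fl))
  out[nz] <- 1 / (1 + x^(2 * ord))
  out
}

# Smallest 5-smooth (2^a 3^b 5^c) integer >= n: fast FFT length.
next_fast_len <- function(n) {
  m <- n
  repeat {
    k <- m
    for (p in c(2L, 3L, 5L)) while (k %% p == 0L) k <- k %/% p
    if (k == 1L) return(m)
    m <- m + 1L
  }
}

# Zero-phase band-pass of a samples x series matrix: multiply the spectrum by
# the squared order-4 Butterworth magnitude (amplitude response identical to
# forward-backward filtering, exactly zero phase). Zero-padded to a 5-smooth
# FFT length.
fft_bandpass_matrix <- function(x, fs, band, ord = 4L) {
  x <- as.matrix(x)
  n <- nrow(x)
  m <- next_fast_len(n)
  if (m > n) x <- rbind(x, matrix(0, m - n, ncol(x)))
  h <- butter_bp_mag2(fft_freqs(m, fs), band, ord)
  y <- Re(stats::mvfft(stats::mvfft(x) * h, inverse = TRUE) / m)
  y[seq_len(n), , drop = FALSE]
}

# Band-passed analytic signal in one spectral pass: the two-sided Butterworth
# response is combined with the one-sided spectrum doubling, so Re() is the
# zero-phase band-passed signal and Mod() its Hilbert envelope.
analytic_bandpass_matrix <- function(x, fs, band, ord = 4L) {
  x <- as.matrix(x)
  n <- nrow(x)
  m <- next_fast_len(n)
  if (m > n) x <- rbind(x, matrix(0, m - n, ncol(x)))
  f <- fft_freqs(m, fs)
  h <- butter_bp_mag2(f, band, ord)
  side <- numeric(m)
  side[f == 0] <- 1
  side[f > 0] <- 2
  if (m %% 2L == 0L) side[m / 2L + 1L] <- 1
  y <- stats::mvfft(stats::mvfft(x) * (h * side), inverse = TRUE) / m
  y[seq_len(n), , drop = FALSE]
}

# Column maxima of a matrix via max.col (C speed).
col_max <- function(m) m[cbind(max.col(t(m), ties.method = "first"),
                               seq_len(ncol(m)))]

#' Zero-phase band-pass filtering of an EpochSet
#'
#' Applies a fourth-order Butterworth band-pass with zero phase shift. The
#' default `"fft"` method multiplies the epoch spectrum by the squared
#' Butterworth magnitude response — the amplitude response of
#' forward-backward (filtfilt) filtering — vectorized over all channels and
#' trials; `"filtfilt"` runs [signal::filtfilt()] per channel and trial.
#'
#' @param epochs an [epoch_set()].
#' @param band numeric `(low, high)` Hz; must lie within the Nyquist range.
#' @param method `"fft"` (default) or `"filtfilt"`.
#' @return a filtered `EpochSet`.
#' @export
bandpass <- function(epochs, band, method = c("fft", "filtfilt")) {
  stopifnot(inherits(epochs, "EpochSet"))
  method <- match.arg(method)
  band <- as.numeric(band)
  if (length(band) != 2L || band[1L] <= 0 || band[1L] >= band[2L])
    stop("'band' must be (low, high) with 0 < low < high")
  if (band[2L] >= epochs$fs / 2)
    stop("band upper edge must be below the Nyquist frequency")
  d <- dim(epochs$data)
  if (method == "fft") {
    flat <- matrix(aperm(epochs$data, c(2L, 1L, 3L)), d[2L], d[1L] * d[3L])
    filt <- fft_bandpass_matrix(flat, epochs$fs, band)
    out <- aperm(array(filt, dim = c(d[2L], d[1L], d[3L])), c(2L, 1L, 3L))
  } else {
    bf <- signal::butter(4, band / (epochs$fs / 2), type = "pass")
    out <- epochs$data
    for (tr in seq_len(d[3L]))
      for (ch in seq_len(d[1L]))
        out[ch, , tr] <- signal::filtfilt(bf, epochs$data[ch, , tr])
  }
  epoch_set(out, epochs$labels, epochs$fs, epochs$t0, epochs$channel_names)
}

# Welch per-trial band power: channels x freqs x trials at ~1 Hz resolution
# using 1 s Hann segments with 50% overlap, restricted to post-stimulus
# samples (discriminative power differences are induced by the task).
welch_trial_power <- function(epochs, freq_range = c(5, 35), seg_sec = 1,
                              post_only = TRUE) {
  d <- dim(epochs$data)
  t <- epoch_times(epochs)
  use <- if (post_only && any(t >= 0)) which(t >= 0) else seq_len(d[2L])
  x <- epochs$data[, use, , drop = FALSE]
  nseg <- as.integer(round(seg_sec * epochs$fs))
  hop <- nseg %/% 2L
  starts <- seq(1L, dim(x)[2L] - nseg + 1L, by = hop)
  win <- hann_window(nseg)
  freqs <- (0:(nseg %/% 2L)) * epochs$fs / nseg
  keep <- which(freqs >= freq_range[1L] & freqs <= freq_range[2L])
  pow <- array(0, dim = c(d[1L], length(keep), d[3L]))
  for (s0 in starts) {
    seg <- x[, s0:(s0 + nseg - 1L), , drop = FALSE]
    flat <- matrix(aperm(seg, c(2L, 1L, 3L)), nseg, d[1L] * d[3L])
    flat <- (flat - rep(colMeans(flat), each = nseg)) * win
    X <- stats::mvfft(flat)[keep, , drop = FALSE]
    pow <- pow + aperm(array(abs(X)^2, dim = c(length(keep), d[1L], d[3L])),
                       c(2L, 1L, 3L))
  }
  list(power = pow / length(starts) / (sum(win^2) * epochs$fs / 2),
       freqs = freqs[keep])
}

#' Signed r-squared discriminability spectrum
#'
#' For every channel and frequency bin, the point-biserial correlation `r`
#' between per-trial band power and the class indicator, reported as
#' `sign(r) * r^2` and smoothed along frequency with a moving average of width
#' `smooth_hz`. Positive values mean more power in `classA`.
#'
#' @param epochs an `EpochSet`.
#' @param classA,classB the two class labels to contrast.
#' @param smooth_hz width of the frequency moving-average smoother, Hz.
#' @param freq_range scanned frequency range, Hz.
#' @return object of class `DiscriminabilityMap`: list with `signed_r2`
#'   (channels x bins), `freqs`.
#' @export
signed_r2_spectrum <- function(epochs, classA, classB, smooth_hz = 3,
                               freq_range = c(5, 35)) {
  stopifnot(inherits(epochs, "EpochSet"))
  sel <- epochs$labels %in% c(classA, classB)
  if (!any(epochs$labels == classA) || !any(epochs$labels == classB))
    stop("both classes must be present")
  if (sum(epochs$labels == classA) < 2L || sum(epochs$labels == classB) < 2L)
    stop("need >= 2 trials per class")
  ep <- subset_trials(epochs, sel)
  wp <- welch_trial_power(ep, freq_range)
  y <- as.numeric(ep$labels == classA)   # 1 for classA, 0 for classB
  signed_r2_core(wp$power, wp$freqs, y, smooth_hz, c(classA, classB))
}

# Point-biserial signed r^2 from precomputed per-trial band power
# (channels x bins x trials) and a 0/1 class indicator.
signed_r2_core <- function(power, freqs, y, smooth_hz, classes) {
  d <- dim(power)
  X <- matrix(aperm(power, c(3L, 1L, 2L)), d[3L], d[1L] * d[2L])
  Xc <- X - rep(colMeans(X), each = nrow(X))
  yc <- y - mean(y)
  denom <- sqrt(colSums(Xc^2) * sum(yc^2))
  r <- ifelse(denom > 0, colSums(Xc * yc) / denom, 0)
  sr2 <- matrix(sign(r) * r^2, d[1L], d[2L])
  df <- mean(diff(freqs))
  w <- max(1L, 2L * floor(smooth_hz / df / 2) + 1L)  # odd bin count
  if (w > 1L) {
    half <- w %/% 2L
    sm <- sr2
    for (j in seq_len(ncol(sr2))) {
      lo <- max(1L, j - half); hi <- min(ncol(sr2), j + half)
      sm[, j] <- rowMeans(sr2[, lo:hi, drop = FALSE])
    }
    sr2 <- sm
  }
  structure(list(signed_r2 = sr2, freqs = freqs, classes = classes),
            class = "DiscriminabilityMap")
}

#' Subject-specific frequency band from a discriminability map
#'
#' Starting at the bin of globally maximal `|signed r^2|` (across channels),
#' the band is grown outward bin by bin for as long as the channel-maximum
#' `|signed r^2|` of the next bin stays at or above one third of the seed
#' value. Returns the band edges at the outermost accepted bin centers (a
#' single-bin band is widened to one bin width).
#'
#' @param map a [signed_r2_spectrum()] result.
#' @param threshold_frac growth threshold as a fraction of the seed value.
#' @param default_band band returned (with a warning) for an all-zero map.
#' @return numeric `(low, high)` Hz with attribute `"default"` set when the
#'   fallback band was used.
#' @export
select_band <- function(map, threshold_frac = 1 / 3, default_band = c(9, 14)) {
  stopifnot(inherits(map, "DiscriminabilityMap"))
  prof <- apply(abs(map$signed_r2), 2L, max)
  if (all(prof == 0)) {
    warning("all-zero discriminability map; falling back to the mu band")
    return(structure(as.numeric(default_band), default = TRUE))
  }
  seedbin <- which.max(prof)
  thr <- threshold_frac * prof[seedbin]
  lo <- seedbin
  while (lo > 1L && prof[lo - 1L] >= thr) lo <- lo - 1L
  hi <- seedbin
  while (hi < length(prof) && prof[hi + 1L] >= thr) hi <- hi + 1L
  band <- c(map$freqs[lo], map$freqs[hi])
  if (band[1L] == band[2L]) {
    df <- mean(diff(map$freqs))
    band <- band + c(-df / 2, df / 2)
  }
  structure(band, default = FALSE)
}

#' Time-resolved ERD/ERS curves per class
#'
#' Band-pass filters the epochs, takes the Hilbert amplitude envelope of each
#' trial, averages envelopes across the trials of each class and expresses
#' each sample as percent change relative to the mean pre-stimulus baseline
#' amplitude: `ERD = 100 * (POST - PRE) / PRE` where `PRE` is the per-channel
#' mean envelope over the baseline interval.
#'
#' @param epochs an `EpochSet`.
#' @param band `(low, high)` Hz.
#' @param baseline `(start, end)` s of the pre-stimulus baseline.
#' @return list of `ERDCurve` objects, one per class: each has `values`
#'   (channels x samples, percent), `baseline` (per-channel PRE amplitude),
#'   `t` (seconds).
#' @export
erd_curve <- function(epochs, band, baseline = c(-0.5, 0)) {
  stopifnot(inherits(epochs, "EpochSet"))
  t <- epoch_times(epochs)
  if (t[1L] > baseline[1L])
    stop("epochs do not span the baseline interval")
  env <- epoch_envelopes(epochs, band)
  erd_from_envelopes(env, epochs$labels, t, epochs$fs, band, baseline)
}

# Hilbert amplitude envelopes of band-passed epochs: ch x samples x trials.
epoch_envelopes <- function(epochs, band) {
  filt <- bandpass(epochs, band)
  d <- dim(filt$data)
  flat <- matrix(aperm(filt$data, c(2L, 1L, 3L)), d[2L], d[1L] * d[3L])
  env <- Mod(analytic_signal(flat))
  aperm(array(env, dim = c(d[2L], d[1L], d[3L])), c(2L, 1L, 3L))
}

erd_from_envelopes <- function(env, labels, t, fs, band,
                               baseline = c(-0.5, 0), classes = NULL) {
  eps <- 0.5 / fs
  base_idx <- which(t >= baseline[1L] - eps & t <= baseline[2L] + eps)
  if (is.null(classes)) classes <- unique(labels)
  out <- list()
  for (cl in classes) {
    sub <- env[, , labels == cl, drop = FALSE]
    avg <- rowSums(sub, dims = 2L) / dim(sub)[3L]
    pre <- rowMeans(avg[, base_idx, drop = FALSE])
    if (any(pre <= 0)) stop("zero baseline amplitude; cannot form ERD")
    out[[cl]] <- structure(
      list(values = 100 * (avg - pre) / pre, baseline = pre, t = t,
           class = cl, band = band),
      class = "ERDCurve")
  }
  out
}

#' Discriminative time-interval selection from ERD curves
#'
#' Scores each candidate window by the time average of the maximal pairwise
#' between-class ERD difference (maximum over channels and class pairs at each
#' sample) and returns the contiguous window of length at least `min_len`
#' with the highest score. Ties are broken toward the earliest start and then
#' the longest window, so a time-constant class contrast yields the full
#' search window. A vanishing contrast everywhere returns the canonical
#' post-stimulus interval `default_interval` with a warning.
#'
#' @param curves list of `ERDCurve` per class (>= 2 classes).
#' @param search `(start, end)` s of the searched range.
#' @param min_len minimum window length, s.
#' @param default_interval fallback interval, s.
#' @return numeric `(start, end)` s.
#' @export
select_interval <- function(curves, search = c(0.75, 4.0), min_len = 1.0,
                            default_interval = c(1.5, 3.0)) {
  stopifnot(is.list(curves), length(curves) >= 2L)
  t <- curves[[1L]]$t
  eps <- 0.5 / (1 / mean(diff(t)))
  idx <- which(t >= search[1L] - eps & t <= search[2L] + eps)
  if (length(idx) < 2L)
    stop("search window lies outside the epoch span")
  ## pointwise maximal pairwise class difference, maximized over channels
  nc <- length(curves)
  diffmax <- numeric(length(idx))
  for (a in seq_len(nc - 1L)) for (b in (a + 1L):nc) {
    dd <- abs(curves[[a]]$values[, idx, drop = FALSE] -
                curves[[b]]$values[, idx, drop = FALSE])
    diffmax <- pmax(diffmax, col_max(dd))
  }
  if (all(diffmax < .Machine$double.eps^0.5)) {
    warning("no class difference in ERD; falling back to default interval")
    return(as.numeric(default_interval))
  }
  fs <- 1 / mean(diff(t))
  min_samp <- as.integer(round(min_len * fs))
  cs <- cumsum(c(0, diffmax))
  n <- length(diffmax)
  tol <- 1e-9 * max(diffmax)
  best_m <- -Inf; best_i <- NA_integer_; best_j <- NA_integer_
  for (i in seq_len(n - min_samp)) {
    js <- (i + min_samp):n
    means <- (cs[js + 1L] - cs[i]) / (js - i + 1L)
    m <- max(means)
    ## strict improvement only: earlier starts win ties; within the winning
    ## start, take the longest window whose mean ties the maximum
    if (m > best_m + tol) {
      best_m <- m
      best_i <- i
      best_j <- max(js[means >= m - tol])
    }
  }
  c(t[idx[best_i]], t[idx[best_j]])
}
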