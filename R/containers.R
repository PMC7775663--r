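#' Epoched multi-channel EEG container
#'
#' The universal signal container of the pipeline: a `channels x samples x
#' trials` numeric array with per-trial class labels, a sampling rate and the
#' epoch time axis (seconds relative to the visual cue at `t = 0`).
#'
#' @param data numeric array, `channels x samples x trials` (microvolts,
#'   arbitrary units accepted).
#' @param labels character vector of per-trial class labels, length = trials.
#' @param fs sampling rate in Hz (`> 0`).
#' @param t0 time of the first sample relative to the cue, in seconds
#'   (negative for pre-stimulus samples).
#' @param channel_names optional character vector of channel names.
#'
#' @return an object of class `EpochSet`.
#' @export
epoch_set <- function(data, labels, fs, t0, channel_names = NULL) {
  if (length(dim(data)) != 3L)
    stop("'data' must be a channels x samples x trials array")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("'fs' must be a positive scalar")
  if (length(labels) != dim(data)[3L])
    stop("length(labels) must equal the number of trials")
  if (!all(is.finite(data)))
    stop("'data' contains non-finite values")
  if (is.null(channel_names))
    channel_names <- paste0("ch", seq_len(dim(data)[1L]))
  structure(
    list(data = data, labels = as.character(labels), fs = fs, t0 = t0,
         channel_names = channel_names),
    class = "EpochSet")
}

#' @export
print.EpochSet <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<EpochSet> %d channels x %d samples x %d trials @ %g Hz\n",
              d[1L], d[2L], d[3L], x$fs))
  cat(sprintf("  time span: [%.3f, %.3f] s; classes: %s\n",
              x$t0, x$t0 + (d[2L] - 1L) / x$fs,
              paste(sprintf("%s (%d)", names(table(x$labels)),
                            as.integer(table(x$labels))), collapse = ", ")))
  invisible(x)
}

#' Epoch time axis
#'
#' @param x an `EpochSet`.
#' @return numeric vector of sample times in seconds relative to the cue.
#' @export
epoch_times <- function(x) {
  stopifnot(inherits(x, "EpochSet"))
  x$t0 + (seq_len(dim(x$data)[2L]) - 1L) / x$fs
}

#' Crop an EpochSet to a time interval
#'
#' Keeps samples with time `>= tmin` and `<= tmax` (half-sample tolerance at
#' the edges so that nominal interval bounds land on samples).
#'
#' @param x an `EpochSet`.
#' @param tmin,tmax interval bounds in seconds relative to the cue.
#' @return an `EpochSet` restricted to the interval.
#' @export
crop_epochs <- function(x, tmin, tmax) {
  stopifnot(inherits(x, "EpochSet"), tmin < tmax)
  t <- epoch_times(x)
  eps <- 0.5 / x$fs
  keep <- which(t >= tmin - eps & t <= tmax + eps)
  if (length(keep) < 2L)
    stop(sprintf("interval [%g, %g] s outside the epoch span [%g, %g] s",
                 tmin, tmax, t[1L], t[length(t)]))
  epoch_set(x$data[, keep, , drop = FALSE], x$labels, x$fs, t[keep[1L]],
            x$channel_names)
}

#' Subset trials of an EpochSet
#'
#' @param x an `EpochSet`.
#' @param idx integer or logical trial index.
#' @return an `EpochSet` with the selected trials, order preserved.
#' @export
subset_trials <- function(x, idx) {
  stopifnot(inherits(x, "EpochSet"))
  epoch_set(x$data[, , idx, drop = FALSE], x$labels[idx], x$fs, x$t0,
            x$channel_names)
}

# Analytic signal of each column via FFT (Marple's one-sided spectrum
# doubling). x: samples x series matrix. Returns a complex matrix.
analytic_signal <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  X <- stats::mvfft(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[c(1L, n / 2L + 1L)] <- 1
    h[2:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1L) / 2L)] <- 2
  }
  stats::mvfft(X * h, inverse = TRUE) / n
}

# Hann (raised-cosine) taper of length n.
hann_window <- function(n) {
  if (n == 1L) return(1)
  0.5 - 0.5 * cos(2 * pi * (0:(n - 1L)) / (n - 1L))
}
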