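# Shared fixtures, generated in code. Heavier objects are memoized for the
# session so several test files can reuse them.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# Small lead field shared across tests.
tiny_lf <- function() memo("tiny_lf", make_lead_field(
  n_background = 12L, n_channels = 10L, roi_size = 3L, seed = 7L))

tiny_inv <- function() memo("tiny_inv", eloreta_inverse(tiny_lf()))

tiny_design <- function(...) {
  args <- list(...)
  do.call(simulation_design,
          utils::modifyList(list(n_per_class = 9L, n_per_class_feedback = 10L),
                            args))
}

# One mid-coupling simulated subject with sources stored.
tiny_subject <- function() memo("tiny_subject", simulate_subject(
  subject_ground_truth(coupling_strength = 0.7, coupling_lag = pi / 2,
                       erd_depth = 0.3, alpha_power = 1, seed = 11L),
  tiny_lf(), tiny_design()))

# Epochs holding pure sinusoids (one frequency per channel), n trials.
tone_epochs <- function(freqs, fs = 100, dur = 5.5, t0 = -1.5, n_trials = 4L,
                        amplitude = 1) {
  n_samp <- as.integer(round(dur * fs)) + 1L
  t <- t0 + (seq_len(n_samp) - 1L) / fs
  data <- array(0, dim = c(length(freqs), n_samp, n_trials))
  for (ch in seq_along(freqs))
    for (tr in seq_len(n_trials))
      data[ch, , tr] <- amplitude * sin(2 * pi * freqs[ch] * t + 0.3 * tr)
  epoch_set(data, rep("left", n_trials), fs, t0)
}

# Narrowband signal pair with a fixed phase lag, as n_series x samples x
# trials arrays (series 1 leads, series 2 is the lagged copy).
lagged_pair <- function(n_trials, lag, fs = 100, n_samp = 100L,
                        band = c(9, 14), seed = 1L) {
  set.seed(seed)
  x <- array(0, dim = c(2L, n_samp, n_trials))
  for (tr in seq_len(n_trials)) {
    w <- matrix(stats::rnorm(4L * n_samp), 4L * n_samp, 1L)
    nb <- smrconn:::fft_bandpass_matrix(w, fs, band)
    a <- smrconn:::analytic_signal(nb)
    mid <- n_samp + seq_len(n_samp)   # interior segment, no filter edges
    x[1L, , tr] <- Re(a[mid, 1L])
    x[2L, , tr] <- Re(a[mid, 1L] * exp(-1i * lag))
  }
  x
}
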