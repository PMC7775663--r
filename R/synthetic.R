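#' Synthetic spherical-head lead field with sensorimotor ROIs
#'
#' Builds a toy forward model: electrodes on the upper half of a spherical
#' head (mirror-symmetric montage across the sagittal plane) and current
#' dipole sources inside the sphere, with four sensorimotor regions of
#' interest (left/right pre- and post-central) placed with exact left/right
#' mirror symmetry plus randomly scattered background sources. The gain of a
#' source with moment `q` at position `r0` on an electrode at `re` is the
#' quasi-static homogeneous-medium dipole potential
#' `q . (re - r0) / (4 pi sigma |re - r0|^3)`, which is smooth, analytic and
#' mirror-symmetric — sufficient for exercising inverse modeling without a
#' multi-shell head model.
#'
#' @param n_background number of background (non-ROI) sources.
#' @param n_channels number of electrodes (even, `>= 8`).
#' @param roi_size sources per ROI (`>= 1`): either one number for all four
#'   ROIs or `(precentral, postcentral)` sizes (e.g. `c(125, 112)` mimicking
#'   atlas-sized sensorimotor regions).
#' @param seed integer seed; the lead field is bitwise reproducible.
#' @param head_radius scalp sphere radius in mm.
#'
#' @return an object of class `LeadField` with elements
#'   \describe{
#'     \item{gain}{`channels x (3 * n_sources)` matrix; columns are grouped in
#'       consecutive triples (x, y, z dipole orientations per source).}
#'     \item{source_positions}{`n_sources x 3` matrix (mm).}
#'     \item{roi_labels}{per-source label in `precentral_L`, `precentral_R`,
#'       `postcentral_L`, `postcentral_R`, `background`.}
#'     \item{channel_positions}{`n_channels x 3` matrix (mm).}
#'     \item{mirror_perm}{channel permutation mapping each electrode to its
#'       sagittal mirror image.}
#'   }
#' @export
make_lead_field <- function(n_background = 40L, n_channels = 24L,
                            roi_size = 6L, seed = 1L, head_radius = 95) {
  if (n_channels < 8L) stop("'n_channels' must be >= 8")
  if (n_channels %% 2L != 0L) stop("'n_channels' must be even (mirror pairs)")
  if (any(roi_size < 1L)) stop("'roi_size' must be >= 1")
  if (n_background < 1L) stop("'n_background' must be >= 1")
  if (length(roi_size) == 1L) roi_size <- c(roi_size, roi_size)
  size_pre <- as.integer(roi_size[1L])   # precentral (motor) ROI size
  size_post <- as.integer(roi_size[2L])  # postcentral (somatosensory)
  rng <- new_rng(seed)

  ## electrodes: right-hemisphere set drawn on the upper scalp, then mirrored
  m <- n_channels %/% 2L
  elev <- runif_rng(rng, m, 15, 80) * pi / 180   # elevation above equator
  azim <- runif_rng(rng, m, -75, 75) * pi / 180  # azimuth around +x (right)
  right <- cbind(cos(elev) * cos(azim), cos(elev) * sin(azim), sin(elev)) *
    head_radius
  left <- right
  left[, 1L] <- -left[, 1L]
  chan_pos <- rbind(right, left)
  mirror_perm <- c(m + seq_len(m), seq_len(m))

  ## ROI sources: seeded jitter around canonical sensorimotor centers,
  ## jitter mirrored exactly so left/right geometry is symmetric
  centers <- list(precentral_L = c(-32, 15, 60), precentral_R = c(32, 15, 60),
                  postcentral_L = c(-36, -12, 58), postcentral_R = c(36, -12, 58))
  jit_pre <- matrix(rnorm_rng(rng, size_pre * 3L, sd = 5), size_pre, 3L)
  jit_post <- matrix(rnorm_rng(rng, size_post * 3L, sd = 5), size_post, 3L)
  mirror_x <- function(p) { p[, 1L] <- -p[, 1L]; p }
  roi_pos <- rbind(
    sweep(jit_pre, 2L, centers$precentral_L, "+"),
    mirror_x(sweep(jit_pre, 2L, centers$precentral_L, "+")),
    sweep(jit_post, 2L, centers$postcentral_L, "+"),
    mirror_x(sweep(jit_post, 2L, centers$postcentral_L, "+")))
  roi_labels <- rep(c("precentral_L", "precentral_R",
                      "postcentral_L", "postcentral_R"),
                    times = c(size_pre, size_pre, size_post, size_post))

  ## background sources: uniform directions, radii inside the cortex shell
  dir <- matrix(rnorm_rng(rng, n_background * 3L), n_background, 3L)
  dir <- dir / sqrt(rowSums(dir^2))
  rad <- runif_rng(rng, n_background, 0.3, 0.85) * (0.85 * head_radius)
  bg_pos <- dir * rad
  bg_pos[, 3L] <- abs(bg_pos[, 3L]) * sign(runif_rng(rng, n_background, -0.3, 1))

  pos <- rbind(roi_pos, bg_pos)
  ## clip inside the source compartment
  r <- sqrt(rowSums(pos^2))
  too_far <- r > 0.85 * head_radius
  pos[too_far, ] <- pos[too_far, ] * (0.85 * head_radius / r[too_far])
  labels <- c(roi_labels, rep("background", n_background))

  gain <- dipole_gain(chan_pos, pos)
  if (any(colSums(abs(gain)) < .Machine$double.eps))
    stop("lead field has an all-zero column")  # cannot occur for interior sources

  structure(list(gain = gain, source_positions = pos, roi_labels = labels,
                 channel_positions = chan_pos, mirror_perm = mirror_perm,
                 head_radius = head_radius, seed = as.integer(seed)),
            class = "LeadField")
}

# Homogeneous-medium current-dipole potentials. chan: C x 3, src: S x 3.
# Returns C x (3 S); columns (s-1)*3 + o give the potential of a unit dipole
# along axis o at source s.
dipole_gain <- function(chan, src) {
  sigma <- 0.33  # S/m, conventional brain conductivity
  C <- nrow(chan); S <- nrow(src)
  g <- matrix(0, C, 3L * S)
  for (s in seq_len(S)) {
    d <- sweep(chan, 2L, src[s, ], "-")          # C x 3
    d3 <- (sqrt(rowSums(d^2)))^3
    g[, (s - 1L) * 3L + (1:3)] <- d / (4 * pi * sigma * d3)
  }
  g
}

#' @export
print.LeadField <- function(x, ...) {
  cat(sprintf("<LeadField> %d channels x %d sources (%d ROI + %d background)\n",
              nrow(x$gain), length(x$roi_labels),
              sum(x$roi_labels != "background"),
              sum(x$roi_labels == "background")))
  invisible(x)
}

#' Per-subject generative ground truth
#'
#' Encodes the causal structure the pipeline is meant to recover: phase-lagged
#' mu-band coupling between pre- and post-central sources (which produces
#' nonzero imaginary coherency), class-dependent contralateral event-related
#' desynchronization, and the power of the ongoing sensorimotor alpha/mu
#' oscillation (which drives the spectral signal-to-noise ratio).
#'
#' @param coupling_strength mixing weight of the lagged pre-central signal in
#'   the post-central source, in `[0, 1]`.
#' @param coupling_lag phase lag in radians at the mu-band center. Must be
#'   nonzero when `coupling_strength > 0` unless `allow_zero_lag = TRUE`:
#'   zero-lag coupling is invisible to the imaginary part of coherency and is
#'   only useful as an explicit degenerate control.
#' @param erd_depth fractional amplitude suppression during imagery, `[0, 1]`.
#' @param mu_band `(low, high)` Hz of the subject's mu rhythm.
#' @param alpha_power power (a.u.) of the ongoing mu/alpha oscillation carried
#'   by the sensorimotor sources.
#' @param seed integer seed for the subject's random draws.
#' @param allow_zero_lag allow `coupling_lag == 0` with positive coupling.
#'
#' @return object of class `SubjectGroundTruth`.
#' @export
subject_ground_truth <- function(coupling_strength, coupling_lag = pi / 2,
                                 erd_depth = 0.4, mu_band = c(9, 14),
                                 alpha_power = 1, seed = 1L,
                                 allow_zero_lag = FALSE) {
  stopifnot(coupling_strength >= 0, coupling_strength <= 1,
            erd_depth >= 0, erd_depth <= 1, alpha_power > 0,
            length(mu_band) == 2L, mu_band[1L] > 0, mu_band[1L] < mu_band[2L])
  if (coupling_strength > 0 && coupling_lag == 0 && !allow_zero_lag)
    stop("coupling_lag = 0 with positive coupling is invisible to iCOH; ",
         "set allow_zero_lag = TRUE if this degenerate case is intended")
  structure(list(coupling_strength = coupling_strength,
                 coupling_lag = coupling_lag, erd_depth = erd_depth,
                 mu_band = as.numeric(mu_band), alpha_power = alpha_power,
                 seed = as.integer(seed)),
            class = "SubjectGroundTruth")
}

#' Default simulation design
#'
#' Trial counts and timing of a single-session calibration + online feedback
#' experiment: three imagery classes (left hand, right hand, feet), epochs
#' from 1.5 s before to 4 s after the cue at a nominal 100 Hz (signals are
#' band-limited to 0.5-45 Hz), 75 calibration trials per class and 150
#' feedback trials per class (so that any chosen class pair yields 300
#' feedback trials).
#'
#' @param n_per_class calibration trials per class.
#' @param n_per_class_feedback feedback trials per class.
#' @param fs sampling rate, Hz.
#' @param t_pre pre-cue epoch span, s (`>= 1`).
#' @param t_post post-cue epoch span, s (`>= 4`).
#' @param snr_db sensor signal-to-noise ratio in dB (mean channel signal power
#'   over mean channel noise power); `Inf` disables sensor noise.
#' @param source_noise relative standard deviation of independent per-source
#'   noise added to ROI sources (0 = rank-1 ROI activity).
#' @param background_power amplitude (a.u.) of the 1/f background sources;
#'   0 silences them (together with `snr_db = Inf` and `source_noise = 0`
#'   this gives a fully noiseless recording).
#' @param erd_ramp `(start, end)` s of the smooth post-cue ERD onset ramp.
#' @return a list of design parameters.
#' @export
simulation_design <- function(n_per_class = 75L, n_per_class_feedback = 150L,
                              fs = 100, t_pre = 1.5, t_post = 4.0,
                              snr_db = 0, source_noise = 0.1,
                              background_power = 1,
                              erd_ramp = c(0.5, 1.5)) {
  list(n_per_class = as.integer(n_per_class),
       n_per_class_feedback = as.integer(n_per_class_feedback),
       fs = fs, t_pre = t_pre, t_post = t_post, snr_db = snr_db,
       source_noise = source_noise, background_power = background_power,
       erd_ramp = erd_ramp,
       fb_arrow_lead = 1.0,
       classes = c("left", "right", "feet"))
}

#' Simulate one subject's calibration and feedback EEG
#'
#' Each hemisphere carries a narrowband mu oscillation (Gaussian noise
#' band-pass filtered to the subject's mu band) in its pre-central ROI; the
#' post-central ROI receives the same oscillation phase-shifted by
#' `coupling_lag` (analytic-signal rotation) mixed with an independent
#' narrowband component weighted `(1 - coupling_strength)`. During the
#' post-stimulus period the amplitude of the hemisphere contralateral to the
#' cued class (both hemispheres for feet imagery) is scaled by
#' `1 - erd_depth * g(t)` with `g` a smooth raised-cosine ramp. Background
#' sources carry 1/f noise; sensor data are `gain x sources` plus spatially
#' mixed 1/f sensor noise at the design SNR.
#'
#' @param gt a [subject_ground_truth()] object.
#' @param lf a [make_lead_field()] lead field.
#' @param design a [simulation_design()] list.
#' @param seed optional integer overriding `gt$seed`.
#' @param store_sources keep the planted per-ROI source signals of the
#'   calibration epochs (for recovery tests).
#' @return list with elements `calibration` and `feedback` (`EpochSet`s) and,
#'   if requested, `roi_signals` (list of `samples x trials` matrices per ROI).
#' @export
simulate_subject <- function(gt, lf, design = simulation_design(),
                             seed = NULL, store_sources = TRUE) {
  stopifnot(inherits(gt, "SubjectGroundTruth"), inherits(lf, "LeadField"))
  if (design$t_pre < 1 || design$t_post < 4)
    stop("design must cover >= 1 s pre-stimulus and >= 4 s post-stimulus")
  seed <- if (is.null(seed)) gt$seed else as.integer(seed)
  rng <- new_rng(seed)

  ## subject anatomy: fixed source orientations and ROI loading vectors,
  ## shared by the calibration and feedback runs
  n_src <- length(lf$roi_labels)
  ori <- matrix(rnorm_rng(rng, n_src * 3L), n_src, 3L)
  ori <- ori / sqrt(rowSums(ori^2))
  geff <- matrix(0, nrow(lf$gain), n_src)
  for (s in seq_len(n_src))
    geff[, s] <- lf$gain[, (s - 1L) * 3L + (1:3)] %*% ori[s, ]
  rois <- c("precentral_L", "precentral_R", "postcentral_L", "postcentral_R")
  loadings <- lapply(rois, function(roi)
    abs(rnorm_rng(rng, sum(lf$roi_labels == roi), mean = 1, sd = 0.25)))
  names(loadings) <- rois
  C <- nrow(lf$gain)
  anat <- list(geff = geff, loadings = loadings,
               noise_mix = matrix(rnorm_rng(rng, C * C, sd = 1 / sqrt(C)),
                                  C, C))

  cal <- simulate_epochs(gt, lf, design, rng, anat,
                         n_per_class = design$n_per_class,
                         store_sources = store_sources)
  ## in the online paradigm the cursor starts moving fb_arrow_lead seconds
  ## after the arrow cue, so at t = 0 (cursor onset) the imagery-driven
  ## amplitude modulation is already established; the sensor-noise scale is
  ## carried over from the calibration run (one stationary recording session)
  fb_design <- design
  fb_design$erd_ramp <- design$erd_ramp - design$fb_arrow_lead
  fb <- simulate_epochs(gt, lf, fb_design, rng, anat,
                        n_per_class = design$n_per_class_feedback,
                        store_sources = FALSE, noise_scale = cal$noise_scale)
  out <- list(calibration = cal$epochs, feedback = fb$epochs, ground_truth = gt)
  if (store_sources) out$roi_signals <- cal$roi_signals
  out
}

# Core generative model for one block of trials. `anat` carries the
# subject-fixed source orientations (collapsed into effective gains) and the
# per-ROI loading vectors.
simulate_epochs <- function(gt, lf, design, rng, anat, n_per_class,
                            store_sources, noise_scale = NULL) {
  fs <- design$fs
  n_samp <- as.integer(round((design$t_pre + design$t_post) * fs)) + 1L
  t <- seq(-design$t_pre, by = 1 / fs, length.out = n_samp)
  classes <- design$classes
  n_trials <- n_per_class * length(classes)
  ## interleaved class order (cue order randomized like a real run)
  labels <- sample_rng(rng, rep(classes, n_per_class))

  ## ERD gate per trial: 1 - d * g(t) on the contralateral hemisphere
  g <- erd_ramp_gate(t, design$erd_ramp)
  mod_L <- matrix(1, n_samp, n_trials)  # gate applied to LEFT-hemisphere rois
  mod_R <- matrix(1, n_samp, n_trials)
  gate <- 1 - gt$erd_depth * g
  mod_L[, labels %in% c("right", "feet")] <- gate
  mod_R[, labels %in% c("left", "feet")] <- gate

  amp <- sqrt(gt$alpha_power)
  sig <- list()
  for (h in c("L", "R")) {
    x <- narrowband_noise(rng, n_samp, n_trials, fs, gt$mu_band)   # pre-central
    z <- narrowband_noise(rng, n_samp, n_trials, fs, gt$mu_band)   # independent
    y <- gt$coupling_strength * Re(analytic_signal(x) *
                                     exp(-1i * gt$coupling_lag)) +
      (1 - gt$coupling_strength) * z
    y <- scale_cols_unit_sd(y)
    mod <- if (h == "L") mod_L else mod_R
    sig[[paste0("precentral_", h)]] <- amp * x * mod
    sig[[paste0("postcentral_", h)]] <- amp * y * mod
  }

  ## sensors = Geff %*% S with the subject's fixed effective gains
  n_src <- length(lf$roi_labels)
  geff <- anat$geff
  rois <- c("precentral_L", "precentral_R", "postcentral_L", "postcentral_R")
  S <- matrix(0, n_src, n_samp * n_trials)
  roi_idx <- which(lf$roi_labels %in% rois)
  for (roi in rois) {
    idx <- which(lf$roi_labels == roi)
    S[idx, ] <- anat$loadings[[roi]] %o% as.vector(sig[[roi]])
  }
  if (design$source_noise > 0 && length(roi_idx) > 0L) {
    ## independent white per-source noise: a nuisance floor that keeps the
    ## ROI activity from being exactly rank one
    S[roi_idx, ] <- S[roi_idx, ] + design$source_noise * amp *
      matrix(rnorm_rng(rng, length(roi_idx) * n_samp * n_trials),
             length(roi_idx), n_samp * n_trials)
  }
  bg <- which(lf$roi_labels == "background")
  if (length(bg) > 0L && design$background_power > 0) {
    eta <- oneoverf_noise(rng, n_samp, n_trials * length(bg))
    S[bg, ] <- design$background_power *
      t(matrix(eta, n_samp * n_trials, length(bg)))
  }

  sensors <- geff %*% S
  if (is.finite(design$snr_db)) {
    C <- nrow(sensors)
    eta <- oneoverf_noise(rng, n_samp, n_trials * C)
    noise <- t(matrix(eta, n_samp * n_trials, C))
    noise <- anat$noise_mix %*% noise
    if (is.null(noise_scale)) {
      sig_pow <- mean(sensors^2)
      noise_pow <- mean(noise^2)
      noise_scale <- sqrt(sig_pow / (10^(design$snr_db / 10) * noise_pow))
    }
    sensors <- sensors + noise * noise_scale
  }

  data <- array(sensors, dim = c(nrow(sensors), n_samp, n_trials))
  out <- list(epochs = epoch_set(data, labels, fs, t[1L]),
              noise_scale = noise_scale)
  if (store_sources)
    out$roi_signals <- lapply(sig, function(m) m)  # samples x trials per ROI
  out
}

# Smooth raised-cosine onset ramp: 0 before ramp[1], 1 after ramp[2].
erd_ramp_gate <- function(t, ramp) {
  g <- numeric(length(t))
  g[t >= ramp[2L]] <- 1
  mid <- t > ramp[1L] & t < ramp[2L]
  g[mid] <- 0.5 - 0.5 * cos(pi * (t[mid] - ramp[1L]) / (ramp[2L] - ramp[1L]))
  g
}

# Stationary Gaussian noise with amplitude spectrum `shape` (length m >=
# n_samp, symmetric in frequency), drawn directly in the frequency domain:
# the real part of the inverse FFT of an iid complex-Gaussian spectrum
# multiplied by the shape is a real Gaussian process with the target
# spectrum (one inverse transform instead of a forward/backward pair).
# Unit sd per column.
spectral_noise <- function(rng, n_samp, n_trials, shape) {
  m <- length(shape)
  ## for a frequency-symmetric shape, the real and imaginary parts of one
  ## complex inverse transform are two independent realizations
  k <- as.integer(ceiling(n_trials / 2))
  z <- matrix(complex(real = rnorm_rng(rng, m * k),
                      imaginary = rnorm_rng(rng, m * k)), m, k)
  Y <- stats::mvfft(z * shape, inverse = TRUE)
  y <- cbind(Re(Y), Im(Y))[, seq_len(n_trials), drop = FALSE]
  scale_cols_unit_sd(y[seq_len(n_samp), , drop = FALSE])
}

# Narrowband Gaussian noise in `band` (squared order-4 Butterworth spectral
# envelope, matching the zero-phase filtered-white-noise construction).
narrowband_noise <- function(rng, n_samp, n_trials, fs, band) {
  m <- next_fast_len(n_samp)
  shape <- butter_bp_mag2(fft_freqs(m, fs), band)
  spectral_noise(rng, n_samp, n_trials, shape)
}

# 1/f ("pink") noise, unit sd per column.
oneoverf_noise <- function(rng, n_samp, n_trials, exponent = 1) {
  m <- next_fast_len(n_samp)
  f <- fft_freqs(m, 1)               # shape only depends on relative frequency
  shape <- c(0, abs(f[-1L])^(-exponent / 2))
  spectral_noise(rng, n_samp, n_trials, shape)
}

scale_cols_unit_sd <- function(x) {
  s <- sqrt(colMeans(x^2) - colMeans(x)^2)
  s[s == 0] <- 1
  sweep(x, 2L, s, "/")
}

#' Simulate a multi-subject cohort specification
#'
#' Draws per-subject generative parameters for `n_subjects` subjects sharing
#' one lead field. Coupling strengths are spread over an even grid on
#' `[0.1, 0.9]`; the `link` argument maps coupling to ERD depth (the planted
#' "connectivity facilitates imagery" effect), and `confound` controls whether
#' the oscillation power (hence SNR) depends on coupling. Subject seeds derive
#' from the cohort seed by a fixed affine rule, so the cohort is bitwise
#' reproducible; subject EEG is generated on demand with
#' [cohort_subject_data()] to keep memory bounded.
#'
#' @param n_subjects number of subjects (`>= 10`).
#' @param link `"increasing"` (default, `erd_depth = 0.05 + 0.35 * coupling`,
#'   i.e. 9-37% amplitude suppression over the coupling grid),
#'   `"constant"` (`erd_depth = 0.2`, severs the planted effect), or a
#'   function of coupling.
#' @param confound if `TRUE`, `alpha_power` increases with coupling (an
#'   SNR-mediated confound); if `FALSE` they are independent.
#' @param seed cohort seed.
#' @param lf optional shared [make_lead_field()]; built from `lf_args`
#'   otherwise.
#' @param design a [simulation_design()].
#' @param lf_args arguments for [make_lead_field()] when `lf` is `NULL`.
#' @return object of class `SMRCohort`: list with `subjects` (list of
#'   `SubjectGroundTruth`), `ground_truth` (data frame), `lead_field`,
#'   `design`, `seed`.
#' @export
simulate_cohort <- function(n_subjects = 80L, link = "increasing",
                            confound = FALSE, seed = 1L, lf = NULL,
                            design = simulation_design(),
                            lf_args = list()) {
  if (n_subjects < 10L) stop("'n_subjects' must be >= 10")
  seed <- as.integer(seed)
  rng <- new_rng(seed + 104729L)
  if (is.null(lf))
    lf <- do.call(make_lead_field, c(list(seed = seed + 15485863L), lf_args))

  link_fun <- if (is.function(link)) link
  else switch(match.arg(link, c("increasing", "constant")),
              increasing = function(c) 0.05 + 0.35 * c,
              constant = function(c) rep(0.2, length(c)))

  coupling <- seq(0.1, 0.9, length.out = n_subjects)
  coupling <- sample_rng(rng, coupling)   # order is immaterial, shuffled anyway
  erd <- link_fun(coupling)
  lag <- runif_rng(rng, n_subjects, pi / 3, 2 * pi / 3)
  mu_low <- runif_rng(rng, n_subjects, 8.5, 10)
  mu_high <- runif_rng(rng, n_subjects, 13, 14.5)
  alpha <- exp(rnorm_rng(rng, n_subjects, sd = 0.25))
  if (confound)
    alpha <- alpha * exp(1.2 * (coupling - 0.5))

  subj_seed <- (seed %% 100000L) * 10007L + seq_len(n_subjects) * 7919L
  subjects <- vector("list", n_subjects)
  for (i in seq_len(n_subjects))
    subjects[[i]] <- subject_ground_truth(
      coupling_strength = coupling[i], coupling_lag = lag[i],
      erd_depth = erd[i], mu_band = c(mu_low[i], mu_high[i]),
      alpha_power = alpha[i], seed = subj_seed[i])

  gt_tab <- data.frame(subject = seq_len(n_subjects), coupling = coupling,
                       lag = lag, erd_depth = erd, mu_low = mu_low,
                       mu_high = mu_high, alpha_power = alpha,
                       seed = subj_seed)
  structure(list(subjects = subjects, ground_truth = gt_tab, lead_field = lf,
                 design = design, seed = seed),
            class = "SMRCohort")
}

#' @export
print.SMRCohort <- function(x, ...) {
  cat(sprintf("<SMRCohort> %d subjects, seed %d, %d-channel lead field\n",
              length(x$subjects), x$seed, nrow(x$lead_field$gain)))
  invisible(x)
}

#' Materialize one cohort subject's EEG
#'
#' @param cohort an `SMRCohort`.
#' @param i subject index.
#' @param store_sources see [simulate_subject()].
#' @return see [simulate_subject()].
#' @export
cohort_subject_data <- function(cohort, i, store_sources = FALSE) {
  stopifnot(inherits(cohort, "SMRCohort"), i >= 1, i <= length(cohort$subjects))
  simulate_subject(cohort$subjects[[i]], cohort$lead_field, cohort$design,
                   store_sources = store_sources)
}
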