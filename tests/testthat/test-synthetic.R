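# Generator: lead-field geometry, determinism, planted ERD and coupling.

test_that("lead field is deterministic, finite and has all four ROIs", {
  lf1 <- make_lead_field(n_background = 10, n_channels = 10, roi_size = 2,
                         seed = 3)
  lf2 <- make_lead_field(n_background = 10, n_channels = 10, roi_size = 2,
                         seed = 3)
  expect_identical(lf1$gain, lf2$gain)
  expect_identical(lf1$source_positions, lf2$source_positions)
  expect_true(all(is.finite(lf1$gain)))
  rois <- c("precentral_L", "precentral_R", "postcentral_L", "postcentral_R")
  expect_true(all(rois %in% lf1$roi_labels))
  expect_true(all(colSums(abs(lf1$gain)) > 0))
  expect_true(all(rowSums(abs(lf1$gain)) > 0))
  ## atlas-sized ROIs are a supported configuration
  lf3 <- make_lead_field(n_background = 10, n_channels = 10,
                         roi_size = c(125, 112), seed = 1)
  expect_equal(sum(lf3$roi_labels == "precentral_L"), 125)
  expect_equal(sum(lf3$roi_labels == "postcentral_R"), 112)
})

test_that("mirrored sources map to mirrored electrodes", {
  lf <- tiny_lf()
  ## left/right ROI sources were placed with exactly mirrored jitter; under
  ## the channel mirror permutation the gain of a mirrored source equals the
  ## original gain with the sign of the x-oriented dipole flipped
  idxL <- which(lf$roi_labels == "precentral_L")
  idxR <- which(lf$roi_labels == "precentral_R")
  expect_equal(lf$source_positions[idxL, 1], -lf$source_positions[idxR, 1])
  for (k in seq_along(idxL)) {
    gl <- lf$gain[, (idxL[k] - 1) * 3 + (1:3)]
    gr <- lf$gain[, (idxR[k] - 1) * 3 + (1:3)]
    gr_mirrored <- gr[lf$mirror_perm, ]
    gr_mirrored[, 1] <- -gr_mirrored[, 1]
    expect_equal(gl, gr_mirrored, tolerance = 1e-12)
  }
})

test_that("subject simulation is seed-deterministic and well-formed", {
  d1 <- simulate_subject(tiny_subject()$ground_truth, tiny_lf(), tiny_design())
  d2 <- simulate_subject(tiny_subject()$ground_truth, tiny_lf(), tiny_design())
  expect_identical(d1$calibration$data, d2$calibration$data)
  expect_identical(d1$feedback$data, d2$feedback$data)
  expect_equal(dim(d1$calibration$data)[3], 27)       # 9 trials x 3 classes
  expect_equal(sort(unique(d1$calibration$labels)), c("feet", "left", "right"))
  expect_equal(d1$calibration$fs, 100)
  expect_error(simulate_subject(tiny_subject()$ground_truth, tiny_lf(),
                                tiny_design(t_post = 2)),
               "post-stimulus")
})

test_that("zero lag with positive coupling is rejected unless explicit", {
  expect_error(subject_ground_truth(coupling_strength = 0.5, coupling_lag = 0),
               "iCOH")
  expect_silent(subject_ground_truth(coupling_strength = 0.5,
                                     coupling_lag = 0, allow_zero_lag = TRUE))
  expect_silent(subject_ground_truth(coupling_strength = 0, coupling_lag = 0,
                                     allow_zero_lag = TRUE))
})

test_that("planted ERD depth is recovered from noiseless sources", {
  ## noiseless: no sensor noise, no per-source noise; measure ERD directly on
  ## the planted ROI signals
  for (d in c(0.2, 0.4)) {
    gt <- subject_ground_truth(coupling_strength = 0.6, erd_depth = d,
                               seed = 5)
    des <- tiny_design(snr_db = Inf, source_noise = 0)
    dat <- simulate_subject(gt, tiny_lf(), des, store_sources = TRUE)
    rs <- dat$roi_signals
    src <- array(0, dim = c(2, nrow(rs[[1]]), ncol(rs[[1]])))
    src[1, , ] <- rs$precentral_L
    src[2, , ] <- rs$postcentral_L
    ep <- epoch_set(src, dat$calibration$labels, 100, -1.5)
    curves <- erd_curve(ep, gt$mu_band)
    t <- curves$right$t
    plateau <- t >= 2 & t <= 3.5
    ## left hemisphere is suppressed for right-hand imagery ...
    erd_meas <- mean(curves$right$values[, plateau])
    expect_equal(erd_meas, -100 * d, tolerance = 0.05 * 100 * d)
    ## ... and unmodulated for left-hand imagery
    expect_lt(abs(mean(curves$left$values[, plateau])), 8)
  }
})

test_that("erd_depth = 0 leaves the class-averaged envelope flat", {
  gt <- subject_ground_truth(coupling_strength = 0.6, erd_depth = 0, seed = 9)
  des <- tiny_design(snr_db = Inf, source_noise = 0)
  dat <- simulate_subject(gt, tiny_lf(), des, store_sources = TRUE)
  src <- array(dat$roi_signals$precentral_R,
               dim = c(1, nrow(dat$roi_signals$precentral_R),
                       ncol(dat$roi_signals$precentral_R)))
  ep <- epoch_set(src, dat$calibration$labels, 100, -1.5)
  curves <- erd_curve(ep, gt$mu_band)
  t <- curves$left$t
  plateau <- t >= 2 & t <= 3.5
  for (cl in names(curves))
    expect_lt(abs(mean(curves[[cl]]$values[, plateau])), 8)
})

test_that("full coupling at quarter-cycle lag gives unit source coherency", {
  gt <- subject_ground_truth(coupling_strength = 1, coupling_lag = pi / 2,
                             erd_depth = 0, seed = 13)
  des <- tiny_design(snr_db = Inf, source_noise = 0)
  dat <- simulate_subject(gt, tiny_lf(), des, store_sources = TRUE)
  rs <- dat$roi_signals
  x <- array(0, dim = c(2, nrow(rs[[1]]), ncol(rs[[1]])))
  x[1, , ] <- rs$precentral_L
  x[2, , ] <- rs$postcentral_L
  cs <- cross_spectrum(x, 100, nfft = 1024)
  bins <- cs$freqs >= 10 & cs$freqs <= 13
  coh <- abs(cs$S[bins, 1, 2]) /
    sqrt(Re(cs$S[bins, 1, 1]) * Re(cs$S[bins, 2, 2]))
  expect_true(all(coh > 0.98))
})

test_that("uncoupled ROI pairs stay below their trial-shuffled iCOH null", {
  gt <- subject_ground_truth(coupling_strength = 0, coupling_lag = pi / 2,
                             erd_depth = 0, seed = 17)
  des <- tiny_design(snr_db = Inf, source_noise = 0)
  dat <- simulate_subject(gt, tiny_lf(), des, store_sources = TRUE)
  rs <- dat$roi_signals
  n_tr <- ncol(rs[[1]])
  build <- function(perm) {
    x <- array(0, dim = c(2, nrow(rs[[1]]), n_tr))
    x[1, , ] <- rs$precentral_L
    x[2, , ] <- rs$postcentral_L[, perm]
    mean(icoh(cross_spectrum(x, 100))[, 1, 2])
  }
  obs <- build(seq_len(n_tr))
  set.seed(42)
  null <- replicate(40, build(sample(n_tr)))
  expect_lt(obs, quantile(null, 0.95))
})

test_that("cohort specification is reproducible and link/confound behave", {
  co1 <- simulate_cohort(n_subjects = 12, seed = 4)
  co2 <- simulate_cohort(n_subjects = 12, seed = 4)
  expect_identical(co1$ground_truth, co2$ground_truth)
  gt <- co1$ground_truth
  expect_true(all(gt$coupling >= 0.1 & gt$coupling <= 0.9))
  expect_equal(length(unique(gt$seed)), 12)
  ## increasing link is monotone in coupling
  expect_true(all(diff(gt$erd_depth[order(gt$coupling)]) > 0))
  ## constant link severs it
  co3 <- simulate_cohort(n_subjects = 12, link = "constant", seed = 4)
  expect_equal(length(unique(co3$ground_truth$erd_depth)), 1)
  ## confound off: oscillation power unrelated to coupling by construction
  co4 <- simulate_cohort(n_subjects = 40, confound = FALSE, seed = 6)
  co5 <- simulate_cohort(n_subjects = 40, confound = TRUE, seed = 6)
  expect_lt(abs(cor(co4$ground_truth$alpha_power, co4$ground_truth$coupling,
                    method = "spearman")), 0.4)
  expect_gt(cor(co5$ground_truth$alpha_power, co5$ground_truth$coupling,
                method = "spearman"), 0.5)
  ## the default cohort size mirrors the reference study
  expect_equal(formals(simulate_cohort)$n_subjects, 80L)
  expect_error(simulate_cohort(n_subjects = 5), ">= 10")
})
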