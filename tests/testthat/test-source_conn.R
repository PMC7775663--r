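# eLORETA inversion, ROI components, cross-spectra, imaginary coherency and
# aggregation.

test_that("eLORETA localizes noiseless point sources and is linear", {
  lf <- tiny_lf()
  inv0 <- eloreta_inverse(lf, reg = 0)
  ## zero sensor data give a zero source estimate
  expect_equal(as.numeric(inv0$kernel %*% rep(0, nrow(lf$gain))),
               rep(0, nrow(inv0$kernel)))
  set.seed(21)
  n_src <- length(lf$roi_labels)
  hits <- 0
  for (rep in 1:8) {
    s <- sample(n_src, 1)
    q <- rnorm(3); q <- q / sqrt(sum(q^2))
    topo <- lf$gain[, (s - 1) * 3 + (1:3)] %*% q
    pm <- source_power_map(inv0, topo)
    hits <- hits + (which.max(pm) == s)
  }
  expect_gte(hits, 7)
})

test_that("converged eLORETA weights satisfy the fixed-point equation", {
  lf <- tiny_lf()
  tol <- 1e-8
  inv <- eloreta_inverse(lf, reg = 0.05, tol = tol)
  L <- lf$gain
  C <- nrow(L)
  S <- length(lf$roi_labels)
  LW <- L
  for (s in seq_len(S)) {
    cols <- (s - 1) * 3 + (1:3)
    LW[, cols] <- L[, cols] %*% inv$winv[[s]]
  }
  M <- solve(LW %*% t(L) + inv$alpha * diag(C))
  resid <- 0
  for (s in seq_len(S)) {
    cols <- (s - 1) * 3 + (1:3)
    W_target <- smrconn:::sym_sqrt(t(L[, cols]) %*% M %*% L[, cols])
    W_current <- solve(inv$winv[[s]])
    resid <- max(resid, norm(W_target - W_current, "F") /
                   norm(W_current, "F"))
  }
  expect_lt(resid, 10 * tol * 1e3)  # relative residual, generous factor
  expect_error(eloreta_inverse(lf, reg = 0.05, max_iter = 2), "converge")
})

test_that("ROI components capture rank-one activity and are scale invariant", {
  dat <- simulate_subject(
    subject_ground_truth(coupling_strength = 0.7, erd_depth = 0.3, seed = 31),
    tiny_lf(), tiny_design(snr_db = Inf, source_noise = 0,
                           background_power = 0),
    store_sources = TRUE)
  rc <- extract_roi_components(dat$calibration, tiny_inv(), tiny_lf(),
                               interval = c(1.5, 3.0))
  for (roi in names(rc$comps)) {
    sv <- rc$svd_gains[[roi]]
    expect_true(all(diff(sv) <= 1e-9))               # non-increasing
    expect_equal(length(sv), 3)
  }
  ## the leading component recovers the planted source signal
  tt <- epoch_times(dat$calibration)
  keep <- which(tt >= 1.5 - 1e-9 & tt <= 3.0 + 1e-9)
  planted <- as.numeric(dat$roi_signals$precentral_L[keep, ])
  recovered <- as.numeric(rc$comps$precentral_L[1, , ])
  expect_gt(abs(cor(planted, recovered)), 0.85)
  ## doubling the raw data leaves the standardized components unchanged
  ep2 <- dat$calibration; ep2$data <- ep2$data * 2
  rc2 <- extract_roi_components(ep2, tiny_inv(), tiny_lf(),
                                interval = c(1.5, 3.0))
  expect_equal(rc2$comps$precentral_L, rc$comps$precentral_L,
               tolerance = 1e-9)
  expect_error(extract_roi_components(dat$calibration, tiny_inv(), tiny_lf(),
                                      rois = "cerebellum"), "absent")
})

test_that("activity from a single ROI is exactly rank one in its components", {
  lf <- tiny_lf()
  set.seed(33)
  idx <- which(lf$roi_labels == "precentral_L")
  topo <- rep(0, nrow(lf$gain))
  for (s in idx) {
    q <- rnorm(3); q <- q / sqrt(sum(q^2))
    topo <- topo + abs(rnorm(1, 1, 0.2)) *
      as.numeric(lf$gain[, (s - 1) * 3 + (1:3)] %*% q)
  }
  n_samp <- 551L; n_tr <- 12L
  sig <- matrix(rnorm(n_samp * n_tr), n_samp, n_tr)
  sig <- smrconn:::fft_bandpass_matrix(sig, 100, c(9, 14))
  data <- array(0, dim = c(nrow(lf$gain), n_samp, n_tr))
  for (tr in seq_len(n_tr)) data[, , tr] <- topo %o% sig[, tr]
  ep <- epoch_set(data, rep("left", n_tr), 100, -1.5)
  rc <- extract_roi_components(ep, tiny_inv(), lf, c(1.5, 3.0))
  sv <- rc$svd_gains$precentral_L
  expect_gt(sv[1]^2 / sum(sv^2), 0.99)
  tt <- seq(-1.5, 4, by = 0.01)
  keep <- which(tt >= 1.5 - 1e-9 & tt <= 3.0 + 1e-9)
  expect_gt(abs(cor(as.numeric(sig[keep, ]),
                    as.numeric(rc$comps$precentral_L[1, , ]))), 0.999)
})

test_that("cross-spectra are Hermitian and match the explicit DFT oracle", {
  set.seed(41)
  x <- array(rnorm(2 * 10 * 4), dim = c(2, 10, 4))
  cs <- cross_spectrum(x, fs = 100, nfft = 16)
  orc <- oracle_cross_spectrum(x, 100, 16)
  expect_equal(cs$S, orc, tolerance = 1e-10)
  for (f in seq_along(cs$freqs)) {
    Sf <- matrix(cs$S[f, , ], 2, 2)
    expect_equal(Sf, Conj(t(Sf)), tolerance = 1e-12)
    expect_true(all(Re(diag(Sf)) >= 0))
    expect_lt(max(abs(Im(diag(Sf)))), 1e-12)
  }
  expect_error(cross_spectrum(x[, , 1, drop = FALSE], 100), "trials")
})

test_that("identical series have unit coherency and zero iCOH", {
  set.seed(42)
  x <- array(rnorm(1 * 20 * 6), dim = c(1, 20, 6))
  xx <- array(0, dim = c(2, 20, 6))
  xx[1, , ] <- x[1, , ]; xx[2, , ] <- x[1, , ]
  cs <- cross_spectrum(xx, 100, nfft = 32)
  ic <- icoh(cs)
  expect_true(all(ic[, 1, 2] < 1e-12))
  coh <- abs(cs$S[, 1, 2]) / sqrt(Re(cs$S[, 1, 1]) * Re(cs$S[, 2, 2]))
  expect_equal(coh, rep(1, length(cs$freqs)), tolerance = 1e-10)
})

test_that("iCOH hits its analytic limits and null levels", {
  ## exact zero for a scaled zero-lag copy
  x <- lagged_pair(20, lag = 0, seed = 2)
  x[2, , ] <- 3.7 * x[1, , ]
  ic0 <- icoh(cross_spectrum(x, 100))
  expect_lt(max(ic0[, 1, 2]), 1e-10)

  ## quarter-cycle lag, 75 trials: band-center iCOH >= 0.9
  xl <- lagged_pair(75, lag = pi / 2, seed = 3)
  cs <- cross_spectrum(xl, 100)
  ic <- icoh(cs)
  center <- which.min(abs(cs$freqs - 11.5))
  expect_gte(ic[center, 1, 2], 0.9)
  expect_true(all(ic >= 0 & ic <= 1))

  ## independent white noise, 75 trials: mean iCOH small
  set.seed(4)
  xw <- array(rnorm(2 * 100 * 75), dim = c(2, 100, 75))
  icw <- icoh(cross_spectrum(xw, 100))
  expect_lte(mean(icw[, 1, 2]), 0.15)
})

test_that("aggregation averages the right pairs and matches a flat loop", {
  ## constant-c icoh arrays aggregate to c
  rois <- c("precentral_L", "precentral_R", "postcentral_L", "postcentral_R")
  freqs <- seq(0, 50, length.out = 65)
  series_roi <- rep(rois, each = 3)
  const <- array(0.37, dim = c(65, 12, 12))
  ric <- list(icoh = list(left = const, right = const), freqs = freqs,
              series_roi = series_roi)
  expect_equal(aggregate_icoh(ric, c(9, 14), "within"), 0.37)
  expect_equal(aggregate_icoh(ric, c(9, 14), "across"), 0.37)

  ## random arrays: flat-loop oracle
  set.seed(5)
  arr <- array(runif(65 * 12 * 12), dim = c(65, 12, 12))
  ric$icoh <- list(left = arr)
  got <- aggregate_icoh(ric, c(9, 14), "within")
  bins <- which(freqs >= 9 & freqs <= 14)
  vals <- c()
  for (pr in list(c("precentral_L", "postcentral_L"),
                  c("precentral_R", "postcentral_R")))
    for (i in which(series_roi == pr[1]))
      for (j in which(series_roi == pr[2]))
        for (b in bins) vals <- c(vals, arr[b, i, j])
  expect_equal(got, mean(vals), tolerance = 1e-12)

  ## hemisphere swap leaves the within aggregate unchanged
  swap <- c(4:6, 1:3, 10:12, 7:9)
  ric_sw <- ric
  ric_sw$icoh$left <- arr[, swap, swap]
  expect_equal(aggregate_icoh(ric_sw, c(9, 14), "within"), got,
               tolerance = 1e-12)
  expect_error(aggregate_icoh(ric, c(60, 70), "within"), "bins")
})

test_that("sensor-level rescaling leaves the connectivity aggregates fixed", {
  dat <- tiny_subject()
  ric1 <- roi_icoh(extract_roi_components(dat$calibration, tiny_inv(),
                                          tiny_lf(), c(1.5, 3.0)))
  ep2 <- dat$calibration; ep2$data <- ep2$data * 4.2
  ric2 <- roi_icoh(extract_roi_components(ep2, tiny_inv(), tiny_lf(),
                                          c(1.5, 3.0)))
  expect_equal(aggregate_icoh(ric1, c(9, 14), "within"),
               aggregate_icoh(ric2, c(9, 14), "within"), tolerance = 1e-9)
  expect_equal(aggregate_icoh(ric1, c(9, 14), "across"),
               aggregate_icoh(ric2, c(9, 14), "across"), tolerance = 1e-9)
})

test_that("aggregate iCOH rises with planted coupling strength", {
  vals <- c()
  grid <- seq(0.1, 0.9, length.out = 8)
  for (i in seq_along(grid)) {
    gt <- subject_ground_truth(coupling_strength = grid[i],
                               coupling_lag = pi / 2, erd_depth = 0.2,
                               seed = 100 + i)
    dat <- simulate_subject(gt, tiny_lf(),
                            tiny_design(n_per_class = 20L,
                                        n_per_class_feedback = 2L),
                            store_sources = FALSE)
    ric <- roi_icoh(extract_roi_components(dat$calibration, tiny_inv(),
                                           tiny_lf(), c(1.5, 3.0)))
    vals <- c(vals, aggregate_icoh(ric, c(9, 14), "within"))
  }
  expect_gt(cor(grid, vals, method = "spearman"), 0.9)
})
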