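# Filtering, discriminability spectra, band and interval selection, ERD.

test_that("bandpass keeps the passband and rejects the stopband", {
  ep10 <- tone_epochs(10)
  out10 <- bandpass(ep10, c(9, 14))
  interior <- 101:450   # clear of filter edge effects
  ratio10 <- sd(out10$data[1, interior, 1]) / sd(ep10$data[1, interior, 1])
  expect_equal(ratio10, 1, tolerance = 0.05)

  ep30 <- tone_epochs(30)
  out30 <- bandpass(ep30, c(9, 14))
  ratio30 <- sd(out30$data[1, interior, 1]) / sd(ep30$data[1, interior, 1])
  expect_lt(ratio30, 0.10)

  expect_error(bandpass(ep10, c(9, 60)), "Nyquist")
  expect_error(bandpass(ep10, c(14, 9)), "low < high")
})

test_that("out-of-band PSD mass of filtered white noise is below 5%", {
  set.seed(1)
  x <- array(rnorm(4 * 551 * 6), dim = c(4, 551, 6))
  ep <- epoch_set(x, rep("a", 6), 100, -1.5)
  out <- bandpass(ep, c(9, 14))
  ## PSD integration oracle: periodogram of every channel/trial
  inb <- 0; tot <- 0
  for (ch in 1:4) for (tr in 1:6) {
    v <- out$data[ch, , tr]
    pg <- Mod(fft(v))^2 / length(v)
    f <- (seq_along(v) - 1) * 100 / length(v)
    keep <- f <= 50
    inband <- f >= 8 & f <= 15      # one transition bin of slack each side
    tot <- tot + sum(pg[keep])
    inb <- inb + sum(pg[keep & inband])
  }
  expect_lt((tot - inb) / tot, 0.05)
})

test_that("fft and filtfilt band-pass agree away from the edges", {
  ep <- tiny_subject()$calibration
  sub <- subset_trials(ep, 1:2)
  a <- bandpass(sub, c(9, 14), method = "fft")
  b <- bandpass(sub, c(9, 14), method = "filtfilt")
  interior <- 101:450
  err <- max(abs(a$data[, interior, ] - b$data[, interior, ]))
  scale <- max(abs(b$data[, interior, ]))
  expect_lt(err / scale, 0.05)
})

test_that("signed r2 matches the point-biserial oracle and its symmetries", {
  ## perfectly separated power levels: big amplitude difference between
  ## classes on channel 1
  set.seed(2)
  n <- 24
  amp <- c(rep(3, n / 2), rep(1, n / 2))
  x <- array(rnorm(2 * 551 * n), dim = c(2, 551, n))
  for (tr in seq_len(n)) x[1, , tr] <- amp[tr] * x[1, , tr]
  ep <- epoch_set(x, rep(c("A", "B"), each = n / 2), 100, -1.5)
  map <- signed_r2_spectrum(ep, "A", "B", smooth_hz = 0)
  ## oracle on the same per-trial Welch powers
  wp <- smrconn:::welch_trial_power(ep)
  orc <- oracle_signed_r2(wp$power, as.numeric(ep$labels == "A"))
  expect_equal(map$signed_r2, orc, tolerance = 1e-10)
  expect_true(all(map$signed_r2[1, ] > 0.5))   # all A powers above all B

  ## swapping the class labels negates the map exactly
  map_sw <- signed_r2_spectrum(ep, "B", "A", smooth_hz = 0)
  expect_equal(map_sw$signed_r2, -map$signed_r2, tolerance = 1e-12)

  ## identical class distributions: near-zero discriminability
  set.seed(3)
  x0 <- array(rnorm(2 * 551 * 100), dim = c(2, 551, 100))
  ep0 <- epoch_set(x0, rep(c("A", "B"), 50), 100, -1.5)
  map0 <- signed_r2_spectrum(ep0, "A", "B")
  expect_lt(max(abs(map0$signed_r2)), 0.1)

  expect_error(signed_r2_spectrum(ep0, "A", "C"), "present")
})

test_that("band growth follows the one-third rule", {
  freqs <- 5:35
  mk <- function(profile) structure(
    list(signed_r2 = matrix(profile, 1), freqs = freqs, classes = c("A", "B")),
    class = "DiscriminabilityMap")

  ## single isolated peak: one-bin band, widened to one bin width
  p <- rep(0.01, length(freqs)); p[freqs == 12] <- 0.6
  expect_equal(as.numeric(select_band(mk(p))), c(11.5, 12.5))

  ## plateau 8..16 passes the threshold everywhere
  p <- rep(0.005, length(freqs)); p[freqs >= 8 & freqs <= 16] <- 0.4
  expect_equal(as.numeric(select_band(mk(p))), c(8, 16))

  ## Gaussian profile, peak 12 Hz, sigma 2: the 1/3 crossings are at
  ## 12 +/- sigma * sqrt(2 log 3) = 12 +/- 2.964 Hz
  p <- exp(-(freqs - 12)^2 / (2 * 2^2))
  band <- as.numeric(select_band(mk(p)))
  expect_lte(abs(band[1] - (12 - 2.964)), 1)
  expect_lte(abs(band[2] - (12 + 2.964)), 1)
  ## the selected band always contains the argmax bin
  expect_true(band[1] <= 12 && band[2] >= 12)

  expect_warning(b0 <- select_band(mk(rep(0, length(freqs)))), "mu band")
  expect_equal(as.numeric(b0), c(9, 14))
})

test_that("the ERD formula and its invariances hold", {
  ## amplitude-modulated tone: post-stimulus amplitude is half the baseline
  fs <- 100
  t <- seq(-1.5, 4, by = 1 / fs)
  gate <- ifelse(t < 0, 1, 0.5)
  x <- array(0, dim = c(1, length(t), 6))
  for (tr in 1:6) x[1, , tr] <- gate * sin(2 * pi * 11 * t + tr)
  ep <- epoch_set(x, rep("left", 6), fs, -1.5)
  cur <- erd_curve(ep, c(9, 14))$left
  mid <- cur$t >= 1 & cur$t <= 3.5
  expect_equal(mean(cur$values[, mid]), -50, tolerance = 2)
  base <- cur$t >= -1.2 & cur$t <= -0.3
  expect_lt(max(abs(cur$values[, base])), 5)

  ## POST == PRE everywhere: identically zero ERD
  y <- array(0, dim = c(1, length(t), 4))
  for (tr in 1:4) y[1, , tr] <- sin(2 * pi * 11 * t + tr)
  flat <- erd_curve(epoch_set(y, rep("a", 4), fs, -1.5), c(9, 14))$a
  expect_lt(max(abs(flat$values[, mid])), 3)

  ## invariance to positive channel rescaling
  ep2 <- ep; ep2$data <- ep$data * 7.3
  cur2 <- erd_curve(ep2, c(9, 14))$left
  expect_equal(cur$values, cur2$values, tolerance = 1e-10)
})

test_that("interval selection matches exhaustive search and handles ties", {
  mk_curves <- function(vals, t) {
    ## two one-channel curves whose difference is `vals`
    list(a = structure(list(values = matrix(vals, 1), t = t, class = "a"),
                       class = "ERDCurve"),
         b = structure(list(values = matrix(0, 1, length(t)), t = t,
                            class = "b"),
                       class = "ERDCurve"))
  }
  ## coarse time axis keeps the exhaustive oracle tiny
  t <- seq(0.75, 4, by = 0.05)

  ## boxcar contrast on (1.5, 3.0): selection inside (1.25, 3.25)
  vals <- ifelse(t >= 1.5 & t <= 3.0, 40, 0)
  iv <- select_interval(mk_curves(vals, t), search = c(0.75, 4))
  expect_gte(iv[1], 1.25); expect_lte(iv[2], 3.25)
  expect_gte(iv[2] - iv[1], 1.0)

  ## random smooth contrasts: equality with the exhaustive oracle
  set.seed(4)
  for (rep in 1:5) {
    vals <- abs(stats::filter(rnorm(length(t) + 20), rep(1, 7) / 7,
                              sides = 2))[11:(10 + length(t))]
    vals <- as.numeric(vals)
    iv <- select_interval(mk_curves(vals, t), search = c(0.75, 4))
    expect_equal(iv, oracle_select_interval(vals, t, 1.0), tolerance = 1e-9)
  }

  ## constant contrast: full search window by the tie rule
  iv <- select_interval(mk_curves(rep(5, length(t)), t), search = c(0.75, 4))
  expect_equal(iv, c(0.75, 4), tolerance = 0.051)

  ## vanishing contrast: canonical default with a warning
  expect_warning(
    iv0 <- select_interval(mk_curves(rep(0, length(t)), t),
                           search = c(0.75, 4)),
    "default")
  expect_equal(iv0, c(1.5, 3.0))

  expect_error(select_interval(mk_curves(rep(1, length(t)), t),
                               search = c(10, 12)),
               "outside")
})
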