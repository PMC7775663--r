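# CSP + log-variance + LDA calibration, chronological validation, simulated
# online cursor feedback and the binomial chance-level threshold.

# Per-trial trace-normalized covariances: channels x channels x trials.
trial_covariances <- function(x) {
  d <- dim(x)
  covs <- array(0, dim = c(d[1L], d[1L], d[3L]))
  for (tr in seq_len(d[3L])) {
    xt <- x[, , tr]
    xt <- xt - rowMeans(xt)
    C <- tcrossprod(xt) / d[2L]
    covs[, , tr] <- C / sum(diag(C))
  }
  covs
}

# Trial-averaged, trace-normalized class covariance. x: channels x samples x
# trials array.
class_covariance <- function(x) {
  covs <- trial_covariances(x)
  rowMeans(covs, dims = 2L)
}

# Shrink a covariance toward nu * I. gamma in [0,1].
shrink_cov <- function(S, gamma) {
  nu <- mean(diag(S))
  (1 - gamma) * S + gamma * nu * diag(nrow(S))
}

# Simple analytic shrinkage intensity toward the scaled identity, computed
# from the dispersion of per-trial covariance estimates (Ledoit-Wolf style:
# sum of estimator variances over squared distance to the target).
auto_gamma_covs <- function(covs) {
  d <- dim(covs)
  n <- d[3L]
  S <- rowMeans(covs, dims = 2L)
  M2 <- rowMeans(covs^2, dims = 2L)
  V <- (M2 - S^2) * n / (n - 1L) / n       # var of the mean estimator
  nu <- mean(diag(S))
  denom <- sum((S - nu * diag(d[1L]))^2)
  if (denom <= 0) return(1)
  min(1, max(0, sum(V) / denom))
}

auto_gamma <- function(x) auto_gamma_covs(trial_covariances(x))

#' Common spatial pattern filters
#'
#' Solves the generalized eigenproblem of the two trial-averaged class
#' covariances (whitening the pooled covariance, then diagonalizing class A's
#' share). Eigenvalues are the fraction of whitened variance explained by
#' `classA` and lie in `[0, 1]`; the `n_per_class` components from each
#' spectral end (most discriminative for either class) are retained, ordered
#' by `max(lambda, 1 - lambda)` descending. Patterns are the corresponding
#' columns of the inverse-transposed full filter matrix, so
#' `t(patterns) %*% filters` is the identity on retained components.
#'
#' @param epochs an `EpochSet`, already band-pass filtered and cropped to the
#'   discriminative interval.
#' @param classA,classB class labels.
#' @param n_per_class components kept per spectral end.
#' @param shrinkage `"auto"` (analytic identity-target shrinkage) or `"none"`.
#' @return object of class `CSPModel` with `filters`, `patterns`
#'   (channels x components), `eigenvalues`, `classes`.
#' @export
fit_csp <- function(epochs, classA, classB, n_per_class = 3L,
                    shrinkage = c("auto", "none")) {
  stopifnot(inherits(epochs, "EpochSet"))
  shrinkage <- match.arg(shrinkage)
  xa <- epochs$data[, , epochs$labels == classA, drop = FALSE]
  xb <- epochs$data[, , epochs$labels == classB, drop = FALSE]
  if (dim(xa)[3L] < 2L || dim(xb)[3L] < 2L)
    stop("need >= 2 trials per class")
  ca <- trial_covariances(xa)
  cb <- trial_covariances(xb)
  Sa <- rowMeans(ca, dims = 2L)
  Sb <- rowMeans(cb, dims = 2L)
  if (shrinkage == "auto") {
    Sa <- shrink_cov(Sa, auto_gamma_covs(ca))
    Sb <- shrink_cov(Sb, auto_gamma_covs(cb))
  }
  P <- Sa + Sb
  ep <- eigen(P, symmetric = TRUE)
  if (min(ep$values) < 1e-10 * max(ep$values))
    stop("pooled covariance is rank deficient; use shrinkage = \"auto\"")
  Tw <- ep$vectors %*% diag(1 / sqrt(ep$values)) %*% t(ep$vectors)
  M <- Tw %*% Sa %*% Tw
  em <- eigen((M + t(M)) / 2, symmetric = TRUE)     # eigenvalues descending
  W_full <- Tw %*% em$vectors
  A_full <- ep$vectors %*% diag(sqrt(ep$values)) %*% t(ep$vectors) %*%
    em$vectors                                       # = (W_full^-T)
  lam <- pmin(pmax(em$values, 0), 1)
  nc <- ncol(W_full)
  n_per_class <- min(n_per_class, nc %/% 2L)
  sel <- c(seq_len(n_per_class), nc - seq_len(n_per_class) + 1L)
  ord <- order(pmax(lam[sel], 1 - lam[sel]), decreasing = TRUE)
  sel <- sel[ord]
  structure(list(filters = W_full[, sel, drop = FALSE],
                 patterns = A_full[, sel, drop = FALSE],
                 eigenvalues = lam[sel],
                 classes = c(classA, classB)),
            class = "CSPModel")
}

#' @export
print.CSPModel <- function(x, ...) {
  cat(sprintf("<CSPModel> %d filters (%s vs %s), eigenvalues: %s\n",
              ncol(x$filters), x$classes[1L], x$classes[2L],
              paste(sprintf("%.3f", x$eigenvalues), collapse = ", ")))
  invisible(x)
}

#' Log-variance features of CSP-projected trials
#'
#' @param epochs an `EpochSet` (band-filtered, cropped) or a
#'   channels x samples x trials array.
#' @param csp a [fit_csp()] model.
#' @return trials x components matrix of `log` variances.
#' @export
logvar_features <- function(epochs, csp) {
  x <- if (inherits(epochs, "EpochSet")) epochs$data else epochs
  d <- dim(x)
  k <- ncol(csp$filters)
  feats <- matrix(0, d[3L], k)
  for (tr in seq_len(d[3L])) {
    z <- crossprod(csp$filters, x[, , tr])   # components x samples
    v <- rowSums((z - rowMeans(z))^2) / (d[2L] - 1L)
    if (any(v <= 0)) stop("zero-variance CSP component")
    feats[tr, ] <- log(v)
  }
  feats
}

#' Regularized linear discriminant analysis
#'
#' Pooled-covariance LDA with analytic identity-target shrinkage. The
#' decision value is `w . x + b`; positive values vote for `classB` (`pos`)
#' and negative for `classA` (`neg`).
#'
#' @param features trials x features matrix.
#' @param labels per-trial labels (exactly two classes).
#' @param shrinkage `"auto"` or `"none"`.
#' @return object of class `LDAModel` with `weights`, `bias`, `class_map`.
#' @export
fit_lda <- function(features, labels, shrinkage = c("auto", "none")) {
  shrinkage <- match.arg(shrinkage)
  features <- as.matrix(features)
  classes <- unique(labels)
  if (length(classes) != 2L) stop("exactly two classes required")
  Xa <- features[labels == classes[1L], , drop = FALSE]
  Xb <- features[labels == classes[2L], , drop = FALSE]
  mu_a <- colMeans(Xa); mu_b <- colMeans(Xb)
  Xc <- rbind(sweep(Xa, 2L, mu_a), sweep(Xb, 2L, mu_b))
  n <- nrow(Xc)
  S <- crossprod(Xc) / (n - 2L)
  if (shrinkage == "auto") {
    nu <- mean(diag(S))
    p <- ncol(S)
    ## Schaefer-Strimmer-style intensity from the variance of the entries
    ## of the sample covariance
    Vhat <- matrix(0, p, p)
    for (i in seq_len(n)) Vhat <- Vhat + (tcrossprod(Xc[i, ]) - S)^2
    Vhat <- Vhat * n / ((n - 1L)^3)
    denom <- sum((S - nu * diag(p))^2)
    gamma <- if (denom > 0) min(1, max(0, sum(Vhat) / denom)) else 1
    S <- shrink_cov(S, gamma)
  }
  w <- tryCatch(solve(S, mu_b - mu_a), error = function(e)
    stop("singular pooled covariance; use shrinkage = \"auto\""))
  b <- -0.5 * sum(w * (mu_a + mu_b))
  if (!all(is.finite(w)) || !is.finite(b)) stop("non-finite LDA solution")
  structure(list(weights = as.numeric(w), bias = b,
                 class_map = c(neg = as.character(classes[1L]),
                               pos = as.character(classes[2L]))),
            class = "LDAModel")
}

#' LDA decision values
#'
#' @param lda an `LDAModel`.
#' @param features trials x features matrix.
#' @return numeric decision values (`> 0` votes for the `pos` class).
#' @export
lda_decision <- function(lda, features) {
  as.numeric(as.matrix(features) %*% lda$weights + lda$bias)
}

# Per-subject calibration cache. Per-trial Welch powers, band-filtered data
# and Hilbert envelopes are identical whether computed on all trials or on a
# subset (every estimate is per-trial), so they are computed once on the full
# calibration set and shared across CV folds and the final fit.
calibration_cache <- function(epochs) {
  env <- new.env(parent = emptyenv())
  env$epochs <- epochs
  env$t <- epoch_times(epochs)
  env$pow <- welch_trial_power(epochs)
  env$ana <- list()
  env$filt <- list()
  env$envl <- list()
  env
}

band_key <- function(band) paste(round(band, 4), collapse = "_")

# Complex band-passed analytic epochs for one band (computed once):
# Re() is the zero-phase filtered signal, Mod() the amplitude envelope.
cache_analytic <- function(cache, band) {
  key <- band_key(band)
  if (is.null(cache$ana[[key]])) {
    d <- dim(cache$epochs$data)
    flat <- matrix(aperm(cache$epochs$data, c(2L, 1L, 3L)), d[2L],
                   d[1L] * d[3L])
    y <- analytic_bandpass_matrix(flat, cache$epochs$fs, band)
    cache$ana[[key]] <- aperm(array(y, dim = c(d[2L], d[1L], d[3L])),
                              c(2L, 1L, 3L))
  }
  cache$ana[[key]]
}

cache_filtered <- function(cache, band) {
  key <- band_key(band)
  if (is.null(cache$filt[[key]]))
    cache$filt[[key]] <- Re(cache_analytic(cache, band))
  cache$filt[[key]]
}

cache_envelopes <- function(cache, band) {
  key <- band_key(band)
  if (is.null(cache$envl[[key]]))
    cache$envl[[key]] <- Mod(cache_analytic(cache, band))
  cache$envl[[key]]
}

# One full training pass on a set of training trials: band + interval
# selection, CSP, LDA. Used both inside CV folds and for the final model.
train_pair_model <- function(cache, train_idx, classA, classB, n_csp = 3L,
                             band = NULL, interval = NULL) {
  labels <- cache$epochs$labels
  sub <- train_idx[labels[train_idx] %in% c(classA, classB)]
  if (is.null(band)) {
    y <- as.numeric(labels[sub] == classA)
    map <- signed_r2_core(cache$pow$power[, , sub, drop = FALSE],
                          cache$pow$freqs, y, smooth_hz = 3,
                          classes = c(classA, classB))
    band <- suppressWarnings(select_band(map))
  }
  band <- as.numeric(band)
  if (is.null(interval)) {
    env <- cache_envelopes(cache, band)
    lab_sub <- rep("unused", length(labels))
    lab_sub[sub] <- labels[sub]
    curves <- suppressWarnings(
      erd_from_envelopes(env, lab_sub, cache$t, cache$epochs$fs, band,
                         classes = c(classA, classB)))
    interval <- suppressWarnings(select_interval(curves))
  }
  x <- cache_filtered(cache, band)
  eps <- 0.5 / cache$epochs$fs
  smp <- which(cache$t >= interval[1L] - eps & cache$t <= interval[2L] + eps)
  ep <- epoch_set(x[, smp, sub, drop = FALSE], labels[sub],
                  cache$epochs$fs, cache$t[smp[1L]])
  csp <- fit_csp(ep, classA, classB, n_per_class = n_csp)
  feats <- logvar_features(ep, csp)
  lda <- fit_lda(feats, ep$labels)
  list(band = band, interval = interval, csp = csp, lda = lda,
       pair = c(classA, classB))
}

predict_pair_model <- function(model, cache, test_idx) {
  x <- cache_filtered(cache, model$band)
  eps <- 0.5 / cache$epochs$fs
  smp <- which(cache$t >= model$interval[1L] - eps &
                 cache$t <= model$interval[2L] + eps)
  feats <- logvar_features(x[, smp, test_idx, drop = FALSE], model$csp)
  dv <- lda_decision(model$lda, feats)
  ifelse(dv > 0, model$lda$class_map["pos"], model$lda$class_map["neg"])
}

#' Chronological cross-validation and class-pair selection
#'
#' Splits the chronologically ordered trials of each class pair into `k`
#' contiguous folds (no shuffling; remainder trials go to the last fold) and,
#' inside every training fold, re-runs the complete calibration chain — band
#' selection, interval selection, CSP, LDA — before scoring the held-out
#' block. Returns the accuracy of every pair and the best pair, ties broken
#' by the fixed pair order left/right, left/feet, right/feet.
#'
#' @param epochs the calibration `EpochSet` in chronological trial order.
#' @param k number of folds.
#' @param pairs list of class-label pairs, in tie-break order.
#' @param n_csp CSP components per spectral end.
#' @return list with `best_pair`, `accuracy` (named per pair), `fold_acc`.
#' @export
chronological_cv <- function(epochs, k = 5L,
                             pairs = list(c("left", "right"),
                                          c("left", "feet"),
                                          c("right", "feet")),
                             n_csp = 3L) {
  stopifnot(inherits(epochs, "EpochSet"))
  cache <- calibration_cache(epochs)
  cv_with_cache(cache, k, pairs, n_csp)
}

cv_with_cache <- function(cache, k, pairs, n_csp) {
  epochs <- cache$epochs
  acc <- numeric(length(pairs))
  fold_acc <- vector("list", length(pairs))
  names(acc) <- vapply(pairs, paste, "", collapse = "_")
  for (pi in seq_along(pairs)) {
    pr <- pairs[[pi]]
    idx <- which(epochs$labels %in% pr)
    n <- length(idx)
    if (k > n) stop("more folds than trials")
    base <- n %/% k
    sizes <- rep(base, k)
    sizes[k] <- n - base * (k - 1L)   # remainder to last fold
    bounds <- cumsum(c(0L, sizes))
    fa <- numeric(k)
    for (f in seq_len(k)) {
      test_i <- idx[(bounds[f] + 1L):bounds[f + 1L]]
      train_i <- setdiff(idx, test_i)
      model <- train_pair_model(cache, train_i, pr[1L], pr[2L], n_csp = n_csp)
      pred <- predict_pair_model(model, cache, test_i)
      fa[f] <- mean(pred == epochs$labels[test_i])
    }
    fold_acc[[pi]] <- fa
    acc[pi] <- mean(fa)
  }
  best <- which.max(acc)   # which.max returns the first maximum: fixed order
  list(best_pair = pairs[[best]], accuracy = acc, fold_acc = fold_acc)
}

#' Full subject calibration
#'
#' Runs [chronological_cv()] to pick the feedback class pair, then trains the
#' final band/interval/CSP/LDA model on all calibration trials of that pair.
#'
#' @inheritParams chronological_cv
#' @return list with the final model (`band`, `interval`, `csp`, `lda`,
#'   `pair`) plus `cv` (the [chronological_cv()] result).
#' @export
calibrate_subject <- function(epochs, k = 5L, n_csp = 3L,
                              pairs = list(c("left", "right"),
                                           c("left", "feet"),
                                           c("right", "feet"))) {
  cache <- calibration_cache(epochs)
  cv <- cv_with_cache(cache, k, pairs, n_csp)
  model <- train_pair_model(cache, seq_along(epochs$labels),
                            cv$best_pair[1L], cv$best_pair[2L], n_csp = n_csp)
  model$cv <- cv
  model
}

#' Simulated online cursor feedback
#'
#' Replays the online feedback loop on held-out trials: the band-passed,
#' CSP-projected signal is scanned with a trailing window of `window` seconds
#' advanced every `step` seconds over the task period; each step's
#' log-variance features are classified with the trained LDA and the decision
#' value is added to the cursor position (a raw cumulative sum; the first
#' output occurs when the first full window is available). A trial is a hit
#' when the sign of the final cursor position matches the target side
#' (`pos`/`neg` per the LDA class map); an exactly zero final position counts
#' as a miss.
#'
#' @param feedback_raw feedback `EpochSet` (only trials of the trained pair
#'   are scored; others are dropped).
#' @param model a [calibrate_subject()] / `train_pair_model` bundle (`band`,
#'   `csp`, `lda`, `pair`).
#' @param window trailing window length, s.
#' @param step hop between classifier outputs, s.
#' @param task_span `(start, end)` s of the cursor-control period.
#' @return object of class `FeedbackResult`: `acc`, `per_trial` logical,
#'   `cursor_traces` (steps x trials), `n_steps`.
#' @export
simulate_feedback <- function(feedback_raw, model, window = 0.75,
                              step = 0.04, task_span = c(0, 4)) {
  stopifnot(inherits(feedback_raw, "EpochSet"))
  keep <- feedback_raw$labels %in% model$pair
  ep <- subset_trials(feedback_raw, keep)
  t <- epoch_times(ep)
  if (t[length(t)] < task_span[2L] - 0.5 / ep$fs)
    stop("feedback trials must span the task period")
  if (window > diff(task_span)) stop("window longer than the task period")
  filt <- bandpass(ep, model$band)
  d <- dim(filt$data)
  k <- ncol(model$csp$filters)
  wlen <- as.integer(round(window * ep$fs))
  hop <- step * ep$fs
  ## classifier output times: first at task start + window, every `step`
  out_t <- seq(task_span[1L] + window, task_span[2L] + 0.25 / ep$fs, by = step)
  ends <- vapply(out_t, function(tt) which.min(abs(t - tt)), 0L)
  n_steps <- length(ends)

  traces <- matrix(0, n_steps, d[3L])
  for (tr in seq_len(d[3L])) {
    z <- crossprod(model$csp$filters, filt$data[, , tr])  # k x samples
    cs1 <- cbind(0, t(apply(z, 1L, cumsum)))
    cs2 <- cbind(0, t(apply(z^2, 1L, cumsum)))
    dv <- numeric(n_steps)
    for (s in seq_len(n_steps)) {
      e <- ends[s]; b <- e - wlen + 1L
      sm <- cs1[, e + 1L] - cs1[, b]
      sq <- cs2[, e + 1L] - cs2[, b]
      v <- (sq - sm^2 / wlen) / (wlen - 1L)
      v[v <= 0] <- .Machine$double.xmin
      dv[s] <- sum(model$lda$weights * log(v)) + model$lda$bias
    }
    traces[, tr] <- cumsum(dv)
  }
  final <- traces[n_steps, ]
  target_pos <- ep$labels == model$lda$class_map["pos"]
  hits <- (final > 0 & target_pos) | (final < 0 & !target_pos)
  structure(list(acc = mean(hits), per_trial = hits, cursor_traces = traces,
                 n_steps = n_steps, labels = ep$labels),
            class = "FeedbackResult")
}

#' @export
print.FeedbackResult <- function(x, ...) {
  cat(sprintf("<FeedbackResult> acc = %.4f over %d trials (%d outputs/trial)\n",
              x$acc, length(x$per_trial), x$n_steps))
  invisible(x)
}

#' Binomial chance-level accuracy threshold
#'
#' The smallest accuracy whose hit count is unreachable by blind guessing at
#' the `alpha` level: the minimal `k` with
#' `P(Binomial(n, 0.5) <= k) >= 1 - alpha`, expressed as `100 * k / n`
#' percent.
#'
#' @param n_trials number of feedback trials.
#' @param alpha significance level in `(0, 1)`.
#' @return threshold accuracy in percent.
#' @export
chance_threshold <- function(n_trials, alpha = 0.05) {
  if (n_trials < 1L) stop("'n_trials' must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must be in (0, 1)")
  k <- stats::qbinom(1 - alpha, n_trials, 0.5)
  100 * k / n_trials
}
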