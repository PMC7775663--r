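# Independent brute-force oracles used to validate the package's statistics
# and estimators. Each one is written from the defining formula, not from the
# implementation it checks.

# Point-biserial correlation per channel/bin: plain cor() against the class
# indicator, no vectorization tricks.
oracle_signed_r2 <- function(power, y) {
  d <- dim(power)
  out <- matrix(0, d[1L], d[2L])
  for (ch in seq_len(d[1L]))
    for (b in seq_len(d[2L])) {
      r <- stats::cor(power[ch, b, ], y)
      out[ch, b] <- sign(r) * r^2
    }
  out
}

# CSP via the plain generalized eigenproblem solve(Sa + Sb) %*% Sa.
oracle_csp_filters <- function(Sa, Sb) {
  e <- eigen(solve(Sa + Sb) %*% Sa)
  Re(e$vectors[, order(Re(e$values), decreasing = TRUE)])
}

# Closed-form LDA direction w = S^-1 (mu1 - mu0).
oracle_lda <- function(X0, X1) {
  mu0 <- colMeans(X0); mu1 <- colMeans(X1)
  Xc <- rbind(sweep(X0, 2L, mu0), sweep(X1, 2L, mu1))
  S <- crossprod(Xc) / (nrow(Xc) - 2L)
  solve(S, mu1 - mu0)
}

# Cross-spectrum by explicit DFT loops over frequencies, series and trials,
# with the same Hann taper / demeaning / zero-padding conventions.
oracle_cross_spectrum <- function(x, fs, nfft) {
  d <- dim(x)
  win <- if (d[2L] == 1L) 1 else 0.5 - 0.5 * cos(2 * pi * (0:(d[2L] - 1L)) /
                                                   (d[2L] - 1L))
  nfreq <- nfft %/% 2L + 1L
  S <- array(0i, dim = c(nfreq, d[1L], d[1L]))
  for (tr in seq_len(d[3L])) {
    X <- matrix(0i, d[1L], nfreq)
    for (s in seq_len(d[1L])) {
      v <- (x[s, , tr] - mean(x[s, , tr])) * win
      for (k in seq_len(nfreq)) {
        n <- 0:(d[2L] - 1L)
        X[s, k] <- sum(v * exp(-2i * pi * (k - 1L) * n / nfft))
      }
    }
    for (i in seq_len(d[1L]))
      for (j in seq_len(d[1L]))
        S[, i, j] <- S[, i, j] + X[i, ] * Conj(X[j, ])
  }
  S / d[3L]
}

# Spearman rho as Pearson on average ranks, from the covariance formula.
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Partial rank correlation via the recursion formula on rank correlations.
oracle_partial_spearman <- function(x, y, z) {
  rxy <- oracle_spearman(x, y)
  rxz <- oracle_spearman(x, z)
  ryz <- oracle_spearman(y, z)
  (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
}

# Benjamini-Yekutieli step-up from the published procedure: adjusted
# p_(i) = min over j >= i of min(1, m * c(m) * p_(j) / j).
oracle_by_adjust <- function(p) {
  m <- length(p)
  cm <- sum(1 / seq_len(m))
  o <- order(p)
  ps <- p[o]
  adj <- pmin(1, m * cm * ps / seq_len(m))
  for (i in (m - 1L):1L) if (m > 1L) adj[i] <- min(adj[i], adj[i + 1L])
  out <- numeric(m)
  out[o] <- adj
  out
}

oracle_bh_adjust <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- pmin(1, m * ps / seq_len(m))
  for (i in (m - 1L):1L) if (m > 1L) adj[i] <- min(adj[i], adj[i + 1L])
  out <- numeric(m)
  out[o] <- adj
  out
}

# Exhaustive interval search: every (start, end) sample pair of length >=
# min_len, highest mean of the pointwise class contrast; ties to the
# earliest start, then the longest window.
oracle_select_interval <- function(diffmax, t, min_len) {
  fs <- 1 / mean(diff(t))
  min_samp <- as.integer(round(min_len * fs))
  n <- length(diffmax)
  tol <- 1e-9 * max(diffmax)
  best_m <- -Inf
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j - i < min_samp) next
    m <- mean(diffmax[i:j])
    if (m > best_m) best_m <- m
  }
  cand <- NULL   # tie rule: earliest start, then longest end
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j - i < min_samp) next
    if (mean(diffmax[i:j]) >= best_m - tol) {
      if (is.null(cand) || i < cand[1L] || (i == cand[1L] && j > cand[2L]))
        cand <- c(i, j)
    }
  }
  c(t[cand[1L]], t[cand[2L]])
}

# Direct binomial CDF scan for the chance threshold.
oracle_chance_threshold <- function(n, alpha) {
  for (k in 0:n)
    if (sum(stats::dbinom(0:k, n, 0.5)) >= 1 - alpha) return(100 * k / n)
  100
}
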