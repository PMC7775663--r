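# The validation layer: Spearman and partial Spearman correlation, FDR
# correction, the subject-shuffling permutation test and the 16-entry
# connectivity-vs-accuracy result table.

#' Spearman rank correlation with a t-approximation p-value
#'
#' Pearson correlation of average-ranked data (ties get average ranks); the
#' two-sided p-value uses the t approximation
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#'
#' @param x,y numeric vectors (`n >= 5`, non-constant).
#' @return object of class `CorrelationResult` with `r`, `p`, `n`.
#' @export
spearman_cor <- function(x, y) {
  n <- length(x)
  if (n != length(y)) stop("x and y must have equal length")
  if (n < 5L) stop("need n >= 5")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input has no rank correlation")
  r <- stats::cor(rank(x), rank(y))
  p <- spearman_p(r, n)
  structure(list(r = r, p = p, n = n), class = "CorrelationResult")
}

spearman_p <- function(r, n, df_loss = 2L) {
  if (abs(r) >= 1) return(.Machine$double.xmin)
  tt <- r * sqrt((n - df_loss) / (1 - r^2))
  2 * stats::pt(-abs(tt), df = n - df_loss)
}

#' @export
print.CorrelationResult <- function(x, ...) {
  cat(sprintf("<CorrelationResult> r = %.4f, p = %.4g (n = %d%s)\n",
              x$r, x$p, x$n,
              if (!is.null(x$partial) && x$partial) ", partial" else ""))
  invisible(x)
}

#' Partial Spearman correlation (regressing out a covariate)
#'
#' Rank-transforms `x`, `y` and `z`, residualizes the x- and y-ranks on the
#' z-ranks by least squares (with intercept) and returns the Pearson
#' correlation of the residuals; the p-value uses the t approximation on
#' `n - 3` degrees of freedom. A constant `z` cannot be regressed out: the
#' plain Spearman correlation is returned with a warning.
#'
#' @param x,y variables of interest.
#' @param z covariate to partial out.
#' @return `CorrelationResult` with `partial = TRUE`.
#' @export
partial_spearman <- function(x, y, z) {
  n <- length(x)
  if (n < 6L) stop("need n >= 6")
  if (stats::sd(z) == 0) {
    warning("constant covariate; returning the plain Spearman correlation")
    out <- spearman_cor(x, y)
    out$partial <- FALSE
    return(out)
  }
  rx <- rank(x); ry <- rank(y); rz <- rank(z)
  ex <- stats::lm.fit(cbind(1, rz), rx)$residuals
  ey <- stats::lm.fit(cbind(1, rz), ry)$residuals
  ## a variable fully explained by the covariate leaves only numerical dust
  r <- if (stats::sd(ex) < 1e-8 * stats::sd(rx) ||
           stats::sd(ey) < 1e-8 * stats::sd(ry)) 0
  else stats::cor(ex, ey)
  structure(list(r = r, p = spearman_p(r, n, df_loss = 3L), n = n,
                 partial = TRUE),
            class = "CorrelationResult")
}

#' False discovery rate correction
#'
#' Benjamini-Yekutieli step-up adjustment (valid under arbitrary dependence,
#' with the harmonic-sum inflation factor) by default; Benjamini-Hochberg
#' available via `method = "BH"`. Thin wrapper over [stats::p.adjust()].
#'
#' @param pvals p-values in `(0, 1]`.
#' @param method `"BY"` or `"BH"`.
#' @param q rejection threshold for the returned flags.
#' @return list with `p_adj` and logical `reject`.
#' @export
fdr_correct <- function(pvals, method = c("BY", "BH"), q = 0.05) {
  method <- match.arg(method)
  if (length(pvals) == 0L) stop("empty p-value vector")
  if (any(pvals <= 0 | pvals > 1)) stop("p-values must be in (0, 1]")
  p_adj <- stats::p.adjust(pvals, method = method)
  list(p_adj = p_adj, reject = p_adj <= q)
}

#' Subject-shuffling permutation test for a Spearman correlation
#'
#' Shuffles `y` `n_perm` times with a seeded generator, recomputes the
#' Spearman correlation against the unshuffled `x`, and compares the observed
#' correlation one-sided to the 95th percentile of the shuffled values (the
#' pass rule); a permutation p-value `(1 + #{r_perm >= r_obs}) / (n_perm +
#' 1)` is reported alongside.
#'
#' @param x,y numeric vectors.
#' @param n_perm number of shuffles.
#' @param seed integer seed.
#' @param percentile pass percentile of the null distribution.
#' @return list with `r_obs`, `perm_percentile_95`, `pass`, `p_perm`,
#'   `null_r` (the shuffled correlations).
#' @export
permutation_test <- function(x, y, n_perm = 1000L, seed = 1L,
                             percentile = 0.95) {
  n <- length(x)
  if (n < 5L) stop("need n >= 5")
  if (n_perm < 100L) warning("fewer than 100 permutations is unreliable")
  rng <- new_rng(seed)
  rx <- rank(x); ry <- rank(y)
  r_obs <- stats::cor(rx, ry)
  perm_idx <- with_rng(rng, replicate(n_perm, sample.int(n)))
  ry_perm <- matrix(ry[perm_idx], n, n_perm)
  null_r <- as.numeric(stats::cor(rx, ry_perm))
  q95 <- stats::quantile(null_r, percentile, names = FALSE)
  list(r_obs = r_obs, perm_percentile_95 = q95, pass = r_obs > q95,
       p_perm = (1 + sum(null_r >= r_obs)) / (n_perm + 1), null_r = null_r)
}

#' The 16-entry connectivity-accuracy result table
#'
#' Correlates each of the eight connectivity aggregates (scheme
#' within/across x interval post/pre x band mu/feedback) with online
#' feedback accuracy, both raw and partially regressing out the SNR of the
#' matching interval — 16 correlations in total. FDR correction is applied
#' jointly across all 16 p-values (per-column correction available via
#' `fdr_scope`), and every entry carries its subject-shuffling permutation
#' flag.
#'
#' @param cohort data frame with one row per subject: column `acc` plus
#'   `within_post_mu`, `within_post_fb`, `within_pre_mu`, `within_pre_fb`,
#'   `across_post_mu`, `across_post_fb`, `across_pre_mu`, `across_pre_fb`,
#'   `snr_post`, `snr_pre`.
#' @param n_perm permutations per entry.
#' @param seed base seed for the permutation draws.
#' @param fdr_method `"BY"` (default) or `"BH"`.
#' @param fdr_scope `"table"` (all 16 p-values jointly) or `"column"`
#'   (raw and partial corrected separately).
#' @param q FDR threshold.
#' @return data frame with columns `row` (scheme + interval), `band`, `type`
#'   (raw/partial), `r`, `p`, `p_fdr`, `reject`, `perm_pass`,
#'   `perm_percentile_95`, `p_perm`.
#' @export
build_result_table <- function(cohort, n_perm = 1000L, seed = 1L,
                               fdr_method = "BY",
                               fdr_scope = c("table", "column"), q = 0.05) {
  fdr_scope <- match.arg(fdr_scope)
  need <- c("acc", "within_post_mu", "within_post_fb", "within_pre_mu",
            "within_pre_fb", "across_post_mu", "across_post_fb",
            "across_pre_mu", "across_pre_fb", "snr_post", "snr_pre")
  miss <- setdiff(need, names(cohort))
  if (length(miss) > 0L)
    stop("cohort is missing columns: ", paste(miss, collapse = ", "))
  bad <- !stats::complete.cases(cohort[, need])
  if (any(bad)) {
    warning("excluding subjects with missing values: ",
            paste(which(bad), collapse = ", "))
    cohort <- cohort[!bad, , drop = FALSE]
  }
  rows <- c("within_post", "within_pre", "across_post", "across_pre")
  bands <- c("mu", "fb")
  out <- list(); k <- 0L
  for (rw in rows) for (bd in bands) for (type in c("raw", "partial")) {
    k <- k + 1L
    conn <- cohort[[paste0(rw, "_", bd)]]
    snr <- cohort[[paste0("snr_", sub(".*_", "", rw))]]
    cr <- if (type == "raw") spearman_cor(conn, cohort$acc)
    else partial_spearman(conn, cohort$acc, snr)
    ## permutation on the same statistic: shuffle accuracy
    pseed <- (seed %% 100000L) * 131L + k * 17L
    pt <- if (type == "raw") {
      permutation_test(conn, cohort$acc, n_perm, seed = pseed)
    } else {
      perm_partial(conn, cohort$acc, snr, n_perm, seed = pseed)
    }
    out[[k]] <- data.frame(row = rw, band = bd, type = type,
                           r = cr$r, p = cr$p,
                           perm_pass = pt$pass,
                           perm_percentile_95 = pt$perm_percentile_95,
                           p_perm = pt$p_perm)
  }
  tab <- do.call(rbind, out)
  if (fdr_scope == "table") {
    fc <- fdr_correct(tab$p, method = fdr_method, q = q)
    tab$p_fdr <- fc$p_adj; tab$reject <- fc$reject
  } else {
    for (type in c("raw", "partial")) {
      i <- tab$type == type
      fc <- fdr_correct(tab$p[i], method = fdr_method, q = q)
      tab$p_fdr[i] <- fc$p_adj; tab$reject[i] <- fc$reject
    }
  }
  tab[, c("row", "band", "type", "r", "p", "p_fdr", "reject",
          "perm_pass", "perm_percentile_95", "p_perm")]
}

# Permutation test for the partial correlation: accuracy is shuffled, the
# covariate stays attached to the connectivity values.
perm_partial <- function(x, y, z, n_perm, seed, percentile = 0.95) {
  n <- length(x)
  rng <- new_rng(seed)
  rx <- rank(x); ry <- rank(y); rz <- rank(z)
  ex <- stats::lm.fit(cbind(1, rz), rx)$residuals
  r_obs <- stats::cor(ex, stats::lm.fit(cbind(1, rz), ry)$residuals)
  perm_idx <- with_rng(rng, replicate(n_perm, sample.int(n)))
  null_r <- numeric(n_perm)
  Z <- cbind(1, rz)
  ## residualizing a permuted y on the fixed covariate
  H <- Z %*% solve(crossprod(Z), t(Z))
  R <- diag(n) - H
  ey_perm <- R %*% matrix(ry[perm_idx], n, n_perm)
  null_r <- as.numeric(stats::cor(ex, ey_perm))
  q95 <- stats::quantile(null_r, percentile, names = FALSE)
  list(r_obs = r_obs, perm_percentile_95 = q95, pass = r_obs > q95,
       p_perm = (1 + sum(null_r >= r_obs)) / (n_perm + 1))
}
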