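# Canonical 22-feature representative set, authored from the published
# definitions. All operate on the z-scored series (affine-invariant by
# construction); returns NaN on degenerate input.

histogram_mode <- function(z, n_bins) {
  edges <- seq(min(z), max(z), length.out = n_bins + 1)
  if (edges[1] == edges[n_bins + 1]) return(NaN)
  b <- findInterval(z, edges, rightmost.closed = TRUE)
  b <- pmin(pmax(b, 1L), n_bins)
  counts <- tabulate(b, n_bins)
  centres <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  mean(centres[counts == max(counts)])
}

# median relative position of points beyond successive amplitude thresholds
outlier_include_mdrmd <- function(z, sign = 1, inc = 0.01) {
  y <- sign * z
  n <- length(y)
  if (max(y) <= 0) return(NaN)
  thr <- seq(0, max(y), by = inc)
  ordpos <- order(-y)                    # positions sorted by decreasing value
  # number of points at or above each threshold, via the ascending sort
  asc <- sort(y)
  ks <- n - findInterval(thr - 1e-12, asc)
  uk <- unique(ks)
  mdr_uk <- vapply(uk, function(k) {
    if (k < 2) return(NaN)
    stats::median(ordpos[seq_len(k)]) / (n / 2) - 1
  }, numeric(1))
  mdr <- mdr_uk[match(ks, uk)]
  keep <- which(ks / n * 100 > 2)        # thresholds retaining > 2% of points
  if (!length(keep)) return(NaN)
  stats::median(mdr[seq_len(max(keep))], na.rm = TRUE)
}

# first 1/e crossing of the acf, linearly interpolated
co_f1ecac <- function(z) {
  L <- min(length(z) - 2, 400)
  a <- acf_vals(z, L)
  th <- exp(-1)
  for (k in seq_len(L)) {
    if (a[k + 1] < th) {
      return((k - 1) + (a[k] - th) / (a[k] - a[k + 1]))
    }
  }
  L
}

co_firstmin_ac <- function(z) {
  L <- min(length(z) - 2, 400)
  a <- acf_vals(z, L)[-1]
  for (k in 2:(L - 1)) if (a[k] < a[k - 1] && a[k] < a[k + 1]) return(k)
  L
}

# one-segment rectangular-window power spectral density (angular frequency)
welch_psd <- function(z) {
  n <- length(z)
  P <- Mod(stats::fft(z))^2 / (n * 2 * pi)
  k <- 0:floor(n / 2)
  list(S = P[k + 1], w = 2 * pi * k / n)
}

sp_area_5_1 <- function(z) {
  p <- welch_psd(z)
  m <- length(p$S)
  dw <- p$w[2] - p$w[1]
  sum(p$S[seq_len(ceiling(m / 5))]) * dw
}

sp_centroid <- function(z) {
  p <- welch_psd(z)
  cs <- cumsum(p$S)
  p$w[which(cs >= cs[length(cs)] / 2)[1]]
}

co_trev_1_num <- function(z) mean(diff(z)^3)

co_histogram_ami_even_2_5 <- function(z) ami_histogram(z, lag = 2, n_bins = 5)

in_ami_fmmi <- function(z) {
  L <- min(40, length(z) - 3)
  rho <- pmin(pmax(acf_vals(z, L)[-1], -1 + 1e-12), 1 - 1e-12)
  ami <- -0.5 * log(1 - rho^2)
  ami <- ami[is.finite(ami)]
  if (length(ami) < 2) return(NaN)
  for (k in seq_len(length(ami) - 1)) if (ami[k + 1] > ami[k]) return(k)
  length(ami)
}

md_pnn40 <- function(z) mean(abs(diff(z)) > 0.04)

sb_binarystats_mean_longstretch1 <- function(z) longest_run(z > mean(z))

sb_binarystats_diff_longstretch0 <- function(z) longest_run(diff(z) <= 0)

sb_motifthree_quantile_hh <- function(z) {
  q <- stats::quantile(z, c(1 / 3, 2 / 3), names = FALSE)
  s <- findInterval(z, q) + 1L
  w <- paste(s[-length(s)], s[-1])
  p <- table(w) / length(w)
  -sum(p * log(p))
}

co_embed2_dist_expfit_meandiff <- function(z) {
  n <- length(z)
  tau <- min(first_zero_ac(z), floor(n / 10))
  if (tau < 1) tau <- 1
  m <- n - tau
  if (m < 10) return(NaN)
  a <- z[seq_len(m)]; b <- z[(tau + 1):n]
  d <- sqrt(diff(a)^2 + diff(b)^2)
  mu <- mean(d)
  if (!is.finite(mu) || mu == 0) return(NaN)
  n_bins <- ceiling(log2(length(d))) + 1
  h <- graphics::hist(d, breaks = seq(min(d), max(d), length.out = n_bins + 1),
                      plot = FALSE)
  mean(abs(h$density - stats::dexp(h$mids, rate = 1 / mu)))
}

# two-regime log-log scaling fit shared by the fluctuation-analysis features:
# proportion of scales assigned to the first regime by the best split
fluct_prop_r1 <- function(logt, logf) {
  ok <- is.finite(logf)
  logt <- logt[ok]; logf <- logf[ok]
  m <- length(logt)
  if (m < 6) return(NaN)
  sse <- function(i, j) {
    tt <- logt[i:j]; ff <- logf[i:j]
    stt <- sum((tt - mean(tt))^2)
    if (stt == 0) return(sum((ff - mean(ff))^2))
    b <- sum((tt - mean(tt)) * (ff - mean(ff))) / stt
    sum((ff - mean(ff) - b * (tt - mean(tt)))^2)
  }
  splits <- 3:(m - 3)
  tot <- vapply(splits, function(k) sse(1, k) + sse(k + 1, m), numeric(1))
  splits[which.min(tot)] / m
}

fluct_scales <- function(n) {
  taus <- unique(round(exp(seq(log(5), log(floor(n / 2)), length.out = 50))))
  taus[taus >= 5]
}

# linear residual operator for windows of length tau: residuals of every
# window in one matrix product
detrended_windows <- function(y, tau) {
  nw <- floor(length(y) / tau)
  Wm <- matrix(y[seq_len(nw * tau)], nrow = tau)
  t <- seq_len(tau)
  X <- cbind(1, t)
  Wm - X %*% solve(crossprod(X), crossprod(X, Wm))
}

# order-1 detrended fluctuation analysis of the cumulative sum
sc_fluct_dfa <- function(z) {
  n <- length(z)
  if (n < 20) return(NaN)
  y <- cumsum(z - mean(z))
  taus <- fluct_scales(n)
  f <- vapply(taus, function(tau) {
    R <- detrended_windows(y, tau)
    sqrt(mean(colMeans(R^2)))
  }, numeric(1))
  fluct_prop_r1(log(taus), log(f))
}

# rescaled-range style fluctuation: range of linearly detrended cumulative sum
sc_fluct_rsrange <- function(z) {
  n <- length(z)
  if (n < 20) return(NaN)
  y <- cumsum(z - mean(z))
  taus <- fluct_scales(n)
  f <- vapply(taus, function(tau) {
    R <- t(detrended_windows(y, tau))
    hi <- R[cbind(seq_len(nrow(R)), max.col(R, ties.method = "first"))]
    lo <- R[cbind(seq_len(nrow(R)), max.col(-R, ties.method = "first"))]
    sqrt(mean((hi - lo)^2))
  }, numeric(1))
  fluct_prop_r1(log(taus), log(f))
}

sb_transition_matrix_3ac_sumdiagcov <- function(z) {
  tau <- max(1, first_zero_ac(z))
  y <- z[seq(1, length(z), by = tau)]
  if (length(y) < 5) return(NaN)
  q <- stats::quantile(y, c(1 / 3, 2 / 3), names = FALSE)
  s <- findInterval(y, q) + 1L
  M <- matrix(0, 3, 3)
  for (k in seq_len(length(s) - 1)) M[s[k], s[k + 1]] <- M[s[k], s[k + 1]] + 1
  M <- M / sum(M)
  sum(diag(stats::cov(M)))
}

# spline-detrended acf periodicity detection
pd_periodicity_wang <- function(z, th = 0.01) {
  n <- length(z)
  if (n < 30) return(NaN)
  fit <- try(stats::smooth.spline(seq_len(n), z, df = 4), silent = TRUE)
  r <- if (inherits(fit, "try-error")) z else z - stats::predict(fit, seq_len(n))$y
  if (stats::sd(r) == 0) return(0)
  L <- floor(n / 3)
  a <- acf_vals(r, L)[-1]
  trough <- -Inf
  for (k in 2:(L - 1)) {
    if (a[k] < a[k - 1] && a[k] < a[k + 1]) trough <- a[k]
    if (a[k] > a[k - 1] && a[k] > a[k + 1] &&
        is.finite(trough) && a[k] - trough >= th && a[k] > 0) return(k)
  }
  0
}
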