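# Core time-series primitives shared by the feature catalogue.

#' Autocorrelation profile of a series
#'
#' Biased sample autocorrelation (normalised by the overall mean and the total
#' count), so the profile is positive semidefinite: the Toeplitz matrix built
#' from it has no negative eigenvalues beyond rounding.
#'
#' @param x numeric vector.
#' @param max_lag largest lag to compute.
#' @return list of class `acf_profile`: `values` (lags 0..max_lag; lag 0 is 1),
#'   `estimator`. Zero-variance input yields all-`NaN` values (flagged, not an
#'   error: downstream zero-fill handles it).
#' @export
acf_profile <- function(x, max_lag) {
  n <- length(x)
  stopifnot(n > max_lag + 1)
  if (!is.finite(stats::var(x)) || stats::var(x) == 0) {
    vals <- rep(NaN, max_lag + 1)
  } else {
    vals <- drop(stats::acf(x, lag.max = max_lag, plot = FALSE,
                            demean = TRUE)$acf)
  }
  structure(list(values = vals, estimator = "biased"), class = "acf_profile")
}

acf_vals <- function(x, max_lag) acf_profile(x, max_lag)$values

# first lag with acf <= 0 (ties at exactly zero end the run); max_lag if none
first_zero_ac <- function(x, max_lag = min(floor(length(x) / 4), 100)) {
  a <- acf_vals(x, max_lag)[-1]
  k <- which(a <= 0)
  if (length(k)) k[1] else max_lag
}

zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(NaN, length(x)))
  (x - mean(x)) / s
}

longest_run <- function(b) {
  if (!any(b)) return(0)
  r <- rle(b)
  max(r$lengths[r$values])
}

# lagged Pearson correlation (unbiased pairing), used by AMI estimators
lag_cor <- function(x, k) {
  n <- length(x)
  if (n <= k + 2) return(NaN)
  stats::cor(x[seq_len(n - k)], x[(k + 1):n])
}

# Gaussian automutual information at lag k: -0.5 log(1 - rho^2)
ami_gaussian <- function(x, k) {
  r <- lag_cor(x, k)
  if (!is.finite(r)) return(NaN)
  r <- max(min(r, 1 - 1e-12), -1 + 1e-12)
  -0.5 * log(1 - r^2)
}

#' Histogram automutual information
#'
#' Discretises the series into `n_bins` equal-width bins and computes the
#' mutual information between the series and its `lag`-shifted copy from the
#' joint bin counts. Provided as the histogram alternative to the Gaussian
#' estimator used by `RM_AMI_*`.
#'
#' @param x numeric vector.
#' @param lag positive lag.
#' @param n_bins number of equal-width bins.
#' @return mutual information in nats.
#' @export
ami_histogram <- function(x, lag, n_bins = 10) {
  n <- length(x)
  if (n <= lag + 2 || stats::sd(x) == 0) return(NaN)
  edges <- seq(min(x), max(x), length.out = n_bins + 1)
  edges[1] <- edges[1] - 1e-9; edges[n_bins + 1] <- edges[n_bins + 1] + 1e-9
  b <- findInterval(x, edges, rightmost.closed = TRUE)
  b <- pmin(pmax(b, 1L), n_bins)
  j <- table(factor(b[seq_len(n - lag)], levels = 1:n_bins),
             factor(b[(lag + 1):n], levels = 1:n_bins))
  p <- j / sum(j)
  px <- rowSums(p); py <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log(p[nz] / outer(px, py)[nz]))
}

# mean-of-last-m local forecast residuals
local_mean_forecast_res <- function(x, m) {
  n <- length(x)
  if (n < m + 2) return(NaN)
  E <- stats::embed(x, m + 1)        # row j: x[j+m], x[j+m-1], ..., x[j]
  E[, 1] - rowMeans(E[, -1, drop = FALSE])
}

# linear fit over the previous w points, forecast one step ahead
local_lfit_forecast_res <- function(x, w) {
  n <- length(x)
  if (n < w + 2) return(NaN)
  E <- stats::embed(x, w + 1)
  past <- E[, (w + 1):2, drop = FALSE]   # oldest..newest, abscissa 1..w
  i <- seq_len(w)
  ibar <- mean(i); Sii <- sum((i - ibar)^2)
  slope <- past %*% (i - ibar) / Sii
  pred <- rowMeans(past) + slope * (w + 1 - ibar)
  E[, 1] - drop(pred)
}
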