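#' Intrinsic neural timescale of one series
#'
#' TR-weighted sum of the autocorrelation function over its initial positive
#' run: \eqn{\tau = TR \sum_{k=1}^{K-1} ACF(k)} where K is the first lag with
#' ACF <= 0. Lag 0 is excluded by default (including it adds a constant TR to
#' every region and cannot change any comparison; the flag exposes the
#' alternative). Returns 0 when ACF(1) <= 0 and `NaN` for zero-variance input.
#'
#' @param x numeric vector (length >= 20).
#' @param TR sampling interval, seconds.
#' @param max_lag cap on the ACF evaluation, default `min(n/4, 100)`.
#' @param include_lag0 add the lag-0 term (one TR)?
#' @return timescale in seconds.
#' @export
intrinsic_timescale <- function(x, TR, max_lag = NULL, include_lag0 = FALSE) {
  n <- length(x)
  stopifnot(n >= 20, TR > 0)
  if (!is.finite(stats::var(x)) || stats::var(x) == 0) return(NaN)
  if (is.null(max_lag)) max_lag <- min(floor(n / 4), 100)
  a <- acf_vals(x, max_lag)[-1]
  K <- which(a <= 0)
  upto <- if (length(K)) K[1] - 1 else max_lag
  tau <- TR * sum(a[seq_len(upto)])
  if (include_lag0) tau <- tau + TR
  tau
}

#' Regional timescale map of one recording
#' @param ts a `regional_ts`.
#' @param ... passed to [intrinsic_timescale()].
#' @return list of class `timescale_map`: `tau` (named, seconds), `TR`,
#'   `condition`, `species`.
#' @export
timescale_map <- function(ts, ...) {
  tau <- apply(ts$x, 1, intrinsic_timescale, TR = ts$TR, ...)
  structure(list(tau = tau, TR = ts$TR, condition = ts$condition,
                 species = ts$species),
            class = "timescale_map")
}

#' Compare regional timescales between conditions
#'
#' Nonparametric comparison across regions of per-region timescale deltas
#' (anaesthesia minus awake): Wilcoxon signed-rank when paired, rank-sum when
#' not; exact test for fewer than 6 regions.
#'
#' @param awake,anaes `timescale_map`s on the same regions and TR, or bare
#'   numeric vectors.
#' @param paired within-subject design?
#' @return list: `statistic`, `p`, `delta` (per region), `mean_delta`.
#' @export
compare_timescale_conditions <- function(awake, anaes, paired = TRUE) {
  ta <- if (inherits(awake, "timescale_map")) awake$tau else awake
  tn <- if (inherits(anaes, "timescale_map")) anaes$tau else anaes
  if (inherits(awake, "timescale_map") && inherits(anaes, "timescale_map") &&
      !isTRUE(all.equal(awake$TR, anaes$TR)))
    stop("timescale maps have different TRs")
  stopifnot(length(ta) == length(tn))
  delta <- tn - ta
  ok <- is.finite(delta)
  exact <- sum(ok) < 6
  wt <- if (all(delta[ok] == 0)) list(statistic = NA, p.value = 1)
  else if (paired)
    suppressWarnings(stats::wilcox.test(tn[ok], ta[ok], paired = TRUE, exact = exact))
  else
    suppressWarnings(stats::wilcox.test(tn[ok], ta[ok], paired = FALSE, exact = exact))
  list(statistic = unname(wt$statistic), p = wt$p.value,
       delta = delta, mean_delta = mean(delta[ok]))
}

#' Correlation between baseline timescale and its anaesthetic change
#'
#' Pearson r of the awake timescale map against the per-region delta, with
#' significance from Moran-spectral-randomisation surrogates of the delta map
#' (two-sided on |r|), so spatial autocorrelation alone cannot masquerade as
#' association.
#'
#' @param awake_tau numeric regional map (baseline timescales).
#' @param delta numeric regional map (anaesthesia minus awake).
#' @param basis a [build_moran_basis()] for the region coordinates, or the
#'   coordinate matrix itself.
#' @param n_surrogates surrogate count.
#' @param seed integer seed.
#' @return list: `r`, `p` (add-one-corrected surrogate proportion),
#'   `surrogate_r`.
#' @export
baseline_change_correlation <- function(awake_tau, delta, basis,
                                        n_surrogates = 1000L, seed = 1L) {
  stopifnot(length(awake_tau) == length(delta))
  if (is.matrix(basis)) basis <- build_moran_basis(basis)
  if (stats::sd(awake_tau) == 0 || stats::sd(delta) == 0)
    return(list(r = NaN, p = NaN, surrogate_r = numeric(0)))
  r <- stats::cor(awake_tau, delta)
  sur <- generate_surrogates(delta, basis, n_surrogates, seed)
  rs <- as.numeric(stats::cor(awake_tau, t(sur)))
  p <- (1 + sum(abs(rs) >= abs(r))) / (n_surrogates + 1)
  list(r = r, p = p, surrogate_r = rs)
}
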