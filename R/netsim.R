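#' Functional connectivity of one recording
#'
#' Zero-lag Pearson correlation between every pair of regional time-series.
#' Zero-variance regions get `NaN` rows/columns (flagged, not dropped).
#'
#' @param ts a `regional_ts` or a regions x timepoints matrix.
#' @return list of class `similarity_matrix`: `values`, `kind = "FC"`.
#' @export
functional_connectivity <- function(ts) {
  x <- if (inherits(ts, "regional_ts")) ts$x else ts
  stopifnot(ncol(x) >= 3)
  v <- apply(x, 1, stats::var)
  fc <- suppressWarnings(stats::cor(t(x)))
  fc[v == 0, ] <- NaN; fc[, v == 0] <- NaN
  diag(fc)[v > 0] <- 1
  structure(list(values = fc, kind = "FC"), class = "similarity_matrix")
}

#' Dynamical profile similarity of one recording
#'
#' Each usable feature is z-scored across regions (features constant across
#' regions or with any non-finite cell handled by dropping / pairwise
#' exclusion), then region rows of the z-scored matrix are correlated: two
#' regions are similar when they express the same dynamical fingerprint,
#' regardless of whether their activity is time-locked.
#'
#' @param fm a `feature_matrix` (>= 3 regions).
#' @return list of class `similarity_matrix`: `values`, `kind = "DPS"`,
#'   `n_features_used`.
#' @export
dynamical_profile_similarity <- function(fm) {
  vals <- fm$values
  stopifnot(nrow(vals) >= 3)
  sds <- apply(vals, 2, function(v) stats::sd(v[is.finite(v)]))
  usable <- is.finite(sds) & sds > 0
  if (sum(usable) < 3) stop("fewer than 3 usable features for DPS")
  Z <- scale(vals[, usable, drop = FALSE])
  Z[!is.finite(Z)] <- NA
  dps <- suppressWarnings(stats::cor(t(Z), use = "pairwise.complete.obs"))
  diag(dps) <- 1
  structure(list(values = dps, kind = "DPS", n_features_used = sum(usable)),
            class = "similarity_matrix")
}

#' Synchrony-dynamics coupling
#'
#' Pearson correlation between the vectorised upper triangles (diagonal
#' excluded) of an FC matrix and a DPS matrix on the same regions.
#'
#' @param fc,dps `similarity_matrix` objects (order is immaterial).
#' @return correlation coefficient (`NaN` if a triangle is constant).
#' @export
synchrony_dynamics_coupling <- function(fc, dps) {
  a <- fc$values; b <- dps$values
  stopifnot(all(dim(a) == dim(b)))
  ut <- upper.tri(a)
  av <- a[ut]; bv <- b[ut]
  ok <- is.finite(av) & is.finite(bv)
  if (sum(ok) < 3 || stats::sd(av[ok]) == 0 || stats::sd(bv[ok]) == 0) return(NaN)
  stats::cor(av[ok], bv[ok])
}

# mean off-diagonal magnitude of a similarity matrix
offdiag_mean <- function(sm, magnitude = TRUE) {
  v <- sm$values[upper.tri(sm$values)]
  v <- v[is.finite(v)]
  if (magnitude) mean(abs(v)) else mean(v)
}

#' Condition comparison of per-subject similarity matrices
#'
#' Summarises each subject's matrix as the mean off-diagonal magnitude
#' (absolute correlation by default; signed mean behind the flag) and runs a
#' Wilcoxon test across subjects between conditions.
#'
#' @param mats_a,mats_b lists of `similarity_matrix` per subject (condition A
#'   = awake, B = anaesthesia by convention).
#' @param paired within-subject design?
#' @param magnitude use |off-diagonal| before averaging?
#' @return list: `mean_a`, `mean_b`, `per_subject_a`, `per_subject_b`, `p`.
#' @export
condition_summary <- function(mats_a, mats_b, paired = TRUE, magnitude = TRUE) {
  stopifnot(length(mats_a) >= 2, length(mats_b) >= 2)
  sa <- vapply(mats_a, offdiag_mean, numeric(1), magnitude = magnitude)
  sb <- vapply(mats_b, offdiag_mean, numeric(1), magnitude = magnitude)
  p <- if (isTRUE(all.equal(sa, sb))) 1
  else suppressWarnings(stats::wilcox.test(sb, sa, paired = paired)$p.value)
  list(mean_a = mean(sa), mean_b = mean(sb),
       per_subject_a = sa, per_subject_b = sb, p = p)
}
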