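#' Moran's I spatial autocorrelation coefficient
#'
#' \deqn{I = \frac{n}{\sum_{ij} W_{ij}} \cdot
#'       \frac{x_c^\top W x_c}{x_c^\top x_c}}
#' with \eqn{x_c} the mean-centred map.
#'
#' @param map numeric regional map (non-constant).
#' @param W symmetric non-negative spatial weight matrix, zero diagonal.
#' @return Moran's I.
#' @export
morans_i <- function(map, W) {
  n <- length(map)
  stopifnot(nrow(W) == n, ncol(W) == n)
  if (stats::sd(map) == 0) stop("Moran's I is undefined for a constant map")
  xc <- map - mean(map)
  (n / sum(W)) * drop(xc %*% W %*% xc) / sum(xc^2)
}

#' Inverse Euclidean distance weight matrix
#' @param coords regions x d coordinate matrix.
#' @return symmetric matrix with `1/d_ij` off-diagonal, zero diagonal.
#' @export
inverse_distance_weights <- function(coords) {
  d <- as.matrix(stats::dist(coords))
  dup <- which(d == 0 & upper.tri(d), arr.ind = TRUE)
  if (nrow(dup) > 0)
    stop("duplicate coordinates give infinite weight: regions ",
         dup[1, 1], " and ", dup[1, 2])
  W <- 1 / d
  diag(W) <- 0
  W
}

#' Moran eigenvector basis for spectral randomisation
#'
#' Builds the inverse-distance weight matrix, double-centres it, and
#' eigendecomposes: the resulting Moran eigenvector maps are orthonormal,
#' orthogonal to the constant vector, and sorted by their Moran eigenvalue
#' (the Moran's I each attains as a map).
#'
#' @param coords regions x d coordinates (>= 3 distinct points).
#' @return list of class `moran_basis`: `W`, `vectors` (n x (n-1)),
#'   `moran_eigenvalues`.
#' @export
build_moran_basis <- function(coords) {
  n <- nrow(coords)
  stopifnot(n >= 3)
  W <- inverse_distance_weights(coords)
  H <- diag(n) - matrix(1 / n, n, n)
  M <- H %*% W %*% H
  M <- (M + t(M)) / 2
  eig <- eigen(M, symmetric = TRUE)
  # drop the constant direction (double-centring puts it in the null space)
  const_like <- which.max(abs(colMeans(eig$vectors)))
  keep <- setdiff(seq_len(n), const_like)
  keep <- keep[order(eig$values[keep], decreasing = TRUE)]
  V <- eig$vectors[, keep, drop = FALSE]
  structure(list(W = W, vectors = V,
                 moran_eigenvalues = (n / sum(W)) * eig$values[keep]),
            class = "moran_basis")
}

#' Moran-spectral-randomisation surrogate maps
#'
#' Singleton procedure: the map is expanded on the Moran eigenvector basis and
#' each coefficient's sign is independently randomised,
#' \eqn{s = \bar{x} + \sum_k \epsilon_k a_k v_k}, \eqn{\epsilon_k = \pm 1}.
#' Every surrogate preserves the map's mean, variance, and Moran's I (the
#' quadratic form is sign-invariant) while scrambling the map itself.
#'
#' @param map numeric regional map.
#' @param basis a [build_moran_basis()] matching the map's regions.
#' @param n number of surrogates.
#' @param seed integer seed.
#' @return n x regions matrix of surrogate maps.
#' @export
generate_surrogates <- function(map, basis, n, seed = 1L) {
  stopifnot(inherits(basis, "moran_basis"),
            length(map) == nrow(basis$vectors), n >= 1)
  V <- basis$vectors
  a <- drop(crossprod(V, map - mean(map)))
  eps <- with_seed(seed, matrix(sample(c(-1, 1), n * length(a), replace = TRUE),
                                length(a), n))
  t(V %*% (eps * a)) + mean(map)
}
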