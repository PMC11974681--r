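#' Z-score per species block and concatenate vertically
#'
#' Within each species, the gene-expression block X and the dynamics block Y
#' are column-wise z-scored; the z-scored blocks are then stacked so each
#' species contributes its regions as rows. Columns that are constant within
#' any block (zero variance) are dropped from all blocks of that side and
#' reported.
#'
#' @param X_blocks,Y_blocks named lists of per-species matrices (regions x
#'   genes, regions x features) sharing column panels.
#' @return list of class `pls_input`: `X`, `Y`, `block_index` (species per
#'   row), `dropped_genes`, `dropped_features`.
#' @export
zscore_concat <- function(X_blocks, Y_blocks) {
  stopifnot(length(X_blocks) == length(Y_blocks), length(X_blocks) >= 1)
  gpanel <- colnames(X_blocks[[1]]); fpanel <- colnames(Y_blocks[[1]])
  for (b in X_blocks) if (!identical(colnames(b), gpanel))
    stop("gene panels differ across species blocks")
  for (b in Y_blocks) if (!identical(colnames(b), fpanel))
    stop("feature panels differ across species blocks")
  const_cols <- function(blocks) {
    bad <- rep(FALSE, ncol(blocks[[1]]))
    for (b in blocks) bad <- bad | apply(b, 2, function(v) {
      f <- v[is.finite(v)]
      length(f) < 2 || stats::sd(f) == 0
    })
    bad
  }
  bad_g <- const_cols(X_blocks); bad_f <- const_cols(Y_blocks)
  if (any(bad_g)) warning("dropping ", sum(bad_g), " constant gene column(s)")
  if (any(bad_f)) warning("dropping ", sum(bad_f), " constant feature column(s)")
  zs <- function(b, bad) scale(b[, !bad, drop = FALSE])
  X <- do.call(rbind, lapply(X_blocks, zs, bad = bad_g))
  Y <- do.call(rbind, lapply(Y_blocks, zs, bad = bad_f))
  species <- names(X_blocks) %||% paste0("sp", seq_along(X_blocks))
  block_index <- rep(species, vapply(X_blocks, nrow, integer(1)))
  structure(list(X = X, Y = Y, block_index = block_index,
                 dropped_genes = gpanel[bad_g], dropped_features = fpanel[bad_f]),
            class = "pls_input")
}

#' PLS correlation by SVD of the cross-product
#'
#' Singular value decomposition of \eqn{Y^\top X} (dynamics-by-genes
#' cross-product of the block-z-scored matrices). Components are ordered by
#' singular value; each component's gene-salience vector is sign-flipped so
#' its largest-magnitude entry is positive. Brain scores are the projections
#' of X on the gene saliences and Y on the feature saliences; loadings are the
#' correlations of each original column with its side's brain score.
#'
#' @param input a [zscore_concat()] result.
#' @return list of class `pls_result`: `singular_values`, `gene_saliences`
#'   (genes x t), `feature_saliences` (features x t), `brain_scores_X`,
#'   `brain_scores_Y`, `cov_explained`, `gene_loadings`, `feature_loadings`.
#' @export
pls_svd <- function(input) {
  R <- crossprod(input$Y, input$X)          # features x genes
  if (all(R == 0)) stop("all-zero cross-product: no association to decompose")
  t_comp <- min(dim(R))
  sv <- svd(R, nu = t_comp, nv = t_comp)
  U <- sv$v                                  # genes x t
  V <- sv$u                                  # features x t
  for (k in seq_len(t_comp)) {
    if (U[which.max(abs(U[, k])), k] < 0) {
      U[, k] <- -U[, k]; V[, k] <- -V[, k]
    }
  }
  sx <- input$X %*% U
  sy <- input$Y %*% V
  structure(list(singular_values = sv$d[seq_len(t_comp)],
                 gene_saliences = U, feature_saliences = V,
                 brain_scores_X = sx, brain_scores_Y = sy,
                 cov_explained = sv$d[seq_len(t_comp)]^2 / sum(sv$d^2),
                 gene_loadings = suppressWarnings(stats::cor(input$X, sx)),
                 feature_loadings = suppressWarnings(stats::cor(input$Y, sy))),
            class = "pls_result")
}

#' Surrogate significance of PLS components
#'
#' For each draw, every dynamics (Y) column is replaced per-species by a
#' Moran-spectral-randomisation surrogate, re-z-scored within species,
#' concatenated, and the PLS re-run against the original X; the p-value per
#' component is the add-one-corrected proportion of null singular values at
#' least as large as the observed one. X is never randomised: the null keeps
#' the gene maps and their spatial structure fixed.
#'
#' @param input a [zscore_concat()] result.
#' @param bases named list of [build_moran_basis()] per species (matching
#'   `input$block_index` labels).
#' @param n_surrogates surrogate count (>= 1).
#' @param seed integer seed.
#' @return list: `p` (per component), `null_singular_values`
#'   (n_surrogates x t).
#' @export
pls_significance <- function(input, bases, n_surrogates = 1000L, seed = 1L) {
  if (n_surrogates < 1) stop("n_surrogates must be >= 1")
  obs <- pls_svd(input)
  t_comp <- length(obs$singular_values)
  species <- unique(input$block_index)
  rows <- lapply(species, function(sp) which(input$block_index == sp))
  names(rows) <- species
  for (sp in species) {
    if (is.null(bases[[sp]]))
      stop("no Moran basis supplied for species ", sp)
    if (nrow(bases[[sp]]$vectors) != length(rows[[sp]]))
      stop("Moran basis size mismatch for species ", sp)
  }
  # per-species spectral coefficients of every Y column, computed once
  coef <- lapply(species, function(sp) {
    blk <- input$Y[rows[[sp]], , drop = FALSE]
    mu <- colMeans(blk)
    list(mu = mu, A = crossprod(bases[[sp]]$vectors, sweep(blk, 2, mu)))
  })
  names(coef) <- species
  nulls <- matrix(NA_real_, n_surrogates, t_comp)
  X <- input$X
  with_seed(seed, {
    for (i in seq_len(n_surrogates)) {
      Yn <- input$Y
      for (sp in species) {
        A <- coef[[sp]]$A
        eps <- matrix(sample(c(-1, 1), length(A), replace = TRUE), nrow(A))
        sur <- bases[[sp]]$vectors %*% (eps * A)
        Yn[rows[[sp]], ] <- scale(sweep(sur, 2, coef[[sp]]$mu, "+"))
      }
      d <- svd(crossprod(Yn, X), nu = 0, nv = 0)$d
      nulls[i, ] <- d[seq_len(t_comp)]
    }
  })
  p <- vapply(seq_len(t_comp), function(k)
    (1 + sum(nulls[, k] >= obs$singular_values[k])) / (n_surrogates + 1),
    numeric(1))
  list(p = p, null_singular_values = nulls)
}
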