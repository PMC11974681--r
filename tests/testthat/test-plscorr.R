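mk_blocks <- function(n_regions = c(a = 20, b = 25), n_genes = 6, n_feat = 4,
                      seed = 1, link = 0) {
  set.seed(seed)
  X <- list(); Y <- list()
  for (sp in names(n_regions)) {
    n <- n_regions[[sp]]
    g <- matrix(rnorm(n * n_genes), n,
                dimnames = list(NULL, paste0("g", seq_len(n_genes))))
    f <- matrix(rnorm(n * n_feat), n,
                dimnames = list(NULL, paste0("f", seq_len(n_feat))))
    if (link > 0) {
      shared <- rnorm(n)
      g[, 1] <- g[, 1] + link * shared
      f[, 1] <- f[, 1] + link * shared
    }
    X[[sp]] <- g; Y[[sp]] <- f
  }
  list(X = X, Y = Y)
}

test_that("zscore_concat z-scores within blocks and drops constants", {
  bl <- mk_blocks()
  inp <- zscore_concat(bl$X, bl$Y)
  expect_equal(nrow(inp$X), 45)
  expect_equal(inp$block_index, c(rep("a", 20), rep("b", 25)))
  # per-block columns have mean 0, sd 1
  for (sp in c("a", "b")) {
    blk <- inp$X[inp$block_index == sp, ]
    expect_equal(colMeans(blk), setNames(rep(0, 6), colnames(blk)),
                 tolerance = 1e-12)
    expect_equal(apply(blk, 2, sd), setNames(rep(1, 6), colnames(blk)),
                 tolerance = 1e-12)
  }
  # constant gene in one block dropped everywhere, with warning
  bl2 <- bl; bl2$X$a[, 3] <- 5
  expect_warning(inp2 <- zscore_concat(bl2$X, bl2$Y), "constant gene")
  expect_equal(inp2$dropped_genes, "g3")
  expect_equal(ncol(inp2$X), 5)
  # mismatched panels rejected
  bl3 <- bl; colnames(bl3$X$b)[1] <- "zzz"
  expect_error(zscore_concat(bl3$X, bl3$Y), "panels differ")
})

test_that("pls_svd satisfies the SVD identities", {
  inp <- zscore_concat(mk_blocks(seed = 2)$X, mk_blocks(seed = 2)$Y)
  res <- pls_svd(inp)
  t_comp <- length(res$singular_values)
  expect_equal(t_comp, 4)
  # cov_explained sums to one
  expect_equal(sum(res$cov_explained), 1, tolerance = 1e-10)
  # singular values non-increasing and non-negative
  expect_true(all(diff(res$singular_values) <= 1e-9))
  expect_true(all(res$singular_values >= 0))
  # saliences orthonormal
  expect_equal(crossprod(res$gene_saliences)[1:t_comp, 1:t_comp],
               diag(t_comp), tolerance = 1e-10)
  expect_equal(crossprod(res$feature_saliences), diag(t_comp), tolerance = 1e-10)
  # reconstruction: R = V diag(d) U'
  R <- crossprod(inp$Y, inp$X)
  expect_equal(res$feature_saliences %*% diag(res$singular_values) %*%
                 t(res$gene_saliences), unname(R), tolerance = 1e-8)
  # sign convention: largest-|entry| gene salience positive
  for (k in 1:t_comp) {
    u <- res$gene_saliences[, k]
    expect_gt(u[which.max(abs(u))], 0)
  }
  # brain scores are projections; loadings are score correlations
  expect_equal(res$brain_scores_X, inp$X %*% res$gene_saliences)
  expect_equal(res$gene_loadings[, 1], cor(inp$X, res$brain_scores_X[, 1])[, 1])
})

test_that("pls recovers a planted rank-1 cross-block association", {
  set.seed(3)
  n <- 60
  axis <- rnorm(n)
  X <- matrix(rnorm(n * 8), n, dimnames = list(NULL, paste0("g", 1:8)))
  Y <- matrix(rnorm(n * 5), n, dimnames = list(NULL, paste0("f", 1:5)))
  wg <- rnorm(8); wf <- rnorm(5)
  X <- X + 5 * axis %*% t(wg)            # SNR 5 planted structure
  Y <- Y + 5 * axis %*% t(wf)
  inp <- zscore_concat(list(s = X), list(s = Y))
  res <- pls_svd(inp)
  expect_gt(res$cov_explained[1], 0.9)
  expect_gt(abs(cor(res$brain_scores_X[, 1], axis)), 0.9)
  expect_gt(abs(cor(res$brain_scores_X[, 1], res$brain_scores_Y[, 1])), 0.9)
})

test_that("pls significance is calibrated and powered", {
  co <- make_region_coords(30, seed = 4)
  basis <- build_moran_basis(co)

  # planted shared axis: LV1 significant
  set.seed(5)
  axis <- dynphen:::gaussian_field(co, 0.5, seed = 6)[, 1]
  X <- matrix(rnorm(30 * 6), 30, dimnames = list(NULL, paste0("g", 1:6)))
  Y <- matrix(rnorm(30 * 4), 30, dimnames = list(NULL, paste0("f", 1:4)))
  X[, 1:3] <- X[, 1:3] + 3 * axis
  Y[, 1:2] <- Y[, 1:2] + 3 * axis
  inp <- zscore_concat(list(s = X), list(s = Y))
  sig <- pls_significance(inp, list(s = basis), n_surrogates = 200, seed = 7)
  expect_lt(sig$p[1], 0.05)
  expect_equal(dim(sig$null_singular_values), c(200, 4))

  # null: independent maps, p-values approximately uniform for LV1
  ps <- vapply(1:30, function(i) {
    set.seed(100 + i)
    Xn <- matrix(rnorm(30 * 5), 30, dimnames = list(NULL, paste0("g", 1:5)))
    Yn <- dynphen:::gaussian_field(co, 0.5, n_fields = 3, seed = 200 + i)
    colnames(Yn) <- paste0("f", 1:3)
    inpn <- zscore_concat(list(s = Xn), list(s = Yn))
    pls_significance(inpn, list(s = basis), n_surrogates = 100,
                     seed = 300 + i)$p[1]
  }, numeric(1))
  expect_gt(mean(ps < 0.05), 0)   # sanity: not all 1
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)

  # missing or mismatched basis rejected
  expect_error(pls_significance(inp, list(), n_surrogates = 10), "no Moran basis")
  wrong <- build_moran_basis(make_region_coords(10, seed = 8))
  expect_error(pls_significance(inp, list(s = wrong), n_surrogates = 10),
               "mismatch")
})
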