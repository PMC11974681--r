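test_that("connectome generation honours density, symmetry and connectivity", {
  full <- make_connectome(4, density = 1, seed = 1)
  expect_equal(sum(full$C[upper.tri(full$C)] > 0), 6)  # complete graph

  cn <- make_connectome(100, density = 0.27, seed = 1)
  expect_gte(cn$density, 0.25)
  expect_lte(cn$density, 0.29)
  expect_equal(cn$C, t(cn$C))
  expect_true(all(diag(cn$C) == 0))
  expect_true(all(cn$C >= 0))

  a <- make_connectome(30, density = 0.3, seed = 1)
  b <- make_connectome(30, density = 0.3, seed = 2)
  expect_false(identical(a$C, b$C))
  for (cn2 in list(a, b)) {
    expect_equal(cn2$C, t(cn2$C))
    expect_true(dynphen:::bfs_connected(cn2$C))
  }
  # determinism
  expect_identical(make_connectome(30, density = 0.3, seed = 1)$C, a$C)
})

test_that("edge probability decays with distance", {
  cn <- make_connectome(80, density = 0.2, seed = 3)
  d <- as.matrix(dist(cn$coords))
  ut <- upper.tri(d)
  present <- cn$C[ut] > 0
  expect_lt(mean(d[ut][present]), mean(d[ut][!present]))
})

test_that("regional time series hit the target lag-1 autocorrelation", {
  blocks <- default_species_blocks(n_regions = c(15L), n_subjects = 2L,
                                   n_contrasts = c(1L))
  sp0 <- study_spec(blocks, n_timepoints = 5000, phi_awake = 0, kappa_awake = 0,
                    phi_anaes = 0.4, gradient_amp = 0, seed = 3)
  ts0 <- make_regional_timeseries(sp0, "human", "awake1")
  ac1 <- apply(ts0$x, 1, function(v) cor(v[-1], v[-length(v)]))
  expect_true(all(abs(ac1) < 0.05))      # white noise

  sp <- study_spec(blocks, n_timepoints = 2000, gradient_amp = 0, seed = 3)
  for (cond in c("awake1", "anaes1")) {
    phi <- if (cond == "awake1") sp$phi_awake else sp$phi_anaes
    tsx <- make_regional_timeseries(sp, "human", cond)
    ac1 <- apply(tsx$x, 1, function(v) cor(v[-1], v[-length(v)]))
    expect_true(all(abs(ac1 - phi) < 0.1))
  }
  expect_error(make_regional_timeseries(sp, "human", "nonsense"), "condition")
})

test_that("inter-regional coupling rises with kappa and a nonstationary phi is rejected", {
  blocks <- default_species_blocks(n_regions = c(20L), n_subjects = 2L,
                                   n_contrasts = c(1L))
  sp <- study_spec(blocks, n_timepoints = 3000, gradient_amp = 0, seed = 5)
  aw <- make_regional_timeseries(sp, "human", "awake1")   # kappa 0.6
  an <- make_regional_timeseries(sp, "human", "anaes1")   # kappa 0.1
  m <- function(ts) {
    fc <- cor(t(ts$x))
    mean(abs(fc[upper.tri(fc)]))
  }
  expect_gt(m(aw), m(an))
  expect_error(study_spec(blocks, phi_awake = 1), "\\[0, 1\\)")
})

test_that("recordings are deterministic given the seed", {
  sp <- small_spec()
  a <- make_regional_timeseries(sp, "human", "awake1", subject = 2)
  b <- make_regional_timeseries(sp, "human", "awake1", subject = 2)
  expect_identical(a$x, b$x)
  c2 <- make_regional_timeseries(sp, "human", "awake1", subject = 3)
  expect_false(identical(a$x, c2$x))
})

test_that("expression maps are sigmoid-normalised with controllable spatial structure", {
  co <- make_region_coords(60, 11)
  basis <- build_moran_basis(co)

  rough <- make_expression_maps(co, 30, smoothness = 0, seed = 2)$expression
  expect_true(all(rough >= 0 & rough <= 1))
  mi <- apply(rough, 2, morans_i, W = basis$W)
  # iid noise: Moran's I centred on its null mean -1/(n-1)
  expect_lt(abs(mean(mi) - (-1 / 59)), 3 * sd(mi) / sqrt(30))

  smooth <- make_expression_maps(co, 30, smoothness = 0.5, seed = 2)$expression
  mi_s <- apply(smooth, 2, morans_i, W = basis$W)
  # null mean/sd of Moran's I for this W via random maps
  null_i <- replicate(200, morans_i(rnorm(60), basis$W))
  expect_gt(mean(mi_s > mean(null_i) + 2 * sd(null_i)), 0.9)

  planted <- make_expression_maps(co, 10, planted_map = basis$vectors[, 1],
                                  planted_gene_weights = rep(1, 10),
                                  smoothness = 0.5, noise_sd = 0.01, seed = 3)
  r <- abs(cor(planted$expression, basis$vectors[, 1]))
  expect_true(all(r >= 0.9))
})

test_that("a full study assembles 14 contrasts with truth and is deterministic", {
  spec <- small_spec(n_timepoints = 120L)
  study <- make_multispecies_study(spec)
  expect_equal(nrow(study$manifest), 14)
  expect_equal(dynphen:::n_contrasts_total(spec), 14)
  expect_equal(length(study$recordings$human$awake1), 10)  # subjects
  expect_true(all(study$expression$human$expression >= 0))
  expect_setequal(names(study$truth$feature_signs),
                  names(planted_feature_signs()))

  study2 <- make_multispecies_study(spec)
  expect_identical(study$recordings$macaque$anaes3[[2]]$x,
                   study2$recordings$macaque$anaes3[[2]]$x)

  spec4 <- study_spec(default_species_blocks(n_regions = c(12L, 10L, 9L, 9L))[1:4],
                      n_timepoints = 120L, seed = 1)
  expect_equal(nrow(make_multispecies_study(spec4)$manifest), 13)
})

test_that("study round-trips through its on-disk form", {
  blocks <- default_species_blocks(n_regions = c(12L, 10L), n_subjects = 2L,
                                   n_contrasts = c(1L, 1L))
  study <- make_multispecies_study(study_spec(blocks, n_timepoints = 60L, seed = 2))
  dir <- tempfile()
  write_study(study, dir)
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  # 2 species x 2 subjects x 2 conditions
  expect_equal(length(man$recordings), 2 * 2 * 2)
  ts <- read_recording_tsv(file.path(dir, man$recordings[[1]]$path %||% man$recordings[[1]][["path"]]),
                           TR = man$TR)
  orig <- study$recordings[[man$recordings[[1]]$species]][[man$recordings[[1]]$condition]][[1]]
  expect_equal(unname(ts$x), unname(orig$x), tolerance = 1e-12)
  C <- read_matrix_tsv(file.path(dir, "connectome.tsv"))
  expect_equal(unname(C), unname(study$connectome$C), tolerance = 1e-12)
})
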