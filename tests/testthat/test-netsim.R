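test_that("functional connectivity is a correlation matrix with NaN flags", {
  set.seed(1)
  x <- matrix(rnorm(5 * 100), 5)
  fc <- functional_connectivity(as_recording(x))
  expect_equal(unname(fc$values), cor(t(x)))
  expect_equal(diag(fc$values), setNames(rep(1, 5), rownames(fc$values)))
  expect_equal(fc$kind, "FC")

  # perfectly shared signal: off-diagonal 1
  y <- rbind(x[1, ], 2 * x[1, ] + 3)
  fc2 <- functional_connectivity(y)
  expect_equal(fc2$values[1, 2], 1)

  # zero-variance region: NaN row/col, rest intact
  z <- rbind(x[1:3, ], 0)
  fc3 <- functional_connectivity(z)
  expect_true(all(is.nan(fc3$values[4, ])))
  expect_equal(fc3$values[1:3, 1:3], cor(t(x[1:3, ])))
})

test_that("dynamical profile similarity correlates regional fingerprints", {
  set.seed(2)
  v <- matrix(rnorm(6 * 10), 6)
  # region 2 duplicates region 1's profile; region 3 is its mirror
  v[2, ] <- v[1, ]
  v[3, ] <- -v[1, ]
  fm <- as_feature_matrix(v)
  dps <- dynamical_profile_similarity(fm)
  # z-scoring across regions preserves equality of profiles
  expect_gt(dps$values[1, 2], 0.99)
  expect_equal(dim(dps$values), c(6, 6))
  expect_equal(dps$kind, "DPS")
  expect_equal(dps$n_features_used, 10)

  # constant feature is dropped, not poisonous
  v2 <- cbind(v, 7)
  dps2 <- dynamical_profile_similarity(as_feature_matrix(v2))
  expect_equal(dps2$n_features_used, 10)
  expect_equal(dps2$values, dps$values)

  # non-finite cells excluded pairwise
  v3 <- v; v3[4, 5] <- NaN
  dps3 <- dynamical_profile_similarity(as_feature_matrix(v3))
  expect_true(all(is.finite(dps3$values)))

  expect_error(dynamical_profile_similarity(as_feature_matrix(matrix(1, 3, 5))),
               "usable")
})

test_that("coupling is the upper-triangle correlation of FC and DPS", {
  set.seed(3)
  A <- cor(matrix(rnorm(100), 20))  # 5x5 correlation-like
  mk <- function(M, kind) structure(list(values = M, kind = kind),
                                    class = "similarity_matrix")
  expect_equal(synchrony_dynamics_coupling(mk(A, "FC"), mk(A, "DPS")), 1)
  expect_equal(synchrony_dynamics_coupling(mk(A, "FC"), mk(-A, "DPS")), -1)
  ut <- upper.tri(A)
  B <- A; B[ut] <- rnorm(sum(ut)); B <- B + t(B) - diag(diag(B))
  expect_equal(synchrony_dynamics_coupling(mk(A, "FC"), mk(B, "DPS")),
               cor(A[ut], B[ut]))
  expect_true(is.nan(synchrony_dynamics_coupling(mk(diag(5), "FC"),
                                                 mk(diag(5) * 0 + diag(5), "DPS"))))
})

test_that("condition summaries detect the planted synchrony drop", {
  mk_fc <- function(level, seed) {
    set.seed(seed)
    n <- 10
    shared <- rnorm(200)
    x <- sqrt(level) * matrix(shared, n, 200, byrow = TRUE) +
      sqrt(1 - level) * matrix(rnorm(n * 200), n)
    functional_connectivity(x)
  }
  hi <- lapply(1:6, function(s) mk_fc(0.5, s))
  lo <- lapply(1:6, function(s) mk_fc(0.05, 100 + s))
  cs <- condition_summary(hi, lo, paired = TRUE)
  expect_gt(cs$mean_a, cs$mean_b)
  expect_lt(cs$p, 0.05)
  expect_length(cs$per_subject_a, 6)

  # identical lists: p = 1
  expect_equal(condition_summary(hi, hi)$p, 1)
})

test_that("anaesthesia lowers FC, DPS and their coupling in the generator", {
  # one replicate of the direction test at desk scale (the acceptance suite
  # repeats this across seeds)
  blocks <- default_species_blocks(n_regions = c(25L), n_subjects = 3L,
                                   n_contrasts = c(1L))
  spec <- study_spec(blocks, n_timepoints = 300L, seed = 42)
  cat <- feature_catalog(reduced = TRUE)
  per_cond <- function(cond) {
    lapply(1:3, function(s) {
      ts <- make_regional_timeseries(spec, "human", cond, subject = s)
      fm <- extract_feature_matrix(ts, cat)
      list(fc = functional_connectivity(ts),
           dps = dynamical_profile_similarity(fm))
    })
  }
  aw <- per_cond("awake1"); an <- per_cond("anaes1")
  m_fc <- function(l) mean(vapply(l, function(e) dynphen:::offdiag_mean(e$fc),
                                  numeric(1)))
  m_dps <- function(l) mean(vapply(l, function(e) dynphen:::offdiag_mean(e$dps),
                                   numeric(1)))
  m_cpl <- function(l) mean(vapply(l, function(e)
    synchrony_dynamics_coupling(e$fc, e$dps), numeric(1)))
  expect_gt(m_fc(aw), m_fc(an))
  expect_gt(m_dps(aw), m_dps(an))
  expect_gt(m_cpl(aw), m_cpl(an))
})
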