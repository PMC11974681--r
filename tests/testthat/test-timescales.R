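test_that("intrinsic timescale matches closed forms", {
  # alternating series: ACF(1) < 0, so the sum is empty and tau = 0
  alt <- rep(c(1, -1), 50)
  expect_equal(intrinsic_timescale(alt, TR = 1), 0)
  expect_equal(intrinsic_timescale(alt, TR = 1, include_lag0 = TRUE), 1)

  # exact linearity in TR
  x <- ar1_series(500, 0.6, seed = 1)
  expect_equal(intrinsic_timescale(x, TR = 2.5),
               2.5 * intrinsic_timescale(x, TR = 1))

  expect_true(is.nan(intrinsic_timescale(rep(4, 100), TR = 1)))
  expect_error(intrinsic_timescale(rnorm(10), TR = 1), "n >= 20")

  # AR(1): tau ~ sum_{k>=1} phi^k = phi/(1-phi) = 4 at phi = 0.8
  taus <- vapply(1:9, function(s)
    intrinsic_timescale(ar1_series(10000, 0.8, seed = s), TR = 1), numeric(1))
  expect_lt(abs(median(taus) - 4) / 4, 0.15)

  # monotone in phi
  med_tau <- function(phi) median(vapply(1:7, function(s)
    intrinsic_timescale(ar1_series(5000, phi, seed = 10 + s), TR = 1),
    numeric(1)))
  ts_by_phi <- vapply(c(0.2, 0.4, 0.6, 0.8), med_tau, numeric(1))
  expect_true(all(diff(ts_by_phi) > 0))

  # white noise: tau near zero
  wn <- vapply(1:9, function(s) {
    set.seed(100 + s); intrinsic_timescale(rnorm(2000), TR = 1)
  }, numeric(1))
  expect_lt(median(wn), 2)
})

test_that("timescale maps act per region and carry metadata", {
  set.seed(2)
  x <- rbind(ar1_series(400, 0.8, seed = 3), rnorm(400))
  ts <- as_recording(x, TR = 2)
  tm <- timescale_map(ts)
  expect_length(tm$tau, 2)
  expect_equal(unname(tm$tau[1]), intrinsic_timescale(x[1, ], TR = 2))
  expect_gt(tm$tau[1], tm$tau[2])
  expect_equal(tm$TR, 2)
})

test_that("condition comparison is a Wilcoxon test with sensible edge cases", {
  # identical maps: p = 1, zero delta
  v <- runif(20, 1, 3)
  cmp0 <- compare_timescale_conditions(v, v)
  expect_equal(cmp0$p, 1)
  expect_equal(cmp0$mean_delta, 0)

  # uniform planted drop: detected, with the right sign
  set.seed(4)
  ta <- runif(30, 2, 4)
  tn <- ta - 1 + rnorm(30, sd = 0.05)
  cmp <- compare_timescale_conditions(ta, tn, paired = TRUE)
  expect_lt(cmp$p, 1e-4)
  expect_lt(cmp$mean_delta, 0)
  # matches the direct call
  ref <- wilcox.test(tn, ta, paired = TRUE, exact = FALSE)
  expect_equal(cmp$p, ref$p.value)

  # unpaired variant matches rank-sum
  cmp_u <- compare_timescale_conditions(ta, tn, paired = FALSE)
  expect_equal(cmp_u$p,
               suppressWarnings(wilcox.test(tn, ta, exact = FALSE)$p.value))

  # null case: no systematic significance
  set.seed(5)
  ps <- replicate(40, {
    a <- runif(15, 1, 3); b <- a + rnorm(15, sd = 0.3)
    compare_timescale_conditions(a, b)$p
  })
  expect_gt(mean(ps > 0.05), 0.8)

  expect_error(compare_timescale_conditions(1:5, 1:6), "length")
})

test_that("baseline-change correlation uses a spatial null correctly", {
  co <- make_region_coords(40, seed = 6)
  basis <- build_moran_basis(co)

  # delta exactly proportional to baseline: r = -1, smallest possible p
  set.seed(7)
  ta <- runif(40, 1, 4)
  bc <- baseline_change_correlation(ta, -0.5 * ta, basis,
                                    n_surrogates = 200, seed = 1)
  expect_equal(bc$r, -1)
  expect_lte(bc$p, 2 / 201 + 1e-12)

  # accepts raw coordinates in place of a prebuilt basis
  bc2 <- baseline_change_correlation(ta, -0.5 * ta, co,
                                     n_surrogates = 200, seed = 1)
  expect_equal(bc2$r, bc$r)
  expect_equal(bc2$p, bc$p)

  # planted smooth association: negative r, significant under the Moran null
  g <- dynphen:::gaussian_field(co, 0.5, seed = 8)[, 1]
  ta_s <- 2 + g
  delta <- -0.6 * g + rnorm(40, sd = 0.15)
  bc3 <- baseline_change_correlation(ta_s, delta, basis,
                                     n_surrogates = 500, seed = 2)
  expect_lt(bc3$r, -0.5)
  expect_lt(bc3$p, 0.05)

  # independent smooth maps: the null p-values stay roughly uniform
  set.seed(9)
  ps <- vapply(1:40, function(i) {
    f <- dynphen:::gaussian_field(co, 0.5, n_fields = 2, seed = 100 + i)
    baseline_change_correlation(f[, 1], f[, 2], basis,
                                n_surrogates = 200, seed = 200 + i)$p
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)

  # degenerate input flagged, not raised
  expect_true(is.nan(baseline_change_correlation(rep(1, 40), ta, basis)$r))
})
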