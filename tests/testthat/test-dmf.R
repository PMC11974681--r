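# deterministic single-region fixed point solved independently by root-finding
isolated_fixed_point <- function(p, J) {
  sI_of_sE <- function(sE) {
    uniroot(function(s)
      p$tau_GABA * dmf_transfer(p$W_I * p$I0 + p$J_NMDA * sE - s,
                                p$g_I, p$I_thr_I, p$d_I) - s,
      c(0, 1), tol = 1e-14)$root
  }
  dsE <- function(sE) {
    IE <- p$W_E * p$I0 + p$w_plus * p$J_NMDA * sE - J * sI_of_sE(sE)
    rE <- dmf_transfer(IE, p$g_E, p$I_thr_E, p$d_E)
    -sE / p$tau_NMDA + (1 - sE) * p$gamma_kin * rE
  }
  uniroot(dsE, c(1e-6, 1 - 1e-6), tol = 1e-12)$root
}

test_that("transfer function has the canonical shape", {
  p <- dmf_params()
  # removable singularity evaluates to 1/d
  expect_equal(dmf_transfer(p$I_thr_E, p$g_E, p$I_thr_E, p$d_E), 1 / p$d_E)
  expect_equal(dmf_transfer(0.403, 310, 0.403, 0.16), 6.25)
  # continuous through the singularity
  eps <- 1e-7
  expect_equal(dmf_transfer(p$I_thr_E + eps, p$g_E, p$I_thr_E, p$d_E),
               1 / p$d_E, tolerance = 1e-2)
  # monotone increasing, ~linear far above threshold, ~0 far below
  I <- seq(0, 1, by = 0.01)
  F <- dmf_transfer(I, p$g_E, p$I_thr_E, p$d_E)
  expect_true(all(diff(F) > 0))
  expect_equal(dmf_transfer(1, p$g_E, p$I_thr_E, p$d_E),
               p$g_E * (1 - p$I_thr_E), tolerance = 1e-6)
  expect_lt(dmf_transfer(0, p$g_E, p$I_thr_E, p$d_E), 1e-6)
})

test_that("noise-free simulation settles on the bisection fixed point", {
  p <- dmf_params(sigma = 0)
  C1 <- matrix(0, 1, 1)
  st <- dmf_simulate(p, C1, duration = 20, burn_in = 5, J_FIC = 1,
                     init = list(sE = 0.15, sI = 0.15))
  expect_equal(drop(st$sE_final), isolated_fixed_point(p, 1), tolerance = 1e-6)

  # a different J moves the fixed point, still matched
  st2 <- dmf_simulate(p, C1, duration = 20, burn_in = 5, J_FIC = 1.5,
                      init = list(sE = 0.15, sI = 0.15))
  expect_equal(drop(st2$sE_final), isolated_fixed_point(p, 1.5),
               tolerance = 1e-6)
  expect_true(drop(st2$sE_final) < drop(st$sE_final))  # more inhibition
  expect_equal(st$clamp_frac, 0)
})

test_that("simulation bookkeeping: shapes, determinism, seeds", {
  cn <- make_connectome(8, density = 0.5, seed = 1)
  p <- dmf_params()
  st <- dmf_simulate(p, cn, duration = 4, burn_in = 1, seed = 2,
                     record_dt = 0.05)
  expect_equal(nrow(st$S_E), 8)
  expect_equal(ncol(st$S_E), round(4 / 0.05))
  expect_length(st$rE_mean, 8)
  expect_true(all(st$S_E >= 0 & st$S_E <= 1))
  st_b <- dmf_simulate(p, cn, duration = 4, burn_in = 1, seed = 2,
                       record_dt = 0.05)
  expect_identical(st$S_E, st_b$S_E)
  st_c <- dmf_simulate(p, cn, duration = 4, burn_in = 1, seed = 3,
                       record_dt = 0.05)
  expect_false(identical(st$S_E, st_c$S_E))
  expect_error(dmf_simulate(p, matrix(c(0, 1, 0, 0), 2), duration = 1),
               "all.equal")
})

test_that("analytic FIC puts a noise-free network at the target rate", {
  cn <- make_connectome(12, density = 0.4, seed = 4)
  p <- dmf_params(G = 1.8, sigma = 0)
  a <- dynphen:::analytic_fic(p, cn$C, target = 3)
  st <- dmf_simulate(p, cn, duration = 10, burn_in = 5, J_FIC = a$J,
                     init = list(sE = a$sE, sI = a$sI))
  expect_lt(max(abs(st$rE_mean - 3)), 0.2)
})

test_that("stochastic FIC calibration reaches the 3 Hz band", {
  cn <- make_connectome(15, density = 0.3, seed = 5)
  p <- dmf_params(G = 1.8)
  cal <- fic_calibrate(p, cn, seed = 6)
  expect_true(cal$converged)
  expect_lt(max(abs(cal$rates - 3)), 0.5)
  expect_true(all(cal$J_FIC > 0))
  # warm-started production run stays in the band
  st <- dmf_simulate(p, cn, duration = 30, seed = 7, J_FIC = cal$J_FIC,
                     init = cal$state)
  expect_lt(abs(mean(st$rE_mean) - 3), 0.5)
})

test_that("uncoupled regions are uncorrelated at G = 0", {
  cn <- make_connectome(12, density = 0.4, seed = 9)
  p <- dmf_params(G = 0)
  cal <- fic_calibrate(p, cn, seed = 9)
  st <- dmf_simulate(p, cn, duration = 240, seed = 10, J_FIC = cal$J_FIC,
                     init = cal$state)
  bold <- bold_from_state(st, band = NULL)
  fc <- functional_connectivity(bold)$values
  expect_lt(mean(abs(fc[upper.tri(fc)])), 0.12)
})

test_that("BOLD generation samples at TR and filters into the band", {
  cn <- make_connectome(6, density = 0.6, seed = 11)
  p <- dmf_params()
  cal <- fic_calibrate(p, cn, seed = 12)
  st <- dmf_simulate(p, cn, duration = 200, seed = 13, J_FIC = cal$J_FIC,
                     init = cal$state)
  raw <- bold_from_state(st, band = NULL, haemo_burn = 20)
  expect_equal(raw$TR, p$TR)
  expect_equal(nrow(raw$x), 6)
  expect_equal(ncol(raw$x), floor(200 / p$TR) - round(20 / p$TR))

  filt <- bold_from_state(st, haemo_burn = 20)
  expect_equal(dim(filt$x), dim(raw$x))
  # band-pass contract as achieved by a zero-phase order-2 Butterworth:
  # less than 1% of power beyond one octave outside the band edges
  v <- filt$x[1, ]
  n <- length(v)
  freq <- (0:(n - 1)) / (n * p$TR)
  pw <- Mod(fft(v))^2
  half <- freq <= 1 / (2 * p$TR)
  far_out <- half & (freq < 0.004 | freq > 0.18)
  expect_lt(sum(pw[far_out]) / sum(pw[half]), 0.01)
  # and most power inside the nominal band itself
  in_band <- half & freq >= 0.008 & freq <= 0.09
  expect_gt(sum(pw[in_band]) / sum(pw[half]), 0.85)
})

test_that("FCD has the expected window geometry and value range", {
  set.seed(14)
  x <- matrix(rnorm(10 * 90), 10)
  f <- fcd(x, window = 30, step = 3)
  expect_equal(dim(f$values), c(21, 21))   # (90 - 30)/3 + 1
  expect_equal(diag(f$values), rep(1, 21))
  v <- fcd_values(f)
  expect_length(v, 21 * 20 / 2)
  expect_true(all(v >= -1 & v <= 1))
  expect_equal(f$values, t(f$values))
  expect_error(fcd(x[, 1:20], window = 30), "Tn >= window")

  # constant window flagged as NaN
  x2 <- x; x2[, 1:30] <- 0
  f2 <- fcd(x2, window = 30, step = 30)
  expect_true(all(is.nan(f2$values[1, -1])))
})

test_that("parameter validation rejects unusable settings", {
  expect_error(dmf_params(dt = 0.002), "dt")
  expect_error(dmf_params(TR = 0), "TR")
  p <- dmf_params()
  expect_s3_class(p, "dmf_params")
  expect_equal(p$G, 1.8)
})
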