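#' Dynamic mean-field parameters
#'
#' Canonical fixed parameters of the reduced excitatory-inhibitory mean-field
#' model with feedback inhibition control: each region holds one excitatory
#' (NMDA) and one inhibitory (GABA) population; regions are coupled through
#' the connectome scaled by the global coupling G.
#'
#' Units: currents nA, gains 1/nC, time constants s, rates Hz.
#'
#' @param G global coupling (dimensionless), default the tuned value 1.8.
#' @param W_E,W_I external-input scalings.
#' @param I0 external current (nA).
#' @param w_plus local recurrent excitation weight.
#' @param J_NMDA excitatory coupling (nA).
#' @param g_E,g_I transfer-function gains (1/nC).
#' @param I_thr_E,I_thr_I threshold currents (nA).
#' @param d_E,d_I transfer-function shape constants (s).
#' @param tau_NMDA,tau_GABA gating time constants (s).
#' @param gamma_kin kinetic rate of excitatory gating.
#' @param sigma noise amplitude (nA).
#' @param dt Euler-Maruyama step (s), at most 1 ms.
#' @param TR BOLD sampling interval (s).
#' @return list of class `dmf_params`.
#' @export
dmf_params <- function(G = 1.8, W_E = 1.0, W_I = 0.7, I0 = 0.382,
                       w_plus = 1.4, J_NMDA = 0.15,
                       g_E = 310, g_I = 615,
                       I_thr_E = 0.403, I_thr_I = 0.288,
                       d_E = 0.16, d_I = 0.087,
                       tau_NMDA = 0.1, tau_GABA = 0.01,
                       gamma_kin = 0.641, sigma = 0.01,
                       dt = 0.001, TR = 0.72) {
  stopifnot(dt <= 0.001 + 1e-12, dt > 0, tau_NMDA > 0, tau_GABA > 0,
            sigma >= 0, TR > 0)
  structure(as.list(environment()), class = "dmf_params")
}

#' Transfer function (F-I curve) of the model's populations
#' @param I input current (nA), vectorised.
#' @param g gain (1/nC).
#' @param I_thr threshold current (nA).
#' @param d shape constant (s).
#' @return firing rate (Hz); the removable singularity at `I = I_thr`
#'   evaluates to `1/d`.
#' @export
dmf_transfer <- function(I, g, I_thr, d) {
  x <- g * (I - I_thr)
  e <- d * x
  out <- ifelse(abs(e) < 1e-9, 1 / d,
                ifelse(e < -50, 0, ifelse(e > 50, x, x / (1 - exp(-e)))))
  as.numeric(out)
}

#' Simulate the dynamic mean-field model
#'
#' Euler-Maruyama integration of the coupled gating equations; the burn-in is
#' discarded, the excitatory gating variable is recorded at `record_dt`, and
#' time-averaged firing rates are returned.
#'
#' @param params a [dmf_params()].
#' @param C a `connectome` or bare symmetric matrix.
#' @param duration simulated seconds after burn-in.
#' @param burn_in discarded initial seconds.
#' @param seed integer seed.
#' @param J_FIC per-region inhibitory weights; default 1 everywhere (run
#'   [fic_calibrate()] first for rate-targeted simulations).
#' @param record_dt recording interval for the gating trajectory (s).
#' @param init optional warm-start state, a list with `sE` and `sI` (e.g. the
#'   `state` returned by [fic_calibrate()]); default starts both gating
#'   variables at 0.001. Warm-starting matters because the coupled network
#'   can be bistable: calibrated weights target the active branch.
#' @return list of class `dmf_state`: `S_E` (regions x samples), `rE_mean`,
#'   `rI_mean`, `clamp_frac`, `record_dt`, `params`.
#' @export
dmf_simulate <- function(params, C, duration, burn_in = 10, seed = 1L,
                         J_FIC = NULL, record_dt = 0.01, init = NULL) {
  Cm <- if (inherits(C, "connectome")) C$C else C
  stopifnot(inherits(params, "dmf_params"), duration > 0,
            isTRUE(all.equal(Cm, t(Cm), tolerance = 1e-12)), all(Cm >= 0))
  n <- nrow(Cm)
  J <- J_FIC %||% rep(1, n)
  stopifnot(length(J) == n)
  sE0 <- init$sE %||% rep(0.001, n)
  sI0 <- init$sI %||% rep(0.001, n)
  out <- with_seed(seed,
    .dmf_simulate_cpp(Cm, params$G, J, params, duration, burn_in,
                      params$dt, record_dt, sE0, sI0))
  out$params <- params
  out$J_FIC <- J
  class(out) <- "dmf_state"
  out
}

# Analytic feedback-inhibition weights for a uniform rate-target state: with
# every excitatory population at the gating value implied by the target rate,
# the required J follows in closed form from the current-balance equations
# (the inhibitory gating solving its own scalar fixed point).
analytic_fic <- function(params, Cm, target = 3) {
  p <- params
  sE <- p$gamma_kin * target * p$tau_NMDA / (1 + p$gamma_kin * target * p$tau_NMDA)
  # invert the excitatory F-I curve at the target rate
  IE <- stats::uniroot(function(I) dmf_transfer(I, p$g_E, p$I_thr_E, p$d_E) - target,
                       c(p$I_thr_E - 1, p$I_thr_E + 1), tol = 1e-12)$root
  sI <- stats::uniroot(function(s)
    p$tau_GABA * dmf_transfer(p$W_I * p$I0 + p$J_NMDA * sE - s,
                              p$g_I, p$I_thr_I, p$d_I) - s,
    c(0, 1), tol = 1e-12)$root
  J <- (p$W_E * p$I0 + p$w_plus * p$J_NMDA * sE +
          p$G * p$J_NMDA * rowSums(Cm) * sE - IE) / sI
  n <- nrow(Cm)
  list(J = J, sE = rep(sE, n), sI = rep(sI, n))
}

#' Calibrate feedback inhibition control
#'
#' Tunes each region's inhibitory weight J_FIC so its time-averaged
#' excitatory firing rate sits at the target (approximately 3 Hz).
#' Initialised at the analytic solution of the noise-free current-balance
#' equations for a uniform target state, then refined over stochastic
#' epochs with damped multiplicative corrections on the log-rate error.
#' Epochs are long enough (burn plus read) that the rate estimates are not
#' biased by the post-correction transient, the per-step correction factor
#' is tightly bounded (more tightly downward, since lowering inhibition is
#' the direction that can tip the bistable network onto its saturated
#' branch), and whenever an epoch's worst rate deviation clearly grows
#' instead of shrinking the calibrator backtracks to the best weights seen
#' so far and halves the step bound. Non-convergence returns the partial
#' result with a diagnostic flag rather than failing silently.
#'
#' @param params a [dmf_params()].
#' @param C connectome.
#' @param target target excitatory rate (Hz).
#' @param tol convergence band (Hz) around the target, per region.
#' @param max_iter epoch cap.
#' @param epoch,burn epoch simulated/discarded seconds.
#' @param gain correction gain on the log-rate error.
#' @param seed integer seed.
#' @return list: `J_FIC`, `converged`, `iterations`, `rates` (final per-region
#'   means), `history` (max |deviation| per iteration).
#' @export
fic_calibrate <- function(params, C, target = 3, tol = 0.5, max_iter = 40L,
                          epoch = 12, burn = 4, gain = 0.15, seed = 1L) {
  Cm <- if (inherits(C, "connectome")) C$C else C
  a <- analytic_fic(params, Cm, target)
  J <- pmax(a$J, 0.001)
  state <- list(sE = a$sE, sI = a$sI)
  history <- numeric(0)
  rates <- rep(NA_real_, nrow(Cm))
  # Tight log-scale step bound (~factor 1.10). The coupled network is
  # bistable near realistic coupling: a few percent of extra disinhibition
  # can tip it from the ~3 Hz branch onto a saturated high-rate attractor,
  # so downward J moves are clamped harder than upward ones.
  step <- 0.10
  best <- list(J = J, state = state, rates = rates, err = Inf)
  for (it in seq_len(max_iter)) {
    st <- dmf_simulate(params, Cm, duration = epoch, burn_in = burn,
                       seed = child_seed(seed, "fic", it), J_FIC = J,
                       record_dt = 0.1, init = state)
    rates <- st$rE_mean
    err_max <- max(abs(rates - target))
    history <- c(history, err_max)
    state <- list(sE = st$sE_final, sI = st$sI_final)
    if (err_max <= tol)
      return(list(J_FIC = J, converged = TRUE, iterations = it,
                  rates = rates, history = history, state = state))
    if (err_max < best$err + 0.1) {
      if (err_max < best$err)
        best <- list(J = J, state = state, rates = rates, err = err_max)
    } else {
      # clearly worse than the best epoch (beyond read noise): back off to
      # it and take a smaller step
      step <- step / 2
      state <- best$state
      rates <- best$rates
    }
    fac <- exp(pmin(pmax(gain * log((rates + 0.1) / (target + 0.1)),
                         -0.6 * step), step))
    J <- pmax(best$J * fac, 0.001)
  }
  warning("FIC calibration did not converge within ", max_iter,
          " iterations (best max rate deviation ",
          round(best$err, 2), " Hz)")
  list(J_FIC = best$J, converged = FALSE, iterations = max_iter,
       rates = best$rates, history = history, state = best$state)
}

#' BOLD signal from a simulated gating trajectory
#'
#' The excitatory gating variable drives balloon-windkessel haemodynamic
#' state variables (vasodilatory signal, inflow, venous volume,
#' deoxyhaemoglobin) with canonical constants (rate constants 0.65 and 0.41
#' /s, transit 0.98 s, stiffness 0.32, resting oxygen extraction 0.34,
#' V0 = 0.02); the BOLD output is sampled at TR and band-pass filtered with a
#' zero-phase second-order Butterworth filter.
#'
#' @param state a `dmf_state`.
#' @param TR output sampling interval (s); defaults to the params' TR.
#' @param band band-pass edges in Hz (set `NULL` to skip filtering).
#' @param haemo_burn seconds of BOLD discarded before filtering, covering the
#'   haemodynamic onset transient (a shared transient would otherwise
#'   dominate every regional signal).
#' @return a `regional_ts` of BOLD signals.
#' @export
bold_from_state <- function(state, TR = NULL, band = c(0.008, 0.09),
                            haemo_burn = 20) {
  TR <- TR %||% state$params$TR
  dt <- state$record_dt
  if (abs(TR / dt - round(TR / dt)) > 1e-6) {
    offset <- TR - round(TR / dt) * dt
    message("TR is not a multiple of the recording step; nearest-sample ",
            "decimation with offset ", signif(offset, 3), " s")
  }
  bold <- .balloon_bold_cpp(state$S_E, dt, TR,
                            0.65, 0.41, 0.98, 0.32, 0.34, 0.02)
  drop_n <- min(round(haemo_burn / TR), ncol(bold) - 3)
  if (drop_n > 0) bold <- bold[, -seq_len(drop_n), drop = FALSE]
  if (!is.null(band)) {
    nyq <- 1 / (2 * TR)
    hi <- min(band[2], 0.99 * nyq)
    bf <- signal::butter(2, c(band[1], hi) / nyq, type = "pass")
    tt <- seq_len(ncol(bold))
    bold <- t(apply(bold, 1, function(x) {
      # detrend before filtering: edge transients from the DC level and slow
      # drift would otherwise swamp the (much smaller) in-band signal
      signal::filtfilt(bf, stats::lm.fit(cbind(1, tt), x)$residuals)
    }))
  }
  rownames(bold) <- sprintf("R%03d", seq_len(nrow(bold)))
  structure(list(x = bold, TR = TR, species = "model",
                 condition = sprintf("G=%g", state$params$G), subject = 1L,
                 region_labels = rownames(bold)),
            class = "regional_ts")
}

#' Functional connectivity dynamics (FCD) matrix
#'
#' Sliding-window FC patterns (window and step in TRs); entry (i, j) is the
#' Pearson correlation between the vectorised upper triangles of windows i
#' and j.
#'
#' @param ts a `regional_ts` (or matrix).
#' @param window window length in TRs.
#' @param step window increment in TRs.
#' @return list of class `fcd_matrix`: `values` (windows x windows, unit
#'   diagonal), `window`, `step`.
#' @export
fcd <- function(ts, window = 30L, step = 3L) {
  x <- if (inherits(ts, "regional_ts")) ts$x else ts
  Tn <- ncol(x)
  stopifnot(Tn >= window)
  starts <- seq(1, Tn - window + 1, by = step)
  ut <- upper.tri(diag(nrow(x)))
  pats <- vapply(starts, function(s) {
    fc <- suppressWarnings(stats::cor(t(x[, s:(s + window - 1)])))
    fc[ut]
  }, numeric(sum(ut)))
  vals <- suppressWarnings(stats::cor(pats))
  bad <- apply(pats, 2, function(v) stats::sd(v[is.finite(v)]) == 0 ||
                 any(!is.finite(v)))
  vals[bad, ] <- NaN; vals[, bad] <- NaN
  diag(vals) <- 1
  structure(list(values = vals, window = as.integer(window),
                 step = as.integer(step)), class = "fcd_matrix")
}

#' Upper-triangle FCD values (the model-fitting sample)
#' @param f an `fcd_matrix`.
#' @return numeric vector.
#' @export
fcd_values <- function(f) {
  v <- f$values[upper.tri(f$values)]
  v[is.finite(v)]
}

#' Fit the global coupling G to an empirical FCD sample
#'
#' Grid search: for each candidate G the model is (optionally re-)calibrated,
#' simulated `n_sims` times, and the pooled upper-triangular FCD values are
#' compared with the empirical sample by the two-sample Kolmogorov-Smirnov
#' statistic; the argmin wins, ties going to the smaller G.
#'
#' @param empirical_fcd_values numeric sample of FCD values.
#' @param params a [dmf_params()] (its G is ignored during the sweep).
#' @param C connectome.
#' @param G_grid candidate couplings.
#' @param n_sims simulations per candidate.
#' @param duration simulated seconds per run.
#' @param seed integer seed.
#' @param recalibrate re-run FIC at each G (otherwise calibrate once at the
#'   grid midpoint and hold J fixed).
#' @param window,step FCD parameters in TRs.
#' @return list: `best_G`, `ks` (named per-G KS statistics).
#' @export
fit_G <- function(empirical_fcd_values, params, C, G_grid, n_sims = 2L,
                  duration = 180, seed = 1L, recalibrate = TRUE,
                  window = 30L, step = 3L) {
  stopifnot(length(G_grid) >= 1)
  G_grid <- sort(G_grid)
  cal_shared <- NULL
  if (!recalibrate) {
    pmid <- params; pmid$G <- stats::median(G_grid)
    cal_shared <- fic_calibrate(pmid, C, seed = child_seed(seed, "fitG-fic"))
  }
  ks <- vapply(G_grid, function(G) {
    p <- params; p$G <- G
    cal <- cal_shared %||% fic_calibrate(p, C, seed = child_seed(seed, "fic", G))
    sim_vals <- unlist(lapply(seq_len(n_sims), function(s) {
      st <- dmf_simulate(p, C, duration = duration,
                         seed = child_seed(seed, "sim", G, s),
                         J_FIC = cal$J_FIC, init = cal$state)
      fcd_values(fcd(bold_from_state(st), window, step))
    }))
    suppressWarnings(stats::ks.test(sim_vals, empirical_fcd_values)$statistic)
  }, numeric(1))
  names(ks) <- G_grid
  list(best_G = G_grid[which.min(ks)], ks = ks)
}

#' Global-coupling sweep of the model's dynamical signature
#'
#' For each G, simulates `n_sims` BOLD runs, extracts the reduced feature set
#' per region (brain-wide mean per feature, non-finite values ignored),
#' reports deltas against the reference G, counts features whose delta sign
#' matches the supplied anaesthesia signs, and tracks synchrony-dynamics
#' coupling (FC vs DPS) per G.
#'
#' @param params a [dmf_params()].
#' @param C connectome.
#' @param G_values sweep grid (must contain `reference_G`).
#' @param reference_G the tuned model's coupling.
#' @param n_sims simulations per G.
#' @param catalog feature catalogue (reduced set by default).
#' @param consistent_signs named vector of +1/-1 anaesthesia directions for a
#'   subset of catalogue features.
#' @param duration simulated seconds per run.
#' @param seed integer seed.
#' @param recalibrate re-run FIC at each G; if `FALSE`, hold the reference-G
#'   calibration fixed.
#' @param band band-pass passed to [bold_from_state()] (`NULL` = unfiltered).
#' @return list: `feature_means` (G x features), `deltas`, `match_count`
#'   (per G), `coupling` (mean FC-DPS coupling per G), `G_values`.
#' @export
g_sweep <- function(params, C, G_values = seq(1.4, 2.1, by = 0.1),
                    reference_G = 1.8, n_sims = 40L,
                    catalog = feature_catalog(reduced = TRUE),
                    consistent_signs = NULL, duration = 180, seed = 1L,
                    recalibrate = TRUE, band = c(0.008, 0.09)) {
  stopifnot(any(abs(G_values - reference_G) < 1e-9))
  cal_ref <- NULL
  if (!recalibrate) {
    pref <- params; pref$G <- reference_G
    cal_ref <- fic_calibrate(pref, C, seed = child_seed(seed, "ref-fic"))
  }
  fmeans <- matrix(NA_real_, length(G_values), nrow(catalog),
                   dimnames = list(sprintf("%.2f", G_values), catalog$feature_id))
  coupling <- numeric(length(G_values))
  for (gi in seq_along(G_values)) {
    p <- params; p$G <- G_values[gi]
    cal <- cal_ref %||% fic_calibrate(p, C, seed = child_seed(seed, "fic", gi))
    per_sim <- matrix(NA_real_, n_sims, nrow(catalog))
    cpl <- numeric(n_sims)
    for (s in seq_len(n_sims)) {
      st <- dmf_simulate(p, C, duration = duration,
                         seed = child_seed(seed, "sweep", gi, s),
                         J_FIC = cal$J_FIC, init = cal$state)
      bold <- bold_from_state(st, band = band)
      fm <- extract_feature_matrix(bold, catalog)
      per_sim[s, ] <- apply(fm$values, 2, function(v) mean(v[is.finite(v)]))
      cpl[s] <- synchrony_dynamics_coupling(functional_connectivity(bold),
                                            dynamical_profile_similarity(fm))
    }
    fmeans[gi, ] <- colMeans(per_sim, na.rm = TRUE)
    coupling[gi] <- mean(cpl[is.finite(cpl)])
  }
  ref_row <- which(abs(G_values - reference_G) < 1e-9)[1]
  deltas <- sweep(fmeans, 2, fmeans[ref_row, ])
  match_count <- rep(NA_integer_, length(G_values))
  if (!is.null(consistent_signs)) {
    ids <- intersect(names(consistent_signs), colnames(deltas))
    match_count <- apply(deltas[, ids, drop = FALSE], 1, function(d)
      sum(sign(d) == sign(consistent_signs[ids])))
  }
  list(feature_means = fmeans, deltas = deltas, match_count = match_count,
       coupling = coupling, G_values = G_values)
}
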