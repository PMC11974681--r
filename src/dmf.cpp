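// Dynamic mean-field integrator (excitatory/inhibitory neural masses coupled
// by a weighted connectome) and balloon-windkessel haemodynamics.
// Euler-Maruyama; noise drawn from R's RNG so R-side seeding governs runs.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// transfer function F(I) = x / (1 - exp(-d x)) with x = g (I - Ithr);
// removable singularity at x = 0 has the limit 1/d
static inline double fcurve(double x, double d) {
  double e = d * x;
  if (std::fabs(e) < 1e-9) return 1.0 / d;
  if (e < -50.0) return 0.0;
  if (e > 50.0) return x;
  return x / (1.0 - std::exp(-e));
}

// [[Rcpp::export(name = ".dmf_simulate_cpp")]]
List dmf_simulate_cpp(const arma::mat& C, double G, const arma::vec& J,
                      List params, double duration, double burn_in,
                      double dt, double record_dt,
                      const arma::vec& sE0, const arma::vec& sI0) {
  const double W_E = params["W_E"], W_I = params["W_I"], I0 = params["I0"];
  const double w_plus = params["w_plus"], J_NMDA = params["J_NMDA"];
  const double g_E = params["g_E"], g_I = params["g_I"];
  const double I_thr_E = params["I_thr_E"], I_thr_I = params["I_thr_I"];
  const double d_E = params["d_E"], d_I = params["d_I"];
  const double tau_NMDA = params["tau_NMDA"], tau_GABA = params["tau_GABA"];
  const double gamma_kin = params["gamma_kin"], sigma = params["sigma"];

  const int n = C.n_rows;
  const long nsteps = (long) std::llround((duration + burn_in) / dt);
  const long burn_steps = (long) std::llround(burn_in / dt);
  const long rec_every = std::max(1L, (long) std::llround(record_dt / dt));
  const long nrec = (nsteps - burn_steps) / rec_every;

  arma::vec sE(sE0), sI(sI0);
  arma::vec rE(n), rI(n), IE(n), II(n), rE_sum(n, arma::fill::zeros),
      rI_sum(n, arma::fill::zeros);
  arma::mat SE_rec(n, nrec);
  const double sqdt = std::sqrt(dt);
  long clamped = 0, rec_i = 0, rate_steps = 0;
  RNGScope scope;

  for (long t = 0; t < nsteps; ++t) {
    IE = W_E * I0 + w_plus * J_NMDA * sE + G * J_NMDA * (C * sE) - J % sI;
    II = W_I * I0 + J_NMDA * sE - sI;
    for (int i = 0; i < n; ++i) {
      rE(i) = fcurve(g_E * (IE(i) - I_thr_E), d_E);
      rI(i) = fcurve(g_I * (II(i) - I_thr_I), d_I);
    }
    for (int i = 0; i < n; ++i) {
      sE(i) += dt * (-sE(i) / tau_NMDA + (1.0 - sE(i)) * gamma_kin * rE(i)) +
               sqdt * sigma * norm_rand();
      sI(i) += dt * (-sI(i) / tau_GABA + rI(i)) + sqdt * sigma * norm_rand();
      if (sE(i) < 0.0) { sE(i) = 0.0; ++clamped; }
      else if (sE(i) > 1.0) { sE(i) = 1.0; ++clamped; }
      if (sI(i) < 0.0) { sI(i) = 0.0; ++clamped; }
      else if (sI(i) > 1.0) { sI(i) = 1.0; ++clamped; }
    }
    if (!sE.is_finite() || !sI.is_finite())
      stop("non-finite state at integration step " + std::to_string(t));
    if (t >= burn_steps) {
      rE_sum += rE; rI_sum += rI; ++rate_steps;
      if ((t - burn_steps) % rec_every == 0 && rec_i < nrec)
        SE_rec.col(rec_i++) = sE;
    }
  }
  return List::create(
      _["S_E"] = SE_rec.cols(0, rec_i - 1),
      _["rE_mean"] = rE_sum / std::max(1L, rate_steps),
      _["rI_mean"] = rI_sum / std::max(1L, rate_steps),
      _["clamp_frac"] = (double) clamped / ((double) nsteps * 2 * n),
      _["record_dt"] = rec_every * dt,
      _["sE_final"] = sE, _["sI_final"] = sI);
}

// Balloon-windkessel haemodynamics driven by the excitatory gating variable.
// Canonical constants; BOLD sampled at TR by nearest-sample decimation.
// [[Rcpp::export(name = ".balloon_bold_cpp")]]
arma::mat balloon_bold_cpp(const arma::mat& SE, double dt, double TR,
                           double kappa, double gam, double tau,
                           double alpha, double rho, double V0) {
  const int n = SE.n_rows;
  const long m = SE.n_cols;
  arma::vec s(n, arma::fill::zeros), f(n, arma::fill::ones),
      v(n, arma::fill::ones), q(n, arma::fill::ones);
  const long out_every = std::max(1L, (long) std::llround(TR / dt));
  const long nout = m / out_every;
  arma::mat bold(n, nout);
  const double k1 = 7.0 * rho, k2 = 2.0, k3 = 2.0 * rho - 0.2;
  const double ialpha = 1.0 / alpha;
  long oi = 0;
  for (long t = 0; t < m; ++t) {
    arma::vec z = SE.col(t);
    for (int i = 0; i < n; ++i) {
      double Ef = 1.0 - std::pow(1.0 - rho, 1.0 / f(i));
      double ds = z(i) - kappa * s(i) - gam * (f(i) - 1.0);
      double df = s(i);
      double dv = (f(i) - std::pow(v(i), ialpha)) / tau;
      double dq = (f(i) * Ef / rho -
                   std::pow(v(i), ialpha) * q(i) / v(i)) / tau;
      s(i) += dt * ds; f(i) += dt * df;
      v(i) += dt * dv; q(i) += dt * dq;
      if (f(i) < 1e-6) f(i) = 1e-6;
      if (v(i) < 1e-6) v(i) = 1e-6;
      if (q(i) < 1e-6) q(i) = 1e-6;
    }
    if ((t + 1) % out_every == 0 && oi < nout) {
      for (int i = 0; i < n; ++i)
        bold(i, oi) = V0 * (k1 * (1.0 - q(i)) + k2 * (1.0 - q(i) / v(i)) +
                            k3 * (1.0 - v(i)));
      ++oi;
    }
  }
  return bold.cols(0, oi - 1);
}
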