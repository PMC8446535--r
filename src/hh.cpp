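#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Canonical squid-axon gating rates (per ms, mV), shifted so rest ~ -65 mV.
static inline double alpha_m(double v) {
  double x = v + 40.0;
  if (std::fabs(x) < 1e-7) return 1.0;
  return 0.1 * x / (1.0 - std::exp(-x / 10.0));
}
static inline double beta_m(double v) { return 4.0 * std::exp(-(v + 65.0) / 18.0); }
static inline double alpha_h(double v) { return 0.07 * std::exp(-(v + 65.0) / 20.0); }
static inline double beta_h(double v) { return 1.0 / (1.0 + std::exp(-(v + 35.0) / 10.0)); }
static inline double alpha_n(double v) {
  double x = v + 55.0;
  if (std::fabs(x) < 1e-7) return 0.1;
  return 0.01 * x / (1.0 - std::exp(-x / 10.0));
}
static inline double beta_n(double v) { return 0.125 * std::exp(-(v + 65.0) / 80.0); }

// High-voltage-activated Kv3 gate: alpha = a * (-(V + b)) / (exp(-(V+b)/c) - 1)
static inline double alpha_kv3(double v, double a, double b, double c) {
  double x = v + b;
  if (std::fabs(x) < 1e-7) return a * c;
  return a * (-x) / (std::exp(-x / c) - 1.0);
}
static inline double beta_kv3(double v, double d, double vref, double vscale) {
  return d * std::exp((v - vref) / vscale);
}

static inline double clamp01(double g) {
  if (g < 0.0) return 0.0;
  if (g > 1.0) return 1.0;
  return g;
}

// Forward-Euler integration of the point-membrane model. `stim` is the
// injected current density (uA/cm^2) sampled at dt (ms). Returns the
// voltage and gate trajectories; `err_step` is the 1-based step index of a
// numerical blow-up (|V| > 200 mV), or -1 when integration completed.
// [[Rcpp::export]]
List hh_integrate(NumericVector stim, double dt,
                  double cm, double g_na, double g_k, double g_l, double g_kv3,
                  double e_na, double e_k, double e_l, double e_kv3,
                  double kv3_a, double kv3_b, double kv3_c, double kv3_d,
                  double kv3_vref, double kv3_vscale,
                  double v0, double m0, double h0, double n0, double nk0) {
  const int N = stim.size();
  NumericVector v(N), m(N), h(N), n(N), nk(N);
  double vi = v0, mi = m0, hi = h0, ni = n0, nki = nk0;
  int err_step = -1;
  for (int i = 0; i < N; ++i) {
    v[i] = vi; m[i] = mi; h[i] = hi; n[i] = ni; nk[i] = nki;
    double i_na  = g_na * mi * mi * mi * hi * (vi - e_na);
    double i_k   = g_k * ni * ni * ni * ni * (vi - e_k);
    double i_l   = g_l * (vi - e_l);
    double i_kv3 = g_kv3 * nki * nki * nki * nki * (vi - e_kv3);
    double vnext = vi + dt / cm * (-i_na - i_k - i_l - i_kv3 + stim[i]);
    mi  = clamp01(mi + dt * (alpha_m(vi) * (1.0 - mi) - beta_m(vi) * mi));
    hi  = clamp01(hi + dt * (alpha_h(vi) * (1.0 - hi) - beta_h(vi) * hi));
    ni  = clamp01(ni + dt * (alpha_n(vi) * (1.0 - ni) - beta_n(vi) * ni));
    nki = clamp01(nki + dt * (alpha_kv3(vi, kv3_a, kv3_b, kv3_c) * (1.0 - nki)
                              - beta_kv3(vi, kv3_d, kv3_vref, kv3_vscale) * nki));
    vi = vnext;
    if (!std::isfinite(vi) || std::fabs(vi) > 200.0) {
      err_step = i + 1;
      break;
    }
  }
  return List::create(_["v"] = v, _["m"] = m, _["h"] = h, _["n"] = n,
                      _["n_kv3"] = nk, _["err_step"] = err_step);
}
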