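#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// x / (exp(x) - 1) with the removable singularity at 0
static inline double vtrap(double x) {
  if (std::fabs(x) < 1e-6) return 1.0 - x / 2.0;
  return x / (std::expm1(x));
}

// Traub-Miles gating rates (ms^-1); v is the potential relative to VT (mV)
static inline void gate_rates(double v, double *am, double *bm, double *ah,
                              double *bh, double *an, double *bn) {
  *am = 0.32 * 4.0 * vtrap((13.0 - v) / 4.0);
  *bm = 0.28 * 5.0 * vtrap((v - 40.0) / 5.0);
  *ah = 0.128 * std::exp((17.0 - v) / 18.0);
  *bh = 4.0 / (1.0 + std::exp((40.0 - v) / 5.0));
  *an = 0.032 * 5.0 * vtrap((15.0 - v) / 5.0);
  *bn = 0.5 * std::exp((10.0 - v) / 40.0);
}

// Conductance-based Hodgkin-Huxley network with current-based drive and
// Tsodyks-Markram style short-term plasticity on the presynaptic side.
// Gating variables use exponential-Euler updates from lookup tables; the
// membrane equation is integrated with exponential Euler (exact for the
// locally linearised conductance sum), which remains stable through the
// stiff sodium upstroke at dt = 0.05 ms.
// [[Rcpp::export]]
List hh_simulate_cpp(int n_exc, int n_inh,
                     IntegerVector syn_ptr, IntegerVector syn_post,
                     NumericVector syn_w,
                     NumericVector v0, NumericVector gl_i,
                     NumericVector I_scale, NumericVector I_steps,
                     double dt, List params) {
  const int n = n_exc + n_inh;
  const int n_steps = I_steps.size();
  const double cm = params["cm"];       // pF
  const double el = params["el"];       // mV
  const double gna = params["gna"];
  const double ena = params["ena"];
  const double gk = params["gk"];
  const double ek = params["ek"];
  const double ee = params["ee"];
  const double ei = params["ei"];
  const double vt = params["vt"];
  const double tau_e = params["tau_e"]; // ms
  const double tau_i = params["tau_i"];
  const double wf = params["omega_f"];  // ms^-1
  const double wd = params["omega_d"];  // ms^-1
  const double U = params["u_rest"];

  if (v0.size() != n) stop("v0 length must equal the number of neurons");
  if (gl_i.size() != n) stop("gl_i length must equal the number of neurons");
  if (I_scale.size() != n) stop("I_scale length must equal the number of neurons");

  // gating lookup tables over V in [-120, 60] mV at 0.05 mV resolution
  const double v_lo = -120.0, v_step = 0.05;
  const int n_tab = (int)((60.0 - v_lo) / v_step) + 1;
  std::vector<double> minf(n_tab), em(n_tab), hinf(n_tab), eh(n_tab),
      ninf(n_tab), en(n_tab);
  for (int i = 0; i < n_tab; ++i) {
    double v = (v_lo + i * v_step) - vt;
    double am, bm, ah, bh, an, bn;
    gate_rates(v, &am, &bm, &ah, &bh, &an, &bn);
    minf[i] = am / (am + bm); em[i] = std::exp(-dt * (am + bm));
    hinf[i] = ah / (ah + bh); eh[i] = std::exp(-dt * (ah + bh));
    ninf[i] = an / (an + bn); en[i] = std::exp(-dt * (an + bn));
  }

  std::vector<double> V(v0.begin(), v0.end());
  std::vector<double> m(n), h(n), nn(n), ge(n, 0.0), gi(n, 0.0);
  std::vector<double> u(n, 0.0), x(n, 1.0), last_spk(n, -1e9);
  std::vector<char> firing(n, 0);
  for (int i = 0; i < n; ++i) {
    double v = V[i] - vt;
    double am, bm, ah, bh, an, bn;
    gate_rates(v, &am, &bm, &ah, &bh, &an, &bn);
    m[i] = am / (am + bm);
    h[i] = ah / (ah + bh);
    nn[i] = an / (an + bn);
  }

  const double de = std::exp(-dt / tau_e);
  const double di = std::exp(-dt / tau_i);
  std::vector<double> sp_t;
  std::vector<int> sp_id;
  std::vector<int> spk_now;
  spk_now.reserve(64);
  double u_max = 0.0, x_min = 1.0;

  for (int s = 0; s < n_steps; ++s) {
    const double I = I_steps[s];
    const double t_ms = s * dt;
    spk_now.clear();
    for (int i = 0; i < n; ++i) {
      ge[i] *= de;
      gi[i] *= di;
      int ti = (int)((V[i] - v_lo) / v_step + 0.5);
      if (ti < 0) ti = 0;
      if (ti >= n_tab) ti = n_tab - 1;
      m[i] = minf[ti] + (m[i] - minf[ti]) * em[ti];
      h[i] = hinf[ti] + (h[i] - hinf[ti]) * eh[ti];
      nn[i] = ninf[ti] + (nn[i] - ninf[ti]) * en[ti];
      const double gna_eff = gna * m[i] * m[i] * m[i] * h[i];
      const double n2 = nn[i] * nn[i];
      const double gk_eff = gk * n2 * n2;
      const double G = gl_i[i] + gna_eff + gk_eff + ge[i] + gi[i];
      const double A = gl_i[i] * el + gna_eff * ena + gk_eff * ek +
                       ge[i] * ee + gi[i] * ei + I * I_scale[i];
      const double vinf = A / G;
      V[i] = vinf + (V[i] - vinf) * std::exp(-dt * G / cm);
      if (!R_finite(V[i]) || std::fabs(V[i]) > 200.0) {
        stop("membrane potential diverged (|V| > 200 mV); reduce dt or input");
      }
      if (!firing[i] && V[i] > 0.0) {
        firing[i] = 1;
        sp_t.push_back(t_ms);
        sp_id.push_back(i + 1);
        spk_now.push_back(i);
      } else if (firing[i] && V[i] < -30.0) {
        firing[i] = 0;
      }
    }
    // propagate this step's spikes with short-term plasticity
    for (size_t k = 0; k < spk_now.size(); ++k) {
      const int j = spk_now[k];
      const double gap = t_ms - last_spk[j];
      u[j] *= std::exp(-wf * gap);
      x[j] = 1.0 - (1.0 - x[j]) * std::exp(-wd * gap);
      u[j] += U * (1.0 - u[j]);
      const double eff = u[j] * x[j];
      x[j] -= eff;
      last_spk[j] = t_ms;
      if (u[j] > u_max) u_max = u[j];
      if (x[j] < x_min) x_min = x[j];
      const bool exc = j < n_exc;
      for (int e = syn_ptr[j]; e < syn_ptr[j + 1]; ++e) {
        if (exc) ge[syn_post[e]] += syn_w[e] * eff;
        else gi[syn_post[e]] += syn_w[e] * eff;
      }
    }
  }

  NumericVector times(sp_t.begin(), sp_t.end());
  IntegerVector ids(sp_id.begin(), sp_id.end());
  times = times / 1000.0;  // ms -> s
  return List::create(_["times"] = times, _["ids"] = ids,
                      _["mean_rate"] = (double)sp_t.size() /
                                       (n * n_steps * dt / 1000.0),
                      _["u_max"] = u_max, _["x_min"] = x_min);
}
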