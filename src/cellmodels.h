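#ifndef FIBROMAP_CELLMODELS_H
#define FIBROMAP_CELLMODELS_H

#include <Rcpp.h>
#include <cmath>

// Phenomenological 4-variable ventricular myocyte (minimal reaction model
// with fast-inward, slow-outward and slow-inward currents and three gates).
// Voltage is carried as the dimensionless u; V_mV = V_rest + V_amp * u.
struct MyoParams {
  double u_o, u_u, th_v, th_w, th_vm, th_o;
  double tau_v1m, tau_v2m, tau_vp;
  double tau_w1m, tau_w2m, k_wm, u_wm, tau_wp;
  double tau_fi, tau_o1, tau_o2, tau_so1, tau_so2, k_so, u_so;
  double tau_s1, tau_s2, k_s, u_s, tau_si, tau_winf, w_inf_star;
  double V_rest, V_amp, Cm;
  // scenario knob: scales the fast-inward (sodium-like) current
  double gna;
};

inline MyoParams myo_from_R(const Rcpp::NumericVector &p) {
  MyoParams m;
  m.u_o = p["u_o"]; m.u_u = p["u_u"]; m.th_v = p["th_v"]; m.th_w = p["th_w"];
  m.th_vm = p["th_vm"]; m.th_o = p["th_o"];
  m.tau_v1m = p["tau_v1m"]; m.tau_v2m = p["tau_v2m"]; m.tau_vp = p["tau_vp"];
  m.tau_w1m = p["tau_w1m"]; m.tau_w2m = p["tau_w2m"]; m.k_wm = p["k_wm"];
  m.u_wm = p["u_wm"]; m.tau_wp = p["tau_wp"];
  m.tau_fi = p["tau_fi"]; m.tau_o1 = p["tau_o1"]; m.tau_o2 = p["tau_o2"];
  m.tau_so1 = p["tau_so1"]; m.tau_so2 = p["tau_so2"]; m.k_so = p["k_so"];
  m.u_so = p["u_so"]; m.tau_s1 = p["tau_s1"]; m.tau_s2 = p["tau_s2"];
  m.k_s = p["k_s"]; m.u_s = p["u_s"]; m.tau_si = p["tau_si"];
  m.tau_winf = p["tau_winf"]; m.w_inf_star = p["w_inf_star"];
  m.V_rest = p["V_rest"]; m.V_amp = p["V_amp"]; m.Cm = p["Cm"];
  m.gna = 1.0;
  return m;
}

struct MyoState { double u, v, w, s; };

inline MyoState myo_rest() { return {0.0, 1.0, 1.0, 0.0}; }

inline double Hs(double x) { return x > 0.0 ? 1.0 : 0.0; }

// One explicit step: u by forward Euler (du_ext in 1/ms added), gates by
// exponential (Rush-Larsen-style) updates. Returns the ionic du/dt (1/ms)
// actually applied, for diagnostics.
inline void myo_step(MyoState &st, const MyoParams &p, double du_ext, double dt) {
  const double u = st.u;
  const double Huv = Hs(u - p.th_v), Huw = Hs(u - p.th_w);
  const double Huvm = Hs(u - p.th_vm), Huo = Hs(u - p.th_o);

  const double tau_vm = (1.0 - Huvm) * p.tau_v1m + Huvm * p.tau_v2m;
  const double tau_wm = p.tau_w1m + (p.tau_w2m - p.tau_w1m) *
    (1.0 + std::tanh(p.k_wm * (u - p.u_wm))) / 2.0;
  const double tau_so = p.tau_so1 + (p.tau_so2 - p.tau_so1) *
    (1.0 + std::tanh(p.k_so * (u - p.u_so))) / 2.0;
  const double tau_s = (1.0 - Huw) * p.tau_s1 + Huw * p.tau_s2;
  const double tau_o = (1.0 - Huo) * p.tau_o1 + Huo * p.tau_o2;

  const double J_fi = -p.gna * st.v * Huv * (u - p.th_v) * (p.u_u - u) / p.tau_fi;
  const double J_so = (u - p.u_o) * (1.0 - Huw) / tau_o + Huw / tau_so;
  const double J_si = -Huw * st.w * st.s / p.tau_si;

  st.u = u + dt * (-(J_fi + J_so + J_si) + du_ext);

  const double v_inf = (u < p.th_vm) ? 1.0 : 0.0;
  if (Huv < 0.5) st.v = v_inf + (st.v - v_inf) * std::exp(-dt / tau_vm);
  else           st.v = st.v * std::exp(-dt / p.tau_vp);

  const double w_inf = (1.0 - Huo) * (1.0 - u / p.tau_winf) + Huo * p.w_inf_star;
  if (Huw < 0.5) st.w = w_inf + (st.w - w_inf) * std::exp(-dt / tau_wm);
  else           st.w = st.w * std::exp(-dt / p.tau_wp);

  const double s_inf = (1.0 + std::tanh(p.k_s * (u - p.u_s))) / 2.0;
  st.s = s_inf + (st.s - s_inf) * std::exp(-dt / tau_s);
}

// Passive fibroblast: capacitive membrane with a linear background
// conductance towards a depolarized reversal potential.
struct FibParams { double Cm, G, E; };

inline FibParams fib_from_R(const Rcpp::NumericVector &p) {
  FibParams f; f.Cm = p["Cm"]; f.G = p["G"]; f.E = p["E"]; return f;
}

#endif
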