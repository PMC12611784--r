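#include "cellmodels.h"
using namespace Rcpp;

// 1D electrotonically coupled myocyte-fibroblast chain.
// Layout: cells 0..9 myocytes, 10..(10+n_fib-1) fibroblasts, last index is
// the end-standing reporter myocyte. Serial nearest-neighbor resistive
// coupling; currents in pA (nS * mV), capacitances in pF, time in ms.
// [[Rcpp::export(name = ".chain_sim")]]
List chain_sim(int n_fib, double rate_hz,
               NumericVector myo_par, NumericVector fib_par,
               double G_mm, double G_mf, double G_ff,
               double dt, int n_precond, int n_analysis,
               int n_stim_cells, double stim_dur_ms, double stim_amp_nA,
               bool record_traces, double sample_ms) {
  const MyoParams mp = myo_from_R(myo_par);
  const FibParams fp = fib_from_R(fib_par);
  const int N = 11 + n_fib;
  const int i_end = N - 1, i_prox = 9;
  const double cl = 1000.0 / rate_hz;
  const int n_cycles = n_precond + n_analysis;
  const int steps_per_cycle = (int)std::round(cl / dt);
  const double V_act = -20.0;  // activation threshold (upstroke crossing), mV

  std::vector<MyoState> ms(N);
  std::vector<double> Vf(N, fp.E);
  std::vector<int> is_myo(N, 0);
  for (int i = 0; i < N; ++i) is_myo[i] = (i < 10 || i == i_end) ? 1 : 0;

  std::vector<double> V(N), Vnew(N);
  for (int i = 0; i < N; ++i) {
    ms[i] = myo_rest();
    V[i] = is_myo[i] ? mp.V_rest : fp.E;
  }

  auto Gpair = [&](int a, int b) {
    if (is_myo[a] && is_myo[b]) return G_mm;
    if (!is_myo[a] && !is_myo[b]) return G_ff;
    return G_mf;
  };

  // per-cycle records
  NumericVector peak_end(n_cycles, R_NegInf), dvdt_end(n_cycles, 0.0);
  NumericVector act_end(n_cycles, NA_REAL), act_prox(n_cycles, NA_REAL);

  // sampled traces: last 2 preconditioning cycles + analysis cycles
  const int first_rec_cycle = record_traces ? std::max(0, n_precond - 2) : n_cycles;
  const int sample_stride = std::max(1, (int)std::round(sample_ms / dt));
  std::vector<double> tr_t;
  std::vector<std::vector<double>> tr_v;
  if (record_traces) {
    int rec_cycles = n_cycles - first_rec_cycle;
    int est = rec_cycles * steps_per_cycle / sample_stride + 16;
    tr_t.reserve(est);
    tr_v.assign(N, {});
    for (auto &v : tr_v) v.reserve(est);
  }

  double Vend_prev = V[i_end];
  long step_global = 0;
  for (int cyc = 0; cyc < n_cycles; ++cyc) {
    bool prox_done = false, end_done = false;
    for (int s = 0; s < steps_per_cycle; ++s, ++step_global) {
      const double t_in = s * dt;
      // coupling + stimulus currents (pA)
      for (int i = 0; i < N; ++i) {
        double I = 0.0;
        if (i > 0) I += Gpair(i, i - 1) * (V[i - 1] - V[i]);
        if (i < N - 1) I += Gpair(i, i + 1) * (V[i + 1] - V[i]);
        if (i < n_stim_cells && t_in < stim_dur_ms) I += stim_amp_nA * 1000.0;
        if (is_myo[i]) {
          myo_step(ms[i], mp, I / (mp.Cm * mp.V_amp), dt);
          Vnew[i] = mp.V_rest + mp.V_amp * ms[i].u;
        } else {
          Vf[i] += dt * (-fp.G * (Vf[i] - fp.E) + I) / fp.Cm;
          Vnew[i] = Vf[i];
        }
      }
      // records
      const double dv = (Vnew[i_end] - Vend_prev) / dt;
      if (Vnew[i_end] > peak_end[cyc]) peak_end[cyc] = Vnew[i_end];
      if (dv > dvdt_end[cyc]) dvdt_end[cyc] = dv;
      if (!end_done && Vend_prev <= V_act && Vnew[i_end] > V_act) {
        act_end[cyc] = t_in + dt; end_done = true;
      }
      if (!prox_done && V[i_prox] <= V_act && Vnew[i_prox] > V_act) {
        act_prox[cyc] = t_in + dt; prox_done = true;
      }
      Vend_prev = Vnew[i_end];
      std::swap(V, Vnew);

      if (!std::isfinite(V[i_end]) || !std::isfinite(V[0]))
        stop("solver instability (non-finite state) at dt = %f ms", dt);

      if (record_traces && cyc >= first_rec_cycle && (step_global % sample_stride == 0)) {
        tr_t.push_back(cyc * cl + t_in);
        for (int i = 0; i < N; ++i) tr_v[i].push_back(V[i]);
      }
    }
  }

  List out = List::create(
    _["peak_end_mV"] = peak_end,
    _["dvdt_end_mV_ms"] = dvdt_end,
    _["act_end_ms"] = act_end,
    _["act_prox_ms"] = act_prox,
    _["cycle_ms"] = cl,
    _["n_precond"] = n_precond,
    _["n_analysis"] = n_analysis);
  if (record_traces) {
    NumericMatrix tv(N, (int)tr_t.size());
    for (int i = 0; i < N; ++i)
      for (size_t k = 0; k < tr_t.size(); ++k) tv(i, k) = tr_v[i][k];
    out["trace_t_ms"] = NumericVector(tr_t.begin(), tr_t.end());
    out["trace_V_mV"] = tv;
    out["first_recorded_cycle"] = first_rec_cycle + 1;  // 1-based
  }
  return out;
}
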