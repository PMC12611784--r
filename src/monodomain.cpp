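#include "cellmodels.h"
using namespace Rcpp;

// Reduced-scale 2D monodomain tissue: finite differences on a regular grid
// (spacing h_mm), anisotropic diffusivity from per-element fiber angles,
// zero-flux boundaries, non-conducting elements carry no flux (harmonic face
// averaging makes their interfaces insulating). Optional per-element
// fibroblast loading (n_fib identical passive fibroblasts per myocyte).
//
// tags: 0 = conducting myocardium (incl. conducting NCF), 1 = non-conducting.
// Dl/Dt: diffusivities (mm^2/ms) on the dimensionless-u monodomain equation.
// gna: per-element scaling of the fast-inward current.
// stim_mask: elements receiving the stimulus; stim_times: pulse onsets (ms).
// rec_start/rec_end: windows in which per-element activation times (first
// upstroke crossing of -20 mV) are recorded, one map per window.
// [[Rcpp::export(name = ".monodomain_sim")]]
List monodomain_sim(IntegerMatrix tags, NumericMatrix Dl, NumericMatrix Dt,
                    NumericMatrix angle_rad, NumericMatrix gna,
                    IntegerMatrix nfib,
                    NumericVector myo_par, NumericVector fib_par, double G_mf,
                    double h_mm, double dt,
                    NumericVector stim_times, double stim_dur_ms,
                    double stim_amp_per_ms, LogicalMatrix stim_mask,
                    NumericVector rec_start, NumericVector rec_end,
                    double t_end, int probe_i, int probe_j, double sample_ms) {
  const int nx = tags.nrow(), ny = tags.ncol();
  const int N = nx * ny;
  const MyoParams mp0 = myo_from_R(myo_par);
  const FibParams fp = fib_from_R(fib_par);
  const double V_act = -20.0;
  const double u_act = (V_act - mp0.V_rest) / mp0.V_amp;
  auto id = [&](int i, int j) { return i + nx * j; };

  // flatten element properties
  std::vector<char> cond(N), stim_el(N);
  std::vector<double> gna_v(N), Dxx(N, 0.0), Dyy(N, 0.0), Dxy(N, 0.0);
  std::vector<int> nfib_v(N);
  bool any_cross = false, any_fib = false;
  for (int j = 0; j < ny; ++j) for (int i = 0; i < nx; ++i) {
    const int c = id(i, j);
    cond[c] = (tags(i, j) == 0);
    stim_el[c] = stim_mask(i, j);
    gna_v[c] = gna(i, j);
    nfib_v[c] = nfib(i, j);
    if (nfib_v[c] > 0) any_fib = true;
    if (cond[c]) {
      double cth = std::cos(angle_rad(i, j)), sth = std::sin(angle_rad(i, j));
      Dxx[c] = Dl(i, j) * cth * cth + Dt(i, j) * sth * sth;
      Dyy[c] = Dl(i, j) * sth * sth + Dt(i, j) * cth * cth;
      Dxy[c] = (Dl(i, j) - Dt(i, j)) * cth * sth;
      if (std::abs(Dxy[c]) > 1e-14) any_cross = true;
    }
  }
  double dmax = 0.0;
  for (int c = 0; c < N; ++c) dmax = std::max(dmax, std::max(Dxx[c], Dyy[c]));
  if (dt > 0.9 * h_mm * h_mm / (4.0 * std::max(dmax, 1e-12)))
    stop("dt = %f ms violates the diffusion stability bound for h = %f mm", dt, h_mm);

  auto harm = [](double a, double b) {
    return (a > 0.0 && b > 0.0) ? 2.0 * a * b / (a + b) : 0.0;
  };
  const double ih2 = 1.0 / (h_mm * h_mm);
  // face coefficients (scaled by 1/h^2): east face of (i,j) and north face
  std::vector<double> fe(N, 0.0), fn(N, 0.0);
  for (int j = 0; j < ny; ++j) for (int i = 0; i < nx; ++i) {
    const int c = id(i, j);
    if (!cond[c]) continue;
    if (i + 1 < nx && cond[id(i + 1, j)]) fe[c] = harm(Dxx[c], Dxx[id(i + 1, j)]) * ih2;
    if (j + 1 < ny && cond[id(i, j + 1)]) fn[c] = harm(Dyy[c], Dyy[id(i, j + 1)]) * ih2;
  }

  std::vector<MyoState> st(N);
  std::vector<double> Vf(N, fp.E);
  for (auto &s : st) s = myo_rest();
  std::vector<double> u(N, 0.0), unew(N, 0.0);

  const int n_rec = rec_start.size();
  std::vector<std::vector<double>> act(n_rec, std::vector<double>(N, NA_REAL));

  std::vector<double> probe_t, probe_v;
  const int sample_stride = std::max(1, (int)std::round(sample_ms / dt));
  const long nsteps = (long)std::round(t_end / dt);
  const double fib_fac = G_mf / (mp0.Cm * mp0.V_amp);

  for (long step = 0; step < nsteps; ++step) {
    const double t = step * dt;
    bool stim_on = false;
    for (int k = 0; k < stim_times.size(); ++k)
      if (t >= stim_times[k] && t < stim_times[k] + stim_dur_ms) { stim_on = true; break; }
    int rec_w = -1;
    for (int w = 0; w < n_rec; ++w)
      if (t >= rec_start[w] && t < rec_end[w]) { rec_w = w; break; }

    for (int j = 0; j < ny; ++j) {
      const int base = nx * j;
      for (int i = 0; i < nx; ++i) {
        const int c = base + i;
        if (!cond[c]) { unew[c] = 0.0; continue; }
        const double uc = u[c];
        double lap = 0.0;
        if (i + 1 < nx) lap += fe[c] * (u[c + 1] - uc);
        if (i > 0)      lap += fe[c - 1] * (u[c - 1] - uc);
        if (j + 1 < ny) lap += fn[c] * (u[c + nx] - uc);
        if (j > 0)      lap += fn[c - nx] * (u[c - nx] - uc);
        if (any_cross) {
          if (i > 0 && i + 1 < nx && j > 0 && j + 1 < ny &&
              cond[c + 1] && cond[c - 1] && cond[c + nx] && cond[c - nx] &&
              cond[c + 1 + nx] && cond[c - 1 - nx] && cond[c + 1 - nx] && cond[c - 1 + nx]) {
            const double duxy = (u[c + 1 + nx] - u[c + 1 - nx] -
                                 u[c - 1 + nx] + u[c - 1 - nx]) / 4.0;
            lap += 2.0 * Dxy[c] * duxy * ih2;
          }
        }
        double du_ext = lap;
        if (stim_on && stim_el[c]) du_ext += stim_amp_per_ms;
        if (any_fib && nfib_v[c] > 0) {
          const double Vm = mp0.V_rest + mp0.V_amp * uc;
          du_ext += nfib_v[c] * fib_fac * (Vf[c] - Vm);
          Vf[c] += dt * (-fp.G * (Vf[c] - fp.E) + G_mf * (Vm - Vf[c])) / fp.Cm;
        }
        MyoParams mp = mp0;
        mp.gna = gna_v[c];
        st[c].u = uc;
        myo_step(st[c], mp, du_ext, dt);
        unew[c] = st[c].u;
        if (rec_w >= 0 && ISNAN(act[rec_w][c]) && uc <= u_act && st[c].u > u_act)
          act[rec_w][c] = t + dt - rec_start[rec_w];
      }
    }
    std::swap(u, unew);
    if (!std::isfinite(u[id(nx / 2, ny / 2)]))
      stop("solver instability (non-finite state) at step %ld (t = %f ms)", step, t);
    if (probe_i >= 0 && (step % sample_stride == 0)) {
      probe_t.push_back(t);
      probe_v.push_back(mp0.V_rest + mp0.V_amp * u[id(probe_i, probe_j)]);
    }
  }

  List actl(n_rec);
  for (int w = 0; w < n_rec; ++w) {
    NumericMatrix m(nx, ny);
    std::copy(act[w].begin(), act[w].end(), m.begin());
    actl[w] = m;
  }
  return List::create(_["activation_ms"] = actl,
                      _["probe_t_ms"] = NumericVector(probe_t.begin(), probe_t.end()),
                      _["probe_V_mV"] = NumericVector(probe_v.begin(), probe_v.end()));
}
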