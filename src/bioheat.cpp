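#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Explicit Pennes bioheat FDTD:
//   rho c_t dT/dt = div(k grad T) + q(t) - w_b c_b (T - T_a)
// 7-point stencil with harmonic-mean face conductivities (exact for layered
// media). Boundary: Dirichlet (ghost voxel pinned at T_a) or insulated
// (zero flux). q is either constant (duty-averaged) or gated by the binary
// pulse envelope (pulse-resolved), with the same period integral.
//
// Returns the final temperature field, a probe time series, and the running
// peak elevation over the whole volume.

// [[Rcpp::export]]
List bioheat_kernel(NumericVector rhoct, NumericVector kcond,
                    NumericVector wbcb, NumericVector q,
                    IntegerVector dims, double dx, double dt, double duration,
                    double t0, double ta, int probe_idx, int record_every,
                    bool dirichlet, bool pulse_resolved,
                    double pd_s, double prf_hz) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t N = (R_xlen_t)nx * ny * nz;
  const int sx = 1, sy = nx, sz = nx * ny;
  const double inv_dx2 = 1.0 / (dx * dx);
  const long nsteps = (long)std::ceil(duration / dt);

  std::vector<double> T(N, t0), Tn(N, t0);
  // face conductivities (harmonic mean) scaled by 1/dx^2
  std::vector<double> kx(N, 0.0), ky(N, 0.0), kz(N, 0.0);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t id = i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
        if (i < nx - 1)
          kx[id] = 2.0 * kcond[id] * kcond[id + sx] /
                   (kcond[id] + kcond[id + sx]) * inv_dx2;
        if (j < ny - 1)
          ky[id] = 2.0 * kcond[id] * kcond[id + sy] /
                   (kcond[id] + kcond[id + sy]) * inv_dx2;
        if (k < nz - 1)
          kz[id] = 2.0 * kcond[id] * kcond[id + sz] /
                   (kcond[id] + kcond[id + sz]) * inv_dx2;
      }

  std::vector<double> probe_t, probe_T, peak_t, peak_T;
  double peak_all = t0;
  const double prf_period = prf_hz > 0 ? 1.0 / prf_hz : 0.0;

  for (long step = 0; step < nsteps; ++step) {
    double t = step * dt;
    double env = 1.0;
    if (pulse_resolved) {
      double phase = t - std::floor(t / prf_period) * prf_period;
      env = (phase < pd_s) ? 1.0 : 0.0;
    }
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j) {
        R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
        for (int i = 0; i < nx; ++i) {
          R_xlen_t id = base + i;
          double Tc = T[id];
          double flux = 0.0;
          // +x / -x
          if (i < nx - 1) flux += kx[id] * (T[id + sx] - Tc);
          else if (dirichlet) flux += kcond[id] * inv_dx2 * (ta - Tc);
          if (i > 0) flux += kx[id - sx] * (T[id - sx] - Tc);
          else if (dirichlet) flux += kcond[id] * inv_dx2 * (ta - Tc);
          // +y / -y
          if (j < ny - 1) flux += ky[id] * (T[id + sy] - Tc);
          else if (dirichlet) flux += kcond[id] * inv_dx2 * (ta - Tc);
          if (j > 0) flux += ky[id - sy] * (T[id - sy] - Tc);
          else if (dirichlet) flux += kcond[id] * inv_dx2 * (ta - Tc);
          // +z / -z
          if (k < nz - 1) flux += kz[id] * (T[id + sz] - Tc);
          else if (dirichlet) flux += kcond[id] * inv_dx2 * (ta - Tc);
          if (k > 0) flux += kz[id - sz] * (T[id - sz] - Tc);
          else if (dirichlet) flux += kcond[id] * inv_dx2 * (ta - Tc);

          Tn[id] = Tc + dt / rhoct[id] *
            (flux + q[id] * env - wbcb[id] * (Tc - ta));
        }
      }
    T.swap(Tn);
    if (!R_finite(T[probe_idx]))
      stop("bioheat solver diverged: non-finite temperature at step %ld", step);
    if (step % record_every == 0 || step == nsteps - 1) {
      probe_t.push_back((step + 1) * dt);
      probe_T.push_back(T[probe_idx]);
      double mx = T[0];
      for (R_xlen_t id = 1; id < N; ++id) if (T[id] > mx) mx = T[id];
      peak_t.push_back((step + 1) * dt);
      peak_T.push_back(mx);
      if (mx > peak_all) peak_all = mx;
    }
    if (step % 1000 == 0) Rcpp::checkUserInterrupt();
  }

  NumericVector Tout(N);
  for (R_xlen_t id = 0; id < N; ++id) Tout[id] = T[id];
  return List::create(
    _["T_final"] = Tout,
    _["probe_t"] = NumericVector(probe_t.begin(), probe_t.end()),
    _["probe_T"] = NumericVector(probe_T.begin(), probe_T.end()),
    _["peak_T_series"] = NumericVector(peak_T.begin(), peak_T.end()),
    _["peak_T"] = peak_all);
}
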