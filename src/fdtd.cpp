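#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// First-order pressure-velocity acoustic FDTD on a staggered grid.
// p lives at cell centres, velocity components on the +x/+y/+z cell faces.
// Attenuation enters as an exponential loss on the velocity update with rate
// gamma = 2 * alpha * c (amplitude decay e^{-alpha x} for a plane wave); the
// absorbing boundary is a quadratic-profile exponential sponge applied to
// both p and v. Degenerate dims (ny==1 and/or nz==1) give planar / 1D modes.
//
// Sources are additive volume-velocity (monopole) injections at given voxels:
//   p[idx] += amp * ramp(t) * sin(2 pi f t + phase)
// with amp precomputed in R as dt * rho * c^2 * Q / dx^3.
//
// The solver runs period blocks until the per-period peak |p| at the focus
// voxel changes by less than steady_tol between consecutive periods, then
// records per-voxel min/max pressure over one further full period.

// [[Rcpp::export]]
List fdtd_kernel(NumericVector rho, NumericVector cc, NumericVector alpha,
                 IntegerVector dims, double dx, double dt, double freq,
                 IntegerVector src_idx, NumericVector src_amp,
                 NumericVector src_phase,
                 int steps_per_period, int min_periods, int max_periods,
                 double steady_tol, int n_sponge, double sponge_sigma_max,
                 int focus_idx, double ramp_periods) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t N = (R_xlen_t)nx * ny * nz;
  const bool use_y = ny > 1, use_z = nz > 1;
  const int sx = 1, sy = nx, sz = nx * ny;

  std::vector<double> p(N, 0.0), vx(N, 0.0), vy(N, 0.0), vz(N, 0.0);
  std::vector<double> cp(N), dpv(N);
  std::vector<double> bx(N, 0.0), by(N, 0.0), bz(N, 0.0);
  std::vector<double> dvx(N, 1.0), dvy(N, 1.0), dvz(N, 1.0);

  // sponge profile per voxel (rate sigma, 1/s)
  std::vector<double> sig(N, 0.0);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int d = nx; // distance (voxels) to nearest boundary over active dims
        d = std::min(d, std::min(i, nx - 1 - i));
        if (use_y) d = std::min(d, std::min(j, ny - 1 - j));
        if (use_z) d = std::min(d, std::min(k, nz - 1 - k));
        R_xlen_t id = i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
        if (d < n_sponge) {
          double w = double(n_sponge - d) / n_sponge;
          sig[id] = sponge_sigma_max * w * w;
        }
      }

  for (R_xlen_t id = 0; id < N; ++id) {
    cp[id] = dt * rho[id] * cc[id] * cc[id] / dx;
    dpv[id] = std::exp(-sig[id] * dt);
  }
  // face coefficients (average of adjacent cells)
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t id = i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
        if (i < nx - 1) {
          double rf = 0.5 * (rho[id] + rho[id + sx]);
          double gf = (alpha[id] * cc[id] + alpha[id + sx] * cc[id + sx]);
          double sf = 0.5 * (sig[id] + sig[id + sx]);
          bx[id] = dt / (dx * rf);
          dvx[id] = std::exp(-(gf + sf) * dt);
        }
        if (use_y && j < ny - 1) {
          double rf = 0.5 * (rho[id] + rho[id + sy]);
          double gf = (alpha[id] * cc[id] + alpha[id + sy] * cc[id + sy]);
          double sf = 0.5 * (sig[id] + sig[id + sy]);
          by[id] = dt / (dx * rf);
          dvy[id] = std::exp(-(gf + sf) * dt);
        }
        if (use_z && k < nz - 1) {
          double rf = 0.5 * (rho[id] + rho[id + sz]);
          double gf = (alpha[id] * cc[id] + alpha[id + sz] * cc[id + sz]);
          double sf = 0.5 * (sig[id] + sig[id + sz]);
          bz[id] = dt / (dx * rf);
          dvz[id] = std::exp(-(gf + sf) * dt);
        }
      }

  const int n_src = src_idx.size();
  const double w0 = 2.0 * M_PI * freq;
  const double ramp_steps = ramp_periods * steps_per_period;

  std::vector<double> pmin, pmax, focus_trace;
  std::vector<double> focus_peaks;
  bool converged = false, recording = false;
  double prev_peak = -1.0;
  int period = 0;
  long step_count = 0;

  while (period < max_periods) {
    double peak = 0.0;
    for (int s = 0; s < steps_per_period; ++s, ++step_count) {
      // velocity updates
      for (int k = 0; k < nz; ++k)
        for (int j = 0; j < ny; ++j) {
          R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
          for (int i = 0; i < nx - 1; ++i) {
            R_xlen_t id = base + i;
            vx[id] = dvx[id] * vx[id] - bx[id] * (p[id + sx] - p[id]);
          }
        }
      if (use_y)
        for (int k = 0; k < nz; ++k)
          for (int j = 0; j < ny - 1; ++j) {
            R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
            for (int i = 0; i < nx; ++i) {
              R_xlen_t id = base + i;
              vy[id] = dvy[id] * vy[id] - by[id] * (p[id + sy] - p[id]);
            }
          }
      if (use_z)
        for (int k = 0; k < nz - 1; ++k)
          for (int j = 0; j < ny; ++j) {
            R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
            for (int i = 0; i < nx; ++i) {
              R_xlen_t id = base + i;
              vz[id] = dvz[id] * vz[id] - bz[id] * (p[id + sz] - p[id]);
            }
          }
      // pressure update
      for (int k = 0; k < nz; ++k)
        for (int j = 0; j < ny; ++j) {
          R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
          for (int i = 0; i < nx; ++i) {
            R_xlen_t id = base + i;
            double div = vx[id] - (i > 0 ? vx[id - sx] : 0.0);
            if (use_y) div += vy[id] - (j > 0 ? vy[id - sy] : 0.0);
            if (use_z) div += vz[id] - (k > 0 ? vz[id - sz] : 0.0);
            p[id] = dpv[id] * p[id] - cp[id] * div;
          }
        }
      // sources
      double t = (step_count + 1) * dt;
      double ramp = step_count < ramp_steps
        ? 0.5 * (1.0 - std::cos(M_PI * step_count / ramp_steps)) : 1.0;
      for (int s2 = 0; s2 < n_src; ++s2)
        p[src_idx[s2]] += src_amp[s2] * ramp * std::sin(w0 * t + src_phase[s2]);

      double pf = std::fabs(p[focus_idx]);
      if (pf > peak) peak = pf;
      if (recording) {
        focus_trace.push_back(p[focus_idx]);
        for (R_xlen_t id = 0; id < N; ++id) {
          if (p[id] < pmin[id]) pmin[id] = p[id];
          if (p[id] > pmax[id]) pmax[id] = p[id];
        }
      }
    }
    ++period;
    if (!R_finite(peak))
      stop("FDTD diverged: non-finite pressure at the focus (period %d)",
           period);
    focus_peaks.push_back(peak);
    if (recording) break;   // recording period done
    if (prev_peak > 0.0 && period >= min_periods &&
        std::fabs(peak - prev_peak) <= steady_tol * prev_peak) {
      converged = true;
    }
    prev_peak = peak;
    if (converged || period == max_periods - 1) {
      recording = true;     // one final full period with min/max capture
      pmin.assign(p.begin(), p.end());
      pmax.assign(p.begin(), p.end());
    }
    Rcpp::checkUserInterrupt();
  }

  NumericVector ppk(N);
  for (R_xlen_t id = 0; id < N; ++id) ppk[id] = pmax[id] - pmin[id];
  return List::create(
    _["p_pp"] = ppk,
    _["converged"] = converged,
    _["periods"] = period,
    _["focus_peaks"] = NumericVector(focus_peaks.begin(), focus_peaks.end()),
    _["focus_trace"] = NumericVector(focus_trace.begin(), focus_trace.end()));
}
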