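#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Explicit forward-Euler advance of the coupled tumor / vasculature
// reaction-diffusion system on a regular anisotropic grid.
//
// Diffusion is flux-conservative with harmonic-mean face diffusivities and
// no-flux (Neumann) conditions at the brain-mask surface. The tumor reaction
// is logistic growth against the combined carrying capacity
// theta_TV = theta_T(phi_V) + theta_V, scaled by the long-term radiotherapy
// factor field RLT_T. The vascular reactions (angiogenesis at the tumor
// periphery, vascular death at depth, both modulated by the normalized
// distance-to-periphery field d) act only inside the tumor mask; elsewhere
// phi_V evolves by diffusion alone.
//
// Returns updated fields plus a run log: count of negative values floored to
// zero, the largest single-step voxel update, and an ok flag (false on
// NaN/Inf or on a vanishing carrying capacity under positive phi_T).
// [[Rcpp::export]]
List cpp_advance(NumericVector phiT0, NumericVector phiV0,
                 NumericVector DT, NumericVector DV,
                 LogicalVector brain, LogicalVector tumor,
                 NumericVector dfield, NumericVector kpV,
                 double kpT, double kdV,
                 double theta_max, double theta_min, double phiV_thresh,
                 double theta_V,
                 NumericVector RLT_T, NumericVector RLT_V,
                 IntegerVector dims, NumericVector spacing,
                 double dt, int nsteps) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  const int stride[3] = {1, nx, nx * ny};
  const double inv_h2[3] = {1.0 / (spacing[0] * spacing[0]),
                            1.0 / (spacing[1] * spacing[1]),
                            1.0 / (spacing[2] * spacing[2])};
  NumericVector phiT = clone(phiT0), phiV = clone(phiV0);
  NumericVector newT(n), newV(n);
  long floor_count = 0;
  double max_delta = 0.0;
  bool ok = true;
  std::string err = "";

  // precompute voxel grid coordinates for bounds checks
  for (int step = 0; step < nsteps && ok; ++step) {
    for (int k = 0; k < nz; ++k) {
      for (int j = 0; j < ny; ++j) {
        for (int i = 0; i < nx; ++i) {
          const int v = i + nx * (j + ny * k);
          if (!brain[v]) { newT[v] = 0.0; newV[v] = 0.0; continue; }
          const int pos[3] = {i, j, k};
          const int lim[3] = {nx, ny, nz};
          double diffT = 0.0, diffV = 0.0;
          for (int ax = 0; ax < 3; ++ax) {
            // + face
            if (pos[ax] + 1 < lim[ax]) {
              const int w = v + stride[ax];
              if (brain[w]) {
                double st = DT[v] + DT[w];
                if (st > 0.0)
                  diffT += (2.0 * DT[v] * DT[w] / st) * (phiT[w] - phiT[v]) * inv_h2[ax];
                double sv = DV[v] + DV[w];
                if (sv > 0.0)
                  diffV += (2.0 * DV[v] * DV[w] / sv) * (phiV[w] - phiV[v]) * inv_h2[ax];
              }
            }
            // - face
            if (pos[ax] - 1 >= 0) {
              const int w = v - stride[ax];
              if (brain[w]) {
                double st = DT[v] + DT[w];
                if (st > 0.0)
                  diffT += (2.0 * DT[v] * DT[w] / st) * (phiT[w] - phiT[v]) * inv_h2[ax];
                double sv = DV[v] + DV[w];
                if (sv > 0.0)
                  diffV += (2.0 * DV[v] * DV[w] / sv) * (phiV[w] - phiV[v]) * inv_h2[ax];
              }
            }
          }
          // vascularity-dependent carrying capacity
          double thT = (phiV[v] >= phiV_thresh)
            ? theta_max
            : theta_min + phiV[v] * (theta_max - theta_min) / phiV_thresh;
          double thTV = thT + theta_V;
          double reacT;
          if (thTV <= 0.0) {
            if (phiT[v] > 0.0) {
              ok = false;
              err = "zero combined carrying capacity under positive phi_T";
              reacT = 0.0;
            } else reacT = 0.0;
          } else {
            reacT = RLT_T[v] * kpT * phiT[v] * (1.0 - (phiT[v] + phiV[v]) / thTV);
          }
          double reacV = 0.0;
          if (tumor[v]) {
            reacV = RLT_V[v] * kpV[v] * dfield[v] * phiV[v] * (1.0 - phiV[v] / theta_V)
                  - kdV * (1.0 - dfield[v]) * phiV[v];
          }
          double dT = dt * (diffT + reacT);
          double dV = dt * (diffV + reacV);
          if (std::fabs(dT) > max_delta) max_delta = std::fabs(dT);
          if (std::fabs(dV) > max_delta) max_delta = std::fabs(dV);
          double tnew = phiT[v] + dT;
          double vnew = phiV[v] + dV;
          if (!std::isfinite(tnew) || !std::isfinite(vnew)) {
            ok = false;
            err = "non-finite field value";
            tnew = vnew = 0.0;
          }
          if (tnew < 0.0) { tnew = 0.0; ++floor_count; }
          if (vnew < 0.0) { vnew = 0.0; ++floor_count; }
          newT[v] = tnew;
          newV[v] = vnew;
        }
      }
    }
    std::swap(phiT, newT);
    std::swap(phiV, newV);
  }
  return List::create(_["phi_T"] = phiT, _["phi_V"] = phiV,
                      _["floor_count"] = (double)floor_count,
                      _["max_delta"] = max_delta,
                      _["ok"] = ok, _["error"] = err);
}

// One-dimensional squared distance transform (Felzenszwalb & Huttenlocher)
// with physical sample spacing h.
static void dt1d(const std::vector<double>& f, std::vector<double>& out,
                 int n, double h) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  const double INF = std::numeric_limits<double>::infinity();
  int q = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int p = 1; p < n; ++p) {
    double xp = p * h;
    while (true) {
      double xq = v[q] * h;
      double s = ((f[p] + xp * xp) - (f[v[q]] + xq * xq)) / (2 * xp - 2 * xq);
      if (s <= z[q]) { --q; continue; }
      ++q;
      v[q] = p;
      z[q] = s;
      z[q + 1] = INF;
      break;
    }
  }
  q = 0;
  for (int p = 0; p < n; ++p) {
    double xp = p * h;
    while (z[q + 1] < xp) ++q;
    double xq = v[q] * h;
    out[p] = (xp - xq) * (xp - xq) + f[v[q]];
  }
}

// Exact anisotropic Euclidean distance transform: for every voxel, the
// physical distance (mm) to the nearest FALSE voxel of `mask`. Voxels
// outside the mask get 0. If the mask covers the whole grid the distance is
// infinite and an error is raised.
// [[Rcpp::export]]
NumericVector cpp_edt(LogicalVector mask, IntegerVector dims,
                      NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  // large finite sentinel keeps the parabola intersections finite
  const double BIG = 1e20;
  bool any_bg = false;
  std::vector<double> d2(n);
  for (int v = 0; v < n; ++v) {
    d2[v] = mask[v] ? BIG : 0.0;
    if (!mask[v]) any_bg = true;
  }
  if (!any_bg) stop("distance transform undefined: mask covers the whole grid");
  std::vector<double> f(std::max(nx, std::max(ny, nz)));
  std::vector<double> o(f.size());
  // x pass
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      const int base = nx * (j + ny * k);
      for (int i = 0; i < nx; ++i) f[i] = d2[base + i];
      dt1d(f, o, nx, spacing[0]);
      for (int i = 0; i < nx; ++i) d2[base + i] = o[i];
    }
  // y pass
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      for (int j = 0; j < ny; ++j) f[j] = d2[i + nx * (j + ny * k)];
      dt1d(f, o, ny, spacing[1]);
      for (int j = 0; j < ny; ++j) d2[i + nx * (j + ny * k)] = o[j];
    }
  // z pass
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      for (int k = 0; k < nz; ++k) f[k] = d2[i + nx * (j + ny * k)];
      dt1d(f, o, nz, spacing[2]);
      for (int k = 0; k < nz; ++k) d2[i + nx * (j + ny * k)] = o[k];
    }
  NumericVector out(n);
  for (int v = 0; v < n; ++v) out[v] = std::sqrt(d2[v]);
  return out;
}
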