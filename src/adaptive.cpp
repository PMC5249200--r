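#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Adaptive local surface refinement: each iso-surface vertex is relocated
// along the local gray-gradient direction to the 50% crossing between
// locally estimated background and material levels (robust low/high
// quantiles within a window), giving a surface that tracks local gray-level
// variations instead of a single global threshold.

namespace {

inline double trilin(const double *vol, int nx, int ny, int nz, double gx,
                     double gy, double gz) {
  // grid coordinates in voxel units (node = voxel center), zero outside
  if (gx < 0 || gy < 0 || gz < 0 || gx > nx - 1 || gy > ny - 1 || gz > nz - 1)
    return 0.0;
  int i0 = (int)std::floor(gx), j0 = (int)std::floor(gy),
      k0 = (int)std::floor(gz);
  if (i0 >= nx - 1) i0 = nx - 2;
  if (j0 >= ny - 1) j0 = ny - 2;
  if (k0 >= nz - 1) k0 = nz - 2;
  const double fx = gx - i0, fy = gy - j0, fz = gz - k0;
  const R_xlen_t s = (R_xlen_t)nx, sz = (R_xlen_t)nx * ny;
  const R_xlen_t b = i0 + s * j0 + sz * k0;
  const double c00 = vol[b] * (1 - fx) + vol[b + 1] * fx;
  const double c10 = vol[b + s] * (1 - fx) + vol[b + s + 1] * fx;
  const double c01 = vol[b + sz] * (1 - fx) + vol[b + sz + 1] * fx;
  const double c11 = vol[b + sz + s] * (1 - fx) + vol[b + sz + s + 1] * fx;
  const double c0 = c00 * (1 - fy) + c10 * fy;
  const double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

inline double quant(std::vector<double> v, double q) {
  std::sort(v.begin(), v.end());
  const double h = q * (v.size() - 1);
  const size_t lo = (size_t)std::floor(h);
  const size_t hi = std::min(lo + 1, v.size() - 1);
  return v[lo] + (h - lo) * (v[hi] - v[lo]);
}

}  // namespace

// [[Rcpp::export]]
NumericMatrix adaptive_relocate_cpp(NumericMatrix verts, NumericVector vol,
                                    IntegerVector dims, NumericVector voxel,
                                    NumericVector origin, int window,
                                    double qlo, double qhi, double step) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double *V = REAL(vol);
  const double vx = voxel[0];
  const int n = verts.nrow();
  NumericMatrix out(n, 3);
  const int nprof = (int)std::floor(2 * window / step) + 1;
  std::vector<double> prof(nprof), svals(nprof);

  for (int i = 0; i < n; ++i) {
    const double px = verts(i, 0), py = verts(i, 1), pz = verts(i, 2);
    out(i, 0) = px;
    out(i, 1) = py;
    out(i, 2) = pz;
    const double gx = (px - origin[0]) / voxel[0];
    const double gy = (py - origin[1]) / voxel[1];
    const double gz = (pz - origin[2]) / voxel[2];
    // central-difference gradient (1 voxel step), points into material
    double g[3] = {
        trilin(V, nx, ny, nz, gx + 1, gy, gz) -
            trilin(V, nx, ny, nz, gx - 1, gy, gz),
        trilin(V, nx, ny, nz, gx, gy + 1, gz) -
            trilin(V, nx, ny, nz, gx, gy - 1, gz),
        trilin(V, nx, ny, nz, gx, gy, gz + 1) -
            trilin(V, nx, ny, nz, gx, gy, gz - 1)};
    const double gn = std::sqrt(g[0] * g[0] + g[1] * g[1] + g[2] * g[2]);
    if (gn < 1e-9) continue;
    for (int m = 0; m < 3; ++m) g[m] /= gn;
    for (int m = 0; m < nprof; ++m) {
      const double s = -window + m * step;  // voxel units along gradient
      svals[m] = s;
      prof[m] = trilin(V, nx, ny, nz, gx + s * g[0], gy + s * g[1],
                       gz + s * g[2]);
    }
    const double lo = quant(prof, qlo), hi = quant(prof, qhi);
    if (hi - lo < 1e-9) continue;
    const double target = 0.5 * (lo + hi);
    // nearest crossing of the target level along the profile
    double best_s = NA_REAL, best_abs = 1e30;
    for (int m = 0; m + 1 < nprof; ++m) {
      const double a = prof[m] - target, b = prof[m + 1] - target;
      if (a == 0 && b == 0) continue;
      if (a * b <= 0) {
        const double frac = a == b ? 0.5 : a / (a - b);
        const double s = svals[m] + frac * step;
        if (std::fabs(s) < best_abs) {
          best_abs = std::fabs(s);
          best_s = s;
        }
      }
    }
    if (!ISNA(best_s) && best_abs <= window) {
      out(i, 0) = px + best_s * vx * g[0];
      out(i, 1) = py + best_s * vx * g[1];
      out(i, 2) = pz + best_s * vx * g[2];
    }
  }
  return out;
}
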