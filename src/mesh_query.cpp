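#include <Rcpp.h>
#include <cmath>
#include <limits>
#include <vector>
using namespace Rcpp;

// Uniform-grid accelerated triangle-mesh queries: closest point on surface
// and (bidirectional) normal-ray intersection.  Used by the rigid ICP
// registration and by the wear-map deviation measurement.

namespace {

inline void tri_closest(const double p[3], const double a[3], const double b[3],
                        const double c[3], double out[3]) {
  // Ericson, Real-Time Collision Detection, closest point on triangle
  double ab[3] = {b[0] - a[0], b[1] - a[1], b[2] - a[2]};
  double ac[3] = {c[0] - a[0], c[1] - a[1], c[2] - a[2]};
  double ap[3] = {p[0] - a[0], p[1] - a[1], p[2] - a[2]};
  double d1 = ab[0] * ap[0] + ab[1] * ap[1] + ab[2] * ap[2];
  double d2 = ac[0] * ap[0] + ac[1] * ap[1] + ac[2] * ap[2];
  if (d1 <= 0 && d2 <= 0) {
    out[0] = a[0]; out[1] = a[1]; out[2] = a[2];
    return;
  }
  double bp[3] = {p[0] - b[0], p[1] - b[1], p[2] - b[2]};
  double d3 = ab[0] * bp[0] + ab[1] * bp[1] + ab[2] * bp[2];
  double d4 = ac[0] * bp[0] + ac[1] * bp[1] + ac[2] * bp[2];
  if (d3 >= 0 && d4 <= d3) {
    out[0] = b[0]; out[1] = b[1]; out[2] = b[2];
    return;
  }
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    double v = d1 / (d1 - d3);
    for (int m = 0; m < 3; ++m) out[m] = a[m] + v * ab[m];
    return;
  }
  double cp[3] = {p[0] - c[0], p[1] - c[1], p[2] - c[2]};
  double d5 = ab[0] * cp[0] + ab[1] * cp[1] + ab[2] * cp[2];
  double d6 = ac[0] * cp[0] + ac[1] * cp[1] + ac[2] * cp[2];
  if (d6 >= 0 && d5 <= d6) {
    out[0] = c[0]; out[1] = c[1]; out[2] = c[2];
    return;
  }
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    double w = d2 / (d2 - d6);
    for (int m = 0; m < 3; ++m) out[m] = a[m] + w * ac[m];
    return;
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    for (int m = 0; m < 3; ++m) out[m] = b[m] + w * (c[m] - b[m]);
    return;
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  for (int m = 0; m < 3; ++m) out[m] = a[m] + ab[m] * v + ac[m] * w;
}

inline bool ray_tri(const double o[3], const double d[3], const double a[3],
                    const double b[3], const double c[3], double &t) {
  // Moller-Trumbore, two-sided
  const double e1[3] = {b[0] - a[0], b[1] - a[1], b[2] - a[2]};
  const double e2[3] = {c[0] - a[0], c[1] - a[1], c[2] - a[2]};
  const double pv[3] = {d[1] * e2[2] - d[2] * e2[1],
                        d[2] * e2[0] - d[0] * e2[2],
                        d[0] * e2[1] - d[1] * e2[0]};
  const double det = e1[0] * pv[0] + e1[1] * pv[1] + e1[2] * pv[2];
  if (std::fabs(det) < 1e-14) return false;
  const double inv = 1.0 / det;
  const double tv[3] = {o[0] - a[0], o[1] - a[1], o[2] - a[2]};
  const double u = (tv[0] * pv[0] + tv[1] * pv[1] + tv[2] * pv[2]) * inv;
  if (u < -1e-9 || u > 1 + 1e-9) return false;
  const double qv[3] = {tv[1] * e1[2] - tv[2] * e1[1],
                        tv[2] * e1[0] - tv[0] * e1[2],
                        tv[0] * e1[1] - tv[1] * e1[0]};
  const double v = (d[0] * qv[0] + d[1] * qv[1] + d[2] * qv[2]) * inv;
  if (v < -1e-9 || u + v > 1 + 1e-9) return false;
  t = (e2[0] * qv[0] + e2[1] * qv[1] + e2[2] * qv[2]) * inv;
  return true;
}

struct MeshGrid {
  const double *V;
  const int *Ta, *Tb, *Tc;
  int ntri;
  double lo[3], cell;
  int nc[3];
  std::vector<std::vector<int>> cells;
  std::vector<int> stamp;
  int cur_stamp = 0;

  void build(const NumericMatrix &verts, const IntegerMatrix &tris) {
    V = REAL(verts);
    nvert = verts.nrow();
    ntri = tris.nrow();
    ta.assign(ntri, 0); tb.assign(ntri, 0); tc.assign(ntri, 0);
    for (int m = 0; m < ntri; ++m) {
      ta[m] = tris(m, 0) - 1;
      tb[m] = tris(m, 1) - 1;
      tc[m] = tris(m, 2) - 1;
    }
    double hi[3];
    for (int m = 0; m < 3; ++m) {
      lo[m] = std::numeric_limits<double>::infinity();
      hi[m] = -lo[m];
    }
    for (int i = 0; i < nvert; ++i)
      for (int m = 0; m < 3; ++m) {
        const double x = V[i + (R_xlen_t)nvert * m];
        if (x < lo[m]) lo[m] = x;
        if (x > hi[m]) hi[m] = x;
      }
    double ext = 0;
    for (int m = 0; m < 3; ++m) ext = std::max(ext, hi[m] - lo[m]);
    int target = std::max(8, std::min(160, (int)(std::sqrt((double)ntri) / 2)));
    cell = std::max(ext / target, 1e-9);
    for (int m = 0; m < 3; ++m) {
      lo[m] -= 0.5 * cell;
      nc[m] = std::max(1, (int)std::ceil((hi[m] - lo[m] + cell) / cell));
    }
    cells.assign((size_t)nc[0] * nc[1] * nc[2], {});
    stamp.assign(ntri, -1);
    for (int m = 0; m < ntri; ++m) {
      int cmin[3], cmax[3];
      tri_bounds(m, cmin, cmax);
      for (int k = cmin[2]; k <= cmax[2]; ++k)
        for (int j = cmin[1]; j <= cmax[1]; ++j)
          for (int i = cmin[0]; i <= cmax[0]; ++i)
            cells[cell_idx(i, j, k)].push_back(m);
    }
  }

  int nvert;
  std::vector<int> ta, tb, tc;

  inline size_t cell_idx(int i, int j, int k) const {
    return (size_t)i + (size_t)nc[0] * ((size_t)j + (size_t)nc[1] * k);
  }
  inline int clampc(int v, int ax) const {
    return v < 0 ? 0 : (v >= nc[ax] ? nc[ax] - 1 : v);
  }
  inline void vert(int id, double p[3]) const {
    p[0] = V[id];
    p[1] = V[id + (R_xlen_t)nvert];
    p[2] = V[id + 2 * (R_xlen_t)nvert];
  }
  void tri_bounds(int m, int cmin[3], int cmax[3]) const {
    double a[3], b[3], c[3];
    vert(ta[m], a); vert(tb[m], b); vert(tc[m], c);
    for (int ax = 0; ax < 3; ++ax) {
      const double mn = std::min(a[ax], std::min(b[ax], c[ax]));
      const double mx = std::max(a[ax], std::max(b[ax], c[ax]));
      cmin[ax] = clampc((int)std::floor((mn - lo[ax]) / cell), ax);
      cmax[ax] = clampc((int)std::floor((mx - lo[ax]) / cell), ax);
    }
  }

  void closest(const double p[3], double out[3], double &best_d, int &best_t) {
    int ci[3];
    for (int ax = 0; ax < 3; ++ax)
      ci[ax] = clampc((int)std::floor((p[ax] - lo[ax]) / cell), ax);
    best_d = std::numeric_limits<double>::infinity();
    best_t = -1;
    ++cur_stamp;
    const int max_ring =
        std::max(nc[0], std::max(nc[1], nc[2]));
    for (int r = 0; r <= max_ring; ++r) {
      // unvisited cells (Chebyshev ring >= r) are at least (r-1)*cell away
      if (best_t >= 0 && best_d <= (double)(r - 1) * cell) break;
      const int i0 = std::max(0, ci[0] - r), i1 = std::min(nc[0] - 1, ci[0] + r);
      const int j0 = std::max(0, ci[1] - r), j1 = std::min(nc[1] - 1, ci[1] + r);
      const int k0 = std::max(0, ci[2] - r), k1 = std::min(nc[2] - 1, ci[2] + r);
      for (int k = k0; k <= k1; ++k)
        for (int j = j0; j <= j1; ++j)
          for (int i = i0; i <= i1; ++i) {
            // only the shell of the ring
            if (r > 0 && i != i0 && i != i1 && j != j0 && j != j1 && k != k0 &&
                k != k1)
              continue;
            if (r > 0 &&
                std::max(std::abs(i - ci[0]),
                         std::max(std::abs(j - ci[1]), std::abs(k - ci[2]))) !=
                    r)
              continue;
            for (int m : cells[cell_idx(i, j, k)]) {
              if (stamp[m] == cur_stamp) continue;
              stamp[m] = cur_stamp;
              double a[3], b[3], c[3], q[3];
              vert(ta[m], a); vert(tb[m], b); vert(tc[m], c);
              tri_closest(p, a, b, c, q);
              const double dx = q[0] - p[0], dy = q[1] - p[1], dz = q[2] - p[2];
              const double d = std::sqrt(dx * dx + dy * dy + dz * dz);
              if (d < best_d) {
                best_d = d;
                best_t = m;
                out[0] = q[0]; out[1] = q[1]; out[2] = q[2];
              }
            }
          }
    }
  }

  // min-|t| signed hit along +/- dir within max_dist; returns NA if none
  double raycast(const double o[3], const double d[3], double max_dist) {
    double best = NA_REAL, best_abs = max_dist;
    ++cur_stamp;
    int cmin[3], cmax[3];
    for (int ax = 0; ax < 3; ++ax) {
      const double mn = o[ax] - max_dist * std::fabs(d[ax]) - 1e-9;
      const double mx = o[ax] + max_dist * std::fabs(d[ax]) + 1e-9;
      cmin[ax] = clampc((int)std::floor((mn - lo[ax]) / cell), ax);
      cmax[ax] = clampc((int)std::floor((mx - lo[ax]) / cell), ax);
    }
    for (int k = cmin[2]; k <= cmax[2]; ++k)
      for (int j = cmin[1]; j <= cmax[1]; ++j)
        for (int i = cmin[0]; i <= cmax[0]; ++i)
          for (int m : cells[cell_idx(i, j, k)]) {
            if (stamp[m] == cur_stamp) continue;
            stamp[m] = cur_stamp;
            double a[3], b[3], c[3], t;
            vert(ta[m], a); vert(tb[m], b); vert(tc[m], c);
            if (ray_tri(o, d, a, b, c, t) && std::fabs(t) <= best_abs) {
              best_abs = std::fabs(t);
              best = t;
            }
          }
    return best;
  }
};

}  // namespace

// [[Rcpp::export]]
List mesh_closest_cpp(NumericMatrix query, NumericMatrix verts,
                      IntegerMatrix tris) {
  MeshGrid g;
  g.build(verts, tris);
  const int n = query.nrow();
  NumericVector dist(n);
  IntegerVector tri(n);
  NumericMatrix pts(n, 3);
  for (int i = 0; i < n; ++i) {
    double p[3] = {query(i, 0), query(i, 1), query(i, 2)};
    double q[3], d;
    int t;
    g.closest(p, q, d, t);
    dist[i] = d;
    tri[i] = t + 1;
    pts(i, 0) = q[0]; pts(i, 1) = q[1]; pts(i, 2) = q[2];
  }
  return List::create(_["dist"] = dist, _["point"] = pts, _["triangle"] = tri);
}

// [[Rcpp::export]]
NumericVector mesh_raycast_cpp(NumericMatrix orig, NumericMatrix dirs,
                               NumericMatrix verts, IntegerMatrix tris,
                               double max_dist) {
  MeshGrid g;
  g.build(verts, tris);
  const int n = orig.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double o[3] = {orig(i, 0), orig(i, 1), orig(i, 2)};
    double d[3] = {dirs(i, 0), dirs(i, 1), dirs(i, 2)};
    out[i] = g.raycast(o, d, max_dist);
  }
  return out;
}
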