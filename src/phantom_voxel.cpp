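#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Occupancy sampling for the cup solid family:
//   intersect( spherical shell r_in <= |q| <= r_out,
//              optional half-space dot(q, n) >= off )
//   minus union of spheres (the displaced articulating head(s)).
// Points are mapped world -> solid frame by q = Rt * (p - t), where `rot`
// holds R row-major (the solid's frame rotation) and Rt its transpose is
// applied here.  Occupancy per voxel is the fraction of supersample points
// inside the material.
// [[Rcpp::export]]
NumericVector cup_occupancy_cpp(IntegerVector dims, NumericVector voxel,
                                NumericVector origin, int supersample,
                                double r_in, double r_out,
                                NumericVector plane_n, double plane_off,
                                NumericMatrix sub_spheres,
                                NumericVector rot, NumericVector trans) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double vx = voxel[0], vy = voxel[1], vz = voxel[2];
  const double ox = origin[0], oy = origin[1], oz = origin[2];
  const int ss = supersample < 1 ? 1 : supersample;
  const double inv_ss3 = 1.0 / double(ss * ss * ss);
  const bool has_plane = std::sqrt(plane_n[0] * plane_n[0] +
                                   plane_n[1] * plane_n[1] +
                                   plane_n[2] * plane_n[2]) > 1e-12;
  const int nsub = sub_spheres.nrow();

  // rotation transpose (world -> solid)
  double R[9];
  for (int i = 0; i < 9; ++i) R[i] = rot[i];

  std::vector<double> offs(ss);
  for (int s = 0; s < ss; ++s) offs[s] = ((s + 0.5) / double(ss) - 0.5);

  NumericVector out((R_xlen_t)nx * ny * nz);
  const double r_in2 = r_in * r_in, r_out2 = r_out * r_out;

  R_xlen_t idx = 0;
  for (int k = 0; k < nz; ++k) {
    const double zc = oz + k * vz;
    for (int j = 0; j < ny; ++j) {
      const double yc = oy + j * vy;
      for (int i = 0; i < nx; ++i, ++idx) {
        const double xc = ox + i * vx;
        int cnt = 0;
        for (int sz = 0; sz < ss; ++sz) {
          const double pz = zc + offs[sz] * vz - trans[2];
          for (int sy = 0; sy < ss; ++sy) {
            const double py = yc + offs[sy] * vy - trans[1];
            for (int sx = 0; sx < ss; ++sx) {
              const double px = xc + offs[sx] * vx - trans[0];
              // q = R^T * p  (rot stored row-major as solid frame rotation)
              const double qx = R[0] * px + R[3] * py + R[6] * pz;
              const double qy = R[1] * px + R[4] * py + R[7] * pz;
              const double qz = R[2] * px + R[5] * py + R[8] * pz;
              const double rr2 = qx * qx + qy * qy + qz * qz;
              if (rr2 < r_in2 || rr2 > r_out2) continue;
              if (has_plane &&
                  qx * plane_n[0] + qy * plane_n[1] + qz * plane_n[2] <
                      plane_off)
                continue;
              bool removed = false;
              for (int m = 0; m < nsub; ++m) {
                const double dx = qx - sub_spheres(m, 0);
                const double dy = qy - sub_spheres(m, 1);
                const double dz = qz - sub_spheres(m, 2);
                const double r = sub_spheres(m, 3);
                if (dx * dx + dy * dy + dz * dz < r * r) {
                  removed = true;
                  break;
                }
              }
              if (!removed) ++cnt;
            }
          }
        }
        out[idx] = cnt * inv_ss3;
      }
    }
  }
  return out;
}

// Separable 3D Gaussian blur, sigma in voxel units, zero outside the grid.
// [[Rcpp::export]]
NumericVector gauss_blur3_cpp(NumericVector vol, IntegerVector dims,
                              double sigma) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (sigma <= 0) return clone(vol);

  const int rad = std::max(1, (int)std::ceil(4.0 * sigma));
  std::vector<double> ker(2 * rad + 1);
  double ksum = 0;
  for (int m = -rad; m <= rad; ++m) {
    ker[m + rad] = std::exp(-0.5 * m * m / (sigma * sigma));
    ksum += ker[m + rad];
  }
  for (double &k : ker) k /= ksum;

  std::vector<double> a(vol.begin(), vol.end()), b(n);

  // pass along x
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      const R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
      for (int i = 0; i < nx; ++i) {
        double acc = 0;
        const int lo = std::max(0, i - rad), hi = std::min(nx - 1, i + rad);
        for (int m = lo; m <= hi; ++m) acc += a[base + m] * ker[m - i + rad];
        b[base + i] = acc;
      }
    }
  // pass along y
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      const R_xlen_t base = i + (R_xlen_t)nx * ny * k;
      for (int j = 0; j < ny; ++j) {
        double acc = 0;
        const int lo = std::max(0, j - rad), hi = std::min(ny - 1, j + rad);
        for (int m = lo; m <= hi; ++m)
          acc += b[base + (R_xlen_t)nx * m] * ker[m - j + rad];
        a[base + (R_xlen_t)nx * j] = acc;
      }
    }
  // pass along z
  NumericVector out(n);
  const R_xlen_t nxy = (R_xlen_t)nx * ny;
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      const R_xlen_t base = i + (R_xlen_t)nx * j;
      for (int k = 0; k < nz; ++k) {
        double acc = 0;
        const int lo = std::max(0, k - rad), hi = std::min(nz - 1, k + rad);
        for (int m = lo; m <= hi; ++m) acc += a[base + nxy * m] * ker[m - k + rad];
        out[base + nxy * k] = acc;
      }
    }
  return out;
}
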