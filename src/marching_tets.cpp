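#include <Rcpp.h>
#include <cmath>
#include <unordered_map>
#include <vector>
using namespace Rcpp;

// Iso-surface extraction by marching tetrahedra on a 6-tet cube
// decomposition sharing the main diagonal.  Vertices are placed on lattice
// edges by linear interpolation of the gray values (sub-voxel), welded via
// an edge hash, and triangles oriented so normals point from material
// (value >= iso) toward background.  The decomposition's face diagonals
// match between neighbouring cubes, so the output is watertight whenever
// the iso-surface does not touch the grid boundary.

namespace {

const int CO[8][3] = {{0, 0, 0}, {1, 0, 0}, {0, 1, 0}, {1, 1, 0},
                      {0, 0, 1}, {1, 0, 1}, {0, 1, 1}, {1, 1, 1}};
// six tetrahedra around the 0-7 diagonal (axis-permutation paths)
const int TETS[6][4] = {{0, 1, 3, 7}, {0, 1, 5, 7}, {0, 2, 3, 7},
                        {0, 2, 6, 7}, {0, 4, 5, 7}, {0, 4, 6, 7}};

struct Extractor {
  const double *vol;
  int nx, ny, nz;
  double iso, vx, vy, vz, ox, oy, oz;
  std::unordered_map<uint64_t, int> edge_map;
  std::vector<double> V;  // x,y,z per vertex
  std::vector<int> T;     // 0-based vertex triples

  inline double val(uint64_t g) const { return vol[g]; }
  inline void node_pos(uint64_t g, double p[3]) const {
    const int i = (int)(g % nx);
    const int j = (int)((g / nx) % ny);
    const int k = (int)(g / ((uint64_t)nx * ny));
    p[0] = ox + i * vx;
    p[1] = oy + j * vy;
    p[2] = oz + k * vz;
  }

  int edge_vertex(uint64_t ga, uint64_t gb) {
    if (ga > gb) std::swap(ga, gb);
    const uint64_t key = ga * (uint64_t)nx * ny * nz + gb;
    auto it = edge_map.find(key);
    if (it != edge_map.end()) return it->second;
    const double va = val(ga), vb = val(gb);
    double t = (iso - va) / (vb - va);
    if (t < 1e-8) t = 1e-8;
    if (t > 1 - 1e-8) t = 1 - 1e-8;
    double pa[3], pb[3];
    node_pos(ga, pa);
    node_pos(gb, pb);
    const int id = (int)(V.size() / 3);
    V.push_back(pa[0] + t * (pb[0] - pa[0]));
    V.push_back(pa[1] + t * (pb[1] - pa[1]));
    V.push_back(pa[2] + t * (pb[2] - pa[2]));
    edge_map.emplace(key, id);
    return id;
  }

  void add_tri(int a, int b, int c, const double dir[3]) {
    if (a == b || b == c || a == c) return;
    const double *pa = &V[3 * a], *pb = &V[3 * b], *pc = &V[3 * c];
    const double u[3] = {pb[0] - pa[0], pb[1] - pa[1], pb[2] - pa[2]};
    const double w[3] = {pc[0] - pa[0], pc[1] - pa[1], pc[2] - pa[2]};
    const double n0 = u[1] * w[2] - u[2] * w[1];
    const double n1 = u[2] * w[0] - u[0] * w[2];
    const double n2 = u[0] * w[1] - u[1] * w[0];
    if (n0 * dir[0] + n1 * dir[1] + n2 * dir[2] < 0) std::swap(b, c);
    T.push_back(a);
    T.push_back(b);
    T.push_back(c);
  }

  void do_tet(const uint64_t g[4], const double v[4]) {
    int in[4], out[4], ni = 0, no = 0;
    for (int m = 0; m < 4; ++m) {
      if (v[m] >= iso)
        in[ni++] = m;
      else
        out[no++] = m;
    }
    if (ni == 0 || ni == 4) return;
    // orientation reference: inside centroid -> outside centroid
    double ci[3] = {0, 0, 0}, co[3] = {0, 0, 0}, p[3];
    for (int m = 0; m < ni; ++m) {
      node_pos(g[in[m]], p);
      ci[0] += p[0] / ni;
      ci[1] += p[1] / ni;
      ci[2] += p[2] / ni;
    }
    for (int m = 0; m < no; ++m) {
      node_pos(g[out[m]], p);
      co[0] += p[0] / no;
      co[1] += p[1] / no;
      co[2] += p[2] / no;
    }
    const double dir[3] = {co[0] - ci[0], co[1] - ci[1], co[2] - ci[2]};
    if (ni == 1) {
      const int a = edge_vertex(g[in[0]], g[out[0]]);
      const int b = edge_vertex(g[in[0]], g[out[1]]);
      const int c = edge_vertex(g[in[0]], g[out[2]]);
      add_tri(a, b, c, dir);
    } else if (ni == 3) {
      const int a = edge_vertex(g[out[0]], g[in[0]]);
      const int b = edge_vertex(g[out[0]], g[in[1]]);
      const int c = edge_vertex(g[out[0]], g[in[2]]);
      add_tri(a, b, c, dir);
    } else {  // ni == 2
      const int a = edge_vertex(g[in[0]], g[out[0]]);
      const int b = edge_vertex(g[in[0]], g[out[1]]);
      const int c = edge_vertex(g[in[1]], g[out[1]]);
      const int d = edge_vertex(g[in[1]], g[out[0]]);
      add_tri(a, b, c, dir);
      add_tri(a, c, d, dir);
    }
  }
};

}  // namespace

// [[Rcpp::export]]
List marching_tets_cpp(NumericVector vol, IntegerVector dims, double iso,
                       NumericVector voxel, NumericVector origin) {
  Extractor ex;
  ex.vol = REAL(vol);
  ex.nx = dims[0];
  ex.ny = dims[1];
  ex.nz = dims[2];
  ex.iso = iso;
  ex.vx = voxel[0];
  ex.vy = voxel[1];
  ex.vz = voxel[2];
  ex.ox = origin[0];
  ex.oy = origin[1];
  ex.oz = origin[2];

  const int nx = ex.nx, ny = ex.ny, nz = ex.nz;
  uint64_t g[8], tg[4];
  double v[8], tv[4];
  for (int k = 0; k + 1 < nz; ++k)
    for (int j = 0; j + 1 < ny; ++j)
      for (int i = 0; i + 1 < nx; ++i) {
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) {
          g[c] = (uint64_t)(i + CO[c][0]) +
                 (uint64_t)nx * ((j + CO[c][1]) + (uint64_t)ny * (k + CO[c][2]));
          v[c] = ex.vol[g[c]];
          if (v[c] >= iso)
            any_in = true;
          else
            any_out = true;
        }
        if (!any_in || !any_out) continue;
        for (int t = 0; t < 6; ++t) {
          for (int m = 0; m < 4; ++m) {
            tg[m] = g[TETS[t][m]];
            tv[m] = v[TETS[t][m]];
          }
          ex.do_tet(tg, tv);
        }
      }

  const int nv = (int)(ex.V.size() / 3), nt = (int)(ex.T.size() / 3);
  NumericMatrix verts(nv, 3);
  for (int m = 0; m < nv; ++m) {
    verts(m, 0) = ex.V[3 * m];
    verts(m, 1) = ex.V[3 * m + 1];
    verts(m, 2) = ex.V[3 * m + 2];
  }
  IntegerMatrix tris(nt, 3);
  for (int m = 0; m < nt; ++m) {
    tris(m, 0) = ex.T[3 * m] + 1;
    tris(m, 1) = ex.T[3 * m + 1] + 1;
    tris(m, 2) = ex.T[3 * m + 2] + 1;
  }
  return List::create(_["vertices"] = verts, _["triangles"] = tris);
}
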