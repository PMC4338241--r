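// Isosurface extraction from a regular scalar grid.
//
// Marching-cubes family extractor using a six-tetrahedron decomposition of
// each cell (all tetrahedra share the cell's main diagonal, so the
// triangulation is crack-free without case tables). Intersections are placed
// by linear interpolation along tetrahedron edges; every intersection lies on
// a segment between two grid corners, so vertices are welded by the global
// corner-id pair of their supporting edge, giving shared (manifold)
// connectivity. Triangles are wound so normals point out of the region with
// intensity above the iso level.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>
#include <cmath>

using namespace Rcpp;

namespace {

struct P3 { double x, y, z; };

// six tetrahedra on cube corners indexed by bits (x + 2y + 4z),
// each containing the main diagonal 0-7
const int TETS[6][4] = {
  {0, 1, 3, 7}, {0, 3, 2, 7}, {0, 2, 6, 7},
  {0, 6, 4, 7}, {0, 4, 5, 7}, {0, 5, 1, 7}
};

struct Extractor {
  std::unordered_map<uint64_t, int> edge_vertex;
  std::vector<double> vx, vy, vz;
  std::vector<int> fa, fb, fc;

  int vertex_on_edge(int64_t g0, int64_t g1, P3 p0, P3 p1,
                     double f0, double f1, double iso) {
    if (g1 < g0) { std::swap(g0, g1); std::swap(p0, p1); std::swap(f0, f1); }
    uint64_t key = (uint64_t)g0 * 0x100000000ULL ^ (uint64_t)g1;
    auto it = edge_vertex.find(key);
    if (it != edge_vertex.end()) return it->second;
    double t = (iso - f0) / (f1 - f0);
    if (t < 0.0) t = 0.0;
    if (t > 1.0) t = 1.0;
    int id = (int)vx.size();
    vx.push_back(p0.x + t * (p1.x - p0.x));
    vy.push_back(p0.y + t * (p1.y - p0.y));
    vz.push_back(p0.z + t * (p1.z - p0.z));
    edge_vertex.emplace(key, id);
    return id;
  }

  // append triangle (i, j, k), flipping so the normal points away from the
  // interior witness point w
  void add_tri(int i, int j, int k, const P3& w) {
    if (i == j || j == k || i == k) return;
    double ax = vx[j] - vx[i], ay = vy[j] - vy[i], az = vz[j] - vz[i];
    double bx = vx[k] - vx[i], by = vy[k] - vy[i], bz = vz[k] - vz[i];
    double nx = ay * bz - az * by, ny = az * bx - ax * bz, nz = ax * by - ay * bx;
    double cx = (vx[i] + vx[j] + vx[k]) / 3.0 - w.x;
    double cy = (vy[i] + vy[j] + vy[k]) / 3.0 - w.y;
    double cz = (vz[i] + vz[j] + vz[k]) / 3.0 - w.z;
    if (nx * cx + ny * cy + nz * cz < 0.0) std::swap(j, k);
    fa.push_back(i); fb.push_back(j); fc.push_back(k);
  }
};

} // namespace

// [[Rcpp::export(name = ".cpp_isosurface")]]
List cpp_isosurface(NumericVector grid, IntegerVector dims, NumericVector spacing,
                    NumericVector origin, double iso) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  const double ox = origin[0], oy = origin[1], oz = origin[2];
  const double* g = grid.begin();
  const double nudge = 1e-6 * (1.0 + std::fabs(iso));

  Extractor ex;
  auto gid = [&](int i, int j, int k) -> int64_t {
    return (int64_t)i + (int64_t)nx * ((int64_t)j + (int64_t)ny * k);
  };

  std::vector<int64_t> cg(8);
  std::vector<P3> cp(8);
  std::vector<double> cf(8);

  for (int k = 0; k + 1 < nz; ++k) {
    for (int j = 0; j + 1 < ny; ++j) {
      for (int i = 0; i + 1 < nx; ++i) {
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) {
          int di = c & 1, dj = (c >> 1) & 1, dk = (c >> 2) & 1;
          int64_t id = gid(i + di, j + dj, k + dk);
          double f = g[id];
          if (f == iso) f = iso + nudge;
          cg[c] = id;
          cf[c] = f;
          cp[c] = {ox + (i + di) * sx, oy + (j + dj) * sy, oz + (k + dk) * sz};
          if (f > iso) any_in = true; else any_out = true;
        }
        if (!any_in || !any_out) continue;

        for (int tt = 0; tt < 6; ++tt) {
          const int* T = TETS[tt];
          int in_idx[4], out_idx[4], ni = 0, no = 0;
          for (int v = 0; v < 4; ++v) {
            if (cf[T[v]] > iso) in_idx[ni++] = T[v]; else out_idx[no++] = T[v];
          }
          if (ni == 0 || ni == 4) continue;

          auto ev = [&](int a, int b) {
            return ex.vertex_on_edge(cg[a], cg[b], cp[a], cp[b], cf[a], cf[b], iso);
          };

          if (ni == 1) {
            int A = in_idx[0];
            P3 w = cp[A];
            ex.add_tri(ev(A, out_idx[0]), ev(A, out_idx[1]), ev(A, out_idx[2]), w);
          } else if (ni == 3) {
            int D = out_idx[0];
            // witness inside: centroid of the three interior corners
            P3 w = {(cp[in_idx[0]].x + cp[in_idx[1]].x + cp[in_idx[2]].x) / 3.0,
                    (cp[in_idx[0]].y + cp[in_idx[1]].y + cp[in_idx[2]].y) / 3.0,
                    (cp[in_idx[0]].z + cp[in_idx[1]].z + cp[in_idx[2]].z) / 3.0};
            ex.add_tri(ev(in_idx[0], D), ev(in_idx[1], D), ev(in_idx[2], D), w);
          } else { // ni == 2, quad split into two triangles
            int A = in_idx[0], B = in_idx[1], C = out_idx[0], D = out_idx[1];
            P3 w = {(cp[A].x + cp[B].x) / 2.0, (cp[A].y + cp[B].y) / 2.0,
                    (cp[A].z + cp[B].z) / 2.0};
            int vAC = ev(A, C), vAD = ev(A, D), vBD = ev(B, D), vBC = ev(B, C);
            ex.add_tri(vAC, vAD, vBD, w);
            ex.add_tri(vAC, vBD, vBC, w);
          }
        }
      }
    }
  }

  int nv = (int)ex.vx.size(), nf = (int)ex.fa.size();
  NumericMatrix V(nv, 3);
  for (int v = 0; v < nv; ++v) {
    V(v, 0) = ex.vx[v]; V(v, 1) = ex.vy[v]; V(v, 2) = ex.vz[v];
  }
  IntegerMatrix F(nf, 3);
  for (int f = 0; f < nf; ++f) {
    F(f, 0) = ex.fa[f] + 1; F(f, 1) = ex.fb[f] + 1; F(f, 2) = ex.fc[f] + 1;
  }
  return List::create(_["vertices"] = V, _["faces"] = F);
}
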