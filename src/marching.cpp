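#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <cstdint>

using namespace Rcpp;

// Isosurface extraction by marching tetrahedra: each grid cube is split into
// six tetrahedra sharing the main diagonal, a decomposition that is mirror-
// consistent across cube faces, so closed level sets give watertight meshes.
// Vertices are placed on tetrahedron edges by linear interpolation and shared
// through an edge->vertex map. Coordinates are 0-based voxel indices.

struct EdgeKey {
  uint64_t k;
  bool operator==(const EdgeKey& o) const { return k == o.k; }
};
struct EdgeHash {
  size_t operator()(const EdgeKey& e) const { return std::hash<uint64_t>()(e.k); }
};

// [[Rcpp::export]]
List cpp_march_tetra(NumericVector field, IntegerVector dim, double level) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double* F = REAL(field);
  const R_xlen_t sy = nx, sz = (R_xlen_t)nx * ny;

  // cube corner offsets (x, y, z)
  static const int CO[8][3] = {
    {0,0,0},{1,0,0},{1,1,0},{0,1,0},{0,0,1},{1,0,1},{1,1,1},{0,1,1}};
  // six tetrahedra around the 0-6 diagonal
  static const int TET[6][4] = {
    {0,5,1,6},{0,1,2,6},{0,2,3,6},{0,3,7,6},{0,7,4,6},{0,4,5,6}};

  std::vector<double> vx, vy, vz;
  std::vector<int> tri;
  std::unordered_map<EdgeKey, int, EdgeHash> emap;
  emap.reserve(1 << 16);

  auto edge_vertex = [&](R_xlen_t ia, R_xlen_t ib, int ax, int ay, int az,
                         int bx, int by, int bz) -> int {
    EdgeKey key;
    if (ia > ib) { std::swap(ia, ib); std::swap(ax, bx); std::swap(ay, by); std::swap(az, bz); }
    key.k = (uint64_t)ia * (uint64_t)(sz * nz + 1) + (uint64_t)ib;
    auto it = emap.find(key);
    if (it != emap.end()) return it->second;
    double fa = F[ia], fb = F[ib];
    double t = (level - fa) / (fb - fa);
    if (t < 0) t = 0; if (t > 1) t = 1;
    int id = (int)vx.size();
    vx.push_back(ax + t * (bx - ax));
    vy.push_back(ay + t * (by - ay));
    vz.push_back(az + t * (bz - az));
    emap.emplace(key, id);
    return id;
  };

  R_xlen_t cidx[8];
  int cpos[8][3];
  double cval[8];

  for (int k = 0; k + 1 < nz; ++k) {
    for (int j = 0; j + 1 < ny; ++j) {
      for (int i = 0; i + 1 < nx; ++i) {
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) {
          int x = i + CO[c][0], y = j + CO[c][1], z = k + CO[c][2];
          R_xlen_t idx = x + sy * y + sz * z;
          cidx[c] = idx;
          cpos[c][0] = x; cpos[c][1] = y; cpos[c][2] = z;
          double v = F[idx];
          cval[c] = v;
          if (v > level) any_in = true; else any_out = true;
        }
        if (!any_in || !any_out) continue;
        for (int t = 0; t < 6; ++t) {
          int in[4], out[4], ni = 0, no = 0;
          for (int c = 0; c < 4; ++c) {
            int v = TET[t][c];
            if (cval[v] > level) in[ni++] = v; else out[no++] = v;
          }
          if (ni == 0 || ni == 4) continue;
          if (ni == 1 || ni == 3) {
            // one vertex isolated -> single triangle on the 3 edges from it
            int apex = (ni == 1) ? in[0] : out[0];
            int* others = (ni == 1) ? out : in;
            int e[3];
            for (int c = 0; c < 3; ++c)
              e[c] = edge_vertex(cidx[apex], cidx[others[c]],
                                 cpos[apex][0], cpos[apex][1], cpos[apex][2],
                                 cpos[others[c]][0], cpos[others[c]][1], cpos[others[c]][2]);
            tri.push_back(e[0]); tri.push_back(e[1]); tri.push_back(e[2]);
          } else {
            // two-two split -> quad from the 4 crossing edges -> 2 triangles
            int e00 = edge_vertex(cidx[in[0]], cidx[out[0]],
                                  cpos[in[0]][0], cpos[in[0]][1], cpos[in[0]][2],
                                  cpos[out[0]][0], cpos[out[0]][1], cpos[out[0]][2]);
            int e01 = edge_vertex(cidx[in[0]], cidx[out[1]],
                                  cpos[in[0]][0], cpos[in[0]][1], cpos[in[0]][2],
                                  cpos[out[1]][0], cpos[out[1]][1], cpos[out[1]][2]);
            int e10 = edge_vertex(cidx[in[1]], cidx[out[0]],
                                  cpos[in[1]][0], cpos[in[1]][1], cpos[in[1]][2],
                                  cpos[out[0]][0], cpos[out[0]][1], cpos[out[0]][2]);
            int e11 = edge_vertex(cidx[in[1]], cidx[out[1]],
                                  cpos[in[1]][0], cpos[in[1]][1], cpos[in[1]][2],
                                  cpos[out[1]][0], cpos[out[1]][1], cpos[out[1]][2]);
            tri.push_back(e00); tri.push_back(e01); tri.push_back(e11);
            tri.push_back(e00); tri.push_back(e11); tri.push_back(e10);
          }
        }
      }
    }
  }

  int nv = (int)vx.size();
  NumericMatrix V(nv, 3);
  for (int v = 0; v < nv; ++v) { V(v, 0) = vx[v]; V(v, 1) = vy[v]; V(v, 2) = vz[v]; }
  int nt = (int)tri.size() / 3;
  IntegerMatrix T(nt, 3);
  for (int t = 0; t < nt; ++t) {
    T(t, 0) = tri[3 * t] + 1;        // 1-based for R
    T(t, 1) = tri[3 * t + 1] + 1;
    T(t, 2) = tri[3 * t + 2] + 1;
  }
  return List::create(_["vertices"] = V, _["triangles"] = T);
}
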