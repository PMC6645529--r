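#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

// 6-connected component labelling of TRUE voxels (BFS). Labels 1..K, 0 elsewhere.
// [[Rcpp::export]]
IntegerVector cpp_label6(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t N = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(N, 0);
  std::vector<R_xlen_t> queue;
  queue.reserve(1 << 16);
  int next = 0;
  const R_xlen_t sy = nx, sz = (R_xlen_t)nx * ny;
  for (R_xlen_t s = 0; s < N; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++next;
    lab[s] = next;
    queue.clear();
    queue.push_back(s);
    while (!queue.empty()) {
      R_xlen_t p = queue.back();
      queue.pop_back();
      int i = p % nx;
      int j = (p / nx) % ny;
      int k = p / sz;
      R_xlen_t nb[6];
      int nn = 0;
      if (i > 0)      nb[nn++] = p - 1;
      if (i < nx - 1) nb[nn++] = p + 1;
      if (j > 0)      nb[nn++] = p - sy;
      if (j < ny - 1) nb[nn++] = p + sy;
      if (k > 0)      nb[nn++] = p - sz;
      if (k < nz - 1) nb[nn++] = p + sz;
      for (int q = 0; q < nn; ++q) {
        R_xlen_t t = nb[q];
        if (mask[t] && !lab[t]) {
          lab[t] = next;
          queue.push_back(t);
        }
      }
    }
  }
  lab.attr("n_components") = next;
  return lab;
}

// TRUE for voxels of `mask` having a 6-neighbour voxel with labels == lab.
// Out-of-grid neighbours are ignored (grid faces are not treated as surface).
// [[Rcpp::export]]
LogicalVector cpp_adjacent_to(LogicalVector mask, IntegerVector labels, int lab,
                              IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t N = (R_xlen_t)nx * ny * nz;
  const R_xlen_t sy = nx, sz = (R_xlen_t)nx * ny;
  LogicalVector out(N, false);
  for (R_xlen_t p = 0; p < N; ++p) {
    if (!mask[p]) continue;
    int i = p % nx;
    int j = (p / nx) % ny;
    int k = p / sz;
    bool hit =
      (i > 0      && labels[p - 1]  == lab) ||
      (i < nx - 1 && labels[p + 1]  == lab) ||
      (j > 0      && labels[p - sy] == lab) ||
      (j < ny - 1 && labels[p + sy] == lab) ||
      (k > 0      && labels[p - sz] == lab) ||
      (k < nz - 1 && labels[p + sz] == lab);
    if (hit) out[p] = true;
  }
  return out;
}
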