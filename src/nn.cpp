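#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// For every row of A (n x 3) the Euclidean distance to the nearest row of
// B (m x 3), via a uniform spatial hash grid on B (points live in voxel
// coordinates, typical nearest distances are below a few voxels).
// [[Rcpp::export]]
NumericVector cpp_nn_dist(NumericMatrix A, NumericMatrix B, double cell) {
  const int n = A.nrow(), m = B.nrow();
  NumericVector out(n);
  if (m == 0) { std::fill(out.begin(), out.end(), R_PosInf); return out; }

  auto key = [](int64_t ix, int64_t iy, int64_t iz) -> int64_t {
    return ((ix + 1048576) << 42) | ((iy + 1048576) << 21) | (iz + 1048576);
  };
  std::unordered_map<int64_t, std::vector<int>> grid;
  grid.reserve(m * 2);
  for (int b = 0; b < m; ++b) {
    int64_t ix = (int64_t)std::floor(B(b, 0) / cell);
    int64_t iy = (int64_t)std::floor(B(b, 1) / cell);
    int64_t iz = (int64_t)std::floor(B(b, 2) / cell);
    grid[key(ix, iy, iz)].push_back(b);
  }

  for (int a = 0; a < n; ++a) {
    double ax = A(a, 0), ay = A(a, 1), az = A(a, 2);
    int64_t cx = (int64_t)std::floor(ax / cell);
    int64_t cy = (int64_t)std::floor(ay / cell);
    int64_t cz = (int64_t)std::floor(az / cell);
    double best = R_PosInf;
    for (int r = 0; ; ++r) {
      // scan the Chebyshev shell of cell radius r
      for (int64_t ix = cx - r; ix <= cx + r; ++ix)
        for (int64_t iy = cy - r; iy <= cy + r; ++iy)
          for (int64_t iz = cz - r; iz <= cz + r; ++iz) {
            if (std::max(std::llabs(ix - cx),
                std::max(std::llabs(iy - cy), std::llabs(iz - cz))) != r)
              continue;
            auto it = grid.find(key(ix, iy, iz));
            if (it == grid.end()) continue;
            for (int b : it->second) {
              double dx = ax - B(b, 0), dy = ay - B(b, 1), dz = az - B(b, 2);
              double d2 = dx * dx + dy * dy + dz * dz;
              if (d2 < best) best = d2;
            }
          }
      // any point in shells > r lies at distance >= r*cell from a
      if (best <= (double)r * cell * (double)r * cell) break;
      if (r > 2100000) break;  // unreachable guard
    }
    out[a] = std::sqrt(best);
  }
  return out;
}
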