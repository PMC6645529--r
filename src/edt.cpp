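#include <Rcpp.h>
#include <vector>
#include <limits>

using namespace Rcpp;

// 1D squared Euclidean distance transform (lower envelope of parabolas),
// Felzenszwalb & Huttenlocher. f: input costs, d: output, n: length.
static void dt1d(const double* f, double* d, int n,
                 std::vector<int>& v, std::vector<double>& z) {
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Squared Euclidean distance (in voxels) from every voxel to the nearest
// TRUE voxel of `site`. Exact, separable, O(N) per axis.
// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector site, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t N = (R_xlen_t)nx * ny * nz;
  // large finite sentinel, not Inf: Inf - Inf = NaN breaks the envelope
  const double FAR = 1e20;
  NumericVector out(N);
  double* D = REAL(out);
  for (R_xlen_t i = 0; i < N; ++i) D[i] = site[i] ? 0.0 : FAR;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along x (stride 1)
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      double* row = D + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
      for (int i = 0; i < nx; ++i) f[i] = row[i];
      dt1d(f.data(), d.data(), nx, v, z);
      for (int i = 0; i < nx; ++i) row[i] = d[i];
    }
  // pass along y (stride nx)
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      double* col = D + i + (R_xlen_t)nx * ny * k;
      for (int j = 0; j < ny; ++j) f[j] = col[(R_xlen_t)nx * j];
      dt1d(f.data(), d.data(), ny, v, z);
      for (int j = 0; j < ny; ++j) col[(R_xlen_t)nx * j] = d[j];
    }
  // pass along z (stride nx*ny)
  const R_xlen_t sz = (R_xlen_t)nx * ny;
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      double* col = D + i + (R_xlen_t)nx * j;
      for (int k = 0; k < nz; ++k) f[k] = col[sz * k];
      dt1d(f.data(), d.data(), nz, v, z);
      for (int k = 0; k < nz; ++k) col[sz * k] = d[k];
    }
  return out;
}
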