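#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// Trilinear sample of src at continuous 0-based (x, y, z); out-of-grid -> fill.
static inline double trilin(const double* S, int nx, int ny, int nz,
                            double x, double y, double z, double fill) {
  if (x < 0 || y < 0 || z < 0 || x > nx - 1 || y > ny - 1 || z > nz - 1)
    return fill;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  if (x0 == nx - 1) --x0;
  if (y0 == ny - 1) --y0;
  if (z0 == nz - 1) --z0;
  double fx = x - x0, fy = y - y0, fz = z - z0;
  const R_xlen_t sy = nx, sz = (R_xlen_t)nx * ny;
  const double* p = S + x0 + sy * y0 + sz * z0;
  double c00 = p[0] * (1 - fx) + p[1] * fx;
  double c10 = p[sy] * (1 - fx) + p[sy + 1] * fx;
  double c01 = p[sz] * (1 - fx) + p[sz + 1] * fx;
  double c11 = p[sz + sy] * (1 - fx) + p[sz + sy + 1] * fx;
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

// Resample `src` under the rigid map: out(x) = src(R (x - c) + c + t),
// R a 3x3 rotation, c the volume centre, t a translation in voxels.
// [[Rcpp::export]]
NumericVector cpp_rigid_resample(NumericVector src, IntegerVector dim,
                                 NumericMatrix R, NumericVector t, double fill) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double* S = REAL(src);
  NumericVector out((R_xlen_t)nx * ny * nz);
  double* O = REAL(out);
  const double cx = (nx - 1) / 2.0, cy = (ny - 1) / 2.0, cz = (nz - 1) / 2.0;
  R_xlen_t p = 0;
  for (int k = 0; k < nz; ++k) {
    double dz = k - cz;
    for (int j = 0; j < ny; ++j) {
      double dy = j - cy;
      for (int i = 0; i < nx; ++i, ++p) {
        double dx = i - cx;
        double sx = R(0,0)*dx + R(0,1)*dy + R(0,2)*dz + cx + t[0];
        double sy_ = R(1,0)*dx + R(1,1)*dy + R(1,2)*dz + cy + t[1];
        double sz_ = R(2,0)*dx + R(2,1)*dy + R(2,2)*dz + cz + t[2];
        O[p] = trilin(S, nx, ny, nz, sx, sy_, sz_, fill);
      }
    }
  }
  return out;
}

// Mean squared intensity difference between `fixed` and the rigidly resampled
// `moving` over every `stride`-th voxel; positions mapped outside the grid
// sample the fill value (so content cannot be hidden off-grid).
// [[Rcpp::export]]
double cpp_rigid_mse(NumericVector moving, NumericVector fixed, IntegerVector dim,
                     NumericMatrix R, NumericVector t, int stride, double fill) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double* M = REAL(moving);
  const double* F = REAL(fixed);
  const double cx = (nx - 1) / 2.0, cy = (ny - 1) / 2.0, cz = (nz - 1) / 2.0;
  double acc = 0.0;
  R_xlen_t n = 0;
  for (int k = 0; k < nz; k += stride) {
    double dz = k - cz;
    for (int j = 0; j < ny; j += stride) {
      double dy = j - cy;
      for (int i = 0; i < nx; i += stride) {
        double dx = i - cx;
        double sx = R(0,0)*dx + R(0,1)*dy + R(0,2)*dz + cx + t[0];
        double sy_ = R(1,0)*dx + R(1,1)*dy + R(1,2)*dz + cy + t[1];
        double sz_ = R(2,0)*dx + R(2,1)*dy + R(2,2)*dz + cz + t[2];
        double v = trilin(M, nx, ny, nz, sx, sy_, sz_, fill);
        double f = F[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)];
        acc += (v - f) * (v - f);
        ++n;
      }
    }
  }
  if (n == 0) return R_PosInf;
  return acc / n;
}

// Separable 1D convolution along one axis (0 = x, 1 = y, 2 = z) with an
// odd-length kernel, reflective (mirror) border handling.
// [[Rcpp::export]]
NumericVector cpp_conv_axis(NumericVector vol, IntegerVector dim,
                            NumericVector kernel, int axis) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int L = kernel.size(), h = L / 2;
  const double* V = REAL(vol);
  const double* K = REAL(kernel);
  NumericVector out((R_xlen_t)nx * ny * nz);
  double* O = REAL(out);
  const R_xlen_t sy = nx, sz = (R_xlen_t)nx * ny;
  int n = (axis == 0) ? nx : (axis == 1) ? ny : nz;
  R_xlen_t stride = (axis == 0) ? 1 : (axis == 1) ? sy : sz;

  R_xlen_t p = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++p) {
        int pos = (axis == 0) ? i : (axis == 1) ? j : k;
        double acc = 0.0;
        for (int q = 0; q < L; ++q) {
          int s = pos + q - h;
          if (s < 0) s = -s - 1;             // half-sample mirror (edge repeated)
          if (s > n - 1) s = 2 * n - 1 - s;
          acc += K[q] * V[p + (R_xlen_t)(s - pos) * stride];
        }
        O[p] = acc;
      }
  return out;
}
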