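// Separable Gaussian filtering, trilinear sampling and bicubic resampling.
// Boundary handling: reflection for filters, clamp-to-edge or constant
// border for samplers (chosen by the caller).

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

std::vector<double> gauss_kernel(double sigma) {
  int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> k(2 * r + 1);
  double s = 0.0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * (double)(i * i) / (sigma * sigma));
    s += k[i + r];
  }
  for (double& v : k) v /= s;
  return k;
}

inline int reflect(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

void conv1_lines(arma::cube& a, const std::vector<double>& k, int axis) {
  const int r = ((int)k.size() - 1) / 2;
  const int nx = a.n_rows, ny = a.n_cols, nz = a.n_slices;
  if (axis == 0) {
    std::vector<double> line(nx);
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y) {
        for (int x = 0; x < nx; ++x) line[x] = a(x, y, z);
        for (int x = 0; x < nx; ++x) {
          double s = 0.0;
          for (int t = -r; t <= r; ++t) s += k[t + r] * line[reflect(x + t, nx)];
          a(x, y, z) = s;
        }
      }
  } else if (axis == 1) {
    std::vector<double> line(ny);
    for (int z = 0; z < nz; ++z)
      for (int x = 0; x < nx; ++x) {
        for (int y = 0; y < ny; ++y) line[y] = a(x, y, z);
        for (int y = 0; y < ny; ++y) {
          double s = 0.0;
          for (int t = -r; t <= r; ++t) s += k[t + r] * line[reflect(y + t, ny)];
          a(x, y, z) = s;
        }
      }
  } else {
    std::vector<double> line(nz);
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        for (int z = 0; z < nz; ++z) line[z] = a(x, y, z);
        for (int z = 0; z < nz; ++z) {
          double s = 0.0;
          for (int t = -r; t <= r; ++t) s += k[t + r] * line[reflect(z + t, nz)];
          a(x, y, z) = s;
        }
      }
  }
}

inline double cubic_cr(double p0, double p1, double p2, double p3, double t) {
  // Catmull-Rom
  return p1 + 0.5 * t * (p2 - p0 +
         t * (2.0 * p0 - 5.0 * p1 + 4.0 * p2 - p3 +
         t * (3.0 * (p1 - p2) + p3 - p0)));
}

}  // namespace

// [[Rcpp::export]]
arma::cube cpp_gauss_blur3(arma::cube a, double sigma) {
  if (sigma <= 0) return a;
  std::vector<double> k = gauss_kernel(sigma);
  conv1_lines(a, k, 0);
  conv1_lines(a, k, 1);
  conv1_lines(a, k, 2);
  return a;
}

// [[Rcpp::export]]
arma::mat cpp_gauss_blur2(const arma::mat& m, double sigma) {
  if (sigma <= 0) return m;
  arma::cube a(m.n_rows, m.n_cols, 1);
  a.slice(0) = m;
  std::vector<double> k = gauss_kernel(sigma);
  conv1_lines(a, k, 0);
  conv1_lines(a, k, 1);
  return a.slice(0);
}

// Trilinear sampling at 0-based voxel coordinates.  border < -1e29 means
// clamp-to-edge, otherwise points outside get the border value.
// [[Rcpp::export]]
NumericVector cpp_sample_trilinear(const arma::cube& a, const arma::mat& pts,
                                   double border) {
  const int nx = a.n_rows, ny = a.n_cols, nz = a.n_slices;
  const bool clamp = border < -1e29;
  NumericVector out(pts.n_rows);
  for (arma::uword p = 0; p < pts.n_rows; ++p) {
    double x = pts(p, 0), y = pts(p, 1), z = pts(p, 2);
    if (!clamp && (x < 0 || y < 0 || z < 0 || x > nx - 1 || y > ny - 1 || z > nz - 1)) {
      out[p] = border;
      continue;
    }
    x = std::min(std::max(x, 0.0), (double)(nx - 1));
    y = std::min(std::max(y, 0.0), (double)(ny - 1));
    z = std::min(std::max(z, 0.0), (double)(nz - 1));
    int i0 = std::min((int)x, nx - 2 >= 0 ? nx - 2 : 0);
    int j0 = std::min((int)y, ny - 2 >= 0 ? ny - 2 : 0);
    int k0 = std::min((int)z, nz - 2 >= 0 ? nz - 2 : 0);
    int i1 = std::min(i0 + 1, nx - 1), j1 = std::min(j0 + 1, ny - 1),
        k1 = std::min(k0 + 1, nz - 1);
    double fx = x - i0, fy = y - j0, fz = z - k0;
    double c00 = a(i0, j0, k0) * (1 - fx) + a(i1, j0, k0) * fx;
    double c10 = a(i0, j1, k0) * (1 - fx) + a(i1, j1, k0) * fx;
    double c01 = a(i0, j0, k1) * (1 - fx) + a(i1, j0, k1) * fx;
    double c11 = a(i0, j1, k1) * (1 - fx) + a(i1, j1, k1) * fx;
    double c0 = c00 * (1 - fy) + c10 * fy;
    double c1 = c01 * (1 - fy) + c11 * fy;
    out[p] = c0 * (1 - fz) + c1 * fz;
  }
  return out;
}

// Catmull-Rom bicubic resize of a matrix onto nr2 x nc2 samples whose
// centres map linearly onto the input index range.
// [[Rcpp::export]]
arma::mat cpp_bicubic_resize(const arma::mat& m, int nr2, int nc2) {
  const int nr = m.n_rows, nc = m.n_cols;
  arma::mat out(nr2, nc2);
  double sr = (nr2 > 1) ? (double)(nr - 1) / (nr2 - 1) : 0.0;
  double sc = (nc2 > 1) ? (double)(nc - 1) / (nc2 - 1) : 0.0;
  auto at = [&](int i, int j) {
    i = std::min(std::max(i, 0), nr - 1);
    j = std::min(std::max(j, 0), nc - 1);
    return m(i, j);
  };
  for (int i = 0; i < nr2; ++i) {
    double ri = i * sr;
    int r0 = (int)std::floor(ri);
    double tr = ri - r0;
    for (int j = 0; j < nc2; ++j) {
      double cj = j * sc;
      int c0 = (int)std::floor(cj);
      double tc = cj - c0;
      double col[4];
      for (int t = -1; t <= 2; ++t)
        col[t + 1] = cubic_cr(at(r0 + t, c0 - 1), at(r0 + t, c0),
                              at(r0 + t, c0 + 1), at(r0 + t, c0 + 2), tc);
      out(i, j) = cubic_cr(col[0], col[1], col[2], col[3], tr);
    }
  }
  return out;
}
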