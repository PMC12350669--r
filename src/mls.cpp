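// Scattered-data interpolation on world-space point clouds.
//
// Local moving-least-squares with a uniform spatial hash for neighbour
// search.  degree 1 ("linear" scheme) fits a weighted affine model to the
// k nearest sites, degree 2 ("natural" scheme) a weighted quadratic; both
// reproduce affine fields exactly and interpolate data sites exactly via
// the coincident-point branch.  Queries whose nearest site lies beyond
// fill_radius return NA (the caller applies its fill policy).

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <unordered_map>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

namespace {

struct HashGrid {
  double h;
  double x0, y0, z0;
  std::unordered_map<long long, std::vector<int> > cells;

  static long long key(long long i, long long j, long long k) {
    // 21 bits per axis; coordinates are offset so indices are small
    return (i << 42) | (j << 21) | k;
  }

  void build(const arma::mat& pts, double cell) {
    h = cell;
    x0 = pts.col(0).min() - h;
    y0 = pts.col(1).min() - h;
    z0 = pts.col(2).min() - h;
    cells.reserve(pts.n_rows / 2 + 8);
    for (arma::uword p = 0; p < pts.n_rows; ++p) {
      long long i = (long long)std::floor((pts(p, 0) - x0) / h);
      long long j = (long long)std::floor((pts(p, 1) - y0) / h);
      long long k = (long long)std::floor((pts(p, 2) - z0) / h);
      cells[key(i, j, k)].push_back((int)p);
    }
  }

  // gather candidate ids in the Chebyshev shell at distance L around (ci,cj,ck)
  void shell(long long ci, long long cj, long long ck, int L,
             std::vector<int>& out) const {
    for (long long i = ci - L; i <= ci + L; ++i)
      for (long long j = cj - L; j <= cj + L; ++j)
        for (long long k = ck - L; k <= ck + L; ++k) {
          if (std::max(std::llabs(i - ci),
                       std::max(std::llabs(j - cj), std::llabs(k - ck))) != L)
            continue;
          auto it = cells.find(key(i, j, k));
          if (it != cells.end())
            out.insert(out.end(), it->second.begin(), it->second.end());
        }
  }
};

inline int basis_size(int degree) { return degree >= 2 ? 10 : (degree == 1 ? 4 : 1); }

inline void fill_basis(double x, double y, double z, int degree, arma::rowvec& b) {
  b(0) = 1.0;
  if (degree >= 1) { b(1) = x; b(2) = y; b(3) = z; }
  if (degree >= 2) {
    b(4) = x * x; b(5) = y * y; b(6) = z * z;
    b(7) = x * y; b(8) = x * z; b(9) = y * z;
  }
}

// weighted polynomial fit centred at the query; returns fitted value at centre
double fit_value(const arma::mat& pts, const arma::vec& vals,
                 const std::vector<std::pair<double, int> >& nb,
                 const double q[3], int degree, double Rfix = 0.0,
                 double aniso_xy = 1.0) {
  int k = (int)nb.size();
  double dmax = nb.back().first;
  double R = Rfix > 0 ? Rfix : (dmax > 0 ? dmax : 1.0) * 1.0001;
  while (degree >= 0) {
    int p = basis_size(degree);
    if (k >= p + 2 || degree == 0) {
      arma::mat A(p, p, arma::fill::zeros);
      arma::vec rhs(p, arma::fill::zeros);
      arma::rowvec b(p);
      for (int t = 0; t < k; ++t) {
        int id = nb[t].second;
        double w;
        if (Rfix > 0) {
          double s2 = Rfix / 2.0;
          double dz = pts(id, 2) - q[2];
          double dxy2 = nb[t].first * nb[t].first - dz * dz;
          if (dxy2 < 0) dxy2 = 0;
          // anisotropic Gaussian: in-plane scale s2*aniso_xy, axial s2
          w = std::exp(-0.5 * (dxy2 / (s2 * s2 * aniso_xy * aniso_xy) +
                               dz * dz / (s2 * s2)));
        } else {
          w = 1.0 - nb[t].first / R;
          w = w * w;
        }
        fill_basis((pts(id, 0) - q[0]) / R, (pts(id, 1) - q[1]) / R,
                   (pts(id, 2) - q[2]) / R, degree, b);
        A += w * (b.t() * b);
        rhs += w * vals(id) * b.t();
      }
      A.diag() += 1e-10 * (arma::trace(A) + 1.0);
      arma::vec coef;
      if (arma::solve(coef, A, rhs, arma::solve_opts::no_approx))
        return coef(0);
    }
    --degree;  // not enough points or singular: drop to a simpler model
  }
  return vals(nb[0].second);  // unreachable in practice
}

// all sites within `rad` of q (unsorted); nearest-first element guaranteed
void gather_within(const HashGrid& g, const arma::mat& pts, const double q[3],
                   double rad, std::vector<std::pair<double, int> >& nb) {
  nb.clear();
  long long ci = (long long)std::floor((q[0] - g.x0) / g.h);
  long long cj = (long long)std::floor((q[1] - g.y0) / g.h);
  long long ck = (long long)std::floor((q[2] - g.z0) / g.h);
  int Lmax = (int)std::ceil(rad / g.h) + 1;
  std::vector<int> cand;
  int best = -1;
  double bestd = 1e300;
  for (int L = 0; L <= Lmax; ++L) {
    cand.clear();
    g.shell(ci, cj, ck, L, cand);
    for (int id : cand) {
      double dx = pts(id, 0) - q[0], dy = pts(id, 1) - q[1],
             dz = pts(id, 2) - q[2];
      double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (d <= rad) {
        nb.push_back(std::make_pair(d, id));
        if (d < bestd) { bestd = d; best = (int)nb.size() - 1; }
      }
    }
  }
  if (best > 0) std::swap(nb[0], nb[best]);
}

// k nearest neighbours of q; empty if nearest exceeds r_cap
void knn(const HashGrid& g, const arma::mat& pts, const double q[3],
         int k, double r_cap, std::vector<std::pair<double, int> >& nb) {
  nb.clear();
  long long ci = (long long)std::floor((q[0] - g.x0) / g.h);
  long long cj = (long long)std::floor((q[1] - g.y0) / g.h);
  long long ck = (long long)std::floor((q[2] - g.z0) / g.h);
  std::vector<int> cand;
  std::vector<std::pair<double, int> > found;
  int Lmax = (int)std::ceil(r_cap / g.h) + 1;
  for (int L = 0; L <= Lmax; ++L) {
    cand.clear();
    g.shell(ci, cj, ck, L, cand);
    for (int id : cand) {
      double dx = pts(id, 0) - q[0], dy = pts(id, 1) - q[1], dz = pts(id, 2) - q[2];
      found.push_back(std::make_pair(std::sqrt(dx * dx + dy * dy + dz * dz), id));
    }
    double confirmed = (double)L * g.h;  // all sites within this radius are seen
    int n_ok = 0;
    for (auto& f : found) if (f.first <= confirmed) ++n_ok;
    if (n_ok >= k || confirmed > r_cap) break;
  }
  if (found.empty()) return;
  int kk = std::min<int>(k, (int)found.size());
  std::partial_sort(found.begin(), found.begin() + kk, found.end());
  found.resize(kk);
  nb = found;
}

}  // namespace

// plane_id: source-plane index per site; at most max_per_plane of the
// nearest sites are taken from any one plane, so the stencil always spans
// several acquisition planes (otherwise the dense in-plane sampling
// starves the through-plane direction and anchors the reconstruction to
// the static slice geometry).  max_per_plane <= 0 disables the cap.
// [[Rcpp::export]]
NumericVector cpp_mls_interp(const arma::mat& pts, const arma::vec& vals,
                             const arma::mat& qry, int degree, int k,
                             double fill_radius,
                             const IntegerVector& plane_id,
                             int max_per_plane, double radius = 0.0,
                             double aniso_xy = 1.0) {
  const arma::uword n = pts.n_rows, m = qry.n_rows;
  NumericVector out(m, NA_REAL);
  if (n == 0) return out;
  if (n == 1) {
    for (arma::uword i = 0; i < m; ++i) {
      double dx = pts(0, 0) - qry(i, 0), dy = pts(0, 1) - qry(i, 1),
             dz = pts(0, 2) - qry(i, 2);
      if (std::sqrt(dx * dx + dy * dy + dz * dz) <= fill_radius) out[i] = vals(0);
    }
    return out;
  }
  // cell size: aims at a handful of sites per cell
  double ext_x = pts.col(0).max() - pts.col(0).min();
  double ext_y = pts.col(1).max() - pts.col(1).min();
  double ext_z = pts.col(2).max() - pts.col(2).min();
  double vol = std::max(ext_x, 1e-6) * std::max(ext_y, 1e-6) * std::max(ext_z, 1e-6);
  double h = std::cbrt(vol / (double)n) * 2.0;
  h = std::max(h, 1e-6);
  HashGrid g;
  g.build(pts, h);

  double r_cap = std::max(fill_radius, 6.0 * h);
  const bool cap = max_per_plane > 0 && plane_id.size() == (int)n;
  const int k_gather = cap ? std::max(4 * k, 160) : k;
  std::vector<std::pair<double, int> > nb, sel;
  std::unordered_map<int, int> per_plane;
  double q[3];
  for (arma::uword i = 0; i < m; ++i) {
    q[0] = qry(i, 0); q[1] = qry(i, 1); q[2] = qry(i, 2);
    if (radius > 0) {
      gather_within(g, pts, q, std::max(radius, fill_radius), nb);
      if (nb.empty() || nb[0].first > fill_radius) continue;
      if (nb[0].first < 1e-9) { out[i] = vals(nb[0].second); continue; }
      sel.clear();
      for (auto& cand : nb) if (cand.first <= radius) sel.push_back(cand);
      if (sel.empty()) sel.push_back(nb[0]);
      out[i] = fit_value(pts, vals, sel, q, degree, radius, aniso_xy);
      continue;
    }
    knn(g, pts, q, k_gather, r_cap, nb);
    if (nb.empty() || nb[0].first > fill_radius) continue;  // fill policy upstream
    if (nb[0].first < 1e-9) { out[i] = vals(nb[0].second); continue; }
    if (cap) {
      sel.clear();
      per_plane.clear();
      for (auto& cand : nb) {
        int pl = plane_id[cand.second];
        int& cnt = per_plane[pl];
        if (cnt < max_per_plane) {
          ++cnt;
          sel.push_back(cand);
          if ((int)sel.size() >= k) break;
        }
      }
      out[i] = fit_value(pts, vals, sel, q, degree);
    } else {
      out[i] = fit_value(pts, vals, nb, q, degree);
    }
  }
  return out;
}

// label of the nearest site (used to carry LR tissue classes to the HR grid)
// [[Rcpp::export]]
IntegerVector cpp_nn_label(const arma::mat& pts, const IntegerVector& labels,
                           const arma::mat& qry) {
  const arma::uword m = qry.n_rows;
  IntegerVector out(m, NA_INTEGER);
  if (pts.n_rows == 0) return out;
  double ext = std::max({pts.col(0).max() - pts.col(0).min(),
                         pts.col(1).max() - pts.col(1).min(),
                         pts.col(2).max() - pts.col(2).min(), 1e-6});
  double vol = std::max(pts.col(0).max() - pts.col(0).min(), 1e-6) *
               std::max(pts.col(1).max() - pts.col(1).min(), 1e-6) *
               std::max(pts.col(2).max() - pts.col(2).min(), 1e-6);
  double h = std::max(std::cbrt(vol / (double)pts.n_rows) * 2.0, 1e-6);
  HashGrid g;
  g.build(pts, h);
  std::vector<std::pair<double, int> > nb;
  double q[3];
  for (arma::uword i = 0; i < m; ++i) {
    q[0] = qry(i, 0); q[1] = qry(i, 1); q[2] = qry(i, 2);
    knn(g, pts, q, 1, 2.0 * ext, nb);
    if (!nb.empty()) out[i] = labels[nb[0].second];
  }
  return out;
}
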