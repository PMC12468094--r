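// Point-cloud geometry kernels: local least-squares sphere curvature and
// local quadratic resampling, both with lateral (x, y) neighbor search on a
// uniform bin grid.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

namespace {

struct BinGrid {
  double x0, y0, cell;
  int nx, ny;
  std::vector<std::vector<int>> bins;
  BinGrid(const mat& P, double cellsize) {
    cell = cellsize;
    x0 = P.col(0).min(); y0 = P.col(1).min();
    nx = (int)std::floor((P.col(0).max() - x0) / cell) + 1;
    ny = (int)std::floor((P.col(1).max() - y0) / cell) + 1;
    bins.resize((size_t)nx * ny);
    for (uword i = 0; i < P.n_rows; ++i) {
      int bx = (int)std::floor((P(i, 0) - x0) / cell);
      int by = (int)std::floor((P(i, 1) - y0) / cell);
      bins[(size_t)by * nx + bx].push_back((int)i);
    }
  }
  // indices of points with lateral distance <= r from (qx, qy)
  void within(const mat& P, double qx, double qy, double r,
              std::vector<int>& out) const {
    out.clear();
    int bx0 = std::max(0, (int)std::floor((qx - r - x0) / cell));
    int bx1 = std::min(nx - 1, (int)std::floor((qx + r - x0) / cell));
    int by0 = std::max(0, (int)std::floor((qy - r - y0) / cell));
    int by1 = std::min(ny - 1, (int)std::floor((qy + r - y0) / cell));
    double r2 = r * r;
    for (int by = by0; by <= by1; ++by)
      for (int bx = bx0; bx <= bx1; ++bx)
        for (int idx : bins[(size_t)by * nx + bx]) {
          double dx = P(idx, 0) - qx, dy = P(idx, 1) - qy;
          if (dx * dx + dy * dy <= r2) out.push_back(idx);
        }
  }
  // k nearest (lateral) points to (qx, qy); expanding ring search
  void knearest(const mat& P, double qx, double qy, int k,
                std::vector<int>& out) const {
    double r = cell;
    std::vector<int> cand;
    for (int it = 0; it < 60; ++it) {
      within(P, qx, qy, r, cand);
      if ((int)cand.size() >= k) break;
      r *= 1.6;
    }
    std::vector<std::pair<double, int>> dd;
    dd.reserve(cand.size());
    for (int idx : cand) {
      double dx = P(idx, 0) - qx, dy = P(idx, 1) - qy;
      dd.emplace_back(dx * dx + dy * dy, idx);
    }
    std::sort(dd.begin(), dd.end());
    out.clear();
    int kk = std::min<int>(k, dd.size());
    for (int i = 0; i < kk; ++i) out.push_back(dd[i].second);
  }
};

}  // namespace

// Algebraic least-squares sphere through points idx; returns radius (mm) or
// NA on degeneracy. Solve [2x 2y 2z 1] beta = x^2+y^2+z^2.
static double sphere_radius(const mat& P, const std::vector<int>& idx) {
  size_t n = idx.size();
  if (n < 4) return NA_REAL;
  // centre the patch first: in global coordinates the R^2 = d + |c|^2
  // evaluation cancels catastrophically for small patches on large spheres
  double mx = 0, my = 0, mz = 0;
  for (size_t i = 0; i < n; ++i) {
    mx += P(idx[i], 0); my += P(idx[i], 1); mz += P(idx[i], 2);
  }
  mx /= n; my /= n; mz /= n;
  mat A(n, 4);
  vec b(n);
  for (size_t i = 0; i < n; ++i) {
    const double x = P(idx[i], 0) - mx, y = P(idx[i], 1) - my,
                 z = P(idx[i], 2) - mz;
    A(i, 0) = 2 * x; A(i, 1) = 2 * y; A(i, 2) = 2 * z; A(i, 3) = 1.0;
    b(i) = x * x + y * y + z * z;
  }
  mat AtA = A.t() * A;
  vec Atb = A.t() * b;
  vec beta;
  bool ok = solve(beta, AtA, Atb, solve_opts::no_approx);
  if (!ok) return NA_REAL;
  double R2 = beta(3) + beta(0) * beta(0) + beta(1) * beta(1) + beta(2) * beta(2);
  if (!std::isfinite(R2) || R2 <= 0) return NA_REAL;
  return std::sqrt(R2);
}

// Per-node radius of the local best-fitting sphere. Neighborhood: all points
// within lateral radius `radius`; if fewer than `min_pts`, fall back to the
// `kfall` nearest nodes (plus the node itself).
// [[Rcpp::export]]
arma::vec local_sphere_radius(const arma::mat& P, double radius, int min_pts,
                              int kfall) {
  BinGrid bg(P, std::max(radius, 1e-6));
  vec R(P.n_rows);
  std::vector<int> idx;
  for (uword i = 0; i < P.n_rows; ++i) {
    bg.within(P, P(i, 0), P(i, 1), radius, idx);
    if ((int)idx.size() < min_pts) {
      bg.knearest(P, P(i, 0), P(i, 1), kfall + 1, idx);  // includes self
    }
    double r = sphere_radius(P, idx);
    if (std::isfinite(r) && (r <= 0 || r > 1e4)) r = NA_REAL;
    R(i) = r;
  }
  return R;
}

// Resample scattered surface points onto query (x, y) locations by local
// quadratic least squares over the k nearest points. NA where the fit is
// under-determined.
// [[Rcpp::export]]
arma::vec resample_quadratic(const arma::mat& P, const arma::vec& qx,
                             const arma::vec& qy, int k) {
  double span = std::max(P.col(0).max() - P.col(0).min(),
                         P.col(1).max() - P.col(1).min());
  double cell = std::max(span / std::sqrt((double)P.n_rows + 1.0), 1e-6);
  BinGrid bg(P, cell);
  vec out(qx.n_elem);
  std::vector<int> idx;
  for (uword i = 0; i < qx.n_elem; ++i) {
    bg.knearest(P, qx(i), qy(i), k, idx);
    if ((int)idx.size() < 6) { out(i) = NA_REAL; continue; }
    size_t n = idx.size();
    mat A(n, 6);
    vec b(n);
    for (size_t jj = 0; jj < n; ++jj) {
      double dx = P(idx[jj], 0) - qx(i), dy = P(idx[jj], 1) - qy(i);
      A(jj, 0) = 1; A(jj, 1) = dx; A(jj, 2) = dy;
      A(jj, 3) = dx * dx; A(jj, 4) = dx * dy; A(jj, 5) = dy * dy;
      b(jj) = P(idx[jj], 2);
    }
    mat AtA = A.t() * A;
    AtA.diag() += 1e-12;
    vec beta;
    bool ok = solve(beta, AtA, A.t() * b, solve_opts::no_approx);
    out(i) = ok ? beta(0) : NA_REAL;
  }
  return out;
}

// Release freed allocator arenas back to the OS. The solver churns large
// CHOLMOD factorizations whose freed memory glibc otherwise retains,
// inflating RSS over long runs.
#ifdef __GLIBC__
#include <malloc.h>
#endif
// [[Rcpp::export]]
void mem_trim() {
#ifdef __GLIBC__
  malloc_trim(0);
#endif
}
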