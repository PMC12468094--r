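// Nonlinear total-Lagrangian FEM kernels: 10-node tetrahedra, HGO-type
// anisotropic hyperelasticity with volumetric penalty, follower pressure on
// 6-node triangle faces. Units: mm, kPa (forces in mN).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// ---------------------------------------------------------------------------
// Material: isochoric neo-Hookean matrix + two dispersed tension-only fiber
// families (generalized structure tensor form) + volumetric penalty.
//   Psi = c/2 (I1b - 3) + sum_f k1/(2 k2) [exp(k2 <Ef>^2) - 1] + K/2 (J-1)^2
//   Ef  = kappa (I1b - 3) + (1 - 3 kappa) (I4b_f - 1), active when Ef > 0
// ---------------------------------------------------------------------------

struct MatPt {
  double c, k1, k2, kap, bulk;
  vec3 a1, a2;
};

// PK2 stress; returns J via Jout. C must be symmetric positive definite.
static mat33 hgo_S(const mat33& C, const MatPt& m, double* Jout) {
  double detC = det(C);
  double J = std::sqrt(detC);
  mat33 Ci = inv(C);
  double Jm23 = std::pow(J, -2.0 / 3.0);
  double I1 = C(0, 0) + C(1, 1) + C(2, 2);
  double I1b = Jm23 * I1;
  mat33 I(fill::eye);
  mat33 dI1b = Jm23 * (I - (I1 / 3.0) * Ci);  // dI1b/dC
  mat33 S = m.c * dI1b;
  const vec3* dirs[2] = { &m.a1, &m.a2 };
  for (int f = 0; f < 2; ++f) {
    const vec3& a = *dirs[f];
    double I4 = as_scalar(a.t() * C * a);
    double E = m.kap * (I1b - 3.0) + (1.0 - 3.0 * m.kap) * (Jm23 * I4 - 1.0);
    if (E > 0.0) {
      double dPsidE = m.k1 * E * std::exp(m.k2 * E * E);
      mat33 dI4b = Jm23 * (a * a.t() - (I4 / 3.0) * Ci);
      S += 2.0 * dPsidE * (m.kap * dI1b + (1.0 - 3.0 * m.kap) * dI4b);
    }
  }
  S += m.bulk * (J - 1.0) * J * Ci;
  if (Jout) *Jout = J;
  return S;
}

static inline vec hgo_S_voigt(const mat33& C, const MatPt& m, double* Jout) {
  mat33 S = hgo_S(C, m, Jout);
  vec Sv(6);
  Sv(0) = S(0, 0); Sv(1) = S(1, 1); Sv(2) = S(2, 2);
  Sv(3) = S(0, 1); Sv(4) = S(1, 2); Sv(5) = S(0, 2);
  return Sv;
}

// Consistent material tangent D = dSv/dEv by central differences on C.
// Voigt strain ordering [E11,E22,E33,2E12,2E23,2E13].
static mat hgo_D(const mat33& C, const MatPt& m) {
  static const int vi[6] = { 0, 1, 2, 0, 1, 0 };
  static const int vj[6] = { 0, 1, 2, 1, 2, 2 };
  double h = 1e-6 * std::max(1.0, norm(C, "fro"));
  mat D(6, 6);
  for (int k = 0; k < 6; ++k) {
    mat33 Cp = C, Cm = C;
    if (k < 3) {
      Cp(vi[k], vj[k]) += 2.0 * h;
      Cm(vi[k], vj[k]) -= 2.0 * h;
    } else {
      Cp(vi[k], vj[k]) += h; Cp(vj[k], vi[k]) += h;
      Cm(vi[k], vj[k]) -= h; Cm(vj[k], vi[k]) -= h;
    }
    vec Sp = hgo_S_voigt(Cp, m, nullptr);
    vec Sm = hgo_S_voigt(Cm, m, nullptr);
    D.col(k) = (Sp - Sm) / (2.0 * h);
  }
  return D;
}

// Exported single-point evaluators (used for unit tests / oracles).
// [[Rcpp::export]]
Rcpp::List hgo_point(const arma::mat& F, double c, double k1, double k2,
                     double kappa, double bulk, const arma::vec& a1,
                     const arma::vec& a2) {
  if (det(F) <= 0.0) Rcpp::stop("deformation gradient has non-positive determinant");
  mat33 Fm = F;
  mat33 C = Fm.t() * Fm;
  MatPt m; m.c = c; m.k1 = k1; m.k2 = k2; m.kap = kappa; m.bulk = bulk;
  m.a1 = a1; m.a2 = a2;
  double J;
  mat33 S = hgo_S(C, m, &J);
  mat33 P = Fm * S;                      // first Piola-Kirchhoff
  mat33 sig = (1.0 / J) * P * Fm.t();    // Cauchy
  mat D = hgo_D(C, m);
  // strain energy for finite-difference checks
  double Jm23 = std::pow(J, -2.0 / 3.0);
  double I1b = Jm23 * trace(C);
  double W = 0.5 * c * (I1b - 3.0) + 0.5 * bulk * (J - 1.0) * (J - 1.0);
  const vec3 dirs[2] = { m.a1, m.a2 };
  for (int f = 0; f < 2; ++f) {
    double I4 = as_scalar(dirs[f].t() * C * dirs[f]);
    double E = kappa * (I1b - 3.0) + (1.0 - 3.0 * kappa) * (Jm23 * I4 - 1.0);
    if (E > 0.0) W += k1 / (2.0 * k2) * (std::exp(k2 * E * E) - 1.0);
  }
  // wrap fixed-size matrices as plain mat so they arrive as 3x3 R matrices
  return Rcpp::List::create(Rcpp::Named("S") = mat(S), Rcpp::Named("P") = mat(P),
                            Rcpp::Named("sigma") = mat(sig), Rcpp::Named("D") = D,
                            Rcpp::Named("J") = J, Rcpp::Named("W") = W);
}

// ---------------------------------------------------------------------------
// Tet10 shape functions (VTK node ordering: corners 0-3, edges 01,12,02,03,13,23)
// ---------------------------------------------------------------------------
static void tet10_shape(double xi, double eta, double zeta, vec& N, mat& dN) {
  double L0 = 1.0 - xi - eta - zeta, L1 = xi, L2 = eta, L3 = zeta;
  N.set_size(10);
  N(0) = L0 * (2 * L0 - 1); N(1) = L1 * (2 * L1 - 1);
  N(2) = L2 * (2 * L2 - 1); N(3) = L3 * (2 * L3 - 1);
  N(4) = 4 * L0 * L1; N(5) = 4 * L1 * L2; N(6) = 4 * L0 * L2;
  N(7) = 4 * L0 * L3; N(8) = 4 * L1 * L3; N(9) = 4 * L2 * L3;
  dN.set_size(10, 3);
  double d0 = 4 * L0 - 1, d1 = 4 * L1 - 1, d2 = 4 * L2 - 1, d3 = 4 * L3 - 1;
  dN.row(0) = rowvec({ -d0, -d0, -d0 });
  dN.row(1) = rowvec({ d1, 0, 0 });
  dN.row(2) = rowvec({ 0, d2, 0 });
  dN.row(3) = rowvec({ 0, 0, d3 });
  dN.row(4) = rowvec({ 4 * (L0 - L1), -4 * L1, -4 * L1 });
  dN.row(5) = rowvec({ 4 * L2, 4 * L1, 0 });
  dN.row(6) = rowvec({ -4 * L2, 4 * (L0 - L2), -4 * L2 });
  dN.row(7) = rowvec({ -4 * L3, -4 * L3, 4 * (L0 - L3) });
  dN.row(8) = rowvec({ 4 * L3, 0, 4 * L1 });
  dN.row(9) = rowvec({ 0, 4 * L3, 4 * L2 });
}

static const double QA = 0.5854101966249685, QB = 0.1381966011250105;
static const double QPTS[4][3] = {
  { QB, QB, QB }, { QA, QB, QB }, { QB, QA, QB }, { QB, QB, QA }
};
static const double QW = 1.0 / 24.0;

// Tri6 shape functions (corners 0-2, edges 01,12,02)
static void tri6_shape(double xi, double eta, vec& N, mat& dN) {
  double L0 = 1.0 - xi - eta, L1 = xi, L2 = eta;
  N.set_size(6);
  N(0) = L0 * (2 * L0 - 1); N(1) = L1 * (2 * L1 - 1); N(2) = L2 * (2 * L2 - 1);
  N(3) = 4 * L0 * L1; N(4) = 4 * L1 * L2; N(5) = 4 * L0 * L2;
  dN.set_size(6, 2);
  double d0 = 4 * L0 - 1, d1 = 4 * L1 - 1, d2 = 4 * L2 - 1;
  dN.row(0) = rowvec({ -d0, -d0 });
  dN.row(1) = rowvec({ d1, 0 });
  dN.row(2) = rowvec({ 0, d2 });
  dN.row(3) = rowvec({ 4 * (L0 - L1), -4 * L1 });
  dN.row(4) = rowvec({ 4 * L2, 4 * L1 });
  dN.row(5) = rowvec({ -4 * L2, 4 * (L0 - L2) });
}
static const double TQP[3][2] = { {1.0/6, 1.0/6}, {2.0/3, 1.0/6}, {1.0/6, 2.0/3} };
static const double TQW = 1.0 / 6.0;

// ---------------------------------------------------------------------------
// Global assembly. X: n x 3 reference coords; tets: m x 10 (0-based);
// u: 3n displacement (dof = 3*node + comp); material arrays per element/qp
// (m x 4); fiber directions A1, A2: (m*4) x 3, row e*4+q.
// faces: q x 6 (0-based) oriented so cross(g_xi, g_eta) is the OUTWARD normal
// of the solid; p: pressure (kPa) acting on those faces.
// Returns residual pieces, stiffness triplets (i, j, x; 1-based), min J.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
Rcpp::List fem_assemble(const arma::mat& X, const arma::imat& tets,
                        const arma::vec& u,
                        const arma::mat& c_eff, const arma::mat& k1_eff,
                        const arma::mat& k2_par, const arma::mat& kap_par,
                        const arma::mat& bulk_par,
                        const arma::mat& A1, const arma::mat& A2,
                        const arma::imat& faces, double p, bool want_K,
                        bool load_stiffness = false) {
  const uword n = X.n_rows, m = tets.n_rows;
  vec fint(3 * n, fill::zeros), fext(3 * n, fill::zeros);
  double minJ = datum::inf;
  uword ntrip = want_K ? (m * 900) : 0;
  std::vector<int> ti, tj; std::vector<double> tx;
  std::vector<int> li, lj; std::vector<double> lx;  // load stiffness (exact)
  if (want_K) { ti.reserve(ntrip); tj.reserve(ntrip); tx.reserve(ntrip); }

  vec N; mat dN;
  mat xe(10, 3), ue(10, 3);
  // Precompute shape data at the 4 quadrature points
  std::vector<vec> Nq(4); std::vector<mat> dNq(4);
  for (int q = 0; q < 4; ++q) tet10_shape(QPTS[q][0], QPTS[q][1], QPTS[q][2], Nq[q], dNq[q]);

  for (uword e = 0; e < m; ++e) {
    uvec conn(10);
    for (int a = 0; a < 10; ++a) conn(a) = (uword)tets(e, a);
    for (int a = 0; a < 10; ++a) {
      xe.row(a) = X.row(conn(a));
      for (int i = 0; i < 3; ++i) ue(a, i) = u(3 * conn(a) + i);
    }
    mat Ke;
    if (want_K) Ke.zeros(30, 30);
    vec fe(30, fill::zeros);
    for (int q = 0; q < 4; ++q) {
      const mat& dNxi = dNq[q];
      mat33 Jac = xe.t() * dNxi;         // dX/dxi
      double detJ0 = det(Jac);
      if (detJ0 <= 0.0) Rcpp::stop("element %d has non-positive reference Jacobian", (int)e + 1);
      mat dNdX = dNxi * inv(Jac);        // 10 x 3
      mat33 F(fill::eye);
      F += ue.t() * dNdX;                // F = I + du/dX
      double Jdef = det(F);
      if (Jdef < minJ) minJ = Jdef;
      if (Jdef <= 0.0) {
        // signal inverted state; caller backtracks
        return Rcpp::List::create(Rcpp::Named("ok") = false,
                                  Rcpp::Named("minJ") = Jdef);
      }
      mat33 C = F.t() * F;
      MatPt mp;
      mp.c = c_eff(e, q); mp.k1 = k1_eff(e, q); mp.k2 = k2_par(e, q);
      mp.kap = kap_par(e, q); mp.bulk = bulk_par(e, q);
      mp.a1 = A1.row(e * 4 + q).t(); mp.a2 = A2.row(e * 4 + q).t();
      double Jch;
      mat33 S = hgo_S(C, mp, &Jch);
      vec Sv(6);
      Sv(0) = S(0,0); Sv(1) = S(1,1); Sv(2) = S(2,2);
      Sv(3) = S(0,1); Sv(4) = S(1,2); Sv(5) = S(0,2);
      double dV = detJ0 * QW;
      // B matrix 6 x 30
      mat B(6, 30, fill::zeros);
      for (int a = 0; a < 10; ++a) {
        double gx = dNdX(a, 0), gy = dNdX(a, 1), gz = dNdX(a, 2);
        for (int i = 0; i < 3; ++i) {
          int col = 3 * a + i;
          B(0, col) = F(i, 0) * gx;
          B(1, col) = F(i, 1) * gy;
          B(2, col) = F(i, 2) * gz;
          B(3, col) = F(i, 0) * gy + F(i, 1) * gx;
          B(4, col) = F(i, 1) * gz + F(i, 2) * gy;
          B(5, col) = F(i, 0) * gz + F(i, 2) * gx;
        }
      }
      fe += B.t() * Sv * dV;
      if (want_K) {
        mat D = hgo_D(C, mp);
        Ke += B.t() * D * B * dV;
        // geometric stiffness: Kg(ab) = (dNa . S dNb) I3
        mat G = dNdX * S * dNdX.t();     // 10 x 10
        for (int a = 0; a < 10; ++a)
          for (int b = 0; b < 10; ++b) {
            double g = G(a, b) * dV;
            Ke(3 * a, 3 * b) += g;
            Ke(3 * a + 1, 3 * b + 1) += g;
            Ke(3 * a + 2, 3 * b + 2) += g;
          }
      }
    }
    for (int a = 0; a < 10; ++a)
      for (int i = 0; i < 3; ++i) fint(3 * conn(a) + i) += fe(3 * a + i);
    if (want_K) {
      // symmetric: keep the lower triangle only (halves the triplet stream,
      // which dominates the solver's transient memory)
      for (int a = 0; a < 10; ++a)
        for (int i = 0; i < 3; ++i) {
          int gi = 3 * conn(a) + i;
          for (int b = 0; b < 10; ++b)
            for (int k = 0; k < 3; ++k) {
              int gj = 3 * conn(b) + k;
              if (gi < gj) continue;
              ti.push_back(gi + 1);
              tj.push_back(gj + 1);
              tx.push_back(Ke(3 * a + i, 3 * b + k));
            }
        }
    }
  }

  // follower pressure on faces (deformed configuration)
  if (faces.n_rows > 0 && p != 0.0) {
    std::vector<vec> Nf(3); std::vector<mat> dNf(3);
    for (int q = 0; q < 3; ++q) tri6_shape(TQP[q][0], TQP[q][1], Nf[q], dNf[q]);
    mat xf(6, 3);
    for (uword f = 0; f < faces.n_rows; ++f) {
      uvec conn(6);
      for (int a = 0; a < 6; ++a) conn(a) = (uword)faces(f, a);
      for (int a = 0; a < 6; ++a)
        for (int i = 0; i < 3; ++i)
          xf(a, i) = X(conn(a), i) + u(3 * conn(a) + i);
      for (int q = 0; q < 3; ++q) {
        const vec& Nq3 = Nf[q]; const mat& dNq3 = dNf[q];
        vec3 gxi = (xf.t() * dNq3.col(0));
        vec3 geta = (xf.t() * dNq3.col(1));
        vec3 t = cross(gxi, geta);       // outward * |area jac|
        for (int a = 0; a < 6; ++a)
          for (int i = 0; i < 3; ++i)
            fext(3 * conn(a) + i) += -p * Nq3(a) * t(i) * TQW;
        if (want_K && load_stiffness) {
          // exact (nonsymmetric) follower-load stiffness K_load = dfext/du,
          // returned separately so the solver can use an SPD preconditioner
          for (int b = 0; b < 6; ++b) {
            for (int k = 0; k < 3; ++k) {
              vec3 ek(fill::zeros); ek(k) = 1.0;
              vec3 dt = cross(ek, geta) * dNq3(b, 0) + cross(gxi, ek) * dNq3(b, 1);
              for (int a = 0; a < 6; ++a) {
                for (int i = 0; i < 3; ++i) {
                  li.push_back(3 * conn(a) + i + 1);
                  lj.push_back(3 * conn(b) + k + 1);
                  lx.push_back(-p * Nq3(a) * dt(i) * TQW);
                }
              }
            }
          }
        }
      }
    }
  }

  Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("ok") = true,
      Rcpp::Named("fint") = fint, Rcpp::Named("fext") = fext,
      Rcpp::Named("minJ") = minJ);
  if (want_K) {
    out["Ki"] = Rcpp::IntegerVector(ti.begin(), ti.end());
    out["Kj"] = Rcpp::IntegerVector(tj.begin(), tj.end());
    out["Kx"] = Rcpp::NumericVector(tx.begin(), tx.end());
    out["Li"] = Rcpp::IntegerVector(li.begin(), li.end());
    out["Lj"] = Rcpp::IntegerVector(lj.begin(), lj.end());
    out["Lx"] = Rcpp::NumericVector(lx.begin(), lx.end());
  }
  return out;
}

// Reference and deformed element volumes plus minimum J across qps.
// [[Rcpp::export]]
Rcpp::List fem_volumes(const arma::mat& X, const arma::imat& tets,
                       const arma::vec& u) {
  const uword m = tets.n_rows;
  vec vol0(m, fill::zeros), vol(m, fill::zeros);
  double minJ0 = datum::inf, minJ = datum::inf;
  std::vector<vec> Nq(4); std::vector<mat> dNq(4);
  for (int q = 0; q < 4; ++q) tet10_shape(QPTS[q][0], QPTS[q][1], QPTS[q][2], Nq[q], dNq[q]);
  mat xe(10, 3), ue(10, 3);
  for (uword e = 0; e < m; ++e) {
    for (int a = 0; a < 10; ++a) {
      uword na = (uword)tets(e, a);
      xe.row(a) = X.row(na);
      for (int i = 0; i < 3; ++i) ue(a, i) = u(3 * na + i);
    }
    for (int q = 0; q < 4; ++q) {
      mat33 Jac = xe.t() * dNq[q];
      double detJ0 = det(Jac);
      if (detJ0 < minJ0) minJ0 = detJ0;
      mat33 F(fill::eye);
      if (norm(ue, "fro") > 0) F += ue.t() * (dNq[q] * inv(Jac));
      double Jd = det(F);
      if (Jd < minJ) minJ = Jd;
      vol0(e) += detJ0 * QW;
      vol(e) += detJ0 * Jd * QW;
    }
  }
  return Rcpp::List::create(Rcpp::Named("vol0") = vol0, Rcpp::Named("vol") = vol,
                            Rcpp::Named("minJ0") = minJ0, Rcpp::Named("minJ") = minJ);
}

// Quadrature-point positions and interpolated nodal scalar (e.g. normalized
// depth) for every element: returns (m*4) x 3 positions and (m*4) scalar.
// [[Rcpp::export]]
Rcpp::List fem_qp_data(const arma::mat& X, const arma::imat& tets,
                       const arma::vec& nodal) {
  const uword m = tets.n_rows;
  mat pos(m * 4, 3);
  vec val(m * 4);
  std::vector<vec> Nq(4); std::vector<mat> dNq(4);
  for (int q = 0; q < 4; ++q) tet10_shape(QPTS[q][0], QPTS[q][1], QPTS[q][2], Nq[q], dNq[q]);
  for (uword e = 0; e < m; ++e) {
    for (int q = 0; q < 4; ++q) {
      vec3 xq(fill::zeros);
      double vq = 0.0;
      for (int a = 0; a < 10; ++a) {
        uword na = (uword)tets(e, a);
        xq += Nq[q](a) * X.row(na).t();
        vq += Nq[q](a) * nodal(na);
      }
      pos.row(e * 4 + q) = xq.t();
      val(e * 4 + q) = vq;
    }
  }
  return Rcpp::List::create(Rcpp::Named("pos") = pos, Rcpp::Named("val") = val);
}
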