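// Nonlinear total-Lagrangian FE kernels: one-term Ogden solid (even exponent,
// volumetric penalty), 20-node serendipity hexahedra with uniform 2x2x2
// integration, and 8-node quadratic surface patches carrying follower pressure.
//
// Conventions
//   - Voigt order (11, 22, 33, 12, 23, 13); strain rows carry engineering shear.
//   - Displacement vector u has dof (3*(node-1) + comp), nodes 1-based from R.
//   - Pressure p > 0 pushes against the solid along minus the stored face
//     normal; faces are stored with normals pointing away from the material.

#include <RcppArmadillo.h>
using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::cube;

static const double GP2 = 0.5773502691896258;  // 1/sqrt(3)

// ---------------------------------------------------------------------------
// One-term Ogden material, W = (mu/alpha) (tr(Cbar^(alpha/2)) - 3) + k/2 (J-1)^2
// with alpha = 2*nhalf an even integer and Cbar = J^(-2/3) C.
// Returns PK2 stress S and material tangent D = 2 dS/dC (Voigt 6x6, minor
// symmetric, engineering-shear columns).
// ---------------------------------------------------------------------------

static const int VI[6] = {0, 1, 2, 0, 1, 0};
static const int VJ[6] = {0, 1, 2, 1, 2, 2};

static void ogden_pk2(const arma::mat33& C, double mu, int nhalf, double kappa,
                      mat& S, mat& D) {
  const int n = nhalf;
  double J2 = arma::det(C);
  double J = std::sqrt(J2);
  arma::mat33 B = arma::inv(C);
  B = 0.5 * (B + B.t());
  // powers C^0 .. C^n (fixed-size, stack temporaries only)
  static thread_local std::vector<arma::mat33> P;
  if ((int)P.size() < n + 1) P.resize(n + 1);
  P[0].eye();
  for (int r = 1; r <= n; ++r) P[r] = P[r - 1] * C;
  const arma::mat33& T = P[n - 1];
  double t = arma::trace(P[n]);
  double a = std::pow(J, -2.0 * n / 3.0);

  arma::mat33 Sdev = mu * a * (T - (t / 3.0) * B);
  arma::mat33 Svol = kappa * (J - 1.0) * J * B;
  S = Sdev + Svol;

  // tangent: D_IJ = [2 dS/dC]_{ijkl} at representative components
  D.zeros(6, 6);
  for (int I = 0; I < 6; ++I) {
    int i = VI[I], j = VJ[I];
    for (int Jc = 0; Jc < 6; ++Jc) {
      int k = VI[Jc], l = VJ[Jc];
      // d(C^{n-1})/dC  (symmetrized in kl)
      double dT = 0.0;
      for (int r = 0; r <= n - 2; ++r) {
        dT += 0.5 * (P[r](i, k) * P[n - 2 - r](l, j) +
                     P[r](i, l) * P[n - 2 - r](k, j));
      }
      double dB = -0.5 * (B(i, k) * B(l, j) + B(i, l) * B(k, j));
      double dev =
          mu * a * (dT - (n / 3.0) * B(i, j) * T(k, l)
                       - (t / 3.0) * dB)
          + Sdev(i, j) * (-(n / 3.0)) * B(k, l);
      double vol = kappa * J * (2.0 * J - 1.0) * 0.5 * B(i, j) * B(k, l) * 2.0
                   // 2 dS/dC: d(vol)/dC = k[(2J-1)(J/2)B_kl B_ij + (J-1)J dB]
                   + 2.0 * kappa * (J - 1.0) * J * dB;
      // note: factor bookkeeping -> 2*dS/dC:
      // dev part above already contains the full 2*d(Sdev)/dC? No: assembled
      // from d(Sdev)/dC pieces, so double it.
      D(I, Jc) = 2.0 * dev + vol;
    }
  }
}

// [[Rcpp::export(name = ".ogden_pk2")]]
List ogden_pk2_R(const arma::mat& C, double mu, int nhalf, double kappa) {
  mat S(3, 3), D(6, 6);
  arma::mat33 C33(C);
  ogden_pk2(C33, mu, nhalf, kappa, S, D);
  return List::create(_["S"] = S, _["D"] = D);
}

// [[Rcpp::export(name = ".ogden_cauchy")]]
arma::mat ogden_cauchy_R(const arma::mat& F, double mu, int nhalf, double kappa) {
  arma::mat33 C(arma::mat(F.t() * F));
  mat S(3, 3), D(6, 6);
  ogden_pk2(C, mu, nhalf, kappa, S, D);
  double J = arma::det(F);
  return (F * S * F.t()) / J;
}

// ---------------------------------------------------------------------------
// Hex20 serendipity shape functions
// ---------------------------------------------------------------------------

static const double XN[20][3] = {
    {-1, -1, -1}, {1, -1, -1}, {1, 1, -1}, {-1, 1, -1},
    {-1, -1, 1},  {1, -1, 1},  {1, 1, 1},  {-1, 1, 1},
    {0, -1, -1},  {1, 0, -1},  {0, 1, -1}, {-1, 0, -1},
    {0, -1, 1},   {1, 0, 1},   {0, 1, 1},  {-1, 0, 1},
    {-1, -1, 0},  {1, -1, 0},  {1, 1, 0},  {-1, 1, 0}};

static void hex20_shape(double xi, double eta, double zeta,
                        double* N, mat& dN /* 3 x 20 */) {
  for (int a = 0; a < 20; ++a) {
    double xa = XN[a][0], ya = XN[a][1], za = XN[a][2];
    if (a < 8) {
      double f = (1 + xi * xa) * (1 + eta * ya) * (1 + zeta * za);
      double g = xi * xa + eta * ya + zeta * za - 2.0;
      N[a] = 0.125 * f * g;
      dN(0, a) = 0.125 * (xa * (1 + eta * ya) * (1 + zeta * za) * g + f * xa);
      dN(1, a) = 0.125 * (ya * (1 + xi * xa) * (1 + zeta * za) * g + f * ya);
      dN(2, a) = 0.125 * (za * (1 + xi * xa) * (1 + eta * ya) * g + f * za);
    } else if (xa == 0) {
      N[a] = 0.25 * (1 - xi * xi) * (1 + eta * ya) * (1 + zeta * za);
      dN(0, a) = -0.5 * xi * (1 + eta * ya) * (1 + zeta * za);
      dN(1, a) = 0.25 * (1 - xi * xi) * ya * (1 + zeta * za);
      dN(2, a) = 0.25 * (1 - xi * xi) * (1 + eta * ya) * za;
    } else if (ya == 0) {
      N[a] = 0.25 * (1 + xi * xa) * (1 - eta * eta) * (1 + zeta * za);
      dN(0, a) = 0.25 * xa * (1 - eta * eta) * (1 + zeta * za);
      dN(1, a) = -0.5 * eta * (1 + xi * xa) * (1 + zeta * za);
      dN(2, a) = 0.25 * (1 + xi * xa) * (1 - eta * eta) * za;
    } else {
      N[a] = 0.25 * (1 + xi * xa) * (1 + eta * ya) * (1 - zeta * zeta);
      dN(0, a) = 0.25 * xa * (1 + eta * ya) * (1 - zeta * zeta);
      dN(1, a) = 0.25 * (1 + xi * xa) * ya * (1 - zeta * zeta);
      dN(2, a) = -0.5 * zeta * (1 + xi * xa) * (1 + eta * ya);
    }
  }
}

// ---------------------------------------------------------------------------
// Volume assembly: internal force and tangent values (reduced CSC layout)
// ---------------------------------------------------------------------------

// map: integer vector length E*3600, 1-based position into x, 0 = dropped dof
// order within an element: column-major over (3a+i, 3b+j) pairs, i.e.
// idx = col*60 + row with row = 3*a + i, col = 3*b + j (0-based).

// Reference-configuration shape gradients and jacobians, computed once per
// geometry and reused across Newton iterations: dNx (3 x 20 per gauss point,
// column-major, gp-major within element) and detJ (E*8).

// [[Rcpp::export(name = ".fem_precompute")]]
List fem_precompute(const arma::mat& nodes, const arma::imat& conn) {
  const int E = conn.n_rows;
  vec detJ(E * 8);
  vec dNx_all((size_t)E * 8 * 60);
  double Ng[20];
  mat dN(3, 20), dNx(3, 20), Xe(3, 20);
  arma::mat33 J0;
  bool ok = true;
  int bad_el = -1;
  for (int e = 0; e < E && ok; ++e) {
    for (int a = 0; a < 20; ++a) {
      int nd = conn(e, a) - 1;
      for (int c = 0; c < 3; ++c) Xe(c, a) = nodes(nd, c);
    }
    for (int g = 0; g < 8; ++g) {
      double xi = (g & 1) ? GP2 : -GP2;
      double eta = (g & 2) ? GP2 : -GP2;
      double zeta = (g & 4) ? GP2 : -GP2;
      hex20_shape(xi, eta, zeta, Ng, dN);
      J0 = dN * Xe.t();
      double dj = arma::det(J0);
      if (!(dj > 0.0)) { ok = false; bad_el = e; break; }
      detJ((size_t)e * 8 + g) = dj;
      dNx = arma::solve(mat(J0), dN);
      std::memcpy(dNx_all.memptr() + ((size_t)e * 8 + g) * 60,
                  dNx.memptr(), 60 * sizeof(double));
    }
  }
  return List::create(_["dNx"] = dNx_all, _["detJ"] = detJ, _["ok"] = ok,
                      _["bad_element"] = bad_el + 1);
}

// [[Rcpp::export(name = ".fem_assemble")]]
List fem_assemble(const arma::mat& nodes, const arma::imat& conn,
                  const arma::vec& u, const arma::vec& mu_el,
                  int nhalf, double kappa,
                  const IntegerVector& map, int nnz, bool want_K,
                  Rcpp::Nullable<Rcpp::List> precomp = R_NilValue) {
  const int E = conn.n_rows;
  const int N = nodes.n_rows;
  vec fint(3 * N, arma::fill::zeros);
  vec x(nnz, arma::fill::zeros);
  bool ok = true;
  int bad_el = -1;

  const bool use_pre = precomp.isNotNull();
  NumericVector pre_dNx, pre_detJ;
  if (use_pre) {
    Rcpp::List pl(precomp);
    pre_dNx = pl["dNx"];
    pre_detJ = pl["detJ"];
  }

  double Ng[20];
  mat dN(3, 20), dNx(3, 20);
  mat Xe(3, 20), Ue(3, 20);
  mat Bm(6, 60), K(60, 60), DB(6, 60), G(20, 20), S(3, 3), D(6, 6);
  arma::mat33 J0, F, C;
  vec fe(60), Sv(6);

  for (int e = 0; e < E && ok; ++e) {
    for (int a = 0; a < 20; ++a) {
      int nd = conn(e, a) - 1;
      for (int c = 0; c < 3; ++c) {
        if (!use_pre) Xe(c, a) = nodes(nd, c);
        Ue(c, a) = u(3 * nd + c);
      }
    }
    K.zeros();
    fe.zeros();
    for (int g = 0; g < 8; ++g) {
      double detJ0;
      if (use_pre) {
        detJ0 = pre_detJ[(size_t)e * 8 + g];
        std::memcpy(dNx.memptr(), REAL(pre_dNx) + ((size_t)e * 8 + g) * 60,
                    60 * sizeof(double));
      } else {
        double xi = (g & 1) ? GP2 : -GP2;
        double eta = (g & 2) ? GP2 : -GP2;
        double zeta = (g & 4) ? GP2 : -GP2;
        hex20_shape(xi, eta, zeta, Ng, dN);
        J0 = dN * Xe.t();                // 3x3, dX/dxi (rows xi, cols X)
        detJ0 = arma::det(J0);
        if (!(detJ0 > 0.0)) { ok = false; bad_el = e; break; }
        dNx = arma::solve(mat(J0), dN);  // dN/dX, 3 x 20
      }
      F = arma::mat33(arma::eye(3, 3) + Ue * dNx.t()); // F_ij = dx_i/dX_j
      double detF = arma::det(F);
      if (!(detF > 0.0)) { ok = false; bad_el = e; break; }
      C = F.t() * F;
      ogden_pk2(C, mu_el(e), nhalf, kappa, S, D);

      // nonlinear strain-displacement matrix (engineering shear rows)
      for (int a = 0; a < 20; ++a) {
        for (int k = 0; k < 3; ++k) {
          int col = 3 * a + k;
          Bm(0, col) = F(k, 0) * dNx(0, a);
          Bm(1, col) = F(k, 1) * dNx(1, a);
          Bm(2, col) = F(k, 2) * dNx(2, a);
          Bm(3, col) = F(k, 0) * dNx(1, a) + F(k, 1) * dNx(0, a);
          Bm(4, col) = F(k, 1) * dNx(2, a) + F(k, 2) * dNx(1, a);
          Bm(5, col) = F(k, 0) * dNx(2, a) + F(k, 2) * dNx(0, a);
        }
      }
      Sv(0) = S(0, 0); Sv(1) = S(1, 1); Sv(2) = S(2, 2);
      Sv(3) = S(0, 1); Sv(4) = S(1, 2); Sv(5) = S(0, 2);
      double w = detJ0;  // unit gauss weights
      fe += w * (Bm.t() * Sv);
      if (want_K) {
        DB = D * Bm;
        K += w * (Bm.t() * DB);
        // geometric stiffness: Kg[3a+i,3b+j] = d_ij gradNa . S gradNb
        G = dNx.t() * S * dNx;  // 20 x 20
        for (int a = 0; a < 20; ++a)
          for (int b = 0; b < 20; ++b) {
            double gab = w * G(a, b);
            K(3 * a, 3 * b) += gab;
            K(3 * a + 1, 3 * b + 1) += gab;
            K(3 * a + 2, 3 * b + 2) += gab;
          }
      }
    }
    if (!ok) break;
    for (int a = 0; a < 20; ++a) {
      int nd = conn(e, a) - 1;
      for (int c = 0; c < 3; ++c) fint(3 * nd + c) += fe(3 * a + c);
    }
    if (want_K) {
      const int* me = INTEGER(map) + (size_t)e * 3600;
      const double* kp = K.memptr();
      for (int q = 0; q < 3600; ++q) {
        int pos = me[q];
        if (pos > 0) x(pos - 1) += kp[q];
      }
    }
  }
  return List::create(_["fint"] = fint, _["x"] = x, _["ok"] = ok,
                      _["bad_element"] = bad_el + 1);
}

// [[Rcpp::export(name = ".fem_triplets")]]
List fem_triplets(const arma::imat& conn) {
  const int E = conn.n_rows;
  IntegerVector ti((size_t)E * 3600), tj((size_t)E * 3600);
  size_t q = 0;
  for (int e = 0; e < E; ++e) {
    int dofs[60];
    for (int a = 0; a < 20; ++a)
      for (int c = 0; c < 3; ++c) dofs[3 * a + c] = 3 * (conn(e, a) - 1) + c + 1;
    for (int col = 0; col < 60; ++col)
      for (int row = 0; row < 60; ++row) {
        ti[q] = dofs[row];
        tj[q] = dofs[col];
        ++q;
      }
  }
  return List::create(_["i"] = ti, _["j"] = tj);
}

// ---------------------------------------------------------------------------
// Quad8 surface shape functions, follower pressure loads
// ---------------------------------------------------------------------------

static const double QN[8][2] = {{-1, -1}, {1, -1}, {1, 1}, {-1, 1},
                                {0, -1},  {1, 0},  {0, 1}, {-1, 0}};

static void quad8_shape(double xi, double eta, double* N, mat& dN /*2x8*/) {
  for (int a = 0; a < 8; ++a) {
    double xa = QN[a][0], ya = QN[a][1];
    if (a < 4) {
      N[a] = 0.25 * (1 + xi * xa) * (1 + eta * ya) * (xi * xa + eta * ya - 1);
      dN(0, a) = 0.25 * xa * (1 + eta * ya) * (2 * xi * xa + eta * ya);
      dN(1, a) = 0.25 * ya * (1 + xi * xa) * (xi * xa + 2 * eta * ya);
    } else if (xa == 0) {
      N[a] = 0.5 * (1 - xi * xi) * (1 + eta * ya);
      dN(0, a) = -xi * (1 + eta * ya);
      dN(1, a) = 0.5 * (1 - xi * xi) * ya;
    } else {
      N[a] = 0.5 * (1 + xi * xa) * (1 - eta * eta);
      dN(0, a) = 0.5 * xa * (1 - eta * eta);
      dN(1, a) = -eta * (1 + xi * xa);
    }
  }
}

static const double G3[3] = {-0.7745966692414834, 0.0, 0.7745966692414834};
static const double W3[3] = {5.0 / 9.0, 8.0 / 9.0, 5.0 / 9.0};

static mat skew(const arma::vec3& v) {
  mat s(3, 3, arma::fill::zeros);
  s(0, 1) = -v(2); s(0, 2) = v(1);
  s(1, 0) = v(2);  s(1, 2) = -v(0);
  s(2, 0) = -v(1); s(2, 1) = v(0);
  return s;
}

// faces: F x 8 node ids (1-based); pgp: F x 9 pressure at the 3x3 gauss points
// (row-major over (i_eta, i_xi)? order: g = 3*ge + gx). Returns external force
// on the solid and dfext/du values in reduced CSC layout via map (length F*576).

// [[Rcpp::export(name = ".surface_load")]]
List surface_load(const arma::mat& nodes, const arma::vec& u,
                  const arma::imat& faces, const arma::mat& pgp,
                  const IntegerVector& map, int nnz, bool want_K) {
  const int Fn = faces.n_rows;
  const int N = nodes.n_rows;
  vec fext(3 * N, arma::fill::zeros);
  vec x(nnz, arma::fill::zeros);
  double Ng[8];
  mat dN(2, 8), Xc(3, 8), K(24, 24);

  for (int f = 0; f < Fn; ++f) {
    for (int a = 0; a < 8; ++a) {
      int nd = faces(f, a) - 1;
      for (int c = 0; c < 3; ++c) Xc(c, a) = nodes(nd, c) + u(3 * nd + c);
    }
    K.zeros();
    vec fe(24, arma::fill::zeros);
    for (int ge = 0; ge < 3; ++ge)
      for (int gx = 0; gx < 3; ++gx) {
        int g = 3 * ge + gx;
        double p = pgp(f, g);
        if (p == 0.0 && !want_K) continue;
        quad8_shape(G3[gx], G3[ge], Ng, dN);
        arma::vec3 g1 = Xc * dN.row(0).t();
        arma::vec3 g2 = Xc * dN.row(1).t();
        arma::vec3 nda = arma::cross(g1, g2);  // normal * dA
        double w = W3[gx] * W3[ge];
        for (int a = 0; a < 8; ++a)
          for (int c = 0; c < 3; ++c) fe(3 * a + c) += -p * w * Ng[a] * nda(c);
        if (want_K && p != 0.0) {
          mat s1 = skew(g1), s2 = skew(g2);
          for (int b = 0; b < 8; ++b) {
            mat blk = -s2 * dN(0, b) + s1 * dN(1, b);  // d(g1 x g2)/du_b
            for (int a = 0; a < 8; ++a) {
              double cfa = -p * w * Ng[a];
              for (int i = 0; i < 3; ++i)
                for (int j = 0; j < 3; ++j)
                  K(3 * a + i, 3 * b + j) += cfa * blk(i, j);
            }
          }
        }
      }
    for (int a = 0; a < 8; ++a) {
      int nd = faces(f, a) - 1;
      for (int c = 0; c < 3; ++c) fext(3 * nd + c) += fe(3 * a + c);
    }
    if (want_K) {
      const int* me = INTEGER(map) + (size_t)f * 576;
      const double* kp = K.memptr();
      for (int q = 0; q < 576; ++q) {
        int pos = me[q];
        if (pos > 0) x(pos - 1) += kp[q];
      }
    }
  }
  return List::create(_["fext"] = fext, _["x"] = x);
}

// [[Rcpp::export(name = ".surf_triplets")]]
List surf_triplets(const arma::imat& faces) {
  const int Fn = faces.n_rows;
  IntegerVector ti((size_t)Fn * 576), tj((size_t)Fn * 576);
  size_t q = 0;
  for (int f = 0; f < Fn; ++f) {
    int dofs[24];
    for (int a = 0; a < 8; ++a)
      for (int c = 0; c < 3; ++c) dofs[3 * a + c] = 3 * (faces(f, a) - 1) + c + 1;
    for (int col = 0; col < 24; ++col)
      for (int row = 0; row < 24; ++row) {
        ti[q] = dofs[row];
        tj[q] = dofs[col];
        ++q;
      }
  }
  return List::create(_["i"] = ti, _["j"] = tj);
}

// Gauss-point positions, area elements and unit normals of faces in the
// configuration nodes + u. Rows: face-major, 9 gauss points each.

// [[Rcpp::export(name = ".face_gp_data")]]
List face_gp_data(const arma::mat& nodes, const arma::vec& u,
                  const arma::imat& faces) {
  const int Fn = faces.n_rows;
  mat pos(Fn * 9, 3), nrm(Fn * 9, 3);
  vec da(Fn * 9);
  double Ng[8];
  mat dN(2, 8), Xc(3, 8);
  for (int f = 0; f < Fn; ++f) {
    for (int a = 0; a < 8; ++a) {
      int nd = faces(f, a) - 1;
      for (int c = 0; c < 3; ++c) Xc(c, a) = nodes(nd, c) + u(3 * nd + c);
    }
    for (int ge = 0; ge < 3; ++ge)
      for (int gx = 0; gx < 3; ++gx) {
        int g = 3 * ge + gx;
        quad8_shape(G3[gx], G3[ge], Ng, dN);
        arma::vec3 xp = Xc * arma::vec(std::vector<double>(Ng, Ng + 8));
        arma::vec3 g1 = Xc * dN.row(0).t();
        arma::vec3 g2 = Xc * dN.row(1).t();
        arma::vec3 nda = arma::cross(g1, g2);
        double A = arma::norm(nda);
        for (int c = 0; c < 3; ++c) {
          pos(f * 9 + g, c) = xp(c);
          nrm(f * 9 + g, c) = A > 0 ? nda(c) / A : 0.0;
        }
        da(f * 9 + g) = A * W3[gx] * W3[ge];
      }
  }
  return List::create(_["pos"] = pos, _["da"] = da, _["normal"] = nrm);
}

// ---------------------------------------------------------------------------
// Mesh utilities
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".mesh_volume")]]
double mesh_volume(const arma::mat& nodes, const arma::imat& conn,
                   const arma::vec& u) {
  const int E = conn.n_rows;
  double Ng[20];
  mat dN(3, 20), Xe(3, 20);
  double V = 0.0;
  for (int e = 0; e < E; ++e) {
    for (int a = 0; a < 20; ++a) {
      int nd = conn(e, a) - 1;
      for (int c = 0; c < 3; ++c) Xe(c, a) = nodes(nd, c) + u(3 * nd + c);
    }
    for (int g3 = 0; g3 < 3; ++g3)
      for (int g2i = 0; g2i < 3; ++g2i)
        for (int g1i = 0; g1i < 3; ++g1i) {
          hex20_shape(G3[g1i], G3[g2i], G3[g3], Ng, dN);
          V += arma::det(dN * Xe.t()) * W3[g1i] * W3[g2i] * W3[g3];
        }
  }
  return V;
}

// [[Rcpp::export(name = ".min_detJ")]]
arma::vec min_detJ(const arma::mat& nodes, const arma::imat& conn) {
  const int E = conn.n_rows;
  double Ng[20];
  mat dN(3, 20), Xe(3, 20);
  vec out(E);
  for (int e = 0; e < E; ++e) {
    for (int a = 0; a < 20; ++a) {
      int nd = conn(e, a) - 1;
      for (int c = 0; c < 3; ++c) Xe(c, a) = nodes(nd, c);
    }
    double mn = arma::datum::inf;
    for (int g = 0; g < 8; ++g) {
      double xi = (g & 1) ? GP2 : -GP2;
      double eta = (g & 2) ? GP2 : -GP2;
      double zeta = (g & 4) ? GP2 : -GP2;
      hex20_shape(xi, eta, zeta, Ng, dN);
      mn = std::min(mn, arma::det(dN * Xe.t()));
    }
    out(e) = mn;
  }
  return out;
}

// [[Rcpp::export(name = ".element_centroids")]]
arma::mat element_centroids(const arma::mat& nodes, const arma::imat& conn) {
  const int E = conn.n_rows;
  double Ng[20];
  mat dN(3, 20), Xe(3, 20), out(E, 3);
  for (int e = 0; e < E; ++e) {
    for (int a = 0; a < 20; ++a) {
      int nd = conn(e, a) - 1;
      for (int c = 0; c < 3; ++c) Xe(c, a) = nodes(nd, c);
    }
    hex20_shape(0.0, 0.0, 0.0, Ng, dN);
    arma::vec3 xc = Xe * arma::vec(std::vector<double>(Ng, Ng + 20));
    out.row(e) = xc.t();
  }
  return out;
}

// Mean Cauchy stress per element (Voigt 6), averaged over gauss points.

// [[Rcpp::export(name = ".element_cauchy")]]
arma::mat element_cauchy(const arma::mat& nodes, const arma::imat& conn,
                         const arma::vec& u, const arma::vec& mu_el,
                         int nhalf, double kappa) {
  const int E = conn.n_rows;
  double Ng[20];
  mat dN(3, 20), dNx(3, 20), Xe(3, 20), Ue(3, 20), S(3, 3), D(6, 6);
  mat out(E, 6, arma::fill::zeros);
  for (int e = 0; e < E; ++e) {
    for (int a = 0; a < 20; ++a) {
      int nd = conn(e, a) - 1;
      for (int c = 0; c < 3; ++c) {
        Xe(c, a) = nodes(nd, c);
        Ue(c, a) = u(3 * nd + c);
      }
    }
    mat acc(3, 3, arma::fill::zeros);
    for (int g = 0; g < 8; ++g) {
      double xi = (g & 1) ? GP2 : -GP2;
      double eta = (g & 2) ? GP2 : -GP2;
      double zeta = (g & 4) ? GP2 : -GP2;
      hex20_shape(xi, eta, zeta, Ng, dN);
      mat J0 = dN * Xe.t();
      dNx = arma::solve(J0, dN);
      mat F = arma::eye(3, 3) + Ue * dNx.t();
      arma::mat33 C33(arma::mat(F.t() * F));
      ogden_pk2(C33, mu_el(e), nhalf, kappa, S, D);
      acc += (F * S * F.t()) / arma::det(F);
    }
    acc /= 8.0;
    out(e, 0) = acc(0, 0); out(e, 1) = acc(1, 1); out(e, 2) = acc(2, 2);
    out(e, 3) = acc(0, 1); out(e, 4) = acc(1, 2); out(e, 5) = acc(0, 2);
  }
  return out;
}

// Locate triplets in a CSC pattern; returns 1-based positions, 0 where the
// triplet was dropped (ti or tj == 0).

// [[Rcpp::export(name = ".csc_locate")]]
IntegerVector csc_locate(const IntegerVector& ti, const IntegerVector& tj,
                         const IntegerVector& Kp, const IntegerVector& Ki) {
  const R_xlen_t n = ti.size();
  IntegerVector out(n, 0);
  for (R_xlen_t q = 0; q < n; ++q) {
    int r = ti[q], c = tj[q];
    if (r <= 0 || c <= 0) continue;
    int lo = Kp[c - 1], hi = Kp[c] - 1;  // 0-based range in Ki
    int target = r - 1;
    while (lo <= hi) {
      int mid = (lo + hi) / 2;
      if (Ki[mid] < target) lo = mid + 1;
      else if (Ki[mid] > target) hi = mid - 1;
      else { out[q] = mid + 1; break; }
    }
  }
  return out;
}
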