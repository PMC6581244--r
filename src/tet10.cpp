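// Element-level kernels for 10-node tetrahedral finite elements.
// Node convention: corners 1-4, mid-edge nodes 5-10 on edges
// (1,2),(2,3),(3,1),(1,4),(2,4),(3,4)  [1-based], i.e. the C3D10 / VTK-24 order.
// Voigt strain order: (xx, yy, zz, gxy, gyz, gzx) with engineering shears.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Shape functions and parent-space derivatives at (r,s,t).
static void tet10_shape(double r, double s, double t, vec &N, mat &dN) {
  const double L1 = 1.0 - r - s - t, L2 = r, L3 = s, L4 = t;
  N.set_size(10);
  dN.set_size(10, 3);
  const double dL[4][3] = {{-1, -1, -1}, {1, 0, 0}, {0, 1, 0}, {0, 0, 1}};
  const double L[4] = {L1, L2, L3, L4};
  for (int i = 0; i < 4; ++i) {
    N(i) = L[i] * (2.0 * L[i] - 1.0);
    for (int k = 0; k < 3; ++k) dN(i, k) = (4.0 * L[i] - 1.0) * dL[i][k];
  }
  // mid-edge pairs (0-based corner indices)
  const int ed[6][2] = {{0, 1}, {1, 2}, {2, 0}, {0, 3}, {1, 3}, {2, 3}};
  for (int e = 0; e < 6; ++e) {
    int i = ed[e][0], j = ed[e][1];
    N(4 + e) = 4.0 * L[i] * L[j];
    for (int k = 0; k < 3; ++k)
      dN(4 + e, k) = 4.0 * (L[i] * dL[j][k] + L[j] * dL[i][k]);
  }
}

// isotropic elasticity matrix, Voigt engineering-shear convention
static mat iso_D(double E, double nu) {
  const double lam = E * nu / ((1.0 + nu) * (1.0 - 2.0 * nu));
  const double mu = E / (2.0 * (1.0 + nu));
  mat D(6, 6, fill::zeros);
  for (int i = 0; i < 3; ++i) {
    for (int j = 0; j < 3; ++j) D(i, j) = lam;
    D(i, i) = lam + 2.0 * mu;
    D(3 + i, 3 + i) = mu;
  }
  return D;
}

static void element_coords(const mat &coords, const imat &conn, int e, mat &Xe) {
  Xe.set_size(10, 3);
  for (int a = 0; a < 10; ++a) {
    int n = conn(e, a) - 1;
    for (int k = 0; k < 3; ++k) Xe(a, k) = coords(n, k);
  }
}

// B matrix (6 x 30) from spatial shape gradients (10 x 3)
static void fill_B(const mat &dNdx, mat &B) {
  B.zeros(6, 30);
  for (int a = 0; a < 10; ++a) {
    const double bx = dNdx(a, 0), by = dNdx(a, 1), bz = dNdx(a, 2);
    const int c = 3 * a;
    B(0, c) = bx;
    B(1, c + 1) = by;
    B(2, c + 2) = bz;
    B(3, c) = by; B(3, c + 1) = bx;
    B(4, c + 1) = bz; B(4, c + 2) = by;
    B(5, c) = bz; B(5, c + 2) = bx;
  }
}

// [[Rcpp::export]]
Rcpp::List cpp_tet10_stiffness(const arma::mat &coords, const arma::imat &conn,
                               const arma::vec &E, const arma::vec &nu,
                               const arma::mat &qp, const arma::vec &w) {
  const int M = conn.n_rows, nq = qp.n_rows;
  // precompute shape derivatives at quadrature points
  std::vector<mat> dNs(nq);
  vec N;
  for (int q = 0; q < nq; ++q) tet10_shape(qp(q, 0), qp(q, 1), qp(q, 2), N, dNs[q]);

  const size_t per = 30 * 31 / 2;  // upper triangle of 30x30
  std::vector<int> I; I.reserve(per * M);
  std::vector<int> J; J.reserve(per * M);
  std::vector<double> X; X.reserve(per * M);

  mat Xe, B(6, 30), ke(30, 30), A(3, 3), dNdx;
  for (int e = 0; e < M; ++e) {
    element_coords(coords, conn, e, Xe);
    mat D = iso_D(E(e), nu(e));
    ke.zeros();
    for (int q = 0; q < nq; ++q) {
      A = Xe.t() * dNs[q];          // A(k,l) = dx_k/dxi_l
      double detA = det(A);
      if (detA <= 0) Rcpp::stop("non-positive Jacobian in element %d", e + 1);
      dNdx = dNs[q] * inv(A);
      fill_B(dNdx, B);
      ke += (w(q) * detA) * (B.t() * D * B);
    }
    // scatter upper triangle with global dof ids
    ivec gd(30);
    for (int a = 0; a < 10; ++a) {
      int n = conn(e, a) - 1;
      for (int k = 0; k < 3; ++k) gd(3 * a + k) = 3 * n + k + 1;
    }
    for (int i = 0; i < 30; ++i)
      for (int j = 0; j < 30; ++j) {
        if (gd(i) <= gd(j)) {
          I.push_back(gd(i));
          J.push_back(gd(j));
          X.push_back(ke(i, j));
        }
      }
  }
  return Rcpp::List::create(Rcpp::Named("i") = I, Rcpp::Named("j") = J,
                            Rcpp::Named("x") = X);
}

// [[Rcpp::export]]
arma::vec cpp_tet10_volumes(const arma::mat &coords, const arma::imat &conn,
                            const arma::mat &qp, const arma::vec &w) {
  const int M = conn.n_rows, nq = qp.n_rows;
  std::vector<mat> dNs(nq);
  vec N;
  for (int q = 0; q < nq; ++q) tet10_shape(qp(q, 0), qp(q, 1), qp(q, 2), N, dNs[q]);
  vec vol(M, fill::zeros);
  mat Xe, A;
  for (int e = 0; e < M; ++e) {
    element_coords(coords, conn, e, Xe);
    for (int q = 0; q < nq; ++q) {
      A = Xe.t() * dNs[q];
      vol(e) += w(q) * det(A);
    }
  }
  return vol;
}

// Smallest corner-Jacobian determinant of each element (x6 = 6V of corner tet)
// [[Rcpp::export]]
arma::vec cpp_corner_jacobians(const arma::mat &coords, const arma::imat &conn) {
  const int M = conn.n_rows;
  vec dets(M);
  for (int e = 0; e < M; ++e) {
    rowvec x0 = coords.row(conn(e, 0) - 1);
    mat A(3, 3);
    for (int a = 0; a < 3; ++a)
      A.col(a) = (coords.row(conn(e, a + 1) - 1) - x0).t();
    dets(e) = det(A);
  }
  return dets;
}

// Volume-averaged element strains and sorted principal strains.
// [[Rcpp::export]]
Rcpp::List cpp_tet10_strains(const arma::mat &coords, const arma::imat &conn,
                             const arma::vec &u, const arma::mat &qp,
                             const arma::vec &w) {
  const int M = conn.n_rows, nq = qp.n_rows;
  std::vector<mat> dNs(nq);
  vec N;
  for (int q = 0; q < nq; ++q) tet10_shape(qp(q, 0), qp(q, 1), qp(q, 2), N, dNs[q]);
  mat eps(M, 6, fill::zeros), prin(M, 3);
  mat Xe, B(6, 30), A, dNdx;
  vec ue(30);
  for (int e = 0; e < M; ++e) {
    element_coords(coords, conn, e, Xe);
    for (int a = 0; a < 10; ++a) {
      int n = conn(e, a) - 1;
      for (int k = 0; k < 3; ++k) ue(3 * a + k) = u(3 * n + k);
    }
    double vsum = 0.0;
    vec acc(6, fill::zeros);
    for (int q = 0; q < nq; ++q) {
      A = Xe.t() * dNs[q];
      double dv = w(q) * det(A);
      dNdx = dNs[q] * inv(A);
      fill_B(dNdx, B);
      acc += dv * (B * ue);
      vsum += dv;
    }
    acc /= vsum;
    eps.row(e) = acc.t();
    mat T = {{acc(0), acc(3) / 2, acc(5) / 2},
             {acc(3) / 2, acc(1), acc(4) / 2},
             {acc(5) / 2, acc(4) / 2, acc(2)}};
    vec ev;
    eig_sym(ev, T);
    prin(e, 0) = ev(2);
    prin(e, 1) = ev(1);
    prin(e, 2) = ev(0);
  }
  return Rcpp::List::create(Rcpp::Named("strain") = eps,
                            Rcpp::Named("principal") = prin);
}

// Second Piola-Kirchhoff stress of the compressible Neo-Hookean model
// W = C10 (J^{-2/3} I1 - 3) + (1/D1)(J - 1)^2
static mat nh_S(const mat &F, double C10, double D1) {
  mat C = F.t() * F;
  double J = det(F);
  mat Cinv = inv_sympd(symmatu(C));
  double I1 = trace(C);
  mat Siso = 2.0 * C10 * std::pow(J, -2.0 / 3.0) * (eye(3, 3) - (I1 / 3.0) * Cinv);
  mat Svol = (2.0 / D1) * (J - 1.0) * J * Cinv;
  return Siso + Svol;
}

// internal force of one NH element (total Lagrangian, reference coords Xe)
static void nh_fint_elem(const mat &Xe, const vec &ue,
                         const std::vector<mat> &dNs, const vec &w,
                         double C10, double D1, vec &fe) {
  fe.zeros(30);
  const int nq = dNs.size();
  mat A, dNdX, H(3, 3), F, S, P;
  for (int q = 0; q < nq; ++q) {
    A = Xe.t() * dNs[q];
    double detA = det(A);
    dNdX = dNs[q] * inv(A);
    H.zeros();
    for (int a = 0; a < 10; ++a)
      for (int k = 0; k < 3; ++k)
        for (int l = 0; l < 3; ++l)
          H(k, l) += ue(3 * a + k) * dNdX(a, l);
    F = eye(3, 3) + H;
    S = nh_S(F, C10, D1);
    P = F * S;
    for (int a = 0; a < 10; ++a)
      for (int k = 0; k < 3; ++k) {
        double val = 0.0;
        for (int l = 0; l < 3; ++l) val += P(k, l) * dNdX(a, l);
        fe(3 * a + k) += w(q) * detA * val;
      }
  }
}

// Residual and forward-difference tangent of the Neo-Hookean element set.
// [[Rcpp::export]]
Rcpp::List cpp_nh_assemble(const arma::mat &coords, const arma::imat &conn,
                           const arma::vec &u, const arma::vec &C10,
                           const arma::vec &D1, const arma::mat &qp,
                           const arma::vec &w, bool want_tangent) {
  const int M = conn.n_rows, nq = qp.n_rows;
  std::vector<mat> dNs(nq);
  vec N;
  for (int q = 0; q < nq; ++q) tet10_shape(qp(q, 0), qp(q, 1), qp(q, 2), N, dNs[q]);
  vec fint(u.n_elem, fill::zeros);
  std::vector<int> I, J;
  std::vector<double> X;
  if (want_tangent) {
    I.reserve((size_t)M * 900);
    J.reserve((size_t)M * 900);
    X.reserve((size_t)M * 900);
  }
  mat Xe;
  vec ue(30), fe(30), fp(30), up(30);
  for (int e = 0; e < M; ++e) {
    element_coords(coords, conn, e, Xe);
    ivec gd(30);
    for (int a = 0; a < 10; ++a) {
      int n = conn(e, a) - 1;
      for (int k = 0; k < 3; ++k) {
        gd(3 * a + k) = 3 * n + k;
        ue(3 * a + k) = u(3 * n + k);
      }
    }
    nh_fint_elem(Xe, ue, dNs, w, C10(e), D1(e), fe);
    for (int i = 0; i < 30; ++i) fint(gd(i)) += fe(i);
    if (want_tangent) {
      const double h = 1e-7 * (1.0 + norm(ue, "inf"));
      for (int j = 0; j < 30; ++j) {
        up = ue;
        up(j) += h;
        nh_fint_elem(Xe, up, dNs, w, C10(e), D1(e), fp);
        for (int i = 0; i < 30; ++i) {
          I.push_back(gd(i) + 1);
          J.push_back(gd(j) + 1);
          X.push_back((fp(i) - fe(i)) / h);
        }
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("fint") = fint, Rcpp::Named("i") = I,
                            Rcpp::Named("j") = J, Rcpp::Named("x") = X);
}

// Poroelastic coupling Q (u-dof x p-dof) and permeability H (p-dof x p-dof)
// for elements with linear (corner-node) pressure interpolation.
// pmap: 1-based pressure dof of each mesh node, 0 when the node carries none.
// [[Rcpp::export]]
Rcpp::List cpp_poro_mats(const arma::mat &coords, const arma::imat &conn,
                         const arma::vec &perm, const arma::ivec &pmap,
                         const arma::mat &qp, const arma::vec &w) {
  const int M = conn.n_rows, nq = qp.n_rows;
  std::vector<mat> dNs(nq);
  std::vector<vec> Ns(nq);
  for (int q = 0; q < nq; ++q) {
    vec N;
    mat dN;
    tet10_shape(qp(q, 0), qp(q, 1), qp(q, 2), N, dN);
    Ns[q] = N;
    dNs[q] = dN;
  }
  const double dL[4][3] = {{-1, -1, -1}, {1, 0, 0}, {0, 1, 0}, {0, 0, 1}};
  std::vector<int> Qi, Qj, Hi, Hj;
  std::vector<double> Qx, Hx;
  mat Xe, A, dNdx;
  for (int e = 0; e < M; ++e) {
    element_coords(coords, conn, e, Xe);
    mat Qe(30, 4, fill::zeros), He(4, 4, fill::zeros);
    for (int q = 0; q < nq; ++q) {
      A = Xe.t() * dNs[q];
      double dv = w(q) * det(A);
      dNdx = dNs[q] * inv(A);
      const double r = qp(q, 0), s = qp(q, 1), t = qp(q, 2);
      const double Lp[4] = {1.0 - r - s - t, r, s, t};
      mat Ainv = inv(A);
      // gradients of corner barycentric (linear) functions
      mat dLdx(4, 3);
      for (int b = 0; b < 4; ++b)
        for (int k = 0; k < 3; ++k) {
          double v = 0.0;
          for (int l = 0; l < 3; ++l) v += dL[b][l] * Ainv(l, k);
          dLdx(b, k) = v;
        }
      for (int a = 0; a < 10; ++a)
        for (int k = 0; k < 3; ++k)
          for (int b = 0; b < 4; ++b)
            Qe(3 * a + k, b) += dv * dNdx(a, k) * Lp[b];
      for (int b = 0; b < 4; ++b)
        for (int c = 0; c < 4; ++c)
          He(b, c) += dv * perm(e) * dot(dLdx.row(b), dLdx.row(c));
    }
    for (int a = 0; a < 10; ++a) {
      int n = conn(e, a) - 1;
      for (int k = 0; k < 3; ++k)
        for (int b = 0; b < 4; ++b) {
          int pd = pmap(conn(e, b) - 1);
          if (pd > 0) {
            Qi.push_back(3 * n + k + 1);
            Qj.push_back(pd);
            Qx.push_back(Qe(3 * a + k, b));
          }
        }
    }
    for (int b = 0; b < 4; ++b)
      for (int c = 0; c < 4; ++c) {
        int pb = pmap(conn(e, b) - 1), pc = pmap(conn(e, c) - 1);
        if (pb > 0 && pc > 0) {
          Hi.push_back(pb);
          Hj.push_back(pc);
          Hx.push_back(He(b, c));
        }
      }
  }
  return Rcpp::List::create(
      Rcpp::Named("qi") = Qi, Rcpp::Named("qj") = Qj, Rcpp::Named("qx") = Qx,
      Rcpp::Named("hi") = Hi, Rcpp::Named("hj") = Hj, Rcpp::Named("hx") = Hx);
}
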