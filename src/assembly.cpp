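// Element-level kernels for the total-Lagrangian hexahedral inflation solver
// and the gradient-descent logistic trainer. All stress math is the modified
// Mooney-Rivlin model:
//   W = c1(I1-3) + c2(I2-3) + D1[exp(D2(I1-3))-1]
//     + (K1/K2)[exp(K2(I4-1)^2)-1] + (kappa/2)(J-1)^2
// Deviatoric/fiber terms are integrated at the 8 Gauss points; the volumetric
// penalty at the element center (selective reduced integration against
// locking). Tangents are exact directional derivatives dS = C:dE evaluated in
// direct tensor form, so the Newton Jacobian is consistent.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

struct Mat {
  double c1, c2, D1, D2, K1, K2, kappa;
};

// shape-function derivatives wrt local coords at (xi, eta, zeta): 8 x 3
inline void hex_dN(double xi, double eta, double zeta, arma::mat &dN) {
  static const double sx[8] = {-1, 1, 1, -1, -1, 1, 1, -1};
  static const double sy[8] = {-1, -1, 1, 1, -1, -1, 1, 1};
  static const double sz[8] = {-1, -1, -1, -1, 1, 1, 1, 1};
  for (int a = 0; a < 8; ++a) {
    dN(a, 0) = 0.125 * sx[a] * (1 + sy[a] * eta) * (1 + sz[a] * zeta);
    dN(a, 1) = 0.125 * sy[a] * (1 + sx[a] * xi) * (1 + sz[a] * zeta);
    dN(a, 2) = 0.125 * sz[a] * (1 + sx[a] * xi) * (1 + sy[a] * eta);
  }
}

// isochoric + fiber PK2 stress; returns energy density, fills S.
// Includes the -beta ln J compensation term with beta = 2 c1 + 4 c2 + 2 D1 D2,
// which makes the reference state exactly stress-free (the straight-invariant
// terms alone carry a spurious rest hydrostatic stress 2 W1(I) + 4 c2).
// On incompressible paths (J = 1) the term contributes no energy and only a
// hydrostatic reaction, so incompressible closed-form solutions are unchanged.
inline double pk2_dev(const Mat &m, const arma::mat33 &C, const arma::vec3 &nf,
                      arma::mat33 &S, arma::mat33 &Cinv, double &beta,
                      double &W1, double &W11, double &dW4dq,
                      bool want_tangent) {
  double I1 = arma::trace(C);
  double I2 = 0.5 * (I1 * I1 - arma::accu(C % C));
  double X = std::exp(m.D2 * (I1 - 3.0));
  W1 = m.c1 + m.D1 * m.D2 * X;
  double W = m.c1 * (I1 - 3.0) + m.c2 * (I2 - 3.0) + m.D1 * (X - 1.0);
  S = 2.0 * W1 * arma::eye(3, 3) + 2.0 * m.c2 * (I1 * arma::eye(3, 3) - C);
  beta = 2.0 * m.c1 + 4.0 * m.c2 + 2.0 * m.D1 * m.D2;
  Cinv = arma::inv_sympd(arma::symmatu(C));
  double detC = arma::det(C);
  W -= 0.5 * beta * std::log(detC);   // = beta ln J
  S -= beta * Cinv;
  dW4dq = 0.0;
  if (m.K1 > 0) {
    double I4 = arma::as_scalar(nf.t() * C * nf);
    double E4 = std::exp(m.K2 * (I4 - 1.0) * (I4 - 1.0));
    W += (m.K1 / m.K2) * (E4 - 1.0);
    double W4 = 2.0 * m.K1 * (I4 - 1.0) * E4;
    S += 2.0 * W4 * (nf * nf.t());
    if (want_tangent) {
      // d(2 W4)/dI4 * dI4, with dI4 = 2 (n.dE.n)
      dW4dq = 8.0 * m.K1 * E4 * (1.0 + 2.0 * m.K2 * (I4 - 1.0) * (I4 - 1.0));
    }
  }
  W11 = want_tangent ? m.D1 * m.D2 * m.D2 * X : 0.0;
  return W;
}

} // namespace

// Internal force vector, total strain energy and (optionally) the consistent
// tangent triplets of the SRI hexahedral model.
// nodes: N x 3 reference coords; disp: N x 3; elems: M x 8 one-based;
// fibers: M x 3 unit vectors; par: c(c1,c2,D1,D2,K1,K2,kappa).
// [[Rcpp::export(name = ".asm_internal", rng = false)]]
List asm_internal(const arma::mat &nodes, const arma::mat &disp,
                  const arma::imat &elems, const arma::mat &fibers,
                  const arma::vec &par, bool want_tangent) {
  const int nel = elems.n_rows, nn = nodes.n_rows;
  Mat m{par[0], par[1], par[2], par[3], par[4], par[5], par[6]};
  Mat mdev = m;  mdev.kappa = 0.0;

  const double g = 1.0 / std::sqrt(3.0);
  arma::cube dN_gp(8, 3, 9);
  for (int q = 0; q < 8; ++q) {
    arma::mat dn(8, 3);
    hex_dN(((q & 1) ? g : -g), ((q & 2) ? g : -g), ((q & 4) ? g : -g), dn);
    dN_gp.slice(q) = dn;
  }
  {
    arma::mat dn(8, 3);
    hex_dN(0.0, 0.0, 0.0, dn);
    dN_gp.slice(8) = dn;
  }

  arma::vec fint(3 * nn, arma::fill::zeros);
  double energy = 0.0;
  double min_detF = arma::datum::inf;
  int bad_elem = 0;

  const int ntrip = want_tangent ? nel * 24 * 24 : 0;
  IntegerVector ti(ntrip), tj(ntrip);
  NumericVector tv(ntrip);
  int tp = 0;

  arma::mat33 I3 = arma::eye(3, 3);
  for (int e = 0; e < nel; ++e) {
    arma::mat Xe(8, 3), Ue(8, 3);
    for (int a = 0; a < 8; ++a) {
      int n = elems(e, a) - 1;
      Xe.row(a) = nodes.row(n);
      Ue.row(a) = disp.row(n);
    }
    arma::vec3 nf = fibers.row(e).t();
    arma::mat Ke(24, 24, arma::fill::zeros);
    arma::mat fe(8, 3, arma::fill::zeros);

    for (int q = 0; q < 9; ++q) {
      const bool vol_pt = (q == 8);
      const double w_gp = vol_pt ? 8.0 : 1.0;
      arma::mat33 J0 = dN_gp.slice(q).t() * Xe;  // dX/dxi
      double detJ0 = arma::det(J0);
      if (detJ0 <= 0) {
        return List::create(_["ok"] = false, _["bad_elem"] = e + 1,
                            _["reason"] = "reference Jacobian non-positive");
      }
      // chain rule with J0(i,j) = dx_j/dxi_i: dN/dx = dN/dxi * inv(J0)^T
      arma::mat gradN = dN_gp.slice(q) * arma::inv(J0).t();  // 8 x 3, dN/dX
      arma::mat33 F = I3 + Ue.t() * gradN;
      double J = arma::det(F);
      if (J < min_detF) { min_detF = J; bad_elem = e + 1; }
      if (J <= 0) {
        return List::create(_["ok"] = false, _["bad_elem"] = e + 1,
                            _["reason"] = "inverted element (det F <= 0)");
      }
      arma::mat33 C = F.t() * F;
      double w = w_gp * detJ0;

      arma::mat33 S;
      double W1, W11, dW4dq, beta = 0.0;
      arma::mat33 Cinv;
      double trp_c = 0.0;  // kappa J (2J - 1) factor for the volumetric tangent
      if (vol_pt) {
        Cinv = arma::inv_sympd(arma::symmatu(C));
        S = m.kappa * (J - 1.0) * J * Cinv;
        energy += w * 0.5 * m.kappa * (J - 1.0) * (J - 1.0);
        trp_c = m.kappa * J * (2.0 * J - 1.0);
        W1 = W11 = dW4dq = 0.0;
      } else {
        energy += w * pk2_dev(mdev, C, nf, S, Cinv, beta, W1, W11, dW4dq,
                              want_tangent);
      }
      arma::mat33 P = F * S;
      fe += w * (gradN * P.t());

      if (want_tangent) {
        for (int b = 0; b < 8; ++b) {
          for (int j = 0; j < 3; ++j) {
            // dF = e_j (x) gradN_b
            arma::mat33 dF(arma::fill::zeros);
            dF.row(j) = gradN.row(b);
            arma::mat33 dE = 0.5 * (F.t() * dF + dF.t() * F);
            arma::mat33 dS;
            if (vol_pt) {
              double p = arma::accu(Cinv % dE);
              dS = trp_c * p * Cinv
                 - 2.0 * m.kappa * (J - 1.0) * J * (Cinv * dE * Cinv);
            } else {
              double tr_dE = arma::trace(dE);
              dS = 4.0 * W11 * tr_dE * I3 + 4.0 * m.c2 * (tr_dE * I3 - dE)
                 + 2.0 * beta * (Cinv * dE * Cinv);
              if (m.K1 > 0) {
                double qn = arma::as_scalar(nf.t() * dE * nf);
                dS += dW4dq * qn * (nf * nf.t());
              }
            }
            arma::mat33 dP = dF * S + F * dS;
            arma::mat dfe = gradN * dP.t();  // 8 x 3
            for (int a = 0; a < 8; ++a)
              for (int i = 0; i < 3; ++i)
                Ke(3 * a + i, 3 * b + j) += w * dfe(a, i);
          }
        }
      }
    }

    for (int a = 0; a < 8; ++a) {
      int n = elems(e, a) - 1;
      for (int i = 0; i < 3; ++i) fint[3 * n + i] += fe(a, i);
    }
    if (want_tangent) {
      for (int a = 0; a < 8; ++a)
        for (int i = 0; i < 3; ++i)
          for (int b = 0; b < 8; ++b)
            for (int j = 0; j < 3; ++j) {
              ti[tp] = 3 * (elems(e, a) - 1) + i + 1;
              tj[tp] = 3 * (elems(e, b) - 1) + j + 1;
              tv[tp] = Ke(3 * a + i, 3 * b + j);
              ++tp;
            }
    }
  }

  return List::create(_["ok"] = true, _["fint"] = fint, _["energy"] = energy,
                      _["min_detF"] = min_detF, _["min_detF_elem"] = bad_elem,
                      _["ti"] = ti, _["tj"] = tj, _["tv"] = tv);
}

// Follower pressure load on 4-node quads of the deformed endocardial surface.
// Faces must be ordered so the bilinear normal points out of the cavity;
// the nodal force is then p * integral N_a (x_,xi x x_,eta).
// [[Rcpp::export(name = ".asm_pressure", rng = false)]]
List asm_pressure(const arma::mat &nodes, const arma::mat &disp,
                  const arma::imat &faces, double p, bool want_tangent) {
  const int nf = faces.n_rows, nn = nodes.n_rows;
  const double g = 1.0 / std::sqrt(3.0);
  const double sx[4] = {-1, 1, 1, -1}, sy[4] = {-1, -1, 1, 1};

  arma::vec fext(3 * nn, arma::fill::zeros);
  const int ntrip = want_tangent ? nf * 12 * 12 : 0;
  IntegerVector ti(ntrip), tj(ntrip);
  NumericVector tv(ntrip);
  int tp = 0;

  for (int f = 0; f < nf; ++f) {
    arma::mat xe(4, 3);
    for (int a = 0; a < 4; ++a) {
      int n = faces(f, a) - 1;
      xe.row(a) = nodes.row(n) + disp.row(n);
    }
    arma::mat fe(4, 3, arma::fill::zeros);
    arma::mat Ke(12, 12, arma::fill::zeros);
    for (int q = 0; q < 4; ++q) {
      double xi = (q & 1) ? g : -g, eta = (q & 2) ? g : -g;
      double N[4], Nxi[4], Neta[4];
      for (int a = 0; a < 4; ++a) {
        N[a] = 0.25 * (1 + sx[a] * xi) * (1 + sy[a] * eta);
        Nxi[a] = 0.25 * sx[a] * (1 + sy[a] * eta);
        Neta[a] = 0.25 * sy[a] * (1 + sx[a] * xi);
      }
      arma::vec3 txi(arma::fill::zeros), teta(arma::fill::zeros);
      for (int a = 0; a < 4; ++a) {
        txi += Nxi[a] * xe.row(a).t();
        teta += Neta[a] * xe.row(a).t();
      }
      arma::vec3 nrm = arma::cross(txi, teta);
      for (int a = 0; a < 4; ++a) fe.row(a) += (p * N[a]) * nrm.t();

      if (want_tangent) {
        arma::mat33 sk_xi = {{0, -txi[2], txi[1]},
                             {txi[2], 0, -txi[0]},
                             {-txi[1], txi[0], 0}};
        arma::mat33 sk_eta = {{0, -teta[2], teta[1]},
                              {teta[2], 0, -teta[0]},
                              {-teta[1], teta[0], 0}};
        for (int a = 0; a < 4; ++a)
          for (int b = 0; b < 4; ++b) {
            // d(txi x teta)/du_b = -skew(teta) Nxi_b + skew(txi) Neta_b
            arma::mat33 blk =
                p * N[a] * (-sk_eta * Nxi[b] + sk_xi * Neta[b]);
            for (int i = 0; i < 3; ++i)
              for (int j = 0; j < 3; ++j)
                Ke(3 * a + i, 3 * b + j) += blk(i, j);
          }
      }
    }
    for (int a = 0; a < 4; ++a) {
      int n = faces(f, a) - 1;
      for (int i = 0; i < 3; ++i) fext[3 * n + i] += fe(a, i);
    }
    if (want_tangent) {
      for (int a = 0; a < 4; ++a)
        for (int i = 0; i < 3; ++i)
          for (int b = 0; b < 4; ++b)
            for (int j = 0; j < 3; ++j) {
              ti[tp] = 3 * (faces(f, a) - 1) + i + 1;
              tj[tp] = 3 * (faces(f, b) - 1) + j + 1;
              tv[tp] = Ke(3 * a + i, 3 * b + j);
              ++tp;
            }
    }
  }
  return List::create(_["fext"] = fext, _["ti"] = ti, _["tj"] = tj,
                      _["tv"] = tv);
}

// Per-Gauss-point fields of a converged state: reference position, deformed
// position, Cauchy stress (xx,yy,zz,xy,xz,yz) and Green-Lagrange strain.
// [[Rcpp::export(name = ".gp_fields", rng = false)]]
List gp_fields(const arma::mat &nodes, const arma::mat &disp,
               const arma::imat &elems, const arma::mat &fibers,
               const arma::vec &par) {
  const int nel = elems.n_rows;
  Mat m{par[0], par[1], par[2], par[3], par[4], par[5], par[6]};
  const double g = 1.0 / std::sqrt(3.0);
  arma::mat ref(nel * 8, 3), cur(nel * 8, 3), sig(nel * 8, 6), eps(nel * 8, 6);
  IntegerVector elem_id(nel * 8);
  arma::mat dn(8, 3);
  arma::mat33 I3 = arma::eye(3, 3);

  int r = 0;
  for (int e = 0; e < nel; ++e) {
    arma::mat Xe(8, 3), Ue(8, 3);
    for (int a = 0; a < 8; ++a) {
      int n = elems(e, a) - 1;
      Xe.row(a) = nodes.row(n);
      Ue.row(a) = disp.row(n);
    }
    arma::vec3 nf = fibers.row(e).t();
    for (int q = 0; q < 8; ++q) {
      double xi = (q & 1) ? g : -g, eta = (q & 2) ? g : -g,
             zeta = (q & 4) ? g : -g;
      hex_dN(xi, eta, zeta, dn);
      double N[8];
      for (int a = 0; a < 8; ++a) {
        double px = ((a == 1 || a == 2 || a == 5 || a == 6) ? 1 + xi : 1 - xi);
        double py = ((a == 2 || a == 3 || a == 6 || a == 7) ? 1 + eta : 1 - eta);
        double pz = (a >= 4 ? 1 + zeta : 1 - zeta);
        N[a] = 0.125 * px * py * pz;
      }
      arma::mat33 J0 = dn.t() * Xe;
      arma::mat gradN = dn * arma::inv(J0).t();
      arma::mat33 F = I3 + Ue.t() * gradN;
      double J = arma::det(F);
      arma::mat33 C = F.t() * F;
      arma::mat33 S, Cinv;
      double W1, W11, dW4, beta;
      Mat mdev = m; mdev.kappa = 0;
      pk2_dev(mdev, C, nf, S, Cinv, beta, W1, W11, dW4, false);
      S += m.kappa * (J - 1.0) * J * Cinv;
      arma::mat33 sg = (F * S * F.t()) / J;
      arma::mat33 E = 0.5 * (C - I3);
      arma::vec3 xr(arma::fill::zeros), xc(arma::fill::zeros);
      for (int a = 0; a < 8; ++a) {
        xr += N[a] * Xe.row(a).t();
        xc += N[a] * (Xe.row(a) + Ue.row(a)).t();
      }
      ref.row(r) = xr.t();
      cur.row(r) = xc.t();
      sig.row(r) = arma::rowvec({sg(0, 0), sg(1, 1), sg(2, 2),
                                 sg(0, 1), sg(0, 2), sg(1, 2)});
      eps.row(r) = arma::rowvec({E(0, 0), E(1, 1), E(2, 2),
                                 E(0, 1), E(0, 2), E(1, 2)});
      elem_id[r] = e + 1;
      ++r;
    }
  }
  return List::create(_["elem"] = elem_id, _["ref"] = ref, _["cur"] = cur,
                      _["sigma"] = sig, _["E"] = eps);
}

// Gradient descent on the average negative log-likelihood of the
// single-predictor logistic model, beta = 0 start, standardized predictor.
// Returns c(beta0, beta1, iterations, converged, capped).
// [[Rcpp::export(name = ".logit_gd", rng = false)]]
NumericVector logit_gd(const arma::vec &z, const arma::vec &y, int max_iter,
                       double tol, double cap) {
  const int n = z.n_elem;
  double b0 = 0.0, b1 = 0.0;
  // average-NLL Hessian for a standardized predictor is bounded by I/4,
  // so a fixed step of 4 (< 2 / Lipschitz = 8) is stable
  const double step = 4.0;
  int it = 0;
  bool conv = false, capped = false;
  for (it = 0; it < max_iter; ++it) {
    double g0 = 0.0, g1 = 0.0;
    for (int i = 0; i < n; ++i) {
      double eta = b0 + b1 * z[i];
      double p = 1.0 / (1.0 + std::exp(-eta));
      double d = p - y[i];
      g0 += d;
      g1 += d * z[i];
    }
    g0 /= n; g1 /= n;
    if (std::max(std::abs(g0), std::abs(g1)) < tol) { conv = true; break; }
    b0 -= step * g0;
    b1 -= step * g1;
    if (std::abs(b0) > cap || std::abs(b1) > cap) {
      b0 = std::max(std::min(b0, cap), -cap);
      b1 = std::max(std::min(b1, cap), -cap);
      capped = true;
      // keep iterating on the boundary; if the gradient keeps pushing
      // outward the loop exits at max_iter with capped = true
    }
  }
  return NumericVector::create(b0, b1, double(it), double(conv),
                               double(capped));
}
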