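// Isoparametric hexahedral stiffness assembly for small-strain isotropic
// elasticity. Supports 8-node trilinear and 20-node serendipity elements
// (VTK node ordering), full Gauss quadrature (2^3 / 3^3 points).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

namespace {

// local node coordinates, VTK ordering
const double HEX8_XI[8][3] = {
  {-1, -1, -1}, {1, -1, -1}, {1, 1, -1}, {-1, 1, -1},
  {-1, -1,  1}, {1, -1,  1}, {1, 1,  1}, {-1, 1,  1}};

const double HEX20_XI[20][3] = {
  {-1, -1, -1}, {1, -1, -1}, {1, 1, -1}, {-1, 1, -1},
  {-1, -1,  1}, {1, -1,  1}, {1, 1,  1}, {-1, 1,  1},
  { 0, -1, -1}, {1,  0, -1}, {0, 1, -1}, {-1, 0, -1},
  { 0, -1,  1}, {1,  0,  1}, {0, 1,  1}, {-1, 0,  1},
  {-1, -1,  0}, {1, -1,  0}, {1, 1,  0}, {-1, 1,  0}};

void shape_hex8(double xi, double eta, double ze, mat &dN) {
  for (int a = 0; a < 8; ++a) {
    const double xa = HEX8_XI[a][0], ya = HEX8_XI[a][1], za = HEX8_XI[a][2];
    dN(0, a) = 0.125 * xa * (1 + ya * eta) * (1 + za * ze);
    dN(1, a) = 0.125 * ya * (1 + xa * xi) * (1 + za * ze);
    dN(2, a) = 0.125 * za * (1 + xa * xi) * (1 + ya * eta);
  }
}

void shape_hex20(double xi, double eta, double ze, mat &dN) {
  for (int a = 0; a < 20; ++a) {
    const double xa = HEX20_XI[a][0], ya = HEX20_XI[a][1], za = HEX20_XI[a][2];
    if (xa != 0.0 && ya != 0.0 && za != 0.0) {
      // corner: N = 1/8 (1+xx)(1+yy)(1+zz)(xx+yy+zz-2)
      const double px = 1 + xa * xi, py = 1 + ya * eta, pz = 1 + za * ze;
      const double s = xa * xi + ya * eta + za * ze - 2.0;
      dN(0, a) = 0.125 * xa * (py * pz * s + px * py * pz);
      dN(1, a) = 0.125 * ya * (px * pz * s + px * py * pz);
      dN(2, a) = 0.125 * za * (px * py * s + px * py * pz);
    } else if (xa == 0.0) {
      // N = 1/4 (1-xi^2)(1+yy)(1+zz)
      const double py = 1 + ya * eta, pz = 1 + za * ze;
      dN(0, a) = -0.5 * xi * py * pz;
      dN(1, a) = 0.25 * (1 - xi * xi) * ya * pz;
      dN(2, a) = 0.25 * (1 - xi * xi) * py * za;
    } else if (ya == 0.0) {
      const double px = 1 + xa * xi, pz = 1 + za * ze;
      dN(0, a) = 0.25 * (1 - eta * eta) * xa * pz;
      dN(1, a) = -0.5 * eta * px * pz;
      dN(2, a) = 0.25 * (1 - eta * eta) * px * za;
    } else {
      const double px = 1 + xa * xi, py = 1 + ya * eta;
      dN(0, a) = 0.25 * (1 - ze * ze) * xa * py;
      dN(1, a) = 0.25 * (1 - ze * ze) * px * ya;
      dN(2, a) = -0.5 * ze * px * py;
    }
  }
}

} // namespace

//' @noRd
// [[Rcpp::export(name = ".hex_assemble")]]
Rcpp::List hex_assemble(const arma::mat &nodes, const arma::imat &elems,
                        const arma::vec &Evec, const arma::vec &nuvec,
                        const bool enhance = true) {
  const int nel = elems.n_rows;
  const int nen = elems.n_cols; // 8 or 20
  if (nen != 8 && nen != 20)
    Rcpp::stop("elements must have 8 or 20 nodes");
  const int ngp1 = (nen == 8) ? 2 : 3;
  const int ndof = 3 * nen;

  // 1-D Gauss rules
  std::vector<double> gp, gw;
  if (ngp1 == 2) {
    const double a = 1.0 / std::sqrt(3.0);
    gp = {-a, a};
    gw = {1.0, 1.0};
  } else {
    const double a = std::sqrt(0.6);
    gp = {-a, 0.0, a};
    gw = {5.0 / 9.0, 8.0 / 9.0, 5.0 / 9.0};
  }

  const std::size_t nnz = static_cast<std::size_t>(nel) * ndof * ndof;
  Rcpp::IntegerVector ti(nnz), tj(nnz);
  Rcpp::NumericVector tx(nnz);
  Rcpp::NumericVector min_detJ(nel);

  mat dN(3, nen), coords(nen, 3), J(3, 3), dNdx(3, nen);
  mat B(6, ndof), ke(ndof, ndof), D(6, 6);
  // incompatible bending modes (Wilson/Taylor) for the trilinear brick:
  // 9 internal DOFs, centroid-Jacobian correction, condensed out per element
  const bool use_enh = enhance && nen == 8;
  mat Ba(6, 9), Kaa(9, 9), Kda(ndof, 9), J0(3, 3), J0inv(3, 3);

  std::size_t pos = 0;
  for (int e = 0; e < nel; ++e) {
    for (int a = 0; a < nen; ++a) {
      const int g = elems(e, a) - 1; // to 0-based
      coords(a, 0) = nodes(g, 0);
      coords(a, 1) = nodes(g, 1);
      coords(a, 2) = nodes(g, 2);
    }
    const double E = Evec(e), nu = nuvec(e);
    const double lam = E * nu / ((1 + nu) * (1 - 2 * nu));
    const double mu = E / (2 * (1 + nu));
    D.zeros();
    D(0, 0) = D(1, 1) = D(2, 2) = lam + 2 * mu;
    D(0, 1) = D(0, 2) = D(1, 0) = D(1, 2) = D(2, 0) = D(2, 1) = lam;
    D(3, 3) = D(4, 4) = D(5, 5) = mu;

    ke.zeros();
    double detJ0 = 1.0;
    bool enh_ok = use_enh;
    if (use_enh) {
      shape_hex8(0.0, 0.0, 0.0, dN);
      J0 = dN * coords;
      detJ0 = det(J0);
      if (detJ0 > 0) {
        J0inv = inv(J0);
        Kaa.zeros();
        Kda.zeros();
      } else {
        enh_ok = false; // degenerate element: flagged via min_detJ below
      }
    }
    double mdj = datum::inf;
    for (int i = 0; i < ngp1; ++i)
      for (int j = 0; j < ngp1; ++j)
        for (int k = 0; k < ngp1; ++k) {
          if (nen == 8)
            shape_hex8(gp[i], gp[j], gp[k], dN);
          else
            shape_hex20(gp[i], gp[j], gp[k], dN);
          J = dN * coords; // 3x3
          const double detJ = det(J);
          if (detJ < mdj) mdj = detJ;
          if (detJ <= 0) continue; // flagged via min_detJ
          dNdx = solve(J, dN);
          B.zeros();
          for (int a = 0; a < nen; ++a) {
            const double bx = dNdx(0, a), by = dNdx(1, a), bz = dNdx(2, a);
            B(0, 3 * a) = bx;
            B(1, 3 * a + 1) = by;
            B(2, 3 * a + 2) = bz;
            B(3, 3 * a) = by; B(3, 3 * a + 1) = bx;
            B(4, 3 * a + 1) = bz; B(4, 3 * a + 2) = by;
            B(5, 3 * a) = bz; B(5, 3 * a + 2) = bx;
          }
          const double w = detJ * gw[i] * gw[j] * gw[k];
          ke += B.t() * D * B * w;
          if (enh_ok) {
            // mode derivatives in physical coords, centroid-corrected
            vec dP = {-2.0 * gp[i], -2.0 * gp[j], -2.0 * gp[k]};
            const double sc = detJ0 / detJ;
            Ba.zeros();
            for (int m = 0; m < 3; ++m) {
              vec g(3, fill::zeros);
              g(m) = dP(m);
              const vec gx = sc * (J0inv * g); // d(P_m)/dx,y,z
              // strain of u_d = P_m * alpha: same pattern as a nodal column
              for (int d = 0; d < 3; ++d) {
                const int c = 3 * m + d;
                Ba(d, c) = gx(d);
                if (d == 0) { Ba(3, c) = gx(1); Ba(5, c) = gx(2); }
                if (d == 1) { Ba(3, c) = gx(0); Ba(4, c) = gx(2); }
                if (d == 2) { Ba(4, c) = gx(1); Ba(5, c) = gx(0); }
              }
            }
            Kaa += Ba.t() * D * Ba * w;
            Kda += B.t() * D * Ba * w;
          }
        }
    if (enh_ok && mdj > 0) {
      ke -= Kda * solve(Kaa, Kda.t());
    }
    min_detJ[e] = mdj;

    for (int a = 0; a < nen; ++a)
      for (int ra = 0; ra < 3; ++ra) {
        const int gi = 3 * (elems(e, a) - 1) + ra + 1; // 1-based dof
        for (int b = 0; b < nen; ++b)
          for (int rb = 0; rb < 3; ++rb) {
            ti[pos] = gi;
            tj[pos] = 3 * (elems(e, b) - 1) + rb + 1;
            tx[pos] = ke(3 * a + ra, 3 * b + rb);
            ++pos;
          }
      }
  }

  return Rcpp::List::create(Rcpp::Named("i") = ti, Rcpp::Named("j") = tj,
                            Rcpp::Named("x") = tx,
                            Rcpp::Named("min_detJ") = min_detJ);
}
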