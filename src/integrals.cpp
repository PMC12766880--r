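// Gaussian integral engine (McMurchie-Davidson scheme) over contracted
// Cartesian Gaussians.  Supports arbitrary angular momentum via the Hermite
// recursions; the packaged basis (STO-3G) only exercises s and p shells.
//
// Conventions: all lengths in Bohr, energies in Hartree.  Two-electron
// integrals are returned in chemists' notation (ij|kl).

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <array>
using namespace Rcpp;

namespace {

struct Shell {
  int l;
  double A[3];
  std::vector<double> exps;
  std::vector<double> coefs;  // includes primitive + contraction normalization
};

std::vector<Shell> parse_shells(const List& shells) {
  std::vector<Shell> out;
  out.reserve(shells.size());
  for (int s = 0; s < shells.size(); ++s) {
    List sh = shells[s];
    Shell S;
    S.l = as<int>(sh["l"]);
    NumericVector A = sh["center"];
    for (int k = 0; k < 3; ++k) S.A[k] = A[k];
    S.exps = as<std::vector<double>>(sh["exponents"]);
    S.coefs = as<std::vector<double>>(sh["coefficients"]);
    out.push_back(S);
  }
  return out;
}

// Cartesian components (lx,ly,lz) in canonical order: lx descending, then ly.
void cart_components(int l, std::vector<std::array<int,3>>& comps) {
  comps.clear();
  for (int lx = l; lx >= 0; --lx)
    for (int ly = l - lx; ly >= 0; --ly)
      comps.push_back({lx, ly, l - lx - ly});
}

int n_cart(int l) { return (l + 1) * (l + 2) / 2; }

// Hermite expansion coefficient E_t^{ij} for one Cartesian direction.
// Qx = Ax - Bx.  Includes the Gaussian product pre-exponential.
double Ecoef(int i, int j, int t, double Qx, double a, double b) {
  double p = a + b, q = a * b / p;
  if (t < 0 || t > i + j) return 0.0;
  if (i == 0 && j == 0 && t == 0) return std::exp(-q * Qx * Qx);
  if (j == 0) {
    return (1.0 / (2.0 * p)) * Ecoef(i - 1, j, t - 1, Qx, a, b)
         - (q * Qx / a)      * Ecoef(i - 1, j, t,     Qx, a, b)
         + (t + 1.0)         * Ecoef(i - 1, j, t + 1, Qx, a, b);
  }
  return (1.0 / (2.0 * p)) * Ecoef(i, j - 1, t - 1, Qx, a, b)
       + (q * Qx / b)      * Ecoef(i, j - 1, t,     Qx, a, b)
       + (t + 1.0)         * Ecoef(i, j - 1, t + 1, Qx, a, b);
}

// Boys function F_m(x) for m = 0..mmax, written into F.
void boys(int mmax, double x, std::vector<double>& F) {
  F.assign(mmax + 1, 0.0);
  if (x < 1e-14) {
    for (int m = 0; m <= mmax; ++m) F[m] = 1.0 / (2.0 * m + 1.0);
    return;
  }
  if (x < 35.0) {
    // series for the highest order, downward recursion below
    double term = 1.0 / (2.0 * mmax + 1.0);
    double sum = term;
    for (int k = 1; k < 300; ++k) {
      term *= x / (mmax + k + 0.5);
      sum += term;
      if (term < 1e-17 * sum) break;
    }
    double ex = std::exp(-x);
    F[mmax] = sum * ex;
    for (int m = mmax - 1; m >= 0; --m)
      F[m] = (2.0 * x * F[m + 1] + ex) / (2.0 * m + 1.0);
  } else {
    F[0] = 0.5 * std::sqrt(M_PI / x);  // erf(sqrt(x)) ~ 1
    double ex = std::exp(-x);
    for (int m = 0; m < mmax; ++m)
      F[m + 1] = ((2.0 * m + 1.0) * F[m] - ex) / (2.0 * x);
  }
}

// Hermite Coulomb integral R^0_{tuv} via auxiliary recursion.
double Rtuv(int t, int u, int v, int n, double p,
            double PCx, double PCy, double PCz,
            const std::vector<double>& F) {
  if (t == 0 && u == 0 && v == 0)
    return std::pow(-2.0 * p, n) * F[n];
  if (t > 0) {
    double val = 0.0;
    if (t > 1) val += (t - 1) * Rtuv(t - 2, u, v, n + 1, p, PCx, PCy, PCz, F);
    val += PCx * Rtuv(t - 1, u, v, n + 1, p, PCx, PCy, PCz, F);
    return val;
  }
  if (u > 0) {
    double val = 0.0;
    if (u > 1) val += (u - 1) * Rtuv(t, u - 2, v, n + 1, p, PCx, PCy, PCz, F);
    val += PCy * Rtuv(t, u - 1, v, n + 1, p, PCx, PCy, PCz, F);
    return val;
  }
  double val = 0.0;
  if (v > 1) val += (v - 1) * Rtuv(t, u, v - 2, n + 1, p, PCx, PCy, PCz, F);
  val += PCz * Rtuv(t, u, v - 1, n + 1, p, PCx, PCy, PCz, F);
  return val;
}

double S1d(int i, int j, double Qx, double a, double b) {
  return Ecoef(i, j, 0, Qx, a, b) * std::sqrt(M_PI / (a + b));
}

// 1D kinetic building block acting on the ket index j.
double K1d(int i, int j, double Qx, double a, double b) {
  double val = b * (2.0 * j + 1.0) * S1d(i, j, Qx, a, b)
             - 2.0 * b * b * S1d(i, j + 2, Qx, a, b);
  if (j >= 2) val -= 0.5 * j * (j - 1.0) * S1d(i, j - 2, Qx, a, b);
  return val;
}

}  // namespace

// One-electron integrals: overlap, kinetic, nuclear attraction, dipole.
// charges: per-nucleus Z; coords: n_at x 3; origin: dipole gauge origin.
// [[Rcpp::export]]
List cpp_one_electron(List shells_in, NumericVector charges,
                      NumericMatrix coords, NumericVector origin) {
  std::vector<Shell> sh = parse_shells(shells_in);
  int nsh = sh.size();
  std::vector<int> offset(nsh, 0);
  int nao = 0;
  for (int s = 0; s < nsh; ++s) { offset[s] = nao; nao += n_cart(sh[s].l); }

  NumericMatrix S(nao, nao), T(nao, nao), V(nao, nao);
  NumericMatrix DX(nao, nao), DY(nao, nao), DZ(nao, nao);
  std::vector<std::array<int,3>> ca, cb;
  std::vector<double> F;

  for (int si = 0; si < nsh; ++si) {
    for (int sj = si; sj < nsh; ++sj) {
      const Shell &A = sh[si], &B = sh[sj];
      cart_components(A.l, ca);
      cart_components(B.l, cb);
      double AB[3] = {A.A[0] - B.A[0], A.A[1] - B.A[1], A.A[2] - B.A[2]};
      int na = ca.size(), nb = cb.size();
      std::vector<double> Sblk(na * nb, 0.0), Tblk(na * nb, 0.0),
          Vblk(na * nb, 0.0), Dxb(na * nb, 0.0), Dyb(na * nb, 0.0),
          Dzb(na * nb, 0.0);

      for (size_t pi = 0; pi < A.exps.size(); ++pi) {
        for (size_t pj = 0; pj < B.exps.size(); ++pj) {
          double a = A.exps[pi], b = B.exps[pj];
          double cc = A.coefs[pi] * B.coefs[pj];
          double p = a + b;
          double P[3];
          for (int k = 0; k < 3; ++k) P[k] = (a * A.A[k] + b * B.A[k]) / p;

          for (int ia = 0; ia < na; ++ia) {
            for (int ib = 0; ib < nb; ++ib) {
              int l1 = ca[ia][0], m1 = ca[ia][1], n1 = ca[ia][2];
              int l2 = cb[ib][0], m2 = cb[ib][1], n2 = cb[ib][2];
              double sx = S1d(l1, l2, AB[0], a, b);
              double sy = S1d(m1, m2, AB[1], a, b);
              double sz = S1d(n1, n2, AB[2], a, b);
              Sblk[ia * nb + ib] += cc * sx * sy * sz;
              Tblk[ia * nb + ib] += cc * (K1d(l1, l2, AB[0], a, b) * sy * sz +
                                          sx * K1d(m1, m2, AB[1], a, b) * sz +
                                          sx * sy * K1d(n1, n2, AB[2], a, b));
              // dipole: <a|(x - Ox)|b> = [E1 + (Px-Ox) E0] * sqrt(pi/p) per dim
              double spi = std::sqrt(M_PI / p);
              double dx = (Ecoef(l1, l2, 1, AB[0], a, b) +
                           (P[0] - origin[0]) * Ecoef(l1, l2, 0, AB[0], a, b)) * spi;
              double dy = (Ecoef(m1, m2, 1, AB[1], a, b) +
                           (P[1] - origin[1]) * Ecoef(m1, m2, 0, AB[1], a, b)) * spi;
              double dz = (Ecoef(n1, n2, 1, AB[2], a, b) +
                           (P[2] - origin[2]) * Ecoef(n1, n2, 0, AB[2], a, b)) * spi;
              Dxb[ia * nb + ib] += cc * dx * sy * sz;
              Dyb[ia * nb + ib] += cc * sx * dy * sz;
              Dzb[ia * nb + ib] += cc * sx * sy * dz;

              // nuclear attraction
              int Lsum = A.l + B.l;
              for (int at = 0; at < coords.nrow(); ++at) {
                double PC[3] = {P[0] - coords(at, 0), P[1] - coords(at, 1),
                                P[2] - coords(at, 2)};
                double r2 = PC[0]*PC[0] + PC[1]*PC[1] + PC[2]*PC[2];
                boys(Lsum, p * r2, F);
                double vsum = 0.0;
                for (int t = 0; t <= l1 + l2; ++t)
                  for (int u = 0; u <= m1 + m2; ++u)
                    for (int v = 0; v <= n1 + n2; ++v) {
                      double e = Ecoef(l1, l2, t, AB[0], a, b) *
                                 Ecoef(m1, m2, u, AB[1], a, b) *
                                 Ecoef(n1, n2, v, AB[2], a, b);
                      if (e != 0.0)
                        vsum += e * Rtuv(t, u, v, 0, p, PC[0], PC[1], PC[2], F);
                    }
                Vblk[ia * nb + ib] -= cc * charges[at] * (2.0 * M_PI / p) * vsum;
              }
            }
          }
        }
      }
      for (int ia = 0; ia < na; ++ia)
        for (int ib = 0; ib < nb; ++ib) {
          int I = offset[si] + ia, J = offset[sj] + ib;
          S(I, J) = S(J, I) = Sblk[ia * nb + ib];
          T(I, J) = T(J, I) = Tblk[ia * nb + ib];
          V(I, J) = V(J, I) = Vblk[ia * nb + ib];
          DX(I, J) = DX(J, I) = Dxb[ia * nb + ib];
          DY(I, J) = DY(J, I) = Dyb[ia * nb + ib];
          DZ(I, J) = DZ(J, I) = Dzb[ia * nb + ib];
        }
    }
  }
  return List::create(_["S"] = S, _["T"] = T, _["V"] = V,
                      _["DX"] = DX, _["DY"] = DY, _["DZ"] = DZ);
}

// Point-charge (nuclear-attraction-type) integrals W_{mu nu}(r) =
// int phi_mu(x) phi_nu(x) / |x - r| dx, one nao x nao slab per point.
// [[Rcpp::export]]
NumericVector cpp_point_charge_ints(List shells_in, NumericMatrix points) {
  std::vector<Shell> sh = parse_shells(shells_in);
  int nsh = sh.size();
  std::vector<int> offset(nsh, 0);
  int nao = 0;
  for (int s = 0; s < nsh; ++s) { offset[s] = nao; nao += n_cart(sh[s].l); }
  int np = points.nrow();
  NumericVector out(Dimension(nao, nao, np));
  std::vector<std::array<int,3>> ca, cb;
  std::vector<double> F;

  for (int si = 0; si < nsh; ++si)
    for (int sj = si; sj < nsh; ++sj) {
      const Shell &A = sh[si], &B = sh[sj];
      cart_components(A.l, ca);
      cart_components(B.l, cb);
      double AB[3] = {A.A[0] - B.A[0], A.A[1] - B.A[1], A.A[2] - B.A[2]};
      int na = ca.size(), nb = cb.size();
      int Lsum = A.l + B.l;
      for (size_t pi = 0; pi < A.exps.size(); ++pi)
        for (size_t pj = 0; pj < B.exps.size(); ++pj) {
          double a = A.exps[pi], b = B.exps[pj];
          double cc = A.coefs[pi] * B.coefs[pj];
          double p = a + b;
          double P[3];
          for (int k = 0; k < 3; ++k) P[k] = (a * A.A[k] + b * B.A[k]) / p;
          for (int pt = 0; pt < np; ++pt) {
            double PC[3] = {P[0] - points(pt, 0), P[1] - points(pt, 1),
                            P[2] - points(pt, 2)};
            double r2 = PC[0]*PC[0] + PC[1]*PC[1] + PC[2]*PC[2];
            boys(Lsum, p * r2, F);
            for (int ia = 0; ia < na; ++ia)
              for (int ib = 0; ib < nb; ++ib) {
                int l1 = ca[ia][0], m1 = ca[ia][1], n1 = ca[ia][2];
                int l2 = cb[ib][0], m2 = cb[ib][1], n2 = cb[ib][2];
                double vsum = 0.0;
                for (int t = 0; t <= l1 + l2; ++t)
                  for (int u = 0; u <= m1 + m2; ++u)
                    for (int v = 0; v <= n1 + n2; ++v) {
                      double e = Ecoef(l1, l2, t, AB[0], a, b) *
                                 Ecoef(m1, m2, u, AB[1], a, b) *
                                 Ecoef(n1, n2, v, AB[2], a, b);
                      if (e != 0.0)
                        vsum += e * Rtuv(t, u, v, 0, p, PC[0], PC[1], PC[2], F);
                    }
                double val = cc * (2.0 * M_PI / p) * vsum;
                int I = offset[si] + ia, J = offset[sj] + ib;
                out[I + nao * J + (R_xlen_t)nao * nao * pt] += val;
                if (I != J)
                  out[J + nao * I + (R_xlen_t)nao * nao * pt] += val;
              }
          }
        }
    }
  return out;
}

// Full two-electron integral tensor, chemists' notation (ij|kl).
// [[Rcpp::export]]
NumericVector cpp_eri(List shells_in) {
  std::vector<Shell> sh = parse_shells(shells_in);
  int nsh = sh.size();
  std::vector<int> offset(nsh, 0);
  int nao = 0;
  for (int s = 0; s < nsh; ++s) { offset[s] = nao; nao += n_cart(sh[s].l); }
  R_xlen_t n = nao;
  NumericVector out(n * n * n * n);
  out.attr("dim") = IntegerVector::create(nao, nao, nao, nao);
  double* g = out.begin();

  std::vector<std::array<int,3>> ca, cb, cc_, cd;
  std::vector<double> F;

  for (int si = 0; si < nsh; ++si)
  for (int sj = 0; sj <= si; ++sj)
  for (int sk = 0; sk <= si; ++sk)
  for (int sl = 0; sl <= (sk == si ? sj : sk); ++sl) {
    const Shell &A = sh[si], &B = sh[sj], &C = sh[sk], &D = sh[sl];
    cart_components(A.l, ca); cart_components(B.l, cb);
    cart_components(C.l, cc_); cart_components(D.l, cd);
    int na = ca.size(), nb = cb.size(), nc = cc_.size(), nd = cd.size();
    double AB[3] = {A.A[0]-B.A[0], A.A[1]-B.A[1], A.A[2]-B.A[2]};
    double CD[3] = {C.A[0]-D.A[0], C.A[1]-D.A[1], C.A[2]-D.A[2]};
    int Ltot = A.l + B.l + C.l + D.l;
    std::vector<double> blk(na * nb * nc * nd, 0.0);

    for (size_t pi = 0; pi < A.exps.size(); ++pi)
    for (size_t pj = 0; pj < B.exps.size(); ++pj)
    for (size_t pk = 0; pk < C.exps.size(); ++pk)
    for (size_t pl = 0; pl < D.exps.size(); ++pl) {
      double a = A.exps[pi], b = B.exps[pj], c = C.exps[pk], d = D.exps[pl];
      double coef = A.coefs[pi] * B.coefs[pj] * C.coefs[pk] * D.coefs[pl];
      double p = a + b, q = c + d;
      double alpha = p * q / (p + q);
      double P[3], Q[3], PQ[3];
      for (int k = 0; k < 3; ++k) {
        P[k] = (a * A.A[k] + b * B.A[k]) / p;
        Q[k] = (c * C.A[k] + d * D.A[k]) / q;
        PQ[k] = P[k] - Q[k];
      }
      double r2 = PQ[0]*PQ[0] + PQ[1]*PQ[1] + PQ[2]*PQ[2];
      boys(Ltot, alpha * r2, F);
      double pref = 2.0 * std::pow(M_PI, 2.5) / (p * q * std::sqrt(p + q));

      for (int ia = 0; ia < na; ++ia)
      for (int ib = 0; ib < nb; ++ib)
      for (int ic = 0; ic < nc; ++ic)
      for (int id = 0; id < nd; ++id) {
        int l1 = ca[ia][0], m1 = ca[ia][1], n1 = ca[ia][2];
        int l2 = cb[ib][0], m2 = cb[ib][1], n2 = cb[ib][2];
        int l3 = cc_[ic][0], m3 = cc_[ic][1], n3 = cc_[ic][2];
        int l4 = cd[id][0], m4 = cd[id][1], n4 = cd[id][2];
        double val = 0.0;
        for (int t = 0; t <= l1 + l2; ++t) {
          double e1t = Ecoef(l1, l2, t, AB[0], a, b);
          if (e1t == 0.0) continue;
          for (int u = 0; u <= m1 + m2; ++u) {
            double e1u = Ecoef(m1, m2, u, AB[1], a, b);
            if (e1u == 0.0) continue;
            for (int v = 0; v <= n1 + n2; ++v) {
              double e1v = Ecoef(n1, n2, v, AB[2], a, b);
              if (e1v == 0.0) continue;
              for (int tt = 0; tt <= l3 + l4; ++tt) {
                double e2t = Ecoef(l3, l4, tt, CD[0], c, d);
                if (e2t == 0.0) continue;
                for (int uu = 0; uu <= m3 + m4; ++uu) {
                  double e2u = Ecoef(m3, m4, uu, CD[1], c, d);
                  if (e2u == 0.0) continue;
                  for (int vv = 0; vv <= n3 + n4; ++vv) {
                    double e2v = Ecoef(n3, n4, vv, CD[2], c, d);
                    if (e2v == 0.0) continue;
                    double sgn = ((tt + uu + vv) % 2 == 0) ? 1.0 : -1.0;
                    val += e1t * e1u * e1v * e2t * e2u * e2v * sgn *
                           Rtuv(t + tt, u + uu, v + vv, 0, alpha,
                                PQ[0], PQ[1], PQ[2], F);
                  }
                }
              }
            }
          }
        }
        blk[((ia * nb + ib) * nc + ic) * nd + id] += coef * pref * val;
      }
    }

    // scatter with 8-fold permutational symmetry
    for (int ia = 0; ia < na; ++ia)
    for (int ib = 0; ib < nb; ++ib)
    for (int ic = 0; ic < nc; ++ic)
    for (int id = 0; id < nd; ++id) {
      double val = blk[((ia * nb + ib) * nc + ic) * nd + id];
      R_xlen_t I = offset[si] + ia, J = offset[sj] + ib,
               K = offset[sk] + ic, L = offset[sl] + id;
      g[I + n*J + n*n*K + n*n*n*L] = val;
      g[J + n*I + n*n*K + n*n*n*L] = val;
      g[I + n*J + n*n*L + n*n*n*K] = val;
      g[J + n*I + n*n*L + n*n*n*K] = val;
      g[K + n*L + n*n*I + n*n*n*J] = val;
      g[L + n*K + n*n*I + n*n*n*J] = val;
      g[K + n*L + n*n*J + n*n*n*I] = val;
      g[L + n*K + n*n*J + n*n*n*I] = val;
    }
  }
  return out;
}

// AO values and (optionally) first/second Cartesian derivatives at points.
// Returns values (np x nao), grad (np x nao x 3), hess (np x nao x 6)
// with second-derivative order xx, xy, xz, yy, yz, zz.
// [[Rcpp::export]]
List cpp_ao_eval(List shells_in, NumericMatrix points, int deriv) {
  std::vector<Shell> sh = parse_shells(shells_in);
  int nsh = sh.size();
  std::vector<int> offset(nsh, 0);
  int nao = 0;
  for (int s = 0; s < nsh; ++s) { offset[s] = nao; nao += n_cart(sh[s].l); }
  int np = points.nrow();
  NumericMatrix vals(np, nao);
  NumericVector grad, hess;
  if (deriv >= 1) grad = NumericVector(Dimension(np, nao, 3));
  if (deriv >= 2) hess = NumericVector(Dimension(np, nao, 6));
  std::vector<std::array<int,3>> comps;

  // 1D factor f(x) = x^l exp(-a x^2) and its first two derivatives
  auto f012 = [](double x, int l, double a, double* f) {
    double e = std::exp(-a * x * x);
    double xl = (l == 0) ? 1.0 : std::pow(x, l);
    double xlm1 = (l >= 1) ? ((l == 1) ? 1.0 : std::pow(x, l - 1)) : 0.0;
    double xlm2 = (l >= 2) ? ((l == 2) ? 1.0 : std::pow(x, l - 2)) : 0.0;
    f[0] = xl * e;
    f[1] = (l * xlm1 - 2.0 * a * x * xl) * e;
    f[2] = (l * (l - 1.0) * xlm2 - 2.0 * a * (2.0 * l + 1.0) * xl +
            4.0 * a * a * x * x * xl) * e;
  };

  for (int s = 0; s < nsh; ++s) {
    const Shell& A = sh[s];
    cart_components(A.l, comps);
    for (int pt = 0; pt < np; ++pt) {
      double d[3] = {points(pt, 0) - A.A[0], points(pt, 1) - A.A[1],
                     points(pt, 2) - A.A[2]};
      for (size_t ic = 0; ic < comps.size(); ++ic) {
        int ao = offset[s] + ic;
        double v = 0.0, g3[3] = {0, 0, 0}, h6[6] = {0, 0, 0, 0, 0, 0};
        for (size_t pi = 0; pi < A.exps.size(); ++pi) {
          double a = A.exps[pi], cc = A.coefs[pi];
          double fx[3], fy[3], fz[3];
          f012(d[0], comps[ic][0], a, fx);
          f012(d[1], comps[ic][1], a, fy);
          f012(d[2], comps[ic][2], a, fz);
          v += cc * fx[0] * fy[0] * fz[0];
          if (deriv >= 1) {
            g3[0] += cc * fx[1] * fy[0] * fz[0];
            g3[1] += cc * fx[0] * fy[1] * fz[0];
            g3[2] += cc * fx[0] * fy[0] * fz[1];
          }
          if (deriv >= 2) {
            h6[0] += cc * fx[2] * fy[0] * fz[0];  // xx
            h6[1] += cc * fx[1] * fy[1] * fz[0];  // xy
            h6[2] += cc * fx[1] * fy[0] * fz[1];  // xz
            h6[3] += cc * fx[0] * fy[2] * fz[0];  // yy
            h6[4] += cc * fx[0] * fy[1] * fz[1];  // yz
            h6[5] += cc * fx[0] * fy[0] * fz[2];  // zz
          }
        }
        vals(pt, ao) = v;
        if (deriv >= 1)
          for (int k = 0; k < 3; ++k)
            grad[pt + (R_xlen_t)np * ao + (R_xlen_t)np * nao * k] = g3[k];
        if (deriv >= 2)
          for (int k = 0; k < 6; ++k)
            hess[pt + (R_xlen_t)np * ao + (R_xlen_t)np * nao * k] = h6[k];
      }
    }
  }
  List out = List::create(_["values"] = vals);
  if (deriv >= 1) out["grad"] = grad;
  if (deriv >= 2) out["hess"] = hess;
  return out;
}
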