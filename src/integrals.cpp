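// Gaussian one- and two-electron integrals over contracted Cartesian
// s/p shells, McMurchie-Davidson scheme (Hermite expansion + Boys function).
// Dimensions here are small (minimal bases); clarity over blocking.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Hermite expansion coefficient E_t^{ij} for one Cartesian direction.
// Qx = Ax - Bx. Recursion after Helgaker/Taylor; depth is tiny (l <= 3).
static double Ecoef(int i, int j, int t, double Qx, double a, double b) {
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

// Boys function F_0..F_mmax at T.
static void boys(int mmax, double T, double* F) {
  if (T < 1e-13) {
    for (int m = 0; m <= mmax; ++m) F[m] = 1.0 / (2.0 * m + 1.0) - T / (2.0 * m + 3.0);
    return;
  }
  if (T > 35.0) {
    F[0] = 0.5 * std::sqrt(M_PI / T);
    double eT = std::exp(-T);
    for (int m = 1; m <= mmax; ++m) F[m] = ((2.0 * m - 1.0) * F[m - 1] - eT) / (2.0 * T);
    return;
  }
  double sum = 1.0 / (2.0 * mmax + 1.0), term = sum;
  for (int k = 1; k < 1000; ++k) {
    term *= 2.0 * T / (2.0 * mmax + 2.0 * k + 1.0);
    sum += term;
    if (term < 1e-17 * sum) break;
  }
  double eT = std::exp(-T);
  F[mmax] = eT * sum;
  for (int m = mmax - 1; m >= 0; --m) F[m] = (2.0 * T * F[m + 1] + eT) / (2.0 * m + 1.0);
}

// Hermite Coulomb integral R^n_{tuv}.
static double hermiteR(int t, int u, int v, int n, double p,
                       double X, double Y, double Z, const double* F) {
  if (t < 0 || u < 0 || v < 0) return 0.0;
  if (t == 0 && u == 0 && v == 0) {
    double val = F[n];
    for (int k = 0; k < n; ++k) val *= -2.0 * p;
    return val;
  }
  if (t > 0)
    return (t - 1.0) * hermiteR(t - 2, u, v, n + 1, p, X, Y, Z, F)
         + X * hermiteR(t - 1, u, v, n + 1, p, X, Y, Z, F);
  if (u > 0)
    return (u - 1.0) * hermiteR(t, u - 2, v, n + 1, p, X, Y, Z, F)
         + Y * hermiteR(t, u - 1, v, n + 1, p, X, Y, Z, F);
  return (v - 1.0) * hermiteR(t, u, v - 2, n + 1, p, X, Y, Z, F)
       + Z * hermiteR(t, u, v - 1, n + 1, p, X, Y, Z, F);
}

struct AO {
  int l[3];
  double R[3];
  std::vector<double> alpha, coef; // coef includes primitive norms
};

static std::vector<AO> unpack(const List& basis) {
  IntegerMatrix l = basis["l"];
  NumericMatrix cen = basis["center"];
  IntegerVector ps = basis["pstart"], pc = basis["pcount"];
  NumericVector al = basis["alpha"], co = basis["coef"];
  int n = l.nrow();
  std::vector<AO> ao(n);
  for (int i = 0; i < n; ++i) {
    for (int d = 0; d < 3; ++d) { ao[i].l[d] = l(i, d); ao[i].R[d] = cen(i, d); }
    for (int k = 0; k < pc[i]; ++k) {
      ao[i].alpha.push_back(al[ps[i] + k]);
      ao[i].coef.push_back(co[ps[i] + k]);
    }
  }
  return ao;
}

// 1D overlap between primitives with angular momenta i, j.
static inline double S1d(int i, int j, double Q, double a, double b) {
  return Ecoef(i, j, 0, Q, a, b) * std::sqrt(M_PI / (a + b));
}

// [[Rcpp::export(name = ".overlap_matrix")]]
NumericMatrix overlap_matrix_cpp(List basis) {
  std::vector<AO> ao = unpack(basis);
  int n = ao.size();
  NumericMatrix S(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = i; j < n; ++j) {
      double s = 0.0;
      for (size_t p = 0; p < ao[i].alpha.size(); ++p)
        for (size_t q = 0; q < ao[j].alpha.size(); ++q) {
          double a = ao[i].alpha[p], b = ao[j].alpha[q], v = 1.0;
          for (int d = 0; d < 3; ++d)
            v *= S1d(ao[i].l[d], ao[j].l[d], ao[i].R[d] - ao[j].R[d], a, b);
          s += ao[i].coef[p] * ao[j].coef[q] * v;
        }
      S(i, j) = S(j, i) = s;
    }
  return S;
}

// 1D kinetic integral via shifted overlaps.
static double T1d(int i, int j, double Q, double a, double b) {
  double t = -2.0 * b * b * S1d(i, j + 2, Q, a, b)
           + b * (2.0 * j + 1.0) * S1d(i, j, Q, a, b);
  if (j >= 2) t -= 0.5 * j * (j - 1.0) * S1d(i, j - 2, Q, a, b);
  return t;
}

// [[Rcpp::export(name = ".kinetic_matrix")]]
NumericMatrix kinetic_matrix_cpp(List basis) {
  std::vector<AO> ao = unpack(basis);
  int n = ao.size();
  NumericMatrix T(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = i; j < n; ++j) {
      double s = 0.0;
      for (size_t p = 0; p < ao[i].alpha.size(); ++p)
        for (size_t q = 0; q < ao[j].alpha.size(); ++q) {
          double a = ao[i].alpha[p], b = ao[j].alpha[q];
          double Sx[3], Tx[3];
          for (int d = 0; d < 3; ++d) {
            double Q = ao[i].R[d] - ao[j].R[d];
            Sx[d] = S1d(ao[i].l[d], ao[j].l[d], Q, a, b);
            Tx[d] = T1d(ao[i].l[d], ao[j].l[d], Q, a, b);
          }
          s += ao[i].coef[p] * ao[j].coef[q] *
               (Tx[0] * Sx[1] * Sx[2] + Sx[0] * Tx[1] * Sx[2] + Sx[0] * Sx[1] * Tx[2]);
        }
      T(i, j) = T(j, i) = s;
    }
  return T;
}

// Electron-nuclear attraction for a subset of nuclei (charges Z at centers C),
// returned with its physical (negative) sign.
// [[Rcpp::export(name = ".nuclear_attraction")]]
NumericMatrix nuclear_attraction_cpp(List basis, NumericVector Z, NumericMatrix C) {
  std::vector<AO> ao = unpack(basis);
  int n = ao.size(), nat = Z.size();
  NumericMatrix V(n, n);
  double F[16];
  for (int i = 0; i < n; ++i)
    for (int j = i; j < n; ++j) {
      double s = 0.0;
      int lt = ao[i].l[0] + ao[j].l[0], lu = ao[i].l[1] + ao[j].l[1],
          lv = ao[i].l[2] + ao[j].l[2];
      for (size_t p = 0; p < ao[i].alpha.size(); ++p)
        for (size_t q = 0; q < ao[j].alpha.size(); ++q) {
          double a = ao[i].alpha[p], b = ao[j].alpha[q], pp = a + b;
          double P[3], E[3][8];
          for (int d = 0; d < 3; ++d) {
            P[d] = (a * ao[i].R[d] + b * ao[j].R[d]) / pp;
            for (int t = 0; t <= ao[i].l[d] + ao[j].l[d]; ++t)
              E[d][t] = Ecoef(ao[i].l[d], ao[j].l[d], t, ao[i].R[d] - ao[j].R[d], a, b);
          }
          for (int A = 0; A < nat; ++A) {
            double X = P[0] - C(A, 0), Y = P[1] - C(A, 1), Zc = P[2] - C(A, 2);
            double T = pp * (X * X + Y * Y + Zc * Zc);
            boys(lt + lu + lv, T, F);
            double acc = 0.0;
            for (int t = 0; t <= lt; ++t)
              for (int u = 0; u <= lu; ++u)
                for (int v = 0; v <= lv; ++v)
                  acc += E[0][t] * E[1][u] * E[2][v] *
                         hermiteR(t, u, v, 0, pp, X, Y, Zc, F);
            s += -Z[A] * ao[i].coef[p] * ao[j].coef[q] * (2.0 * M_PI / pp) * acc;
          }
        }
      V(i, j) = V(j, i) = s;
    }
  return V;
}

// Full two-electron integral array (mu nu | la si), chemists' notation,
// returned as an n^4 vector in column-major (mu fastest) order.
// [[Rcpp::export(name = ".eri_array")]]
NumericVector eri_array_cpp(List basis) {
  std::vector<AO> ao = unpack(basis);
  int n = ao.size();
  NumericVector out((double)n * n * n * n);
  double F[32];
  std::vector<int> idx;
  // loop unique (i<=j), (k<=l), (ij)<=(kl)
  for (int i = 0; i < n; ++i)
    for (int j = i; j < n; ++j)
      for (int k = i; k < n; ++k)
        for (int l = (k == i ? j : k); l < n; ++l) {
          double val = 0.0;
          int l1t = ao[i].l[0] + ao[j].l[0], l1u = ao[i].l[1] + ao[j].l[1],
              l1v = ao[i].l[2] + ao[j].l[2];
          int l2t = ao[k].l[0] + ao[l].l[0], l2u = ao[k].l[1] + ao[l].l[1],
              l2v = ao[k].l[2] + ao[l].l[2];
          int mtot = l1t + l1u + l1v + l2t + l2u + l2v;
          for (size_t p1 = 0; p1 < ao[i].alpha.size(); ++p1)
            for (size_t p2 = 0; p2 < ao[j].alpha.size(); ++p2) {
              double a = ao[i].alpha[p1], b = ao[j].alpha[p2], p = a + b;
              double Pc[3], E1[3][8];
              for (int d = 0; d < 3; ++d) {
                Pc[d] = (a * ao[i].R[d] + b * ao[j].R[d]) / p;
                for (int t = 0; t <= ao[i].l[d] + ao[j].l[d]; ++t)
                  E1[d][t] = Ecoef(ao[i].l[d], ao[j].l[d], t,
                                   ao[i].R[d] - ao[j].R[d], a, b);
              }
              double c12 = ao[i].coef[p1] * ao[j].coef[p2];
              for (size_t p3 = 0; p3 < ao[k].alpha.size(); ++p3)
                for (size_t p4 = 0; p4 < ao[l].alpha.size(); ++p4) {
                  double c = ao[k].alpha[p3], d2 = ao[l].alpha[p4], q = c + d2;
                  double Qc[3], E2[3][8];
                  for (int d = 0; d < 3; ++d) {
                    Qc[d] = (c * ao[k].R[d] + d2 * ao[l].R[d]) / q;
                    for (int t = 0; t <= ao[k].l[d] + ao[l].l[d]; ++t)
                      E2[d][t] = Ecoef(ao[k].l[d], ao[l].l[d], t,
                                       ao[k].R[d] - ao[l].R[d], c, d2);
                  }
                  double alpha = p * q / (p + q);
                  double X = Pc[0] - Qc[0], Y = Pc[1] - Qc[1], Zc = Pc[2] - Qc[2];
                  boys(mtot, alpha * (X * X + Y * Y + Zc * Zc), F);
                  double acc = 0.0;
                  for (int t = 0; t <= l1t; ++t)
                    for (int u = 0; u <= l1u; ++u)
                      for (int v = 0; v <= l1v; ++v) {
                        double e1 = E1[0][t] * E1[1][u] * E1[2][v];
                        if (e1 == 0.0) continue;
                        for (int tt = 0; tt <= l2t; ++tt)
                          for (int uu = 0; uu <= l2u; ++uu)
                            for (int vv = 0; vv <= l2v; ++vv) {
                              double e2 = E2[0][tt] * E2[1][uu] * E2[2][vv];
                              if (e2 == 0.0) continue;
                              double sgn = ((tt + uu + vv) % 2) ? -1.0 : 1.0;
                              acc += e1 * e2 * sgn *
                                     hermiteR(t + tt, u + uu, v + vv, 0, alpha,
                                              X, Y, Zc, F);
                            }
                      }
                  val += c12 * ao[k].coef[p3] * ao[l].coef[p4] *
                         2.0 * std::pow(M_PI, 2.5) /
                         (p * q * std::sqrt(p + q)) * acc;
                }
            }
          // scatter to the 8 permutation-equivalent slots
          long N = n;
          long combos[8][4] = {
            {i, j, k, l}, {j, i, k, l}, {i, j, l, k}, {j, i, l, k},
            {k, l, i, j}, {l, k, i, j}, {k, l, j, i}, {l, k, j, i}};
          for (int m = 0; m < 8; ++m) {
            long a1 = combos[m][0], a2 = combos[m][1], a3 = combos[m][2],
                 a4 = combos[m][3];
            out[a1 + N * (a2 + N * (a3 + N * a4))] = val;
          }
        }
  out.attr("dim") = IntegerVector::create(n, n, n, n);
  return out;
}

// AO values chi_mu(r) at a set of points (m x 3), returns m x n matrix.
// [[Rcpp::export(name = ".ao_values")]]
NumericMatrix ao_values_cpp(List basis, NumericMatrix pts) {
  std::vector<AO> ao = unpack(basis);
  int n = ao.size(), m = pts.nrow();
  NumericMatrix X(m, n);
  for (int j = 0; j < n; ++j)
    for (int i = 0; i < m; ++i) {
      double dx = pts(i, 0) - ao[j].R[0], dy = pts(i, 1) - ao[j].R[1],
             dz = pts(i, 2) - ao[j].R[2];
      double r2 = dx * dx + dy * dy + dz * dz, ang = 1.0;
      for (int k = 0; k < ao[j].l[0]; ++k) ang *= dx;
      for (int k = 0; k < ao[j].l[1]; ++k) ang *= dy;
      for (int k = 0; k < ao[j].l[2]; ++k) ang *= dz;
      double v = 0.0;
      for (size_t p = 0; p < ao[j].alpha.size(); ++p)
        v += ao[j].coef[p] * std::exp(-ao[j].alpha[p] * r2);
      X(i, j) = ang * v;
    }
  return X;
}
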