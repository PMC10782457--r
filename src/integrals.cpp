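// McMurchie-Davidson evaluation of Gaussian AO integrals.
//
// Contracted Cartesian Gaussians; general angular momentum in the recursions
// (the shipped basis registry uses s and p shells). One-electron operators:
// overlap, kinetic, nuclear attraction, Cartesian moment about an origin,
// del (d/dx_k) and (r - O) x del. Two-electron repulsion integrals over the
// full AO quartet list with 8-fold permutational symmetry.

#include <Rcpp.h>
#include <cmath>
#include <map>
#include <vector>

using namespace Rcpp;

// Boys function F_0..F_mmax at x
static void boys_array(int mmax, double x, std::vector<double>& F) {
  F.assign(mmax + 1, 0.0);
  if (x < 1e-13) {
    for (int m = 0; m <= mmax; ++m) F[m] = 1.0 / (2.0 * m + 1.0);
    return;
  }
  if (x < 35.0) {
    // convergent series at mmax, then stable downward recursion
    double t = 1.0 / (2.0 * mmax + 1.0), s = t;
    for (int i = 0; i < 300; ++i) {
      t *= 2.0 * x / (2.0 * mmax + 2.0 * i + 3.0);
      s += t;
      if (t < 1e-17 * s) break;
    }
    double ex = std::exp(-x);
    F[mmax] = s * ex;
    for (int m = mmax - 1; m >= 0; --m)
      F[m] = (2.0 * x * F[m + 1] + ex) / (2.0 * m + 1.0);
  } else {
    double ex = std::exp(-x);
    F[0] = 0.5 * std::sqrt(M_PI / x);
    for (int m = 0; m < mmax; ++m)
      F[m + 1] = ((2.0 * m + 1.0) * F[m] - ex) / (2.0 * x);
  }
}

// Hermite expansion coefficient E_t^{ij}
static double Ecoef(int i, int j, int t, double Qx, double a, double b) {
  double p = a + b, q = a * b / p;
  if (t < 0 || t > i + j) return 0.0;
  if (i == 0 && j == 0 && t == 0) return std::exp(-q * Qx * Qx);
  if (j == 0) {
    return (1.0 / (2.0 * p)) * Ecoef(i - 1, j, t - 1, Qx, a, b)
         - (q * Qx / a) * Ecoef(i - 1, j, t, Qx, a, b)
         + (t + 1.0) * Ecoef(i - 1, j, t + 1, Qx, a, b);
  }
  return (1.0 / (2.0 * p)) * Ecoef(i, j - 1, t - 1, Qx, a, b)
       + (q * Qx / b) * Ecoef(i, j - 1, t, Qx, a, b)
       + (t + 1.0) * Ecoef(i, j - 1, t + 1, Qx, a, b);
}

static double overlap1d(int i, int j, double a, double b, double Ax, double Bx) {
  return Ecoef(i, j, 0, Ax - Bx, a, b) * std::sqrt(M_PI / (a + b));
}

static double kinetic1d(int i, int j, double a, double b, double Ax, double Bx) {
  double t = 4.0 * b * b * overlap1d(i, j + 2, a, b, Ax, Bx)
           - 2.0 * b * (2.0 * j + 1.0) * overlap1d(i, j, a, b, Ax, Bx);
  if (j >= 2) t += j * (j - 1.0) * overlap1d(i, j - 2, a, b, Ax, Bx);
  return t;
}

static double moment1d(int i, int j, int e, double a, double b,
                       double Ax, double Bx, double Cx) {
  // <i|(x - Cx)^e|j> via binomial expansion about Bx
  double val = 0.0, bc = Bx - Cx;
  for (int k = 0; k <= e; ++k) {
    double binom = (e == 1) ? 1.0 : R::choose(e, k);
    val += binom * std::pow(bc, e - k) * overlap1d(i, j + k, a, b, Ax, Bx);
  }
  return val;
}

static double deriv1d(int i, int j, double a, double b, double Ax, double Bx) {
  double v = 2.0 * b * overlap1d(i, j + 1, a, b, Ax, Bx);
  if (j >= 1) v -= j * overlap1d(i, j - 1, a, b, Ax, Bx);
  return v;
}

// Hermite Coulomb integral R_{tuv}^{(0)} with memoization
struct RKey { int t, u, v, n; bool operator<(const RKey& o) const {
  if (t != o.t) return t < o.t;
  if (u != o.u) return u < o.u;
  if (v != o.v) return v < o.v;
  return n < o.n; } };

static double Rherm(int t, int u, int v, int n, double p, const double* PC,
                    std::map<RKey, double>& cache, const std::vector<double>& F) {
  if (t < 0 || u < 0 || v < 0) return 0.0;
  if (t == 0 && u == 0 && v == 0) {
    double s = 1.0;
    for (int k = 0; k < n; ++k) s *= -2.0 * p;
    return s * F[n];
  }
  RKey key{t, u, v, n};
  auto it = cache.find(key);
  if (it != cache.end()) return it->second;
  double val;
  if (t > 0) {
    val = (t - 1.0) * Rherm(t - 2, u, v, n + 1, p, PC, cache, F)
        + PC[0] * Rherm(t - 1, u, v, n + 1, p, PC, cache, F);
  } else if (u > 0) {
    val = (u - 1.0) * Rherm(t, u - 2, v, n + 1, p, PC, cache, F)
        + PC[1] * Rherm(t, u - 1, v, n + 1, p, PC, cache, F);
  } else {
    val = (v - 1.0) * Rherm(t, u, v - 2, n + 1, p, PC, cache, F)
        + PC[2] * Rherm(t, u, v - 1, n + 1, p, PC, cache, F);
  }
  cache[key] = val;
  return val;
}

struct AO {
  int l[3];
  double A[3];
  std::vector<double> exps, coefs;
};

static std::vector<AO> unpack(const IntegerMatrix& lmn, const NumericMatrix& centers,
                              const List& exps, const List& coefs) {
  int n = lmn.nrow();
  std::vector<AO> aos(n);
  for (int i = 0; i < n; ++i) {
    for (int d = 0; d < 3; ++d) { aos[i].l[d] = lmn(i, d); aos[i].A[d] = centers(i, d); }
    aos[i].exps = as<std::vector<double> >(exps[i]);
    aos[i].coefs = as<std::vector<double> >(coefs[i]);
  }
  return aos;
}

// kind: 0 overlap, 1 kinetic, 2 moment(comp, origin), 3 deriv(comp),
//       4 angmom(comp, origin) i.e. [(r-O) x del]_comp
// [[Rcpp::export(name = ".ao_int1e")]]
NumericMatrix ao_int1e(IntegerMatrix lmn, NumericMatrix centers, List exps,
                       List coefs, int kind, int comp, NumericVector origin) {
  std::vector<AO> aos = unpack(lmn, centers, exps, coefs);
  int n = aos.size();
  NumericMatrix M(n, n);
  const int cyc[3][2] = {{1, 2}, {2, 0}, {0, 1}};
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      const AO &P = aos[i], &Q = aos[j];
      double v = 0.0;
      for (size_t pi = 0; pi < P.exps.size(); ++pi) {
        for (size_t qi = 0; qi < Q.exps.size(); ++qi) {
          double a = P.exps[pi], b = Q.exps[qi];
          double c12 = P.coefs[pi] * Q.coefs[qi];
          double S[3], val = 0.0;
          for (int d = 0; d < 3; ++d)
            S[d] = overlap1d(P.l[d], Q.l[d], a, b, P.A[d], Q.A[d]);
          if (kind == 0) {
            val = S[0] * S[1] * S[2];
          } else if (kind == 1) {
            val = 0.0;
            for (int d = 0; d < 3; ++d) {
              double D2 = kinetic1d(P.l[d], Q.l[d], a, b, P.A[d], Q.A[d]);
              double prod = D2;
              for (int e = 0; e < 3; ++e) if (e != d) prod *= S[e];
              val += prod;
            }
            val *= -0.5;
          } else if (kind == 2) {
            double f[3] = {S[0], S[1], S[2]};
            f[comp] = moment1d(P.l[comp], Q.l[comp], 1, a, b,
                               P.A[comp], Q.A[comp], origin[comp]);
            val = f[0] * f[1] * f[2];
          } else if (kind == 3) {
            double f[3] = {S[0], S[1], S[2]};
            f[comp] = deriv1d(P.l[comp], Q.l[comp], a, b, P.A[comp], Q.A[comp]);
            val = f[0] * f[1] * f[2];
          } else if (kind == 4) {
            int m = cyc[comp][0], dd = cyc[comp][1];
            double f1[3] = {S[0], S[1], S[2]}, f2[3] = {S[0], S[1], S[2]};
            f1[m] = moment1d(P.l[m], Q.l[m], 1, a, b, P.A[m], Q.A[m], origin[m]);
            f1[dd] = deriv1d(P.l[dd], Q.l[dd], a, b, P.A[dd], Q.A[dd]);
            f2[dd] = moment1d(P.l[dd], Q.l[dd], 1, a, b, P.A[dd], Q.A[dd], origin[dd]);
            f2[m] = deriv1d(P.l[m], Q.l[m], a, b, P.A[m], Q.A[m]);
            val = f1[0] * f1[1] * f1[2] - f2[0] * f2[1] * f2[2];
          }
          v += c12 * val;
        }
      }
      M(i, j) = v;
    }
  }
  return M;
}

// [[Rcpp::export(name = ".ao_nuclear")]]
NumericMatrix ao_nuclear(IntegerMatrix lmn, NumericMatrix centers, List exps,
                         List coefs, NumericVector charges, NumericMatrix coords) {
  std::vector<AO> aos = unpack(lmn, centers, exps, coefs);
  int n = aos.size(), nat = charges.size();
  NumericMatrix M(n, n);
  std::vector<double> F;
  for (int i = 0; i < n; ++i) {
    for (int j = i; j < n; ++j) {
      const AO &Pa = aos[i], &Qb = aos[j];
      int ltot = Pa.l[0] + Pa.l[1] + Pa.l[2] + Qb.l[0] + Qb.l[1] + Qb.l[2];
      double v = 0.0;
      for (size_t pi = 0; pi < Pa.exps.size(); ++pi) {
        for (size_t qi = 0; qi < Qb.exps.size(); ++qi) {
          double a = Pa.exps[pi], b = Qb.exps[qi], p = a + b;
          double c12 = Pa.coefs[pi] * Qb.coefs[qi];
          double P[3];
          for (int d = 0; d < 3; ++d) P[d] = (a * Pa.A[d] + b * Qb.A[d]) / p;
          // precompute E coefficients per dimension
          std::vector<std::vector<double> > E(3);
          for (int d = 0; d < 3; ++d) {
            E[d].resize(Pa.l[d] + Qb.l[d] + 1);
            for (int t = 0; t <= Pa.l[d] + Qb.l[d]; ++t)
              E[d][t] = Ecoef(Pa.l[d], Qb.l[d], t, Pa.A[d] - Qb.A[d], a, b);
          }
          for (int at = 0; at < nat; ++at) {
            double PC[3], r2 = 0.0;
            for (int d = 0; d < 3; ++d) {
              PC[d] = P[d] - coords(at, d);
              r2 += PC[d] * PC[d];
            }
            boys_array(ltot, p * r2, F);
            std::map<RKey, double> cache;
            double s = 0.0;
            for (int t = 0; t <= Pa.l[0] + Qb.l[0]; ++t)
              for (int u = 0; u <= Pa.l[1] + Qb.l[1]; ++u)
                for (int w = 0; w <= Pa.l[2] + Qb.l[2]; ++w)
                  s += E[0][t] * E[1][u] * E[2][w]
                     * Rherm(t, u, w, 0, p, PC, cache, F);
            v += -charges[at] * c12 * 2.0 * M_PI / p * s;
          }
        }
      }
      M(i, j) = v;
      M(j, i) = v;
    }
  }
  return M;
}

static double prim_eri(const AO& A, const AO& B, const AO& C, const AO& D,
                       double a, double b, double c, double d,
                       std::vector<double>& F) {
  double p = a + b, q = c + d;
  double P[3], Q[3], PQ[3], r2 = 0.0;
  for (int k = 0; k < 3; ++k) {
    P[k] = (a * A.A[k] + b * B.A[k]) / p;
    Q[k] = (c * C.A[k] + d * D.A[k]) / q;
    PQ[k] = P[k] - Q[k];
    r2 += PQ[k] * PQ[k];
  }
  double alpha = p * q / (p + q);
  int l1[3], l2[3];
  int ltot = 0;
  for (int k = 0; k < 3; ++k) {
    l1[k] = A.l[k] + B.l[k];
    l2[k] = C.l[k] + D.l[k];
    ltot += l1[k] + l2[k];
  }
  boys_array(ltot, alpha * r2, F);
  std::map<RKey, double> cache;
  std::vector<std::vector<double> > E1(3), E2(3);
  for (int k = 0; k < 3; ++k) {
    E1[k].resize(l1[k] + 1);
    E2[k].resize(l2[k] + 1);
    for (int t = 0; t <= l1[k]; ++t)
      E1[k][t] = Ecoef(A.l[k], B.l[k], t, A.A[k] - B.A[k], a, b);
    for (int t = 0; t <= l2[k]; ++t)
      E2[k][t] = Ecoef(C.l[k], D.l[k], t, C.A[k] - D.A[k], c, d);
  }
  double val = 0.0;
  for (int t = 0; t <= l1[0]; ++t)
    for (int u = 0; u <= l1[1]; ++u)
      for (int w = 0; w <= l1[2]; ++w) {
        double e1 = E1[0][t] * E1[1][u] * E1[2][w];
        if (e1 == 0.0) continue;
        for (int tt = 0; tt <= l2[0]; ++tt)
          for (int uu = 0; uu <= l2[1]; ++uu)
            for (int ww = 0; ww <= l2[2]; ++ww) {
              double e2 = E2[0][tt] * E2[1][uu] * E2[2][ww];
              if (e2 == 0.0) continue;
              double sgn = ((tt + uu + ww) % 2) ? -1.0 : 1.0;
              val += e1 * e2 * sgn
                   * Rherm(t + tt, u + uu, w + ww, 0, alpha, PQ, cache, F);
            }
      }
  return val * 2.0 * std::pow(M_PI, 2.5) / (p * q * std::sqrt(p + q));
}

// [[Rcpp::export(name = ".ao_eri")]]
NumericVector ao_eri(IntegerMatrix lmn, NumericMatrix centers, List exps, List coefs) {
  std::vector<AO> aos = unpack(lmn, centers, exps, coefs);
  int n = aos.size();
  NumericVector G((R_xlen_t)n * n * n * n);
  std::vector<double> F;
  auto idx = [n](int p, int q, int r, int s) -> R_xlen_t {
    return ((R_xlen_t)p) + n * ((R_xlen_t)q + n * ((R_xlen_t)r + (R_xlen_t)n * s));
  };
  for (int i = 0; i < n; ++i)
    for (int j = 0; j <= i; ++j) {
      R_xlen_t ij = (R_xlen_t)i * (i + 1) / 2 + j;
      for (int k = 0; k <= i; ++k)
        for (int l = 0; l <= k; ++l) {
          R_xlen_t kl = (R_xlen_t)k * (k + 1) / 2 + l;
          if (kl > ij) continue;
          double v = 0.0;
          const AO &A = aos[i], &B = aos[j], &C = aos[k], &D = aos[l];
          for (size_t pa = 0; pa < A.exps.size(); ++pa)
            for (size_t pb = 0; pb < B.exps.size(); ++pb)
              for (size_t pc = 0; pc < C.exps.size(); ++pc)
                for (size_t pd = 0; pd < D.exps.size(); ++pd)
                  v += A.coefs[pa] * B.coefs[pb] * C.coefs[pc] * D.coefs[pd]
                     * prim_eri(A, B, C, D, A.exps[pa], B.exps[pb],
                                C.exps[pc], D.exps[pd], F);
          int pq[2][2] = {{i, j}, {j, i}};
          int rs[2][2] = {{k, l}, {l, k}};
          for (int x = 0; x < 2; ++x)
            for (int y = 0; y < 2; ++y) {
              G[idx(pq[x][0], pq[x][1], rs[y][0], rs[y][1])] = v;
              G[idx(rs[y][0], rs[y][1], pq[x][0], pq[x][1])] = v;
            }
        }
    }
  G.attr("dim") = IntegerVector::create(n, n, n, n);
  return G;
}
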