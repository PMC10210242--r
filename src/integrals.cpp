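// Gaussian one- and two-electron integrals over contracted Cartesian shells,
// McMurchie-Davidson scheme (Hermite expansion + Hermite Coulomb recursion).
// Shells arrive from R with contraction coefficients already scaled so that
// the raw Cartesian primitives x^i y^j z^k exp(-a r^2) can be used directly.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const double PI = 3.14159265358979323846;

// Boys function F_0..F_nmax via regularized incomplete gamma, downward recursion.
static void boys(int nmax, double x, double *F) {
  if (x < 1e-13) {
    for (int n = 0; n <= nmax; ++n) F[n] = 1.0 / (2.0 * n + 1.0);
    return;
  }
  double a = nmax + 0.5;
  F[nmax] = 0.5 * std::pow(x, -a) * ::Rf_gammafn(a) * ::Rf_pgamma(x, a, 1.0, 1, 0);
  double ex = std::exp(-x);
  for (int n = nmax; n > 0; --n)
    F[n - 1] = (2.0 * x * F[n] + ex) / (2.0 * n - 1.0);
}

// Hermite expansion coefficients E(i,j,t) for one direction.
// dims: (li+1) x (lj+1) x (li+lj+1), index [i][j][t].
struct Etab {
  int li, lj;
  std::vector<double> v;
  double at(int i, int j, int t) const {
    if (t < 0 || t > i + j) return 0.0;
    return v[(i * (lj + 1) + j) * (li + lj + 1) + t];
  }
  double &ref(int i, int j, int t) {
    return v[(i * (lj + 1) + j) * (li + lj + 1) + t];
  }
};

static Etab make_E(int li, int lj, double a, double b, double AB) {
  Etab E;
  E.li = li; E.lj = lj;
  E.v.assign((li + 1) * (lj + 1) * (li + lj + 1), 0.0);
  double p = a + b, mu = a * b / p;
  double Xpa = -b * AB / p * -1.0; // P - A = -(b/p) * (A-B) ... see below
  // with AB = A - B: P = (aA + bB)/p, P - A = -(b/p)(A-B), P - B = (a/p)(A-B)
  Xpa = -(b / p) * AB;
  double Xpb = (a / p) * AB;
  E.ref(0, 0, 0) = std::exp(-mu * AB * AB);
  for (int i = 0; i <= li; ++i) {
    for (int j = 0; j <= lj; ++j) {
      if (i == 0 && j == 0) continue;
      for (int t = 0; t <= i + j; ++t) {
        double val;
        if (j == 0) { // build up i
          val = (1.0 / (2.0 * p)) * E.at(i - 1, 0, t - 1)
              + Xpa * E.at(i - 1, 0, t)
              + (t + 1.0) * E.at(i - 1, 0, t + 1);
        } else {      // build up j
          val = (1.0 / (2.0 * p)) * E.at(i, j - 1, t - 1)
              + Xpb * E.at(i, j - 1, t)
              + (t + 1.0) * E.at(i, j - 1, t + 1);
        }
        E.ref(i, j, t) = val;
      }
    }
  }
  return E;
}

// Hermite Coulomb integrals R(0,t,u,v) for t+u+v <= L at exponent p, vector PC.
static void hermite_R(int L, double p, const double *PC, std::vector<double> &R0) {
  int d = L + 1;
  double T = p * (PC[0] * PC[0] + PC[1] * PC[1] + PC[2] * PC[2]);
  std::vector<double> F(L + 1);
  boys(L, T, F.data());
  // layers R[n][t][u][v]; compute from n = L down to 0
  std::vector<double> cur(d * d * d, 0.0), nxt(d * d * d, 0.0);
  auto idx = [d](int t, int u, int v) { return (t * d + u) * d + v; };
  for (int n = L; n >= 0; --n) {
    std::fill(cur.begin(), cur.end(), 0.0);
    double base = std::pow(-2.0 * p, n) * F[n];
    for (int t = 0; t <= L - n; ++t)
      for (int u = 0; u <= L - n - t; ++u)
        for (int v = 0; v <= L - n - t - u; ++v) {
          double val;
          if (t == 0 && u == 0 && v == 0) val = base;
          else if (t > 0)
            val = (t - 1) * (t > 1 ? nxt[idx(t - 2, u, v)] : 0.0)
                + PC[0] * nxt[idx(t - 1, u, v)];
          else if (u > 0)
            val = (u - 1) * (u > 1 ? nxt[idx(t, u - 2, v)] : 0.0)
                + PC[1] * nxt[idx(t, u - 1, v)];
          else
            val = (v - 1) * (v > 1 ? nxt[idx(t, u, v - 2)] : 0.0)
                + PC[2] * nxt[idx(t, u, v - 1)];
          cur[idx(t, u, v)] = val;
        }
    std::swap(cur, nxt);
  }
  R0 = nxt;
}

struct Shell {
  int l;
  std::vector<double> exps, coefs;
  double A[3];
  int ncart, offset;
  std::vector<int> lx, ly, lz;
};

static std::vector<Shell> parse_shells(List shells) {
  int n = shells.size();
  std::vector<Shell> out(n);
  int off = 0;
  for (int s = 0; s < n; ++s) {
    List sh = shells[s];
    Shell S;
    S.l = as<int>(sh["l"]);
    S.exps = as<std::vector<double> >(sh["exps"]);
    S.coefs = as<std::vector<double> >(sh["coefs"]);
    NumericVector A = sh["center"];
    S.A[0] = A[0]; S.A[1] = A[1]; S.A[2] = A[2];
    S.ncart = (S.l + 1) * (S.l + 2) / 2;
    for (int a = S.l; a >= 0; --a)
      for (int b = S.l - a; b >= 0; --b) {
        S.lx.push_back(a); S.ly.push_back(b); S.lz.push_back(S.l - a - b);
      }
    S.offset = off;
    off += S.ncart;
    out[s] = S;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_one_electron(List shells, NumericVector Z, NumericMatrix coords) {
  std::vector<Shell> sh = parse_shells(shells);
  int nbf = 0;
  for (size_t s = 0; s < sh.size(); ++s) nbf += sh[s].ncart;
  NumericMatrix S(nbf, nbf), T(nbf, nbf), V(nbf, nbf);
  int natm = Z.size();

  for (size_t si = 0; si < sh.size(); ++si)
    for (size_t sj = si; sj < sh.size(); ++sj) {
      const Shell &A = sh[si], &B = sh[sj];
      int L = A.l + B.l;
      std::vector<double> R0;
      for (size_t pi = 0; pi < A.exps.size(); ++pi)
        for (size_t pj = 0; pj < B.exps.size(); ++pj) {
          double a = A.exps[pi], b = B.exps[pj], p = a + b;
          double cc = A.coefs[pi] * B.coefs[pj];
          double P[3];
          for (int d = 0; d < 3; ++d) P[d] = (a * A.A[d] + b * B.A[d]) / p;
          // E tables with lj extended by 2 for kinetic
          Etab Ex = make_E(A.l, B.l + 2, a, b, A.A[0] - B.A[0]);
          Etab Ey = make_E(A.l, B.l + 2, a, b, A.A[1] - B.A[1]);
          Etab Ez = make_E(A.l, B.l + 2, a, b, A.A[2] - B.A[2]);
          double sp = std::sqrt(PI / p);
          double pref = sp * sp * sp;
          for (int ca = 0; ca < A.ncart; ++ca)
            for (int cb = 0; cb < B.ncart; ++cb) {
              int i1 = A.lx[ca], i2 = A.ly[ca], i3 = A.lz[ca];
              int j1 = B.lx[cb], j2 = B.ly[cb], j3 = B.lz[cb];
              double sx = Ex.at(i1, j1, 0) * sp;
              double sy = Ey.at(i2, j2, 0) * sp;
              double sz = Ez.at(i3, j3, 0) * sp;
              double Sv = sx * sy * sz;
              // 1D kinetic pieces
              auto kin = [&](const Etab &E, int i, int j, double spd) {
                double t0 = (j >= 2) ? j * (j - 1) * E.at(i, j - 2, 0) * spd : 0.0;
                double t1 = -2.0 * b * (2.0 * j + 1.0) * E.at(i, j, 0) * spd;
                double t2 = 4.0 * b * b * E.at(i, j + 2, 0) * spd;
                return -0.5 * (t0 + t1 + t2);
              };
              double kx = kin(Ex, i1, j1, sp), ky = kin(Ey, i2, j2, sp),
                     kz = kin(Ez, i3, j3, sp);
              double Tv = kx * sy * sz + sx * ky * sz + sx * sy * kz;
              int I = A.offset + ca, J = B.offset + cb;
              S(I, J) += cc * Sv;
              T(I, J) += cc * Tv;
            }
          // nuclear attraction
          for (int at = 0; at < natm; ++at) {
            double PC[3] = {P[0] - coords(at, 0), P[1] - coords(at, 1),
                            P[2] - coords(at, 2)};
            hermite_R(L, p, PC, R0);
            int d = L + 1;
            for (int ca = 0; ca < A.ncart; ++ca)
              for (int cb = 0; cb < B.ncart; ++cb) {
                int i1 = A.lx[ca], i2 = A.ly[ca], i3 = A.lz[ca];
                int j1 = B.lx[cb], j2 = B.ly[cb], j3 = B.lz[cb];
                double acc = 0.0;
                for (int t = 0; t <= i1 + j1; ++t)
                  for (int u = 0; u <= i2 + j2; ++u)
                    for (int v = 0; v <= i3 + j3; ++v)
                      acc += Ex.at(i1, j1, t) * Ey.at(i2, j2, u) *
                             Ez.at(i3, j3, v) * R0[(t * d + u) * d + v];
                V(A.offset + ca, B.offset + cb) +=
                    -Z[at] * cc * (2.0 * PI / p) * acc;
              }
          }
        }
    }
  // symmetrize
  for (int i = 0; i < nbf; ++i)
    for (int j = i + 1; j < nbf; ++j) {
      S(j, i) = S(i, j); T(j, i) = T(i, j); V(j, i) = V(i, j);
    }
  return List::create(_["S"] = S, _["T"] = T, _["V"] = V);
}

struct PrimPair {
  double p, P[3], cc;
  Etab Ex, Ey, Ez;
};

static std::vector<PrimPair> shell_pair(const Shell &A, const Shell &B) {
  std::vector<PrimPair> out;
  for (size_t pi = 0; pi < A.exps.size(); ++pi)
    for (size_t pj = 0; pj < B.exps.size(); ++pj) {
      PrimPair pp;
      double a = A.exps[pi], b = B.exps[pj];
      pp.p = a + b;
      for (int d = 0; d < 3; ++d) pp.P[d] = (a * A.A[d] + b * B.A[d]) / pp.p;
      pp.cc = A.coefs[pi] * B.coefs[pj];
      pp.Ex = make_E(A.l, B.l, a, b, A.A[0] - B.A[0]);
      pp.Ey = make_E(A.l, B.l, a, b, A.A[1] - B.A[1]);
      pp.Ez = make_E(A.l, B.l, a, b, A.A[2] - B.A[2]);
      out.push_back(pp);
    }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_eri(List shells) {
  std::vector<Shell> sh = parse_shells(shells);
  int ns = sh.size(), nbf = 0;
  for (int s = 0; s < ns; ++s) nbf += sh[s].ncart;
  NumericVector G((R_xlen_t)nbf * nbf * nbf * nbf);
  G.attr("dim") = IntegerVector::create(nbf, nbf, nbf, nbf);
  double *g = REAL(G);
  size_t n1 = nbf, n2 = n1 * nbf, n3 = n2 * nbf;
  std::vector<std::vector<PrimPair> > pairs(ns * ns);
  for (int i = 0; i < ns; ++i)
    for (int j = 0; j <= i; ++j)
      pairs[i * ns + j] = shell_pair(sh[i], sh[j]);

  std::vector<double> R0;
  for (int i = 0; i < ns; ++i)
    for (int j = 0; j <= i; ++j)
      for (int k = 0; k <= i; ++k)
        for (int l = 0; l <= ((k == i) ? j : k); ++l) {
          const Shell &A = sh[i], &B = sh[j], &C = sh[k], &D = sh[l];
          int L = A.l + B.l + C.l + D.l, dL = L + 1;
          std::vector<double> block(A.ncart * B.ncart * C.ncart * D.ncart, 0.0);
          const std::vector<PrimPair> &bra = pairs[i * ns + j];
          const std::vector<PrimPair> &ket = pairs[k * ns + l];
          for (size_t bp = 0; bp < bra.size(); ++bp)
            for (size_t kp = 0; kp < ket.size(); ++kp) {
              const PrimPair &P1 = bra[bp], &P2 = ket[kp];
              double p = P1.p, q = P2.p;
              double alpha = p * q / (p + q);
              double PQ[3] = {P1.P[0] - P2.P[0], P1.P[1] - P2.P[1],
                              P1.P[2] - P2.P[2]};
              hermite_R(L, alpha, PQ, R0);
              double pref = 2.0 * std::pow(PI, 2.5) /
                            (p * q * std::sqrt(p + q)) * P1.cc * P2.cc;
              int bi = 0;
              for (int ca = 0; ca < A.ncart; ++ca)
                for (int cb = 0; cb < B.ncart; ++cb)
                  for (int cc2 = 0; cc2 < C.ncart; ++cc2)
                    for (int cd = 0; cd < D.ncart; ++cd, ++bi) {
                      int a1 = A.lx[ca], a2 = A.ly[ca], a3 = A.lz[ca];
                      int b1 = B.lx[cb], b2 = B.ly[cb], b3 = B.lz[cb];
                      int c1 = C.lx[cc2], c2 = C.ly[cc2], c3 = C.lz[cc2];
                      int d1 = D.lx[cd], d2 = D.ly[cd], d3 = D.lz[cd];
                      double acc = 0.0;
                      for (int t = 0; t <= a1 + b1; ++t) {
                        double e1x = P1.Ex.at(a1, b1, t);
                        if (e1x == 0.0) continue;
                        for (int u = 0; u <= a2 + b2; ++u) {
                          double e1y = P1.Ey.at(a2, b2, u);
                          if (e1y == 0.0) continue;
                          for (int v = 0; v <= a3 + b3; ++v) {
                            double e1 = e1x * e1y * P1.Ez.at(a3, b3, v);
                            if (e1 == 0.0) continue;
                            double inner = 0.0;
                            for (int tt = 0; tt <= c1 + d1; ++tt) {
                              double e2x = P2.Ex.at(c1, d1, tt);
                              if (e2x == 0.0) continue;
                              for (int uu = 0; uu <= c2 + d2; ++uu) {
                                double e2y = P2.Ey.at(c2, d2, uu);
                                if (e2y == 0.0) continue;
                                for (int vv = 0; vv <= c3 + d3; ++vv) {
                                  double e2 = e2x * e2y * P2.Ez.at(c3, d3, vv);
                                  if (e2 == 0.0) continue;
                                  double sgn = ((tt + uu + vv) & 1) ? -1.0 : 1.0;
                                  inner += sgn * e2 *
                                           R0[((t + tt) * dL + (u + uu)) * dL +
                                              (v + vv)];
                                }
                              }
                            }
                            acc += e1 * inner;
                          }
                        }
                      }
                      block[bi] += pref * acc;
                    }
            }
          // scatter with 8-fold symmetry
          int bi = 0;
          for (int ca = 0; ca < A.ncart; ++ca)
            for (int cb = 0; cb < B.ncart; ++cb)
              for (int cc2 = 0; cc2 < C.ncart; ++cc2)
                for (int cd = 0; cd < D.ncart; ++cd, ++bi) {
                  size_t I = A.offset + ca, J = B.offset + cb,
                         K = C.offset + cc2, Lx = D.offset + cd;
                  double val = block[bi];
                  g[I + J * n1 + K * n2 + Lx * n3] = val;
                  g[J + I * n1 + K * n2 + Lx * n3] = val;
                  g[I + J * n1 + Lx * n2 + K * n3] = val;
                  g[J + I * n1 + Lx * n2 + K * n3] = val;
                  g[K + Lx * n1 + I * n2 + J * n3] = val;
                  g[Lx + K * n1 + I * n2 + J * n3] = val;
                  g[K + Lx * n1 + J * n2 + I * n3] = val;
                  g[Lx + K * n1 + J * n2 + I * n3] = val;
                }
        }
  return G;
}

// Apply one Pauli string to a statevector. Masks are bit masks over qubits
// (bit j of the index = occupation of qubit j). Returns op * amps.
// [[Rcpp::export]]
ComplexVector cpp_apply_pauli(ComplexVector amps, int xmask, int ymask,
                              int zmask) {
  int N = amps.size();
  ComplexVector out(N);
  int flip = xmask | ymask;
  int phasemask = ymask | zmask;
  int ny = 0;
  for (int b = ymask; b; b >>= 1) ny += b & 1;
  // i^ny
  double pr[4] = {1.0, 0.0, -1.0, 0.0};
  double pi[4] = {0.0, 1.0, 0.0, -1.0};
  double re0 = pr[ny & 3], im0 = pi[ny & 3];
  for (int t = 0; t < N; ++t) {
    int s = t ^ flip;
    int par = s & phasemask;
    par ^= par >> 16; par ^= par >> 8; par ^= par >> 4;
    par ^= par >> 2; par ^= par >> 1;
    double sgn = (par & 1) ? -1.0 : 1.0;
    Rcomplex a = amps[s];
    Rcomplex o;
    o.r = sgn * (re0 * a.r - im0 * a.i);
    o.i = sgn * (re0 * a.i + im0 * a.r);
    out[t] = o;
  }
  return out;
}
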