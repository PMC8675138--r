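// Gaussian integral engine (McMurchie-Davidson) and the screened direct
// Fock builds. Shells are contracted Cartesian Gaussians with l <= 1 in
// practice (the recursions are general in l). All lengths in Bohr, energies
// in Hartree.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <cstring>
using namespace Rcpp;

namespace {

struct Shell {
  int l, nprim, ao_offset, ncart;
  const double *exps, *coefs;
  double A[3];
};

// Unpack the flat shell description produced by shell_basis() on the R side.
std::vector<Shell> unpack(const List& sh) {
  IntegerVector l = sh["l"], np = sh["nprim"], pptr = sh["prim_ptr"],
                off = sh["ao_offset"];
  NumericVector ex = sh["exps"], cf = sh["coefs"];
  NumericMatrix ctr = sh["centers"];  // 3 x nshell
  int ns = l.size();
  std::vector<Shell> out(ns);
  for (int i = 0; i < ns; ++i) {
    out[i].l = l[i];
    out[i].nprim = np[i];
    out[i].ao_offset = off[i];
    out[i].ncart = (l[i] + 1) * (l[i] + 2) / 2;
    out[i].exps = &ex[0] + pptr[i];
    out[i].coefs = &cf[0] + pptr[i];
    for (int k = 0; k < 3; ++k) out[i].A[k] = ctr(k, i);
  }
  return out;
}

// Cartesian component exponents in canonical order (x first).
inline void components(int l, int comp, int* lxyz) {
  int idx = 0;
  for (int ix = l; ix >= 0; --ix)
    for (int iy = l - ix; iy >= 0; --iy, ++idx)
      if (idx == comp) { lxyz[0] = ix; lxyz[1] = iy; lxyz[2] = l - ix - iy; return; }
}

// Hermite expansion coefficient E_t^{ij} for one dimension.
double Ecoef(int i, int j, int t, double Qx, double a, double b) {
  if (t < 0 || t > i + j || i < 0 || j < 0) return 0.0;
  double p = a + b, q = a * b / p;
  if (i == 0 && j == 0) return std::exp(-q * Qx * Qx);  // t == 0 here
  if (j == 0)
    return Ecoef(i - 1, j, t - 1, Qx, a, b) / (2.0 * p)
         - (q * Qx / a) * Ecoef(i - 1, j, t, Qx, a, b)
         + (t + 1) * Ecoef(i - 1, j, t + 1, Qx, a, b);
  return Ecoef(i, j - 1, t - 1, Qx, a, b) / (2.0 * p)
       + (q * Qx / b) * Ecoef(i, j - 1, t, Qx, a, b)
       + (t + 1) * Ecoef(i, j - 1, t + 1, Qx, a, b);
}

// Boys function F_0..F_mmax(T): convergent series + downward recursion for
// moderate T, asymptotic start + upward recursion for large T.
void boys(int mmax, double T, double* F) {
  if (T < 1e-13) {
    for (int m = 0; m <= mmax; ++m) F[m] = 1.0 / (2.0 * m + 1.0);
    return;
  }
  if (T > 35.0) {
    F[0] = 0.5 * std::sqrt(M_PI / T);
    double eT = std::exp(-T);
    for (int m = 0; m < mmax; ++m) F[m + 1] = ((2.0 * m + 1.0) * F[m] - eT) / (2.0 * T);
    return;
  }
  double term = 1.0 / (2.0 * mmax + 1.0), sum = term;
  for (int k = 1; k < 300; ++k) {
    term *= 2.0 * T / (2.0 * mmax + 2.0 * k + 1.0);
    sum += term;
    if (term < 1e-17 * sum) break;
  }
  double eT = std::exp(-T);
  F[mmax] = eT * sum;
  for (int m = mmax - 1; m >= 0; --m) F[m] = (2.0 * T * F[m + 1] + eT) / (2.0 * m + 1.0);
}

// Hermite Coulomb integral R^n_{tuv}.
double Rcoef(int t, int u, int v, int n, double p, const double* PC, const double* F) {
  if (t < 0 || u < 0 || v < 0) return 0.0;
  if (t == 0 && u == 0 && v == 0) return std::pow(-2.0 * p, n) * F[n];
  if (t > 0)
    return (t - 1) * Rcoef(t - 2, u, v, n + 1, p, PC, F)
         + PC[0] * Rcoef(t - 1, u, v, n + 1, p, PC, F);
  if (u > 0)
    return (u - 1) * Rcoef(t, u - 2, v, n + 1, p, PC, F)
         + PC[1] * Rcoef(t, u - 1, v, n + 1, p, PC, F);
  return (v - 1) * Rcoef(t, u, v - 2, n + 1, p, PC, F)
       + PC[2] * Rcoef(t, u, v - 1, n + 1, p, PC, F);
}

inline double s1d(int i, int j, double Qx, double a, double b) {
  return Ecoef(i, j, 0, Qx, a, b) * std::sqrt(M_PI / (a + b));
}

inline double k1d(int i, int j, double Qx, double a, double b) {
  double t = -2.0 * b * b * s1d(i, j + 2, Qx, a, b)
           + b * (2.0 * j + 1.0) * s1d(i, j, Qx, a, b);
  if (j >= 2) t -= 0.5 * j * (j - 1.0) * s1d(i, j - 2, Qx, a, b);
  return t;
}

// Contracted shell-pair one-electron blocks. kind: 0 overlap, 1 kinetic.
void one_el_block(const Shell& sa, const Shell& sb, int kind, double* blk) {
  int na = sa.ncart, nb = sb.ncart;
  std::memset(blk, 0, sizeof(double) * na * nb);
  double Q[3];
  for (int k = 0; k < 3; ++k) Q[k] = sa.A[k] - sb.A[k];
  int la[3], lb[3];
  for (int ip = 0; ip < sa.nprim; ++ip)
    for (int jp = 0; jp < sb.nprim; ++jp) {
      double a = sa.exps[ip], b = sb.exps[jp];
      double cc = sa.coefs[ip] * sb.coefs[jp];
      for (int ca = 0; ca < na; ++ca) {
        components(sa.l, ca, la);
        for (int cb = 0; cb < nb; ++cb) {
          components(sb.l, cb, lb);
          double sx = s1d(la[0], lb[0], Q[0], a, b);
          double sy = s1d(la[1], lb[1], Q[1], a, b);
          double sz = s1d(la[2], lb[2], Q[2], a, b);
          double val;
          if (kind == 0) val = sx * sy * sz;
          else
            val = k1d(la[0], lb[0], Q[0], a, b) * sy * sz
                + sx * k1d(la[1], lb[1], Q[1], a, b) * sz
                + sx * sy * k1d(la[2], lb[2], Q[2], a, b);
          blk[ca + na * cb] += cc * val;
        }
      }
    }
}

void nuclear_block(const Shell& sa, const Shell& sb,
                   const NumericMatrix& xyz, const NumericVector& Z, double* blk) {
  int na = sa.ncart, nb = sb.ncart;
  std::memset(blk, 0, sizeof(double) * na * nb);
  double Q[3];
  for (int k = 0; k < 3; ++k) Q[k] = sa.A[k] - sb.A[k];
  int la[3], lb[3];
  int L = sa.l + sb.l;
  std::vector<double> F(L + 1);
  for (int ip = 0; ip < sa.nprim; ++ip)
    for (int jp = 0; jp < sb.nprim; ++jp) {
      double a = sa.exps[ip], b = sb.exps[jp], p = a + b;
      double cc = sa.coefs[ip] * sb.coefs[jp];
      double P[3];
      for (int k = 0; k < 3; ++k) P[k] = (a * sa.A[k] + b * sb.A[k]) / p;
      for (int ia = 0; ia < xyz.nrow(); ++ia) {
        double PC[3], r2 = 0.0;
        for (int k = 0; k < 3; ++k) { PC[k] = P[k] - xyz(ia, k); r2 += PC[k] * PC[k]; }
        boys(L, p * r2, &F[0]);
        for (int ca = 0; ca < na; ++ca) {
          components(sa.l, ca, la);
          for (int cb = 0; cb < nb; ++cb) {
            components(sb.l, cb, lb);
            double sum = 0.0;
            for (int t = 0; t <= la[0] + lb[0]; ++t)
              for (int u = 0; u <= la[1] + lb[1]; ++u)
                for (int v = 0; v <= la[2] + lb[2]; ++v)
                  sum += Ecoef(la[0], lb[0], t, Q[0], a, b)
                       * Ecoef(la[1], lb[1], u, Q[1], a, b)
                       * Ecoef(la[2], lb[2], v, Q[2], a, b)
                       * Rcoef(t, u, v, 0, p, PC, &F[0]);
            blk[ca + na * cb] += -Z[ia] * cc * (2.0 * M_PI / p) * sum;
          }
        }
      }
    }
}

// Contracted ERI shell quartet (s1 s2 | s3 s4), chemists' notation, stored
// column-major over (c1, c2, c3, c4).
void eri_block(const Shell& s1, const Shell& s2, const Shell& s3, const Shell& s4,
               double* blk) {
  int n1 = s1.ncart, n2 = s2.ncart, n3 = s3.ncart, n4 = s4.ncart;
  std::memset(blk, 0, sizeof(double) * n1 * n2 * n3 * n4);
  double Qab[3], Qcd[3];
  for (int k = 0; k < 3; ++k) { Qab[k] = s1.A[k] - s2.A[k]; Qcd[k] = s3.A[k] - s4.A[k]; }
  int L = s1.l + s2.l + s3.l + s4.l;
  std::vector<double> F(L + 1);
  int l1[3], l2[3], l3[3], l4[3];
  for (int ip = 0; ip < s1.nprim; ++ip)
    for (int jp = 0; jp < s2.nprim; ++jp) {
      double a = s1.exps[ip], b = s2.exps[jp], p = a + b;
      double P[3];
      for (int k = 0; k < 3; ++k) P[k] = (a * s1.A[k] + b * s2.A[k]) / p;
      double cab = s1.coefs[ip] * s2.coefs[jp];
      for (int kp = 0; kp < s3.nprim; ++kp)
        for (int lp = 0; lp < s4.nprim; ++lp) {
          double c = s3.exps[kp], d = s4.exps[lp], q = c + d;
          double Qc[3], PQ[3], r2 = 0.0;
          for (int k = 0; k < 3; ++k) {
            Qc[k] = (c * s3.A[k] + d * s4.A[k]) / q;
            PQ[k] = P[k] - Qc[k];
            r2 += PQ[k] * PQ[k];
          }
          double alpha = p * q / (p + q);
          boys(L, alpha * r2, &F[0]);
          double pref = cab * s3.coefs[kp] * s4.coefs[lp]
                      * 2.0 * std::pow(M_PI, 2.5) / (p * q * std::sqrt(p + q));
          for (int c1 = 0; c1 < n1; ++c1) {
            components(s1.l, c1, l1);
            for (int c2 = 0; c2 < n2; ++c2) {
              components(s2.l, c2, l2);
              // bra Hermite expansion for this component pair
              double Eb[3][5];
              int tb[3];
              for (int k = 0; k < 3; ++k) {
                tb[k] = l1[k] + l2[k];
                for (int t = 0; t <= tb[k]; ++t)
                  Eb[k][t] = Ecoef(l1[k], l2[k], t, Qab[k], a, b);
              }
              for (int c3 = 0; c3 < n3; ++c3) {
                components(s3.l, c3, l3);
                for (int c4 = 0; c4 < n4; ++c4) {
                  components(s4.l, c4, l4);
                  double Ek[3][5];
                  int tk[3];
                  for (int k = 0; k < 3; ++k) {
                    tk[k] = l3[k] + l4[k];
                    for (int t = 0; t <= tk[k]; ++t)
                      Ek[k][t] = Ecoef(l3[k], l4[k], t, Qcd[k], c, d);
                  }
                  double sum = 0.0;
                  for (int t = 0; t <= tb[0]; ++t)
                    for (int u = 0; u <= tb[1]; ++u)
                      for (int v = 0; v <= tb[2]; ++v) {
                        double eb = Eb[0][t] * Eb[1][u] * Eb[2][v];
                        if (eb == 0.0) continue;
                        for (int tt = 0; tt <= tk[0]; ++tt)
                          for (int uu = 0; uu <= tk[1]; ++uu)
                            for (int vv = 0; vv <= tk[2]; ++vv) {
                              double ek = Ek[0][tt] * Ek[1][uu] * Ek[2][vv];
                              if (ek == 0.0) continue;
                              double sgn = ((tt + uu + vv) % 2) ? -1.0 : 1.0;
                              sum += eb * ek * sgn
                                   * Rcoef(t + tt, u + uu, v + vv, 0, alpha, PQ, &F[0]);
                            }
                      }
                  blk[c1 + n1 * (c2 + n2 * (c3 + n3 * c4))] += pref * sum;
                }
              }
            }
          }
        }
    }
}

NumericMatrix assemble_one_el(const std::vector<Shell>& sh, int kind,
                              const NumericMatrix* xyz, const NumericVector* Z) {
  int nao = 0;
  for (size_t i = 0; i < sh.size(); ++i) nao += sh[i].ncart;
  NumericMatrix M(nao, nao);
  std::vector<double> blk(16);
  for (size_t i = 0; i < sh.size(); ++i)
    for (size_t j = 0; j <= i; ++j) {
      blk.assign(sh[i].ncart * sh[j].ncart, 0.0);
      if (kind == 2) nuclear_block(sh[i], sh[j], *xyz, *Z, &blk[0]);
      else one_el_block(sh[i], sh[j], kind, &blk[0]);
      for (int ca = 0; ca < sh[i].ncart; ++ca)
        for (int cb = 0; cb < sh[j].ncart; ++cb) {
          double v = blk[ca + sh[i].ncart * cb];
          M(sh[i].ao_offset + ca, sh[j].ao_offset + cb) = v;
          M(sh[j].ao_offset + cb, sh[i].ao_offset + ca) = v;
        }
    }
  return M;
}

}  // namespace

// [[Rcpp::export]]
NumericMatrix cpp_overlap(List shells) {
  std::vector<Shell> sh = unpack(shells);
  return assemble_one_el(sh, 0, NULL, NULL);
}

// [[Rcpp::export]]
NumericMatrix cpp_kinetic(List shells) {
  std::vector<Shell> sh = unpack(shells);
  return assemble_one_el(sh, 1, NULL, NULL);
}

// [[Rcpp::export]]
NumericMatrix cpp_nuclear(List shells, NumericMatrix atom_xyz, NumericVector charges) {
  std::vector<Shell> sh = unpack(shells);
  return assemble_one_el(sh, 2, &atom_xyz, &charges);
}

// [[Rcpp::export]]
NumericVector cpp_eri_quartet(List shells, int s1, int s2, int s3, int s4) {
  std::vector<Shell> sh = unpack(shells);
  int ns = sh.size();
  if (s1 < 1 || s2 < 1 || s3 < 1 || s4 < 1 || s1 > ns || s2 > ns || s3 > ns || s4 > ns)
    stop("shell index out of range");
  const Shell &a = sh[s1 - 1], &b = sh[s2 - 1], &c = sh[s3 - 1], &d = sh[s4 - 1];
  NumericVector out(a.ncart * b.ncart * c.ncart * d.ncart);
  eri_block(a, b, c, d, &out[0]);
  out.attr("dim") = IntegerVector::create(a.ncart, b.ncart, c.ncart, d.ncart);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_eri_dense(List shells) {
  std::vector<Shell> sh = unpack(shells);
  int nao = 0;
  for (size_t i = 0; i < sh.size(); ++i) nao += sh[i].ncart;
  NumericVector g((R_xlen_t)nao * nao * nao * nao);
  std::vector<double> blk;
  for (size_t i = 0; i < sh.size(); ++i)
    for (size_t j = 0; j < sh.size(); ++j)
      for (size_t k = 0; k < sh.size(); ++k)
        for (size_t l = 0; l < sh.size(); ++l) {
          int n1 = sh[i].ncart, n2 = sh[j].ncart, n3 = sh[k].ncart, n4 = sh[l].ncart;
          blk.assign(n1 * n2 * n3 * n4, 0.0);
          eri_block(sh[i], sh[j], sh[k], sh[l], &blk[0]);
          for (int c1 = 0; c1 < n1; ++c1)
            for (int c2 = 0; c2 < n2; ++c2)
              for (int c3 = 0; c3 < n3; ++c3)
                for (int c4 = 0; c4 < n4; ++c4) {
                  R_xlen_t a = sh[i].ao_offset + c1, b = sh[j].ao_offset + c2,
                           cc = sh[k].ao_offset + c3, dd = sh[l].ao_offset + c4;
                  g[a + nao * (b + nao * (cc + nao * dd))] =
                      blk[c1 + n1 * (c2 + n2 * (c3 + n3 * c4))];
                }
        }
  g.attr("dim") = IntegerVector::create(nao, nao, nao, nao);
  return g;
}

// Shell-pair Cauchy-Schwarz norms Q[s1,s2] = max_{a in s1, b in s2} (ab|ab)^(1/2).
// [[Rcpp::export]]
NumericMatrix cpp_schwarz(List shells) {
  std::vector<Shell> sh = unpack(shells);
  int ns = sh.size();
  NumericMatrix Q(ns, ns);
  std::vector<double> blk;
  for (int i = 0; i < ns; ++i)
    for (int j = 0; j <= i; ++j) {
      int n1 = sh[i].ncart, n2 = sh[j].ncart;
      blk.assign(n1 * n2 * n1 * n2, 0.0);
      eri_block(sh[i], sh[j], sh[i], sh[j], &blk[0]);
      double mx = 0.0;
      for (int a = 0; a < n1; ++a)
        for (int b = 0; b < n2; ++b) {
          double v = blk[a + n1 * (b + n2 * (a + n1 * b))];
          if (v < -1e-12) stop("negative Schwarz diagonal from integral engine");
          if (v > mx) mx = v;
        }
      Q(i, j) = Q(j, i) = std::sqrt(std::max(mx, 0.0));
    }
  return Q;
}

// Screened direct build of the Coulomb and/or exchange matrices.
//
// Pairs are the master significant list (s1 >= s2, 1-based, in ascending
// canonical order so that the list position is the canonical rank). bra_order
// and ket_order are 1-based permutations of the list. A quartet (bra, ket) is
// processed when rank(ket) <= rank(bra); each unique AO quartet is computed
// once and accumulated to every distinct index permutation.
//
// Neglect conditions (tau_J / tau_K) follow Cauchy-Schwarz bounds weighted by
// per-shell active-MO coefficient maxima (Cshell) and per-shell-pair density
// maxima (Dshell), maximised over the symmetry-equivalent targets actually
// accumulated. early_exit enables leaving the ket loop for the Coulomb part
// when the descending-ordered ket product can no longer pass.
// [[Rcpp::export]]
List cpp_fock_screened(List shells, NumericMatrix D, NumericMatrix Q,
                       NumericVector Cshell, NumericMatrix Dshell,
                       IntegerVector pair_s1, IntegerVector pair_s2,
                       IntegerVector bra_order, IntegerVector ket_order,
                       double tau_J, double tau_K,
                       bool do_J, bool do_K, bool early_exit) {
  std::vector<Shell> sh = unpack(shells);
  int nao = D.nrow();
  int npair = pair_s1.size();
  NumericMatrix J(nao, nao), K(nao, nao);
  double nq_J = 0.0, nq_K = 0.0, nq_tot = 0.0;

  // global maxima over the master list for the partial-information screens
  double maxQD = 0.0, maxQ = 0.0, maxD = 0.0, maxC = 0.0;
  for (int k = 0; k < npair; ++k) {
    int a = pair_s1[k] - 1, b = pair_s2[k] - 1;
    double qd = Q(a, b) * Dshell(a, b);
    if (qd > maxQD) maxQD = qd;
    if (Q(a, b) > maxQ) maxQ = Q(a, b);
    if (Dshell(a, b) > maxD) maxD = Dshell(a, b);
  }
  for (int s = 0; s < Cshell.size(); ++s) if (Cshell[s] > maxC) maxC = Cshell[s];

  // suffix maxima along the ket ordering, for a sound early exit: after
  // position ik no later ket can beat these bounds
  std::vector<double> sufQD(npair + 1, 0.0), sufCCQ(npair + 1, 0.0);
  for (int ik = npair - 1; ik >= 0; --ik) {
    int k = ket_order[ik] - 1;
    int a = pair_s1[k] - 1, b = pair_s2[k] - 1;
    double qd = Q(a, b) * Dshell(a, b);
    double ccq = Cshell[a] * Cshell[b] * Q(a, b);
    sufQD[ik] = std::max(sufQD[ik + 1], qd);
    sufCCQ[ik] = std::max(sufCCQ[ik + 1], ccq);
  }

  std::vector<double> blk;
  int perms[8][4], uniq[8][4];

  for (int ib = 0; ib < npair; ++ib) {
    int bra = bra_order[ib] - 1;
    int s1 = pair_s1[bra] - 1, s2 = pair_s2[bra] - 1;
    double C1 = Cshell[s1], C2 = Cshell[s2], Q12 = Q(s1, s2);
    double D12bra = Dshell(s1, s2);
    // partial-information screens: remaining factors replaced by their maxima
    bool braJ = do_J && (C1 * C2 * Q12 * maxQD > tau_J ||
                         D12bra * Q12 * sufCCQ[0] > tau_J);
    bool braK = do_K && (std::max(C1, C2) * maxC * Q12 * maxQ * maxD > tau_K);
    if (!braJ && !braK) continue;
    bool jAlive = braJ;

    for (int ik = 0; ik < npair; ++ik) {
      int ket = ket_order[ik] - 1;
      if (ket > bra) continue;  // canonical rank restriction
      int s3 = pair_s1[ket] - 1, s4 = pair_s2[ket] - 1;
      double C3 = Cshell[s3], C4 = Cshell[s4], Q34 = Q(s3, s4);
      double D34 = Dshell(s3, s4), D12 = Dshell(s1, s2);

      if (jAlive && early_exit &&
          C1 * C2 * Q12 * sufQD[ik] <= tau_J &&
          D12 * Q12 * sufCCQ[ik] <= tau_J) {
        // neither Coulomb target (at the bra or at the ket pair) can pass at
        // this or any later ket of the descending-ordered list
        jAlive = false;
        if (!braK) break;
      }
      bool incJ = jAlive &&
                  std::max(C1 * C2 * D34, C3 * C4 * D12) * Q12 * Q34 > tau_J;
      double kb = std::max(std::max(C1 * C3 * Dshell(s2, s4), C1 * C4 * Dshell(s2, s3)),
                           std::max(C2 * C3 * Dshell(s1, s4), C2 * C4 * Dshell(s1, s3)));
      bool incK = braK && kb * Q12 * Q34 > tau_K;
      if (!incJ && !incK) continue;

      const Shell &S1 = sh[s1], &S2 = sh[s2], &S3 = sh[s3], &S4 = sh[s4];
      int n1 = S1.ncart, n2 = S2.ncart, n3 = S3.ncart, n4 = S4.ncart;
      blk.assign(n1 * n2 * n3 * n4, 0.0);
      eri_block(S1, S2, S3, S4, &blk[0]);
      nq_tot += 1.0;
      if (incJ) nq_J += 1.0;
      if (incK) nq_K += 1.0;

      bool same12 = (s1 == s2), same34 = (s3 == s4), samepair = (bra == ket);
      for (int c1 = 0; c1 < n1; ++c1) {
        int a = S1.ao_offset + c1;
        for (int c2 = 0; c2 < n2; ++c2) {
          int b = S2.ao_offset + c2;
          if (same12 && b > a) continue;
          R_xlen_t iab = (R_xlen_t)a * (a + 1) / 2 + b;
          for (int c3 = 0; c3 < n3; ++c3) {
            int c = S3.ao_offset + c3;
            for (int c4 = 0; c4 < n4; ++c4) {
              int d = S4.ao_offset + c4;
              if (same34 && d > c) continue;
              if (samepair && (R_xlen_t)c * (c + 1) / 2 + d > iab) continue;
              double g = blk[c1 + n1 * (c2 + n2 * (c3 + n3 * c4))];
              if (g == 0.0) continue;
              // enumerate the distinct index permutations of (ab|cd)
              int p8[8][4] = {{a,b,c,d},{b,a,c,d},{a,b,d,c},{b,a,d,c},
                              {c,d,a,b},{d,c,a,b},{c,d,b,a},{d,c,b,a}};
              int nu = 0;
              for (int t = 0; t < 8; ++t) {
                bool dup = false;
                for (int s = 0; s < nu; ++s)
                  if (uniq[s][0] == p8[t][0] && uniq[s][1] == p8[t][1] &&
                      uniq[s][2] == p8[t][2] && uniq[s][3] == p8[t][3]) { dup = true; break; }
                if (!dup) {
                  for (int k = 0; k < 4; ++k) uniq[nu][k] = p8[t][k];
                  ++nu;
                }
              }
              for (int t = 0; t < nu; ++t) {
                int p = uniq[t][0], q = uniq[t][1], r = uniq[t][2], s = uniq[t][3];
                if (incJ) J(p, q) += D(r, s) * g;
                if (incK) K(p, r) += D(q, s) * g;
              }
            }
          }
        }
      }
      (void)perms;
    }
  }
  return List::create(_["J"] = J, _["K"] = K,
                      _["n_quartets_J"] = nq_J, _["n_quartets_K"] = nq_K,
                      _["n_quartets"] = nq_tot);
}
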