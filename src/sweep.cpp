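// Core combinatorial kernels for ECDF-based conditional-FDR computations.
//
// Conventions shared by all kernels (and mirrored by the plain-R reference
// implementations used in the test suite):
//  * All count comparisons are closed (<=); tied values count with
//    multiplicity.
//  * "Augmentation" adds the moving evaluation point (p', q) to the defining
//    set before counting, so that the estimator is defined on the whole unit
//    square (the X+(p',q) convention). It applies to the numerator count
//    #{q_i <= q} and the denominator count #{p_i <= p', q_i <= q} only; the
//    adjustment factor Pr(H0|Q<=q) is always computed from the defining set
//    alone.
//  * The adjustment factor is
//      min(1, [max(1, #{q_i<=q, p_i>1/2}) / max(1, #{p_i>1/2})]
//             / [max(1, #{q_i<=q}) / |X|]),
//    with zero-count guards on every count so the factor stays positive.
//  * remove_self = leave-one-out: the test point itself is removed from the
//    defining set; pT/qT must then alias pD/qD elementwise.
//
// Within a q-stratum (between consecutive order statistics of the defining
// q-values) the estimator is linear in p' between consecutive order
// statistics of the relevant p-values, so minima and region boundaries are
// attained at data points; the kernels search only those candidates.

#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

static inline void sorted_insert(std::vector<double>& s, double x) {
  s.insert(std::lower_bound(s.begin(), s.end(), x), x);
}

static std::vector<int> order_by(const NumericVector& key) {
  std::vector<int> o(key.size());
  for (int i = 0; i < (int)o.size(); ++i) o[i] = i;
  std::stable_sort(o.begin(), o.end(),
                   [&](int a, int b) { return key[a] < key[b]; });
  return o;
}

// Rightmost index l in [1, m] with val[l] <= C, maintained under a
// nondecreasing stream of C values. P is the running answer (0 if none).
// sufmin[l] = min(val[l..m]), sufmin[m+1] = +Inf.
static inline void advance_rightmost(int& P, double C,
                                     const std::vector<double>& val,
                                     const std::vector<double>& sufmin,
                                     int m) {
  while (P < m && sufmin[P + 1] <= C) {
    int j = P + 1;
    while (val[j] > C) ++j;  // terminates: sufmin guarantees a hit
    P = j;
  }
}

// Rightmost l in [1, R] with val[l] <= C; backward scan with block skipping.
static inline int rightmost_upto(int R, double C,
                                 const std::vector<double>& val,
                                 const std::vector<double>& blockmin,
                                 int bsz) {
  int l = R;
  while (l >= 1) {
    if (l % bsz == 0) {
      int b = l / bsz;  // block b covers [(b-1)*bsz+1, b*bsz]
      if (blockmin[b] > C) { l -= bsz; continue; }
    }
    if (val[l] <= C) return l;
    --l;
  }
  return 0;
}

// Minimised cFDR levels c_i = min over p' >= p_i of the (optionally
// adjusted, optionally test-point-augmented) estimator at (p', q_i), with
// the defining set equal to D (remove_self = false) or D minus the test
// point (remove_self = true).
// [[Rcpp::export]]
NumericVector cpp_cvalues(NumericVector pD, NumericVector qD,
                          NumericVector pT, NumericVector qT,
                          bool remove_self, bool augment, bool adjusted) {
  const int mD = pD.size(), nT = pT.size();
  NumericVector out(nT);
  std::vector<int> oD = order_by(qD), oT = order_by(qT);
  int bS = 0;
  for (int l = 0; l < mD; ++l) bS += pD[l] > 0.5;
  std::vector<double> s;
  s.reserve(mD);
  int aS = 0, kins = 0;
  const int rs = remove_self ? 1 : 0, ag = augment ? 1 : 0;
  const int nX = mD - rs;
  for (int ii = 0; ii < nT; ++ii) {
    const int i = oT[ii];
    const double p0 = pT[i], q0 = qT[i];
    while (kins < mD && qD[oD[kins]] <= q0) {
      const double pv = pD[oD[kins]];
      sorted_insert(s, pv);
      if (pv > 0.5) ++aS;
      ++kins;
    }
    const int m = (int)s.size();
    const int h = (p0 > 0.5) ? 1 : 0;
    const int mX = m - rs, aX = aS - rs * h, bX = bS - rs * h;
    double adj = 1.0;
    if (adjusted) {
      const double qf = (double)std::max(mX, 1) / (double)std::max(nX, 1);
      adj = (std::max(aX, 1) / (double)std::max(bX, 1)) / qf;
      if (adj > 1.0) adj = 1.0;
      if (adj <= 0.0) { out[i] = 0.0; continue; }
    }
    const int N = std::max(mX + ag, 1);
    const int rank0 =
        (int)(std::upper_bound(s.begin(), s.end(), p0) - s.begin());
    const int D0 = std::max(rank0 - rs + ag, 1);
    double best = p0 * N / (double)D0 * adj;
    const int lb =
        (int)(std::lower_bound(s.begin(), s.end(), p0) - s.begin());
    for (int kk = lb; kk < m; ++kk) {
      const int D = std::max(kk + 1 - rs + ag, 1);
      const double e = s[kk] * N / (double)D * adj;
      if (e < best) best = e;
    }
    out[i] = best;
  }
  return out;
}

// v-values for all test points: v_i = integral of the fitted null density
// f0 over the L-region at level c_i defined by the (leave-out) set, using
// the test-point-augmented estimator for the region boundary. deltaF gives
// the f0 q-marginal mass of each stratum: deltaF[0] covers [0, Q_1) and
// deltaF[j] covers [Q_j, Q_{j+1}) with Q the distinct sorted q of D and
// Q_{M+1} = 1.
// [[Rcpp::export]]
NumericVector cpp_vsweep(NumericVector pD, NumericVector qD,
                         NumericVector pT, NumericVector qT,
                         NumericVector cT, NumericVector deltaF,
                         bool remove_self, bool adjusted) {
  const int mD = pD.size(), nT = pT.size();
  std::vector<double> Q(qD.begin(), qD.end());
  std::sort(Q.begin(), Q.end());
  Q.erase(std::unique(Q.begin(), Q.end()), Q.end());
  const int M = (int)Q.size();
  if ((int)deltaF.size() != M + 1) stop("deltaF length mismatch");

  // stratum index of each test point's q (1-based in Q); only used when
  // remove_self, where qT aliases qD so the value is always found
  std::vector<int> ji(nT, M + 1);
  if (remove_self) {
    for (int i = 0; i < nT; ++i)
      ji[i] = (int)(std::lower_bound(Q.begin(), Q.end(), qT[i]) -
                    Q.begin()) + 1;
  }
  std::vector<int> oD = order_by(qD), oC = order_by(cT);

  int bS = 0;
  for (int l = 0; l < mD; ++l) bS += pD[l] > 0.5;
  const int rs = remove_self ? 1 : 0;
  const int nX = mD - rs;

  std::vector<long double> acc(nT, 0.0L);
  std::vector<double> s;
  s.reserve(mD);
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> t(mD + 2), u(mD + 2), sfT(mD + 2), sfU(mD + 2);
  const int bsz = 64;
  std::vector<double> bmT(mD / bsz + 2);
  int aS = 0, kins = 0;

  for (int j = 0; j <= M; ++j) {
    if (j >= 1) {
      while (kins < mD && qD[oD[kins]] <= Q[j - 1]) {
        const double pv = pD[oD[kins]];
        sorted_insert(s, pv);
        if (pv > 0.5) ++aS;
        ++kins;
      }
    }
    const double dF = deltaF[j];
    if (dF == 0.0) continue;
    const int m = (int)s.size();

    for (int l = 1; l <= m; ++l) {
      t[l] = s[l - 1] / (double)(l + 1);
      u[l] = s[l - 1] / (double)l;
    }
    sfT[m + 1] = INF;
    sfU[m + 1] = INF;
    for (int l = m; l >= 1; --l) {
      sfT[l] = std::min(t[l], sfT[l + 1]);
      sfU[l] = std::min(u[l], sfU[l + 1]);
    }
    const int nb = (m + bsz - 1) / bsz;
    for (int b = 1; b <= nb; ++b) {
      double mn = INF;
      const int hi = std::min(b * bsz, m);
      for (int l = (b - 1) * bsz + 1; l <= hi; ++l) mn = std::min(mn, t[l]);
      bmT[b] = mn;
    }

    // per-stratum, per-class constants; class = (case A/B) x (h = p_i>1/2)
    const int NA = std::max(m + 1, 1);
    const double qfA = (double)std::max(m, 1) / (double)std::max(nX, 1);
    const int NB = std::max(m, 1);
    const double qfB =
        (double)std::max(m - 1, 1) / (double)std::max(nX, 1);
    double adjA[2], adjB[2];
    for (int h = 0; h <= 1; ++h) {
      if (!adjusted) { adjA[h] = 1.0; adjB[h] = 1.0; continue; }
      double a = (std::max(aS, 1) / (double)std::max(bS - rs * h, 1)) / qfA;
      adjA[h] = std::min(1.0, a);
      double b2 = (std::max(aS - h, 1) / (double)std::max(bS - h, 1)) / qfB;
      adjB[h] = std::min(1.0, b2);
    }
    int PtA[2] = {0, 0}, PtB[2] = {0, 0}, PuB[2] = {0, 0};

    for (int ii = 0; ii < nT; ++ii) {
      const int i = oC[ii];
      const double alpha = cT[i];
      const int h = remove_self ? ((pT[i] > 0.5) ? 1 : 0) : 0;
      const bool caseB = remove_self && j >= ji[i];
      double pb;
      if (!caseB) {
        const double adj = adjA[h];
        if (adjusted && adj <= 0.0) {
          pb = 1.0;
        } else {
          const double C = alpha / (NA * adj);
          advance_rightmost(PtA[h], C, t, sfT, m);
          const int k = PtA[h];
          const double snext = (k < m) ? s[k] : 1.0;
          pb = std::min(snext, C * (k + 1));
          if (pb > 1.0) pb = 1.0;
        }
      } else {
        const double adj = adjB[h];
        if (adjusted && adj <= 0.0) {
          pb = 1.0;
        } else {
          const double C = alpha / (NB * adj);
          advance_rightmost(PtB[h], C, t, sfT, m);
          advance_rightmost(PuB[h], C, u, sfU, m);
          const int r =
              (int)(std::lower_bound(s.begin(), s.end(), pT[i]) -
                    s.begin()) + 1;
          const int k2 = (PuB[h] >= r + 1) ? PuB[h] : 0;
          if (k2 > 0) {
            const int K = k2 - 1;
            const double snext = (k2 + 1 <= m) ? s[k2] : 1.0;
            pb = std::min(snext, C * (K + 1));
          } else {
            const int k1 = (PtB[h] <= r - 1)
                               ? PtB[h]
                               : rightmost_upto(r - 1, C, t, bmT, bsz);
            const int K = k1;
            double snext;
            if (K + 1 <= r - 1) snext = s[K];
            else snext = (K + 2 <= m) ? s[K + 1] : 1.0;
            pb = std::min(snext, C * (K + 1));
          }
          if (pb > 1.0) pb = 1.0;
        }
      }
      // product in double precision, accumulation in extended precision:
      // matches R's sum() over a vector of double products exactly
      acc[i] += (long double)(pb * dF);
    }
  }
  NumericVector out(nT);
  for (int i = 0; i < nT; ++i) out[i] = (double)acc[i];
  return out;
}

// Step-function right boundary of the L-region at a single level alpha:
// p_bound per stratum, strata delimited by (0, distinct q of X, 1).
// [[Rcpp::export]]
NumericVector cpp_lcurve(NumericVector pX, NumericVector qX, double alpha,
                         bool augment, bool adjusted) {
  const int n = pX.size();
  std::vector<double> Q(qX.begin(), qX.end());
  std::sort(Q.begin(), Q.end());
  Q.erase(std::unique(Q.begin(), Q.end()), Q.end());
  const int M = (int)Q.size();
  NumericVector pb(M + 1);
  std::vector<int> oX = order_by(qX);
  std::vector<double> s;
  s.reserve(n);
  int bS = 0;
  for (int l = 0; l < n; ++l) bS += pX[l] > 0.5;
  int aS = 0, kins = 0;
  const int ag = augment ? 1 : 0;
  for (int j = 0; j <= M; ++j) {
    if (j >= 1) {
      while (kins < n && qX[oX[kins]] <= Q[j - 1]) {
        const double pv = pX[oX[kins]];
        sorted_insert(s, pv);
        if (pv > 0.5) ++aS;
        ++kins;
      }
    }
    const int m = (int)s.size();
    double adj = 1.0;
    if (adjusted) {
      const double qf = (double)std::max(m, 1) / (double)std::max(n, 1);
      adj = std::min(1.0, (std::max(aS, 1) / (double)std::max(bS, 1)) / qf);
      if (adj <= 0.0) { pb[j] = 1.0; continue; }
    }
    const int N = std::max(m + ag, 1);
    const double C = alpha / (N * adj);
    // rightmost interval k (0..m) with s_k / max(D_k, 1) <= C,
    // D_k = k + ag; then p_bound = min(s_{k+1}, C * max(D_k, 1)).
    // The division form of the feasibility test matches the other kernels
    // exactly, including floating-point ties.
    double best = 0.0;
    for (int k = m; k >= 0; --k) {
      const double sk = (k >= 1) ? s[k - 1] : 0.0;
      const int Dk = std::max(k + ag, 1);
      if (sk / Dk <= C) {
        const double snext = (k < m) ? s[k] : 1.0;
        best = std::min(snext, C * Dk);
        break;
      }
    }
    pb[j] = std::min(best, 1.0);
  }
  return pb;
}
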