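#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Hidden-parameter marginalization for one binned profile.
//
// The joint likelihood factorizes given the TSS-bin level S:
//   L(x | S,B,T,Kp,Kt) = Pois(x0; S) * Prod_up f(x_j; S,B,Kp)
//                                    * Prod_down f(x_j; S,T,Kt)
// so the 5-D prior expectation reduces, for each S node, to two independent
// 2-D quadratures (over (B,Kp) upstream and (T,Kt) downstream). Node/weight
// vectors are Gauss-Legendre on each Gamma prior's quantile scale, i.e.
// sum(w) = 1 and sum(w * g(node)) ~ E_prior[g(Y)].

// Per-block quadrature: log of the weighted likelihood sum plus the
// block-posterior means of the level parameter (B or T), its log, the decay
// parameter (Kp or Kt) and its log. Empty blocks fall back to prior moments.
static void block_stats(const std::vector<double> &x,
                        const std::vector<double> &lgx,
                        const std::vector<double> &absd, double s,
                        const NumericVector &ln, const NumericVector &lw,
                        const NumericVector &kn, const NumericVector &kw,
                        double *out) {
  const int nb = (int)x.size(), nl = ln.size(), nk = kn.size();
  if (nb == 0) {
    double mL = 0, mlL = 0, mK = 0, mlK = 0;
    for (int i = 0; i < nl; ++i) { mL += lw[i] * ln[i]; mlL += lw[i] * std::log(ln[i]); }
    for (int i = 0; i < nk; ++i) { mK += kw[i] * kn[i]; mlK += kw[i] * std::log(kn[i]); }
    out[0] = 0.0; out[1] = mL; out[2] = mlL; out[3] = mK; out[4] = mlK;
    return;
  }
  std::vector<double> ll((size_t)nl * nk);
  std::vector<double> edk((size_t)nk * nb);  // exp(-K*|d|) cache
  for (int b = 0; b < nk; ++b)
    for (int j = 0; j < nb; ++j)
      edk[(size_t)b * nb + j] = std::exp(-kn[b] * absd[j]);
  double mx = R_NegInf;
  for (int a = 0; a < nl; ++a) {
    const double L = ln[a];
    for (int b = 0; b < nk; ++b) {
      const double *e = &edk[(size_t)b * nb];
      double acc = 0.0;
      for (int j = 0; j < nb; ++j) {
        const double lam = L + (s - L) * e[j];
        acc -= lam;                       // empty bins need no log term
        if (x[j] > 0.0) acc += x[j] * std::log(lam) - lgx[j];
      }
      ll[(size_t)a * nk + b] = acc;
      if (acc > mx) mx = acc;
    }
  }
  double Z = 0, mL = 0, mlL = 0, mK = 0, mlK = 0;
  for (int a = 0; a < nl; ++a) {
    const double la = std::log(ln[a]);
    for (int b = 0; b < nk; ++b) {
      const double w = lw[a] * kw[b] * std::exp(ll[(size_t)a * nk + b] - mx);
      Z += w;
      mL += w * ln[a]; mlL += w * la;
      mK += w * kn[b]; mlK += w * std::log(kn[b]);
    }
  }
  out[0] = mx + std::log(Z);
  out[1] = mL / Z; out[2] = mlL / Z; out[3] = mK / Z; out[4] = mlK / Z;
}

static void profile_grid_one(const int *counts, const int *offsets, int nbin,
                             const NumericVector &sN, const NumericVector &sW,
                             const NumericVector &bN, const NumericVector &bW,
                             const NumericVector &tN, const NumericVector &tW,
                             const NumericVector &kpN, const NumericVector &kpW,
                             const NumericVector &ktN, const NumericVector &ktW,
                             double *res) {
  std::vector<double> xu, xd, lgu, lgd, du, dd;
  double x0 = NA_REAL, lg0 = 0.0;
  bool has_center = false;
  for (int j = 0; j < nbin; ++j) {
    const double xj = counts[j];
    const double lgj = std::lgamma(xj + 1.0);
    if (offsets[j] < 0) {
      xu.push_back(xj); lgu.push_back(lgj); du.push_back(-(double)offsets[j]);
    } else if (offsets[j] > 0) {
      xd.push_back(xj); lgd.push_back(lgj); dd.push_back((double)offsets[j]);
    } else {
      has_center = true; x0 = xj; lg0 = lgj;
    }
  }
  const int nS = sN.size();
  std::vector<double> la(nS), up(5 * nS), dn(5 * nS);
  double mx = R_NegInf;
  for (int a = 0; a < nS; ++a) {
    const double s = sN[a];
    double lc = 0.0;
    if (has_center) lc = x0 * std::log(s) - s - lg0;
    block_stats(xu, lgu, du, s, bN, bW, kpN, kpW, &up[5 * a]);
    block_stats(xd, lgd, dd, s, tN, tW, ktN, ktW, &dn[5 * a]);
    la[a] = std::log(sW[a]) + lc + up[5 * a] + dn[5 * a];
    if (la[a] > mx) mx = la[a];
  }
  double Z = 0, mS = 0, mlS = 0, mB = 0, mlB = 0, mT = 0, mlT = 0;
  double mKp = 0, mlKp = 0, mKt = 0, mlKt = 0;
  for (int a = 0; a < nS; ++a) {
    const double w = std::exp(la[a] - mx);
    Z += w;
    mS += w * sN[a]; mlS += w * std::log(sN[a]);
    mB += w * up[5 * a + 1]; mlB += w * up[5 * a + 2];
    mKp += w * up[5 * a + 3]; mlKp += w * up[5 * a + 4];
    mT += w * dn[5 * a + 1]; mlT += w * dn[5 * a + 2];
    mKt += w * dn[5 * a + 3]; mlKt += w * dn[5 * a + 4];
  }
  res[0] = mx + std::log(Z);           // log marginal likelihood
  res[1] = mS / Z;  res[2] = mB / Z;  res[3] = mT / Z;
  res[4] = mKp / Z; res[5] = mKt / Z;
  res[6] = mlS / Z; res[7] = mlB / Z; res[8] = mlT / Z;
  res[9] = mlKp / Z; res[10] = mlKt / Z;
}

// [[Rcpp::export]]
NumericVector cpp_profile_grid(IntegerVector counts, IntegerVector offsets,
                               NumericVector sN, NumericVector sW,
                               NumericVector bN, NumericVector bW,
                               NumericVector tN, NumericVector tW,
                               NumericVector kpN, NumericVector kpW,
                               NumericVector ktN, NumericVector ktW) {
  if (counts.size() != offsets.size())
    stop("counts and offsets lengths differ");
  NumericVector res(11);
  profile_grid_one(counts.begin(), offsets.begin(), counts.size(),
                   sN, sW, bN, bW, tN, tW, kpN, kpW, ktN, ktW, res.begin());
  res.names() = CharacterVector::create(
      "logM", "S", "B", "T", "Kp", "Kt",
      "logS", "logB", "logT", "logKp", "logKt");
  return res;
}

// Rows of `counts` are profiles sharing one offsets vector (the E-step path).
// [[Rcpp::export]]
NumericMatrix cpp_profiles_grid(IntegerMatrix counts, IntegerVector offsets,
                                NumericVector sN, NumericVector sW,
                                NumericVector bN, NumericVector bW,
                                NumericVector tN, NumericVector tW,
                                NumericVector kpN, NumericVector kpW,
                                NumericVector ktN, NumericVector ktW) {
  const int n = counts.nrow(), nbin = counts.ncol();
  if (nbin != offsets.size())
    stop("ncol(counts) and length(offsets) differ");
  NumericMatrix out(n, 11);
  std::vector<int> row(nbin);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < nbin; ++j) row[j] = counts(i, j);
    double res[11];
    profile_grid_one(row.data(), offsets.begin(), nbin,
                     sN, sW, bN, bW, tN, tW, kpN, kpW, ktN, ktW, res);
    for (int k = 0; k < 11; ++k) out(i, k) = res[k];
  }
  colnames(out) = CharacterVector::create(
      "logM", "S", "B", "T", "Kp", "Kt",
      "logS", "logB", "logT", "logKp", "logKt");
  return out;
}
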