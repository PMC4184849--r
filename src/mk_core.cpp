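#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Per-pattern log-likelihood of binary Mk patterns by Felsenstein pruning.
//
// edge: (nedge x 2) parent/child node ids (1-based), rows ordered so every
//       child appears before it is used as a parent (postorder); the last
//       row's parent is the root. The root may be a leaf (then its own
//       state enters as its initial partial) or an internal node of any
//       degree.
// elen: branch length per edge row, in expected changes per character.
// ntip: leaves are node ids 1..ntip.
// tips: (npat x ntip) integer states, 0 / 1 / 2 (2 = missing, partial (1,1)).
// rates: equi-probable rate-category multipliers (mean 1); the site
//        likelihood is averaged over categories.
//
// Transition probabilities: P(same) = 1/2 + 1/2 exp(-2 t r),
// P(diff) = 1/2 - 1/2 exp(-2 t r); root frequencies (1/2, 1/2).
// Partials are rescaled when both states drop below 1e-260 so low-rate
// matrices on large trees cannot underflow.
// [[Rcpp::export]]
NumericVector mk_pattern_loglik_cpp(IntegerMatrix edge, NumericVector elen,
                                    int ntip, IntegerMatrix tips,
                                    NumericVector rates) {
  const int nedge = edge.nrow();
  const int npat = tips.nrow();
  const int ncat = rates.size();
  if (tips.ncol() < ntip) stop("tip state matrix narrower than ntip");
  int maxid = 0;
  for (int e = 0; e < nedge; ++e) {
    if (edge(e, 0) > maxid) maxid = edge(e, 0);
    if (edge(e, 1) > maxid) maxid = edge(e, 1);
  }
  const int root = edge(nedge - 1, 0);
  std::vector<double> L0(maxid + 1), L1(maxid + 1);
  std::vector<double> ps(nedge), pd(nedge);
  // log-likelihood per (pattern, category), combined by log-sum-exp
  std::vector<double> lpc(static_cast<size_t>(npat) * ncat);

  for (int c = 0; c < ncat; ++c) {
    const double r = rates[c];
    for (int e = 0; e < nedge; ++e) {
      double ee = std::exp(-2.0 * elen[e] * r);
      ps[e] = 0.5 + 0.5 * ee;
      pd[e] = 0.5 - 0.5 * ee;
    }
    for (int p = 0; p < npat; ++p) {
      for (int i = 1; i <= maxid; ++i) { L0[i] = 1.0; L1[i] = 1.0; }
      for (int t = 0; t < ntip; ++t) {
        int s = tips(p, t);
        if (s == 0) L1[t + 1] = 0.0;
        else if (s == 1) L0[t + 1] = 0.0;
        else if (s != 2) stop("tip state outside {0,1,2}");
      }
      double logscale = 0.0;
      for (int e = 0; e < nedge; ++e) {
        const int par = edge(e, 0), ch = edge(e, 1);
        const double c0 = ps[e] * L0[ch] + pd[e] * L1[ch];
        const double c1 = pd[e] * L0[ch] + ps[e] * L1[ch];
        L0[par] *= c0;
        L1[par] *= c1;
        if (L0[par] < 1e-260 && L1[par] < 1e-260) {
          L0[par] *= 1e260;
          L1[par] *= 1e260;
          logscale -= 598.7491402782245;  // log(1e260)
        }
      }
      double lik = 0.5 * L0[root] + 0.5 * L1[root];
      lpc[static_cast<size_t>(p) * ncat + c] =
          (lik > 0.0) ? std::log(lik) + logscale : R_NegInf;
    }
  }

  NumericVector out(npat);
  const double lncat = std::log(static_cast<double>(ncat));
  for (int p = 0; p < npat; ++p) {
    double m = R_NegInf;
    for (int c = 0; c < ncat; ++c) {
      double v = lpc[static_cast<size_t>(p) * ncat + c];
      if (v > m) m = v;
    }
    if (m == R_NegInf) { out[p] = R_NegInf; continue; }
    double s = 0.0;
    for (int c = 0; c < ncat; ++c)
      s += std::exp(lpc[static_cast<size_t>(p) * ncat + c] - m);
    out[p] = m + std::log(s) - lncat;
  }
  return out;
}

// Weighted Fitch parsimony score over site patterns.
//
// edge/ntip: as above; the tree must be binary with the root a leaf
// (every internal node then has exactly two children, which the two-set
// intersection rule requires). tips: (npat x ntip) state-set bitmasks,
// 1 = {0}, 2 = {1}, 3 = {0,1} (missing). weights: pattern multiplicities.
// [[Rcpp::export]]
double fitch_score_cpp(IntegerMatrix edge, int ntip, IntegerMatrix tips,
                       NumericVector weights) {
  const int nedge = edge.nrow();
  const int npat = tips.nrow();
  int maxid = 0;
  for (int e = 0; e < nedge; ++e) {
    if (edge(e, 0) > maxid) maxid = edge(e, 0);
    if (edge(e, 1) > maxid) maxid = edge(e, 1);
  }
  std::vector<int> S(maxid + 1);
  double total = 0.0;
  for (int p = 0; p < npat; ++p) {
    for (int i = 1; i <= maxid; ++i) S[i] = 0;
    for (int t = 0; t < ntip; ++t) {
      int m = tips(p, t);
      if (m < 1 || m > 3) stop("tip mask outside {1,2,3}");
      S[t + 1] = m;
    }
    int changes = 0;
    for (int e = 0; e < nedge; ++e) {
      const int par = edge(e, 0), ch = edge(e, 1);
      if (S[par] == 0) {
        S[par] = S[ch];
      } else {
        int inter = S[par] & S[ch];
        if (inter) {
          S[par] = inter;
        } else {
          S[par] |= S[ch];
          ++changes;
        }
      }
    }
    total += static_cast<double>(changes) * weights[p];
  }
  return total;
}
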