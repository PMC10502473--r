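// Unsupervised conditional-inference-style forest.
//
// The forest discriminates real samples (class 1) from a synthetic contrast
// set built by independently permuting each feature column (class 0; the
// contrast rows are generated on the R side and appended below the real
// rows). Splits are chosen by an association test between candidate feature
// and class label -- the asymptotic permutation z-test for continuous
// features, chi-square for categorical ones -- with Bonferroni correction
// over the mtry candidates and a stopping alpha, the canonical
// conditional-inference construction. Proximity(i,j) is the fraction of
// trees in which real samples i and j share a terminal node; the exported
// function returns 1 - proximity.

#include <Rcpp.h>
#include <random>
#include <algorithm>
#include <numeric>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

namespace {

struct Node {
  int feature = -1;          // -1: leaf
  double cut = 0.0;          // continuous: x <= cut goes left
  std::uint64_t leftMask = 0;// categorical: level bit set -> left
  int left = -1, right = -1;
  bool isCat = false;
};

// two-sample permutation z-test of a continuous x against binary y
double pContinuous(const std::vector<double>& x, const std::vector<int>& y) {
  const int n = (int)x.size();
  int n1 = 0;
  double sx = 0.0, sxx = 0.0, t = 0.0;
  for (int i = 0; i < n; ++i) {
    sx += x[i];
    sxx += x[i] * x[i];
    if (y[i]) { ++n1; t += x[i]; }
  }
  if (n1 == 0 || n1 == n) return 1.0;
  const double mean = sx / n;
  const double ssq = sxx - n * mean * mean;
  if (ssq <= 1e-12) return 1.0;
  const double ev = n1 * mean;
  const double var = (double)n1 * (n - n1) / ((double)n * (n - 1)) * ssq;
  const double z = (t - ev) / std::sqrt(var);
  return 2.0 * R::pnorm(-std::fabs(z), 0.0, 1.0, 1, 0);
}

// chi-square test of a categorical x (integer codes) against binary y
double pCategorical(const std::vector<double>& x, const std::vector<int>& y,
                    int nLev) {
  const int n = (int)x.size();
  std::vector<double> cnt(nLev, 0.0), cnt1(nLev, 0.0);
  int n1 = 0;
  for (int i = 0; i < n; ++i) {
    const int l = (int)x[i];
    cnt[l] += 1.0;
    if (y[i]) { cnt1[l] += 1.0; ++n1; }
  }
  if (n1 == 0 || n1 == n) return 1.0;
  const double p1 = (double)n1 / n;
  double stat = 0.0;
  int used = 0;
  for (int l = 0; l < nLev; ++l) {
    if (cnt[l] == 0) continue;
    ++used;
    const double e1 = cnt[l] * p1, e0 = cnt[l] * (1.0 - p1);
    const double d1 = cnt1[l] - e1, d0 = (cnt[l] - cnt1[l]) - e0;
    stat += d1 * d1 / e1 + d0 * d0 / e0;
  }
  if (used < 2) return 1.0;
  return R::pchisq(stat, used - 1, 0, 0);
}

struct Grower {
  const NumericMatrix& X;
  const std::vector<int>& isCat;
  const std::vector<int>& nLev;
  int mtry, minsplit, minbucket, maxdepth;
  double alpha;
  std::mt19937_64& rng;
  std::vector<Node> nodes;

  Grower(const NumericMatrix& X_, const std::vector<int>& isCat_,
         const std::vector<int>& nLev_, int mtry_, int minsplit_,
         int minbucket_, int maxdepth_, double alpha_, std::mt19937_64& rng_)
    : X(X_), isCat(isCat_), nLev(nLev_), mtry(mtry_), minsplit(minsplit_),
      minbucket(minbucket_), maxdepth(maxdepth_), alpha(alpha_), rng(rng_) {}

  int grow(const std::vector<int>& rows, const std::vector<int>& yAll,
           int depth) {
    const int me = (int)nodes.size();
    nodes.push_back(Node());
    const int n = (int)rows.size();
    int n1 = 0;
    for (int r : rows) n1 += yAll[r];
    if (n < minsplit || n1 == 0 || n1 == n || depth >= maxdepth) return me;

    // candidate features: mtry drawn without replacement
    const int p = X.ncol();
    std::vector<int> feats(p);
    for (int j = 0; j < p; ++j) feats[j] = j;
    std::shuffle(feats.begin(), feats.end(), rng);
    const int m = std::min(mtry, p);

    std::vector<double> xv(n);
    std::vector<int> yv(n);
    for (int i = 0; i < n; ++i) yv[i] = yAll[rows[i]];

    double bestP = 2.0;
    int bestF = -1;
    for (int jj = 0; jj < m; ++jj) {
      const int f = feats[jj];
      for (int i = 0; i < n; ++i) xv[i] = X(rows[i], f);
      const double pv = isCat[f] ? pCategorical(xv, yv, nLev[f])
                                 : pContinuous(xv, yv);
      if (pv < bestP) { bestP = pv; bestF = f; }
    }
    // The contrast set matches every feature's marginal distribution, so
    // the root association test is powerless by construction; the root is
    // exempt from the stopping rule (cf. forests grown with the stopping
    // criterion disabled). Below the root, conditioning on earlier splits
    // gives the test real power against the independent contrast.
    if (bestF < 0) return me;
    if (depth > 0 && std::min(1.0, bestP * m) > alpha) return me;

    for (int i = 0; i < n; ++i) xv[i] = X(rows[i], bestF);

    double cut = 0.0;
    std::uint64_t leftMask = 0;
    bool found = false;

    if (!isCat[bestF]) {
      // maximise the standardised difference in class rate over cutpoints
      std::vector<int> ord(n);
      for (int i = 0; i < n; ++i) ord[i] = i;
      std::sort(ord.begin(), ord.end(),
                [&](int a, int b) { return xv[a] < xv[b]; });
      double cum1 = 0.0, best = -1.0;
      const double ybar = (double)std::accumulate(yv.begin(), yv.end(), 0) / n;
      for (int i = 0; i < n - 1; ++i) {
        cum1 += yv[ord[i]];
        const int nL = i + 1, nR = n - nL;
        if (xv[ord[i]] == xv[ord[i + 1]]) continue;
        if (nL < minbucket || nR < minbucket) continue;
        const double crit = std::fabs(cum1 - nL * ybar) /
                            std::sqrt((double)nL * nR);
        if (crit > best) {
          best = crit;
          cut = 0.5 * (xv[ord[i]] + xv[ord[i + 1]]);
          found = true;
        }
      }
    } else {
      // order levels by class rate, then scan as ordered (CART shortcut)
      const int L = nLev[bestF];
      std::vector<double> lc(L, 0.0), lc1(L, 0.0);
      for (int i = 0; i < n; ++i) {
        const int l = (int)xv[i];
        lc[l] += 1.0; lc1[l] += yv[i];
      }
      std::vector<int> levs;
      for (int l = 0; l < L; ++l) if (lc[l] > 0) levs.push_back(l);
      if (levs.size() >= 2) {
        std::sort(levs.begin(), levs.end(), [&](int a, int b) {
          return lc1[a] / lc[a] < lc1[b] / lc[b];
        });
        const double ybar = (double)std::accumulate(yv.begin(), yv.end(), 0) / n;
        double cum1 = 0.0, cumn = 0.0, best = -1.0;
        std::uint64_t mask = 0;
        for (size_t i = 0; i + 1 < levs.size(); ++i) {
          mask |= (std::uint64_t)1 << levs[i];
          cum1 += lc1[levs[i]];
          cumn += lc[levs[i]];
          const double nL = cumn, nR = n - cumn;
          if (nL < minbucket || nR < minbucket) continue;
          const double crit = std::fabs(cum1 - nL * ybar) / std::sqrt(nL * nR);
          if (crit > best) { best = crit; leftMask = mask; found = true; }
        }
      }
    }
    if (!found) return me;

    std::vector<int> rl, rr;
    for (int i = 0; i < n; ++i) {
      bool goLeft;
      if (isCat[bestF])
        goLeft = (leftMask >> (std::uint64_t)xv[i]) & 1;
      else
        goLeft = xv[i] <= cut;
      (goLeft ? rl : rr).push_back(rows[i]);
    }
    if ((int)rl.size() < minbucket || (int)rr.size() < minbucket) return me;

    nodes[me].feature = bestF;
    nodes[me].cut = cut;
    nodes[me].leftMask = leftMask;
    nodes[me].isCat = isCat[bestF] != 0;
    nodes[me].left = grow(rl, yAll, depth + 1);
    nodes[me].right = grow(rr, yAll, depth + 1);
    return me;
  }

  int route(int row) const {
    int cur = 0;
    while (nodes[cur].feature >= 0) {
      const Node& nd = nodes[cur];
      const double v = X(row, nd.feature);
      bool goLeft = nd.isCat ? ((nd.leftMask >> (std::uint64_t)v) & 1)
                             : (v <= nd.cut);
      cur = goLeft ? nd.left : nd.right;
    }
    return cur;
  }
};

} // namespace

// [[Rcpp::export(name = ".cifDistance")]]
NumericMatrix cifDistance(NumericMatrix X, IntegerVector isCatV,
                          IntegerVector nLevV, int nReal, int nTrees,
                          double alpha, int mtry, int minsplit, int minbucket,
                          int maxdepth, int seed) {
  const int n = X.nrow();
  std::vector<int> isCat(isCatV.begin(), isCatV.end());
  std::vector<int> nLev(nLevV.begin(), nLevV.end());
  std::vector<int> y(n, 0);
  for (int i = 0; i < nReal; ++i) y[i] = 1;

  std::mt19937_64 rng((std::uint64_t)seed * 2654435761u + 1u);
  std::uniform_int_distribution<int> rowDist(0, n - 1);

  std::vector<double> prox((size_t)nReal * nReal, 0.0);
  std::vector<int> leafOf(nReal);

  for (int t = 0; t < nTrees; ++t) {
    std::vector<int> rows(n);
    for (int i = 0; i < n; ++i) rows[i] = rowDist(rng);  // bootstrap
    Grower g(X, isCat, nLev, mtry, minsplit, minbucket, maxdepth, alpha, rng);
    g.grow(rows, y, 0);
    for (int i = 0; i < nReal; ++i) leafOf[i] = g.route(i);
    // group real samples by terminal node, accumulate co-membership
    std::vector<int> ord(nReal);
    for (int i = 0; i < nReal; ++i) ord[i] = i;
    std::sort(ord.begin(), ord.end(),
              [&](int a, int b) { return leafOf[a] < leafOf[b]; });
    size_t s = 0;
    while (s < ord.size()) {
      size_t e = s;
      while (e < ord.size() && leafOf[ord[e]] == leafOf[ord[s]]) ++e;
      for (size_t a = s; a < e; ++a)
        for (size_t b = s; b < e; ++b)
          prox[(size_t)ord[a] * nReal + ord[b]] += 1.0;
      s = e;
    }
  }

  NumericMatrix dist(nReal, nReal);
  for (int i = 0; i < nReal; ++i)
    for (int j = 0; j < nReal; ++j)
      dist(i, j) = (i == j) ? 0.0 : 1.0 - prox[(size_t)i * nReal + j] / nTrees;
  return dist;
}
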