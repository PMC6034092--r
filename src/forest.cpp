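#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Binary-classification CART forest grown to purity with Gini impurity.
// Conventions (they define the reproducibility contract of the package):
//  * split thresholds are midpoints between consecutive distinct sorted values,
//    test "x <= threshold" goes left;
//  * among candidate splits with equal impurity decrease the lowest feature
//    index wins, then the lowest threshold;
//  * a node becomes a leaf when it is pure or when none of the K candidate
//    features varies within the node;
//  * leaf prediction is the majority class, ties toward class 0.
// All randomness (bootstrap, per-node feature subsampling) is drawn from R's
// RNG stream so that set.seed() in R makes fits reproducible.
//
// For speed each feature column is argsorted once per forest; per node the
// split scan walks the presorted order restricted to in-node samples (small
// nodes fall back to gathering and sorting their own values). The per-feature
// MDI importance (sum over splits of (n(N)/n) * DeltaI(N), averaged over
// trees) is accumulated during fitting.

static inline double gini2(int a, int b) {
  double m = (double)a + (double)b;
  double p0 = a / m, p1 = b / m;
  return 1.0 - p0 * p0 - p1 * p1;
}

struct TreeNodes {
  std::vector<int> feature;      // 0-based split feature, -1 for leaf
  std::vector<double> threshold; // NA for leaf
  std::vector<int> left, right;  // 0-based child node index, -1 for leaf
  std::vector<int> nnode, c0, c1;

  int add(int n, int cc0, int cc1) {
    feature.push_back(-1);
    threshold.push_back(NA_REAL);
    left.push_back(-1);
    right.push_back(-1);
    nnode.push_back(n);
    c0.push_back(cc0);
    c1.push_back(cc1);
    return (int)feature.size() - 1;
  }
};

struct Builder {
  const double* x;            // column-major n x p
  const int* y;
  int n, p, mtry, nRoot;
  const std::vector<int>& order; // p columns of presorted sample indices
  std::vector<int> mult;      // in-node multiplicity of each sample
  std::vector<int> pool, cand;
  std::vector<std::pair<double, int> > buf;
  TreeNodes nodes;
  double* imp;                // forest-level importance accumulator

  Builder(const double* x_, const int* y_, int n_, int p_, int mtry_,
          const std::vector<int>& order_, double* imp_)
      : x(x_), y(y_), n(n_), p(p_), mtry(mtry_), nRoot(0), order(order_),
        mult(n_, 0), imp(imp_) {}

  void drawCandidates() {
    if (mtry >= p) {
      cand.resize(p);
      for (int f = 0; f < p; ++f) cand[f] = f;
      return;
    }
    pool.resize(p);
    for (int f = 0; f < p; ++f) pool[f] = f;
    cand.resize(mtry);
    for (int i = 0; i < mtry; ++i) {
      int j = i + (int)(unif_rand() * (double)(p - i));
      if (j >= p) j = p - 1;
      std::swap(pool[i], pool[j]);
      cand[i] = pool[i];
    }
    std::sort(cand.begin(), cand.end());
  }

  // scan one candidate feature; update the incumbent best split
  void scanFeature(int f, const std::vector<int>& idx, int c0, int c1,
                   double g, double m, double& bestDelta, int& bestF,
                   double& bestThr) {
    const double* col = x + (size_t)f * n;
    int l0 = 0, l1 = 0;
    double prevv = 0.0;
    bool seen = false;
    if ((int)idx.size() * 6 < n) {
      // small node: gather and sort its own values
      buf.clear();
      for (size_t t = 0; t < idx.size(); ++t)
        buf.push_back(std::make_pair(col[idx[t]], idx[t]));
      std::sort(buf.begin(), buf.end(),
                [](const std::pair<double, int>& a,
                   const std::pair<double, int>& b) {
                  return a.first < b.first;
                });
      for (size_t t = 0; t < buf.size(); ++t) {
        int s = buf[t].second;
        double v = buf[t].first;
        if (seen && v > prevv) {
          double ml = (double)(l0 + l1), mr = m - ml;
          double delta = g - (ml / m) * gini2(l0, l1)
                           - (mr / m) * gini2(c0 - l0, c1 - l1);
          if (delta > bestDelta) {
            bestDelta = delta;
            bestF = f;
            bestThr = (prevv + v) / 2.0;
          }
        }
        int c = mult[s];
        if (y[s] == 0) l0 += c; else l1 += c;
        prevv = v;
        seen = true;
      }
    } else {
      const int* ord = order.data() + (size_t)f * n;
      for (int t = 0; t < n; ++t) {
        int s = ord[t];
        int c = mult[s];
        if (!c) continue;
        double v = col[s];
        if (seen && v > prevv) {
          double ml = (double)(l0 + l1), mr = m - ml;
          double delta = g - (ml / m) * gini2(l0, l1)
                           - (mr / m) * gini2(c0 - l0, c1 - l1);
          if (delta > bestDelta) {
            bestDelta = delta;
            bestF = f;
            bestThr = (prevv + v) / 2.0;
          }
        }
        if (y[s] == 0) l0 += c; else l1 += c;
        prevv = v;
        seen = true;
      }
    }
  }

  // idx: distinct sample indices of the node; multiplicities in mult[]
  int build(std::vector<int>& idx) {
    int c0 = 0, c1 = 0;
    for (size_t t = 0; t < idx.size(); ++t) {
      int s = idx[t];
      if (y[s] == 0) c0 += mult[s]; else c1 += mult[s];
    }
    int m = c0 + c1;
    int me = nodes.add(m, c0, c1);
    if (c0 == 0 || c1 == 0 || m < 2) {
      for (size_t t = 0; t < idx.size(); ++t) mult[idx[t]] = 0;
      return me;
    }

    drawCandidates();
    double g = gini2(c0, c1);
    double bestDelta = -1.0, bestThr = 0.0;
    int bestF = -1;
    for (size_t ci = 0; ci < cand.size(); ++ci)
      scanFeature(cand[ci], idx, c0, c1, g, (double)m, bestDelta, bestF,
                  bestThr);

    if (bestF < 0) { // no candidate feature varies: leaf
      for (size_t t = 0; t < idx.size(); ++t) mult[idx[t]] = 0;
      return me;
    }

    imp[bestF] += ((double)m / (double)nRoot) * bestDelta;

    const double* col = x + (size_t)bestF * n;
    std::vector<int> lidx, ridx, lmul, rmul;
    for (size_t t = 0; t < idx.size(); ++t) {
      int s = idx[t];
      if (col[s] <= bestThr) { lidx.push_back(s); lmul.push_back(mult[s]); }
      else { ridx.push_back(s); rmul.push_back(mult[s]); }
      mult[s] = 0;
    }
    idx.clear();
    idx.shrink_to_fit();

    nodes.feature[me] = bestF;
    nodes.threshold[me] = bestThr;
    for (size_t t = 0; t < lidx.size(); ++t) mult[lidx[t]] = lmul[t];
    nodes.left[me] = build(lidx);
    for (size_t t = 0; t < ridx.size(); ++t) mult[ridx[t]] = rmul[t];
    nodes.right[me] = build(ridx);
    return me;
  }
};

static List treeToR(const TreeNodes& nd) {
  int k = (int)nd.feature.size();
  IntegerVector feature(k), left(k), right(k), nnode(k), c0(k), c1(k);
  NumericVector threshold(k);
  for (int i = 0; i < k; ++i) {
    feature[i] = nd.feature[i] < 0 ? NA_INTEGER : nd.feature[i] + 1;
    threshold[i] = nd.threshold[i];
    left[i] = nd.left[i] < 0 ? NA_INTEGER : nd.left[i] + 1;
    right[i] = nd.right[i] < 0 ? NA_INTEGER : nd.right[i] + 1;
    nnode[i] = nd.nnode[i];
    c0[i] = nd.c0[i];
    c1[i] = nd.c1[i];
  }
  return List::create(_["feature"] = feature, _["threshold"] = threshold,
                      _["left"] = left, _["right"] = right, _["n"] = nnode,
                      _["c0"] = c0, _["c1"] = c1);
}

// [[Rcpp::export(name = ".rf_fit")]]
List rf_fit(NumericMatrix x, IntegerVector y, int ntree, int mtry,
            bool bootstrap, bool returnTrees) {
  int n = x.nrow(), p = x.ncol();
  const double* xp = REAL(x);

  // presort every column once per forest
  std::vector<int> order((size_t)n * p);
  {
    std::vector<int> tmp(n);
    for (int f = 0; f < p; ++f) {
      const double* col = xp + (size_t)f * n;
      for (int i = 0; i < n; ++i) tmp[i] = i;
      std::sort(tmp.begin(), tmp.end(),
                [col](int a, int b) { return col[a] < col[b]; });
      std::copy(tmp.begin(), tmp.end(), order.begin() + (size_t)f * n);
    }
  }

  NumericVector importance(p);
  List trees(returnTrees ? ntree : 0);
  std::vector<int> yv(y.begin(), y.end());
  Builder b(xp, yv.data(), n, p, mtry, order, REAL(importance));

  for (int t = 0; t < ntree; ++t) {
    std::vector<int> idx;
    std::fill(b.mult.begin(), b.mult.end(), 0);
    if (bootstrap) {
      for (int i = 0; i < n; ++i) {
        int j = (int)(unif_rand() * (double)n);
        if (j >= n) j = n - 1;
        if (b.mult[j]++ == 0) idx.push_back(j);
      }
      std::sort(idx.begin(), idx.end());
    } else {
      idx.resize(n);
      for (int i = 0; i < n; ++i) { idx[i] = i; b.mult[i] = 1; }
    }
    b.nRoot = n;
    b.nodes = TreeNodes();
    b.build(idx);
    if (returnTrees) trees[t] = treeToR(b.nodes);
  }
  for (int f = 0; f < p; ++f) importance[f] /= (double)ntree;
  return List::create(_["trees"] = trees, _["importance"] = importance);
}

// [[Rcpp::export(name = ".rf_predict_votes")]]
IntegerVector rf_predict_votes(List trees, NumericMatrix x) {
  int n = x.nrow(), T = trees.size();
  IntegerVector votes1(n); // votes for class 1
  for (int t = 0; t < T; ++t) {
    List tr = trees[t];
    IntegerVector feature = tr["feature"], left = tr["left"],
                  right = tr["right"], c0 = tr["c0"], c1 = tr["c1"];
    NumericVector threshold = tr["threshold"];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (feature[node] != NA_INTEGER) {
        int f = feature[node] - 1;
        node = (x(i, f) <= threshold[node] ? left[node] : right[node]) - 1;
      }
      if (c1[node] > c0[node]) ++votes1[i];
    }
  }
  return votes1;
}
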