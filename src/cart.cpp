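// Classification and regression trees used by the decision-tree,
// random-forest and boosted-tree faller classifiers.  Binary targets are
// coded 0/1; leaf values are class-1 probabilities (classification) or
// weighted means (regression).  Trees are returned as flat parallel arrays
// so they can be stored and re-applied cheaply from R.

#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

namespace {

// deterministic portable RNG (xorshift64*); R's RNG is left untouched
struct XRng {
  uint64_t s;
  explicit XRng(uint32_t seed) {
    s = 0x9E3779B97F4A7C15ULL ^ (static_cast<uint64_t>(seed) + 1ULL);
    for (int i = 0; i < 12; ++i) next();
  }
  uint64_t next() {
    s ^= s << 13; s ^= s >> 7; s ^= s << 17;
    return s * 0x2545F4914F6CDD1DULL;
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  int below(int n) { return static_cast<int>(unif() * n) % n; }
};

struct TreeBuf {
  std::vector<int> feature, left, right, nobs;
  std::vector<double> threshold, value;
  int push_leaf(double v, int n) {
    feature.push_back(-1); threshold.push_back(NA_REAL);
    left.push_back(-1); right.push_back(-1);
    value.push_back(v); nobs.push_back(n);
    return static_cast<int>(feature.size()) - 1;
  }
  int push_split(int f, double thr, int n) {
    feature.push_back(f); threshold.push_back(thr);
    left.push_back(-1); right.push_back(-1);
    value.push_back(NA_REAL); nobs.push_back(n);
    return static_cast<int>(feature.size()) - 1;
  }
};

struct GrowCtx {
  const NumericMatrix* X;
  const NumericVector* y;
  const NumericVector* w;
  bool classif;
  int max_depth, min_node, min_split, mtry;
  double cp, root_cost;
  XRng* rng;
  TreeBuf buf;
};

// weighted impurity cost of a node: gini * W (classif) or SSE (regression)
inline double node_cost(double sw, double swy, double swyy, bool classif) {
  if (sw <= 0.0) return 0.0;
  if (classif) {
    double p = swy / sw;
    return sw * 2.0 * p * (1.0 - p);
  }
  return swyy - swy * swy / sw;
}

int grow_node(GrowCtx& C, std::vector<int>& idx, int depth) {
  const NumericMatrix& X = *C.X;
  const NumericVector& y = *C.y;
  const NumericVector& w = *C.w;
  const int n = static_cast<int>(idx.size());

  double sw = 0.0, swy = 0.0, swyy = 0.0;
  for (int i : idx) { sw += w[i]; swy += w[i] * y[i]; swyy += w[i] * y[i] * y[i]; }
  const double node_val = sw > 0 ? swy / sw : 0.5;
  const double parent_cost = node_cost(sw, swy, swyy, C.classif);

  bool pure = true;
  for (int i : idx) if (y[i] != y[idx[0]]) { pure = false; break; }
  if (depth >= C.max_depth || n < C.min_split || pure || parent_cost <= 1e-12)
    return C.buf.push_leaf(node_val, n);

  // candidate features: partial Fisher-Yates over 0..d-1
  const int d = X.ncol();
  std::vector<int> feats(d);
  for (int j = 0; j < d; ++j) feats[j] = j;
  int m = std::min(C.mtry, d);
  for (int j = 0; j < m; ++j)
    std::swap(feats[j], feats[j + C.rng->below(d - j)]);

  double best_gain = 0.0, best_thr = 0.0;
  int best_f = -1;
  std::vector<int> ord(idx);

  for (int jj = 0; jj < m; ++jj) {
    const int f = feats[jj];
    std::sort(ord.begin(), ord.end(),
              [&](int a, int b) { return X(a, f) < X(b, f); });
    double lw = 0.0, lwy = 0.0, lwyy = 0.0;
    for (int k = 0; k < n - 1; ++k) {
      const int i = ord[k];
      lw += w[i]; lwy += w[i] * y[i]; lwyy += w[i] * y[i] * y[i];
      if (X(ord[k + 1], f) <= X(i, f)) continue;      // not a boundary
      const int nl = k + 1, nr = n - nl;
      if (nl < C.min_node || nr < C.min_node) continue;
      const double cost = node_cost(lw, lwy, lwyy, C.classif) +
        node_cost(sw - lw, swy - lwy, swyy - lwyy, C.classif);
      const double gain = parent_cost - cost;
      if (gain > best_gain) {
        best_gain = gain;
        best_f = f;
        best_thr = 0.5 * (X(i, f) + X(ord[k + 1], f));
      }
    }
  }

  if (best_f < 0 || best_gain < C.cp * C.root_cost)
    return C.buf.push_leaf(node_val, n);

  std::vector<int> li, ri;
  li.reserve(n); ri.reserve(n);
  for (int i : idx) (X(i, best_f) <= best_thr ? li : ri).push_back(i);
  if (li.empty() || ri.empty())
    return C.buf.push_leaf(node_val, n);

  const int self = C.buf.push_split(best_f, best_thr, n);
  const int l = grow_node(C, li, depth + 1);
  const int r = grow_node(C, ri, depth + 1);
  C.buf.left[self] = l;
  C.buf.right[self] = r;
  return self;
}

List buf_to_list(const TreeBuf& b) {
  return List::create(
    _["feature"] = wrap(b.feature), _["threshold"] = wrap(b.threshold),
    _["left"] = wrap(b.left), _["right"] = wrap(b.right),
    _["value"] = wrap(b.value), _["n"] = wrap(b.nobs));
}

inline int descend(const IntegerVector& feature, const NumericVector& threshold,
                   const IntegerVector& left, const IntegerVector& right,
                   const NumericMatrix& X, int row) {
  int node = 0;
  while (feature[node] >= 0)
    node = X(row, feature[node]) <= threshold[node] ? left[node] : right[node];
  return node;
}

} // namespace

// [[Rcpp::export(name = ".cart_grow")]]
List cart_grow(NumericMatrix X, NumericVector y, NumericVector w,
               bool classif, int max_depth, int min_node, int min_split,
               int mtry, double cp, int seed) {
  XRng rng(static_cast<uint32_t>(seed));
  GrowCtx C;
  C.X = &X; C.y = &y; C.w = &w; C.classif = classif;
  C.max_depth = max_depth; C.min_node = min_node; C.min_split = min_split;
  C.mtry = mtry <= 0 ? X.ncol() : mtry; C.cp = cp; C.rng = &rng;

  std::vector<int> idx(X.nrow());
  for (int i = 0; i < X.nrow(); ++i) idx[i] = i;
  double sw = 0, swy = 0, swyy = 0;
  for (int i : idx) { sw += w[i]; swy += w[i] * y[i]; swyy += w[i] * y[i] * y[i]; }
  C.root_cost = std::max(node_cost(sw, swy, swyy, classif), 1e-12);
  grow_node(C, idx, 0);
  return buf_to_list(C.buf);
}

// [[Rcpp::export(name = ".cart_predict")]]
NumericVector cart_predict(List tree, NumericMatrix X) {
  IntegerVector feature = tree["feature"], left = tree["left"], right = tree["right"];
  NumericVector threshold = tree["threshold"], value = tree["value"];
  NumericVector out(X.nrow());
  for (int i = 0; i < X.nrow(); ++i)
    out[i] = value[descend(feature, threshold, left, right, X, i)];
  return out;
}

// [[Rcpp::export(name = ".cart_apply")]]
IntegerVector cart_apply(List tree, NumericMatrix X) {
  IntegerVector feature = tree["feature"], left = tree["left"], right = tree["right"];
  NumericVector threshold = tree["threshold"];
  IntegerVector out(X.nrow());
  for (int i = 0; i < X.nrow(); ++i)
    out[i] = descend(feature, threshold, left, right, X, i) + 1; // 1-based
  return out;
}

// [[Rcpp::export(name = ".forest_grow")]]
List forest_grow(NumericMatrix X, NumericVector y, int ntree, int mtry,
                 int min_node, int max_depth, int seed) {
  const int n = X.nrow();
  List trees(ntree);
  IntegerMatrix inbag(n, ntree);
  NumericVector w(n);
  XRng boot(static_cast<uint32_t>(seed) ^ 0xA5A5A5A5u);

  for (int t = 0; t < ntree; ++t) {
    std::fill(w.begin(), w.end(), 0.0);
    for (int i = 0; i < n; ++i) {
      int k = boot.below(n);
      w[k] += 1.0;
      inbag(k, t) += 1;
    }
    std::vector<int> idx;
    idx.reserve(n);
    for (int i = 0; i < n; ++i) if (w[i] > 0) idx.push_back(i);

    XRng rng(static_cast<uint32_t>(seed + 7919 * (t + 1)));
    GrowCtx C;
    C.X = &X; C.y = &y; C.w = &w; C.classif = true;
    C.max_depth = max_depth; C.min_node = min_node; C.min_split = 2 * min_node;
    C.mtry = mtry; C.cp = 0.0; C.rng = &rng;
    double sw = 0, swy = 0, swyy = 0;
    for (int i : idx) { sw += w[i]; swy += w[i] * y[i]; swyy += w[i] * y[i] * y[i]; }
    C.root_cost = std::max(node_cost(sw, swy, swyy, true), 1e-12);
    grow_node(C, idx, 0);
    trees[t] = buf_to_list(C.buf);
  }
  return List::create(_["trees"] = trees, _["inbag"] = inbag,
                      _["ntree"] = ntree);
}

// [[Rcpp::export(name = ".forest_predict")]]
NumericVector forest_predict(List forest, NumericMatrix X) {
  List trees = forest["trees"];
  const int ntree = trees.size(), n = X.nrow();
  NumericVector acc(n);
  for (int t = 0; t < ntree; ++t) {
    NumericVector p = cart_predict(trees[t], X);
    for (int i = 0; i < n; ++i) acc[i] += p[i];
  }
  for (int i = 0; i < n; ++i) acc[i] /= ntree;
  return acc;
}

// [[Rcpp::export(name = ".forest_oob_predict")]]
NumericVector forest_oob_predict(List forest, NumericMatrix X) {
  List trees = forest["trees"];
  IntegerMatrix inbag = forest["inbag"];
  const int ntree = trees.size(), n = X.nrow();
  NumericVector acc(n), cnt(n);
  for (int t = 0; t < ntree; ++t) {
    NumericVector p = cart_predict(trees[t], X);
    for (int i = 0; i < n; ++i)
      if (inbag(i, t) == 0) { acc[i] += p[i]; cnt[i] += 1.0; }
  }
  for (int i = 0; i < n; ++i) acc[i] = cnt[i] > 0 ? acc[i] / cnt[i] : 0.5;
  return acc;
}

// Breiman-style mean decrease accuracy: per tree, out-of-bag accuracy drop
// after permuting one feature among that tree's OOB rows; averaged over trees.
// [[Rcpp::export(name = ".forest_mda")]]
NumericVector forest_mda(List forest, NumericMatrix X, NumericVector y,
                         int seed) {
  List trees = forest["trees"];
  IntegerMatrix inbag = forest["inbag"];
  const int ntree = trees.size(), n = X.nrow(), d = X.ncol();
  NumericVector mda(d);
  IntegerVector ntree_used(d);
  XRng rng(static_cast<uint32_t>(seed) ^ 0x5EEDFACEu);

  for (int t = 0; t < ntree; ++t) {
    List tree = trees[t];
    IntegerVector feature = tree["feature"], left = tree["left"], right = tree["right"];
    NumericVector threshold = tree["threshold"], value = tree["value"];
    std::vector<int> oob;
    for (int i = 0; i < n; ++i) if (inbag(i, t) == 0) oob.push_back(i);
    const int m = static_cast<int>(oob.size());
    if (m < 2) continue;

    int correct = 0;
    for (int i : oob) {
      double p = value[descend(feature, threshold, left, right, X, i)];
      if ((p > 0.5 ? 1.0 : 0.0) == y[i]) ++correct;
    }
    const double acc0 = static_cast<double>(correct) / m;

    for (int f = 0; f < d; ++f) {
      // permutation of oob positions
      std::vector<int> perm(oob);
      for (int k = m - 1; k > 0; --k)
        std::swap(perm[k], perm[rng.below(k + 1)]);
      int corr = 0;
      for (int k = 0; k < m; ++k) {
        const int i = oob[k];
        const double saved = X(i, f);
        // walk the tree substituting feature f with the permuted value
        int node = 0;
        while (feature[node] >= 0) {
          double xv = feature[node] == f ? X(perm[k], f) : X(i, feature[node]);
          node = xv <= threshold[node] ? left[node] : right[node];
        }
        (void)saved;
        if ((value[node] > 0.5 ? 1.0 : 0.0) == y[i]) ++corr;
      }
      mda[f] += acc0 - static_cast<double>(corr) / m;
      ntree_used[f] += 1;
    }
  }
  for (int f = 0; f < d; ++f)
    mda[f] = ntree_used[f] > 0 ? mda[f] / ntree_used[f] : 0.0;
  return mda;
}
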