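#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Random forest of unpruned binary-threshold trees split by weighted
// information gain (class entropy in bits). Bootstrap samples are drawn with
// replacement with probability proportional to instance weight, which is how
// cost-sensitive reweighting enters training. mtry features are drawn
// without replacement at every node. All randomness comes from R's RNG, so
// results are reproducible under set.seed().

struct Tree {
  std::vector<int> feature;      // -1 for leaf
  std::vector<double> threshold; // go left if x <= threshold
  std::vector<int> left, right;
  std::vector<int> pred;         // leaf class (0/1), -1 for internal
};

static inline double entropy2(double w0, double w1) {
  double W = w0 + w1;
  if (W <= 0.0) return 0.0;
  double h = 0.0;
  if (w0 > 0.0) { double p = w0 / W; h -= p * std::log2(p); }
  if (w1 > 0.0) { double p = w1 / W; h -= p * std::log2(p); }
  return h;
}

// sample `k` distinct integers from 0..(p-1), ascending order
static void sample_features(int p, int k, std::vector<int> &out) {
  std::vector<int> pool(p);
  for (int i = 0; i < p; ++i) pool[i] = i;
  out.clear();
  for (int i = 0; i < k; ++i) {
    int j = i + (int)(unif_rand() * (p - i));
    if (j >= p) j = p - 1;
    std::swap(pool[i], pool[j]);
    out.push_back(pool[i]);
  }
  std::sort(out.begin(), out.end());
}

static int grow_node(const NumericMatrix &X, const IntegerVector &y,
                     const NumericVector &w, std::vector<int> &idx,
                     int lo, int hi, int mtry, Tree &tree,
                     std::vector<std::pair<double,int> > &buf) {
  double w0 = 0.0, w1 = 0.0;
  for (int i = lo; i < hi; ++i) {
    if (y[idx[i]] == 1) w1 += w[idx[i]]; else w0 += w[idx[i]];
  }
  int node = (int)tree.feature.size();
  tree.feature.push_back(-1); tree.threshold.push_back(0.0);
  tree.left.push_back(-1); tree.right.push_back(-1);
  tree.pred.push_back(w1 > w0 ? 1 : 0);  // tie -> class 0 (FP), conservative

  if (w0 == 0.0 || w1 == 0.0 || hi - lo < 2) return node;

  double H = entropy2(w0, w1), W = w0 + w1;
  double best_gain = 1e-12, best_thr = 0.0;
  int best_feat = -1;

  std::vector<int> feats;
  int p = X.ncol();
  sample_features(p, mtry < p ? mtry : p, feats);

  for (size_t fi = 0; fi < feats.size(); ++fi) {
    int f = feats[fi];
    buf.clear();
    for (int i = lo; i < hi; ++i) buf.push_back(std::make_pair(X(idx[i], f), idx[i]));
    std::sort(buf.begin(), buf.end());
    // Scan tie groups; by the boundary-point property of concave impurity,
    // a cut can only be optimal between two groups that are not both pure
    // for the same class, so pure same-class runs are skipped wholesale.
    double l0 = 0.0, l1 = 0.0;
    double prev_val = 0.0;
    int prev_class = -1;
    bool prev_mixed = false, have_prev = false;
    size_t g = 0;
    while (g < buf.size()) {
      size_t ge = g;
      double v = buf[g].first;
      double g0 = 0.0, g1 = 0.0;
      while (ge < buf.size() && buf[ge].first == v) {
        int ii = buf[ge].second;
        if (y[ii] == 1) g1 += w[ii]; else g0 += w[ii];
        ++ge;
      }
      bool mixed = g0 > 0.0 && g1 > 0.0;
      int gclass = g1 > 0.0 ? 1 : 0;
      if (have_prev && (prev_mixed || mixed || prev_class != gclass)) {
        double gain = H - ((l0 + l1) / W) * entropy2(l0, l1)
                        - ((W - l0 - l1) / W) * entropy2(w0 - l0, w1 - l1);
        if (gain > best_gain) {
          best_gain = gain;
          best_feat = f;
          best_thr = prev_val + (v - prev_val) / 2.0;
        }
      }
      l0 += g0; l1 += g1;
      prev_val = v; prev_class = gclass; prev_mixed = mixed; have_prev = true;
      g = ge;
    }
  }
  if (best_feat < 0) return node;  // no usable split: leaf

  // partition idx[lo,hi) in a stable way
  std::vector<int> lpart, rpart;
  for (int i = lo; i < hi; ++i) {
    if (X(idx[i], best_feat) <= best_thr) lpart.push_back(idx[i]);
    else rpart.push_back(idx[i]);
  }
  for (size_t i = 0; i < lpart.size(); ++i) idx[lo + i] = lpart[i];
  for (size_t i = 0; i < rpart.size(); ++i) idx[lo + lpart.size() + i] = rpart[i];
  int mid = lo + (int)lpart.size();

  tree.feature[node] = best_feat;
  tree.threshold[node] = best_thr;
  tree.pred[node] = -1;
  tree.left[node]  = grow_node(X, y, w, idx, lo, mid, mtry, tree, buf);
  tree.right[node] = grow_node(X, y, w, idx, mid, hi, mtry, tree, buf);
  return node;
}

static inline int tree_predict(const Tree &t, const NumericMatrix &X, int row) {
  int node = 0;
  while (t.feature[node] >= 0)
    node = (X(row, t.feature[node]) <= t.threshold[node]) ? t.left[node] : t.right[node];
  return t.pred[node];
}

// [[Rcpp::export(name = ".cpp_grow_forest")]]
List cpp_grow_forest(NumericMatrix X, IntegerVector y, NumericVector w,
                     int ntree, int mtry) {
  int n = X.nrow();
  RNGScope scope;

  // cumulative weights for the weighted bootstrap
  std::vector<double> cum(n);
  double tot = 0.0;
  for (int i = 0; i < n; ++i) { tot += w[i]; cum[i] = tot; }
  if (tot <= 0.0) stop("total instance weight must be positive");

  List trees(ntree);
  std::vector<int> oob1(n, 0), oobn(n, 0);
  std::vector<int> idx(n);
  std::vector<char> inbag(n);
  std::vector<std::pair<double,int> > buf;
  buf.reserve(n);

  for (int t = 0; t < ntree; ++t) {
    std::fill(inbag.begin(), inbag.end(), 0);
    for (int i = 0; i < n; ++i) {
      double u = unif_rand() * tot;
      int j = (int)(std::lower_bound(cum.begin(), cum.end(), u) - cum.begin());
      if (j >= n) j = n - 1;
      idx[i] = j;
      inbag[j] = 1;
    }
    Tree tr;
    grow_node(X, y, w, idx, 0, n, mtry, tr, buf);
    for (int i = 0; i < n; ++i) {
      if (!inbag[i]) {
        ++oobn[i];
        oob1[i] += tree_predict(tr, X, i);
      }
    }
    trees[t] = List::create(
      _["feature"] = wrap(tr.feature), _["threshold"] = wrap(tr.threshold),
      _["left"] = wrap(tr.left), _["right"] = wrap(tr.right),
      _["pred"] = wrap(tr.pred));
  }

  int n_scored = 0, n_err = 0;
  IntegerVector oob_pred(n, NA_INTEGER);
  for (int i = 0; i < n; ++i) {
    if (oobn[i] > 0) {
      int pred = (2 * oob1[i] > oobn[i]) ? 1 : 0;  // tie -> 0
      oob_pred[i] = pred;
      ++n_scored;
      if (pred != y[i]) ++n_err;
    }
  }
  double oob_error = n_scored > 0 ? (double)n_err / n_scored : NA_REAL;
  return List::create(_["trees"] = trees, _["oob_error"] = oob_error,
                      _["oob_pred"] = oob_pred);
}

static Tree tree_from_list(List tl) {
  Tree t;
  t.feature = as<std::vector<int> >(tl["feature"]);
  t.threshold = as<std::vector<double> >(tl["threshold"]);
  t.left = as<std::vector<int> >(tl["left"]);
  t.right = as<std::vector<int> >(tl["right"]);
  t.pred = as<std::vector<int> >(tl["pred"]);
  return t;
}

// [[Rcpp::export(name = ".cpp_predict_forest")]]
IntegerVector cpp_predict_forest(List trees, NumericMatrix X) {
  int n = X.nrow(), ntree = trees.size();
  std::vector<Tree> ts(ntree);
  for (int t = 0; t < ntree; ++t) ts[t] = tree_from_list(trees[t]);
  IntegerVector votes1(n, 0);
  for (int i = 0; i < n; ++i)
    for (int t = 0; t < ntree; ++t)
      votes1[i] += tree_predict(ts[t], X, i);
  return votes1;
}
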