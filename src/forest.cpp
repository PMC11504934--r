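// Minimal bagged regression forest for iterative nonparametric imputation.
// One-shot fit-and-predict keeps no state on the R side; determinism comes
// from a per-tree mt19937 stream derived from `seed`.
#include <Rcpp.h>
#include <algorithm>
#include <random>
#include <vector>

using namespace Rcpp;

namespace {

struct Node {
  int feature = -1;      // -1 marks a leaf
  double threshold = 0.0;
  int left = -1, right = -1;
  double value = 0.0;
};

struct TreeBuilder {
  const NumericMatrix &X;
  const NumericVector &y;
  int mtry, min_node, max_depth;
  std::mt19937 &rng;
  std::vector<Node> nodes;
  std::vector<int> feat_pool;
  std::vector<std::pair<double, double>> xy; // reused split workspace

  TreeBuilder(const NumericMatrix &X_, const NumericVector &y_, int mtry_,
              int min_node_, int max_depth_, std::mt19937 &rng_)
      : X(X_), y(y_), mtry(mtry_), min_node(min_node_), max_depth(max_depth_),
        rng(rng_) {
    feat_pool.resize(X.ncol());
    for (int j = 0; j < X.ncol(); ++j) feat_pool[j] = j;
    xy.resize(X.nrow());
  }

  int build(std::vector<int> &idx, int lo, int hi, int depth) {
    int node_id = (int)nodes.size();
    nodes.push_back(Node());
    int n = hi - lo;
    double sum = 0.0;
    for (int i = lo; i < hi; ++i) sum += y[idx[i]];
    double mean = sum / n;
    nodes[node_id].value = mean;
    if (n <= min_node || depth >= max_depth) return node_id;

    double total_ss = 0.0;
    for (int i = lo; i < hi; ++i) {
      double d = y[idx[i]] - mean;
      total_ss += d * d;
    }
    if (total_ss <= 1e-12) return node_id;

    // candidate features
    for (int k = 0; k < mtry; ++k) {
      std::uniform_int_distribution<int> d(k, (int)feat_pool.size() - 1);
      std::swap(feat_pool[k], feat_pool[d(rng)]);
    }

    double best_gain = 1e-12;
    int best_feat = -1;
    double best_thr = 0.0;
    for (int k = 0; k < mtry; ++k) {
      int f = feat_pool[k];
      for (int i = 0; i < n; ++i)
        xy[i] = std::make_pair(X(idx[lo + i], f), y[idx[lo + i]]);
      std::sort(xy.begin(), xy.begin() + n);
      if (xy[0].first == xy[n - 1].first) continue;
      double left_sum = 0.0;
      for (int i = 0; i < n - 1; ++i) {
        left_sum += xy[i].second;
        if (xy[i].first == xy[i + 1].first) continue;
        int nl = i + 1, nr = n - nl;
        double right_sum = sum - left_sum;
        double gain = left_sum * left_sum / nl + right_sum * right_sum / nr -
                      sum * sum / n;
        if (gain > best_gain) {
          best_gain = gain;
          best_feat = f;
          best_thr = 0.5 * (xy[i].first + xy[i + 1].first);
        }
      }
    }
    if (best_feat < 0) return node_id;

    int mid = lo;
    for (int i = lo; i < hi; ++i)
      if (X(idx[i], best_feat) <= best_thr) std::swap(idx[mid++], idx[i]);
    if (mid == lo || mid == hi) return node_id;

    nodes[node_id].feature = best_feat;
    nodes[node_id].threshold = best_thr;
    int l = build(idx, lo, mid, depth + 1);
    int r = build(idx, mid, hi, depth + 1);
    nodes[node_id].left = l;
    nodes[node_id].right = r;
    return node_id;
  }

  double predict_row(const NumericMatrix &Xp, int row) const {
    int cur = 0;
    while (nodes[cur].feature >= 0)
      cur = (Xp(row, nodes[cur].feature) <= nodes[cur].threshold)
                ? nodes[cur].left
                : nodes[cur].right;
    return nodes[cur].value;
  }
};

} // namespace

// [[Rcpp::export(name = ".rf_regress")]]
NumericVector rf_regress(NumericMatrix X, NumericVector y, NumericMatrix Xpred,
                         int n_trees, int mtry, int min_node, int seed) {
  int n = X.nrow();
  if (n != y.size()) stop("X and y disagree on n");
  if (n == 0) stop("no training rows");
  if (mtry < 1) mtry = 1;
  if (mtry > X.ncol()) mtry = X.ncol();

  NumericVector out(Xpred.nrow(), 0.0);
  std::vector<int> idx(n);
  for (int t = 0; t < n_trees; ++t) {
    std::mt19937 rng((unsigned)seed + 0x9e3779b9u * (unsigned)(t + 1));
    std::uniform_int_distribution<int> boot(0, n - 1);
    for (int i = 0; i < n; ++i) idx[i] = boot(rng);
    TreeBuilder tb(X, y, mtry, min_node, 25, rng);
    tb.nodes.reserve(2 * n / std::max(1, min_node));
    tb.build(idx, 0, n, 0);
    for (int r = 0; r < Xpred.nrow(); ++r) out[r] += tb.predict_row(Xpred, r);
  }
  for (int r = 0; r < Xpred.nrow(); ++r) out[r] /= n_trees;
  return out;
}
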