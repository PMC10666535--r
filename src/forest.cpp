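// Regression trees, random forests and gradient-boosted trees.
//
// Written here rather than borrowed because the package has no compiled
// ensemble dependency available; the implementation is the standard CART
// variance-reduction machinery with per-node feature subsampling and
// bootstrap aggregation.  All randomness comes from an internal xorshift64*
// generator seeded explicitly, so fits are reproducible across platforms
// and independent of R's RNG state.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

namespace {

struct XRng {
  uint64_t s;
  explicit XRng(uint64_t seed) : s(seed ? seed : 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {
    s ^= s >> 12;
    s ^= s << 25;
    s ^= s >> 27;
    return s * 0x2545F4914F6CDD1DULL;
  }
  // uniform in [0, 1)
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  // uniform integer in [0, n)
  int unif_int(int n) {
    int k = static_cast<int>(unif() * n);
    return k >= n ? n - 1 : k;
  }
};

struct Node {
  int feature;       // -1 for a leaf
  double threshold;  // go left when x <= threshold
  int left, right;   // node indices, -1 for none
  double value;      // node mean (prediction for leaves)
};

class TreeBuilder {
 public:
  TreeBuilder(const NumericMatrix& X, const NumericVector& y, int mtry,
              int min_node, int max_depth, XRng& rng)
      : X_(X), y_(y), mtry_(mtry), min_node_(min_node),
        max_depth_(max_depth), rng_(rng), p_(X.ncol()) {
    feat_pool_.resize(p_);
    for (int j = 0; j < p_; ++j) feat_pool_[j] = j;
  }

  // idx is consumed (reordered in place during partitioning)
  std::vector<Node> build(std::vector<int>& idx) {
    nodes_.clear();
    build_node(idx, 0, static_cast<int>(idx.size()), 0);
    return nodes_;
  }

 private:
  const NumericMatrix& X_;
  const NumericVector& y_;
  int mtry_, min_node_, max_depth_;
  XRng& rng_;
  int p_;
  std::vector<int> feat_pool_;
  std::vector<Node> nodes_;
  std::vector<std::pair<double, int> > buf_;

  int make_leaf(double mean) {
    Node nd;
    nd.feature = -1;
    nd.threshold = 0.0;
    nd.left = nd.right = -1;
    nd.value = mean;
    nodes_.push_back(nd);
    return static_cast<int>(nodes_.size()) - 1;
  }

  int build_node(std::vector<int>& idx, int lo, int hi, int depth) {
    const int n = hi - lo;
    double sum = 0.0, sum2 = 0.0;
    for (int i = lo; i < hi; ++i) {
      const double v = y_[idx[i]];
      sum += v;
      sum2 += v * v;
    }
    const double mean = sum / n;
    const double sse = sum2 - sum * sum / n;

    if (n < min_node_ || sse <= 1e-12 ||
        (max_depth_ > 0 && depth >= max_depth_))
      return make_leaf(mean);

    // sample mtry distinct candidate features (partial Fisher-Yates)
    int best_feat = -1;
    double best_thr = 0.0;
    // baseline score: single node; a split must strictly improve it
    double best_score = sum * sum / n + 1e-12;
    for (int t = 0; t < mtry_; ++t) {
      const int swap_with = t + rng_.unif_int(p_ - t);
      std::swap(feat_pool_[t], feat_pool_[swap_with]);
      const int f = feat_pool_[t];

      buf_.clear();
      for (int i = lo; i < hi; ++i)
        buf_.push_back(std::make_pair(X_(idx[i], f), idx[i]));
      std::sort(buf_.begin(), buf_.end());
      if (buf_.front().first == buf_.back().first) continue;  // constant

      double sl = 0.0;
      for (int i = 0; i < n - 1; ++i) {
        sl += y_[buf_[i].second];
        if (buf_[i].first == buf_[i + 1].first) continue;
        const int nl = i + 1, nr = n - nl;
        const double sr = sum - sl;
        const double score = sl * sl / nl + sr * sr / nr;
        if (score > best_score) {
          best_score = score;
          best_feat = f;
          best_thr = 0.5 * (buf_[i].first + buf_[i + 1].first);
        }
      }
    }

    if (best_feat < 0) return make_leaf(mean);

    // partition idx[lo:hi) on the chosen split
    int mid = lo;
    for (int i = lo; i < hi; ++i)
      if (X_(idx[i], best_feat) <= best_thr) std::swap(idx[i], idx[mid++]);
    if (mid == lo || mid == hi) return make_leaf(mean);  // numeric guard

    Node nd;
    nd.feature = best_feat;
    nd.threshold = best_thr;
    nd.value = mean;
    nodes_.push_back(nd);
    const int self = static_cast<int>(nodes_.size()) - 1;
    const int left = build_node(idx, lo, mid, depth + 1);
    const int right = build_node(idx, mid, hi, depth + 1);
    nodes_[self].left = left;
    nodes_[self].right = right;
    return self;
  }
};

NumericMatrix pack_tree(const std::vector<Node>& nodes) {
  NumericMatrix m(static_cast<int>(nodes.size()), 5);
  for (size_t i = 0; i < nodes.size(); ++i) {
    m(i, 0) = nodes[i].feature;
    m(i, 1) = nodes[i].threshold;
    m(i, 2) = nodes[i].left;
    m(i, 3) = nodes[i].right;
    m(i, 4) = nodes[i].value;
  }
  return m;
}

double predict_row(const NumericMatrix& tree, const NumericMatrix& X, int row) {
  int node = 0;
  while (tree(node, 0) >= 0) {
    const int f = static_cast<int>(tree(node, 0));
    node = (X(row, f) <= tree(node, 1)) ? static_cast<int>(tree(node, 2))
                                        : static_cast<int>(tree(node, 3));
  }
  return tree(node, 4);
}

}  // namespace

// [[Rcpp::export]]
List cpp_forest_fit(NumericMatrix X, NumericVector y, int ntree, int mtry,
                    int min_node, int max_depth, double seed, bool bootstrap) {
  const int n = X.nrow();
  if (n < 1) stop("empty training matrix");
  if (mtry < 1 || mtry > X.ncol()) stop("invalid mtry");
  XRng rng(static_cast<uint64_t>(seed) * 2654435761ULL + 1ULL);
  List trees(ntree);
  std::vector<int> idx(n);
  for (int t = 0; t < ntree; ++t) {
    if (bootstrap) {
      for (int i = 0; i < n; ++i) idx[i] = rng.unif_int(n);
    } else {
      for (int i = 0; i < n; ++i) idx[i] = i;
    }
    TreeBuilder tb(X, y, mtry, min_node, max_depth, rng);
    trees[t] = pack_tree(tb.build(idx));
  }
  return trees;
}

// [[Rcpp::export]]
NumericVector cpp_forest_predict(List trees, NumericMatrix X) {
  const int n = X.nrow(), T = trees.size();
  NumericVector out(n);
  for (int t = 0; t < T; ++t) {
    NumericMatrix tree = trees[t];
    for (int i = 0; i < n; ++i) out[i] += predict_row(tree, X, i);
  }
  for (int i = 0; i < n; ++i) out[i] /= T;
  return out;
}

// [[Rcpp::export]]
List cpp_gbt_fit(NumericMatrix X, NumericVector y, int nrounds, int depth,
                 double rate, int min_node, double seed) {
  const int n = X.nrow();
  if (n < 1) stop("empty training matrix");
  XRng rng(static_cast<uint64_t>(seed) * 2654435761ULL + 7ULL);
  const double init = mean(y);
  NumericVector resid(n), fit(n, init);
  List trees(nrounds);
  std::vector<int> idx(n);
  for (int m = 0; m < nrounds; ++m) {
    for (int i = 0; i < n; ++i) resid[i] = y[i] - fit[i];
    for (int i = 0; i < n; ++i) idx[i] = i;
    TreeBuilder tb(X, resid, X.ncol(), min_node, depth, rng);
    NumericMatrix tree = pack_tree(tb.build(idx));
    trees[m] = tree;
    for (int i = 0; i < n; ++i) fit[i] += rate * predict_row(tree, X, i);
  }
  return List::create(_["init"] = init, _["rate"] = rate, _["trees"] = trees);
}

// [[Rcpp::export]]
NumericVector cpp_gbt_predict(List model, NumericMatrix X) {
  const double init = as<double>(model["init"]);
  const double rate = as<double>(model["rate"]);
  List trees = model["trees"];
  const int n = X.nrow(), M = trees.size();
  NumericVector out(n, init);
  for (int m = 0; m < M; ++m) {
    NumericMatrix tree = trees[m];
    for (int i = 0; i < n; ++i) out[i] += rate * predict_row(tree, X, i);
  }
  return out;
}
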