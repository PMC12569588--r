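// Random-forest classifier: CART trees, gini impurity, per-node feature
// subsampling, bootstrap subsampling with replacement.  Semantics follow the
// common scikit-learn parameterisation (n_estimators, min_samples_leaf on
// node sample counts, max_samples as bootstrap fraction, mtry = sqrt(p)),
// since no tree learner package is available as a dependency.
#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <random>
#include <vector>

using namespace Rcpp;

namespace {

struct Node {
  int feature;      // -1 for leaf
  double threshold; // go left when x <= threshold
  int left, right;  // child node ids, -1 for leaf
  int pred;         // leaf majority class (ties -> 0)
};

struct Tree {
  std::vector<Node> nodes;
};

// Best split of `idx` (rows may repeat: bootstrap) on one feature.
// Returns gini improvement (weighted child impurity), or -1 if none valid.
struct SplitResult {
  double score = -1.0; // lower child impurity is better; -1 = invalid
  double threshold = 0.0;
};

SplitResult best_split_on_feature(const NumericMatrix &X, const IntegerVector &y,
                                  const std::vector<int> &idx, int feat,
                                  int min_leaf,
                                  std::vector<std::pair<double, int>> &buf) {
  const int n = static_cast<int>(idx.size());
  buf.clear();
  buf.reserve(n);
  for (int i = 0; i < n; ++i)
    buf.emplace_back(X(idx[i], feat), y[idx[i]]);
  std::sort(buf.begin(), buf.end());

  int total_pos = 0;
  for (auto &p : buf) total_pos += p.second;

  SplitResult best;
  int left_n = 0, left_pos = 0;
  for (int i = 0; i < n - 1; ++i) {
    left_n += 1;
    left_pos += buf[i].second;
    if (buf[i].first == buf[i + 1].first) continue; // not a boundary
    const int right_n = n - left_n;
    if (left_n < min_leaf || right_n < min_leaf) continue;
    const double lp = static_cast<double>(left_pos) / left_n;
    const double rp = static_cast<double>(total_pos - left_pos) / right_n;
    const double gini = left_n * 2.0 * lp * (1.0 - lp) +
                        right_n * 2.0 * rp * (1.0 - rp);
    if (best.score < 0 || gini < best.score) {
      best.score = gini;
      best.threshold = 0.5 * (buf[i].first + buf[i + 1].first);
    }
  }
  return best;
}

void grow(Tree &tree, const NumericMatrix &X, const IntegerVector &y,
          std::vector<int> idx, int depth, int max_depth, int min_leaf,
          int mtry, std::mt19937 &rng) {
  const int node_id = static_cast<int>(tree.nodes.size());
  tree.nodes.push_back(Node{-1, 0.0, -1, -1, 0});

  const int n = static_cast<int>(idx.size());
  int pos = 0;
  for (int i : idx) pos += y[i];

  auto make_leaf = [&]() {
    tree.nodes[node_id].pred = (2 * pos > n) ? 1 : 0;
  };

  if (pos == 0 || pos == n || n < 2 * min_leaf || depth >= max_depth) {
    make_leaf();
    return;
  }

  // sample mtry features without replacement (partial Fisher-Yates)
  const int p = X.ncol();
  std::vector<int> feats(p);
  for (int j = 0; j < p; ++j) feats[j] = j;
  const int m = std::min(mtry, p);
  for (int j = 0; j < m; ++j) {
    std::uniform_int_distribution<int> pick(j, p - 1);
    std::swap(feats[j], feats[pick(rng)]);
  }

  std::vector<std::pair<double, int>> buf;
  int best_feat = -1;
  SplitResult best;
  for (int j = 0; j < m; ++j) {
    SplitResult s = best_split_on_feature(X, y, idx, feats[j], min_leaf, buf);
    if (s.score >= 0 && (best_feat < 0 || s.score < best.score)) {
      best = s;
      best_feat = feats[j];
    }
  }
  if (best_feat < 0) { // no valid split among sampled features
    make_leaf();
    return;
  }

  std::vector<int> left_idx, right_idx;
  left_idx.reserve(n);
  right_idx.reserve(n);
  for (int i : idx)
    (X(i, best_feat) <= best.threshold ? left_idx : right_idx).push_back(i);
  idx.clear();
  idx.shrink_to_fit();

  tree.nodes[node_id].feature = best_feat;
  tree.nodes[node_id].threshold = best.threshold;
  tree.nodes[node_id].left = static_cast<int>(tree.nodes.size());
  grow(tree, X, y, std::move(left_idx), depth + 1, max_depth, min_leaf, mtry, rng);
  tree.nodes[node_id].right = static_cast<int>(tree.nodes.size());
  grow(tree, X, y, std::move(right_idx), depth + 1, max_depth, min_leaf, mtry, rng);
}

int predict_tree(const IntegerVector &feature, const NumericVector &threshold,
                 const IntegerVector &left, const IntegerVector &right,
                 const IntegerVector &pred, const NumericMatrix &X, int row) {
  int node = 0;
  while (feature[node] >= 0)
    node = (X(row, feature[node]) <= threshold[node]) ? left[node] : right[node];
  return pred[node];
}

} // namespace

// [[Rcpp::export]]
List rf_fit_cpp(NumericMatrix X, IntegerVector y, int n_trees, int mtry,
                int min_leaf, double max_samples, int max_depth, int seed) {
  const int n = X.nrow();
  const int n_boot = std::max(1, static_cast<int>(std::lround(max_samples * n)));
  List forest(n_trees);
  for (int t = 0; t < n_trees; ++t) {
    std::mt19937 rng(static_cast<unsigned>(seed) + 0x9e3779b9u * t);
    std::uniform_int_distribution<int> draw(0, n - 1);
    std::vector<int> idx(n_boot);
    for (int i = 0; i < n_boot; ++i) idx[i] = draw(rng);

    Tree tree;
    grow(tree, X, y, std::move(idx), 0, max_depth, min_leaf, mtry, rng);

    const int k = static_cast<int>(tree.nodes.size());
    IntegerVector feature(k), left(k), right(k), pred(k);
    NumericVector threshold(k);
    for (int i = 0; i < k; ++i) {
      feature[i] = tree.nodes[i].feature;
      threshold[i] = tree.nodes[i].threshold;
      left[i] = tree.nodes[i].left;
      right[i] = tree.nodes[i].right;
      pred[i] = tree.nodes[i].pred;
    }
    forest[t] = List::create(_["feature"] = feature, _["threshold"] = threshold,
                             _["left"] = left, _["right"] = right,
                             _["pred"] = pred);
  }
  return forest;
}

// [[Rcpp::export]]
IntegerVector rf_predict_cpp(List forest, NumericMatrix X) {
  const int n = X.nrow();
  const int n_trees = forest.size();
  std::vector<int> votes(n, 0);
  for (int t = 0; t < n_trees; ++t) {
    List tr = forest[t];
    IntegerVector feature = tr["feature"], left = tr["left"],
                  right = tr["right"], pred = tr["pred"];
    NumericVector threshold = tr["threshold"];
    for (int i = 0; i < n; ++i)
      votes[i] += predict_tree(feature, threshold, left, right, pred, X, i);
  }
  IntegerVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = (2 * votes[i] > n_trees) ? 1 : 0; // tie -> negative
  return out;
}
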