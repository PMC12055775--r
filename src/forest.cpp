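// Compact CART random forest for binary classification.
// Bootstrap resampling, Gini impurity splits over mtry random features,
// trees grown to purity (or min_node), majority-vote prediction.

#include <Rcpp.h>
#include <random>
#include <algorithm>
#include <vector>

using namespace Rcpp;

struct Node {
  int feature;     // -1 for leaf
  double threshold;
  int left, right; // child indices
  double prob1;    // leaf: fraction of class 1
};

struct Tree {
  std::vector<Node> nodes;
};

static double gini(int n1, int n) {
  if (n == 0) return 0.0;
  double p = (double)n1 / n;
  return 2.0 * p * (1.0 - p);
}

static int grow(const NumericMatrix& X, const IntegerVector& y,
                std::vector<int>& idx, int lo, int hi, int mtry,
                int min_node, std::mt19937& rng, Tree& tree) {
  int n = hi - lo;
  int n1 = 0;
  for (int i = lo; i < hi; ++i) n1 += y[idx[i]];
  int self = (int)tree.nodes.size();
  tree.nodes.push_back(Node{-1, 0.0, -1, -1, n ? (double)n1 / n : 0.0});
  if (n <= min_node || n1 == 0 || n1 == n) return self;

  int p = X.ncol();
  double parent = gini(n1, n);
  double best_gain = 1e-12;
  int best_f = -1; double best_thr = 0.0;

  // sample mtry features without replacement (partial Fisher-Yates)
  std::vector<int> feats(p);
  for (int j = 0; j < p; ++j) feats[j] = j;
  for (int j = 0; j < mtry && j < p; ++j) {
    std::uniform_int_distribution<int> d(j, p - 1);
    std::swap(feats[j], feats[d(rng)]);
  }

  std::vector<std::pair<double,int>> vals(n);
  for (int j = 0; j < mtry && j < p; ++j) {
    int f = feats[j];
    for (int i = 0; i < n; ++i)
      vals[i] = {X(idx[lo + i], f), y[idx[lo + i]]};
    std::sort(vals.begin(), vals.end());
    int l1 = 0;
    for (int i = 0; i < n - 1; ++i) {
      l1 += vals[i].second;
      if (vals[i + 1].first <= vals[i].first + 1e-12) continue;
      int nl = i + 1, nr = n - nl;
      double g = parent - ((double)nl / n) * gini(l1, nl)
                        - ((double)nr / n) * gini(n1 - l1, nr);
      if (g > best_gain) {
        best_gain = g;
        best_f = f;
        best_thr = 0.5 * (vals[i].first + vals[i + 1].first);
      }
    }
  }
  if (best_f < 0) return self;

  // partition idx[lo, hi) by the chosen split
  int mid = lo;
  for (int i = lo; i < hi; ++i)
    if (X(idx[i], best_f) <= best_thr) std::swap(idx[i], idx[mid++]);
  if (mid == lo || mid == hi) return self;

  tree.nodes[self].feature = best_f;
  tree.nodes[self].threshold = best_thr;
  int l = grow(X, y, idx, lo, mid, mtry, min_node, rng, tree);
  int r = grow(X, y, idx, mid, hi, mtry, min_node, rng, tree);
  tree.nodes[self].left = l;
  tree.nodes[self].right = r;
  return self;
}

static double predict_tree(const Tree& tree, const NumericMatrix& X, int row) {
  int cur = 0;
  while (tree.nodes[cur].feature >= 0)
    cur = (X(row, tree.nodes[cur].feature) <= tree.nodes[cur].threshold)
            ? tree.nodes[cur].left : tree.nodes[cur].right;
  return tree.nodes[cur].prob1;
}

// [[Rcpp::export(rng = false)]]
List rf_fit_cpp(NumericMatrix X, IntegerVector y, int ntree, int mtry,
                int min_node, int seed) {
  int n = X.nrow();
  std::mt19937 rng((unsigned)seed);
  std::uniform_int_distribution<int> boot(0, n - 1);
  List trees(ntree);
  for (int t = 0; t < ntree; ++t) {
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = boot(rng);
    Tree tree;
    grow(X, y, idx, 0, n, mtry, min_node, rng, tree);
    int m = (int)tree.nodes.size();
    IntegerVector feature(m), left(m), right(m);
    NumericVector thr(m), prob1(m);
    for (int i = 0; i < m; ++i) {
      feature[i] = tree.nodes[i].feature;
      thr[i] = tree.nodes[i].threshold;
      left[i] = tree.nodes[i].left;
      right[i] = tree.nodes[i].right;
      prob1[i] = tree.nodes[i].prob1;
    }
    trees[t] = List::create(_["feature"] = feature, _["threshold"] = thr,
                            _["left"] = left, _["right"] = right,
                            _["prob1"] = prob1);
  }
  return trees;
}

// [[Rcpp::export(rng = false)]]
NumericVector rf_predict_cpp(List trees, NumericMatrix X) {
  int n = X.nrow(), ntree = trees.size();
  NumericVector votes(n);
  for (int t = 0; t < ntree; ++t) {
    List tl = trees[t];
    IntegerVector feature = tl["feature"], left = tl["left"], right = tl["right"];
    NumericVector thr = tl["threshold"], prob1 = tl["prob1"];
    Tree tree;
    int m = feature.size();
    tree.nodes.resize(m);
    for (int i = 0; i < m; ++i)
      tree.nodes[i] = Node{feature[i], thr[i], left[i], right[i], prob1[i]};
    for (int r = 0; r < n; ++r)
      votes[r] += (predict_tree(tree, X, r) > 0.5) ? 1.0 : 0.0;
  }
  for (int r = 0; r < n; ++r) votes[r] /= ntree;
  return votes;  // fraction of trees voting class 1
}
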