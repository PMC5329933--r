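#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Classification random forest with out-of-bag vote tracking.
//
// Each tree is grown on a bootstrap sample (with replacement, size n) of the
// rows; splits minimise Gini impurity over `mtry` features drawn without
// replacement at every node; trees are grown to purity (no depth limit,
// leaves may hold a single sample).  Rows out of bag for a tree receive one
// vote from that tree (leaf majority class, ties to the lowest class index).
// Vote fractions over a row's OOB trees are the classifier scores used
// downstream for one-vs-rest ROC curves.
//
// Uses R's RNG so results are reproducible under set.seed().

struct Node {
  int feature;      // -1 for leaf
  double threshold;
  int left, right;
  int pred;         // leaf class
};

static int grow_node(const NumericMatrix &X, const IntegerVector &y,
                     int n_class, int mtry, std::vector<int> &idx, int lo,
                     int hi, std::vector<Node> &nodes,
                     std::vector<int> &feat_pool,
                     std::vector<std::pair<double,int> > &buf) {
  const int n = hi - lo;
  std::vector<int> counts(n_class, 0);
  for (int i = lo; i < hi; ++i) counts[y[idx[i]]]++;

  int maj = 0;
  for (int c = 1; c < n_class; ++c) if (counts[c] > counts[maj]) maj = c;
  bool pure = counts[maj] == n;

  const int me = (int)nodes.size();
  nodes.push_back(Node{-1, 0.0, -1, -1, maj});
  if (pure || n < 2) return me;

  const int p = X.ncol();
  // sample mtry distinct features (partial Fisher-Yates on feat_pool)
  for (int j = 0; j < p; ++j) feat_pool[j] = j;
  int m = std::min(mtry, p);
  for (int j = 0; j < m; ++j) {
    int k = j + (int)std::floor(unif_rand() * (p - j));
    if (k >= p) k = p - 1;
    std::swap(feat_pool[j], feat_pool[k]);
  }

  double best_gain = 0.0, best_thr = 0.0;
  int best_feat = -1;
  double total = 0.0;
  for (int c = 0; c < n_class; ++c)
    total += (double)counts[c] * counts[c];
  const double parent_gini = 1.0 - total / ((double)n * n);

  std::vector<int> left_counts(n_class);
  for (int j = 0; j < m; ++j) {
    const int f = feat_pool[j];
    buf.clear();
    for (int i = lo; i < hi; ++i)
      buf.push_back(std::make_pair(X(idx[i], f), idx[i]));
    std::sort(buf.begin(), buf.end());
    if (buf.front().first == buf.back().first) continue;

    std::fill(left_counts.begin(), left_counts.end(), 0);
    int nl = 0;
    for (int i = 0; i < n - 1; ++i) {
      left_counts[y[buf[i].second]]++;
      ++nl;
      if (buf[i].first == buf[i + 1].first) continue;
      const int nr = n - nl;
      double sl = 0.0, sr = 0.0;
      for (int c = 0; c < n_class; ++c) {
        sl += (double)left_counts[c] * left_counts[c];
        const double rc = counts[c] - left_counts[c];
        sr += rc * rc;
      }
      const double gini_l = 1.0 - sl / ((double)nl * nl);
      const double gini_r = 1.0 - sr / ((double)nr * nr);
      const double gain =
          parent_gini - (nl * gini_l + nr * gini_r) / n;
      if (gain > best_gain + 1e-12) {
        best_gain = gain;
        best_feat = f;
        best_thr = 0.5 * (buf[i].first + buf[i + 1].first);
      }
    }
  }
  if (best_feat < 0) return me;  // no improving split found

  // partition idx[lo:hi) in place
  int i = lo, jx = hi - 1;
  while (i <= jx) {
    if (X(idx[i], best_feat) <= best_thr) ++i;
    else std::swap(idx[i], idx[jx--]);
  }
  const int mid = i;
  if (mid == lo || mid == hi) return me;  // numerically degenerate

  nodes[me].feature = best_feat;
  nodes[me].threshold = best_thr;
  int l = grow_node(X, y, n_class, mtry, idx, lo, mid, nodes, feat_pool, buf);
  int r = grow_node(X, y, n_class, mtry, idx, mid, hi, nodes, feat_pool, buf);
  nodes[me].left = l;
  nodes[me].right = r;
  return me;
}

static int predict_row(const std::vector<Node> &nodes, const NumericMatrix &X,
                       int row) {
  int cur = 0;
  while (nodes[cur].feature >= 0) {
    cur = (X(row, nodes[cur].feature) <= nodes[cur].threshold)
              ? nodes[cur].left
              : nodes[cur].right;
  }
  return nodes[cur].pred;
}

// [[Rcpp::export]]
List cpp_rf_oob_votes(NumericMatrix X, IntegerVector y, int n_class,
                      int n_trees, int mtry) {
  const int n = X.nrow();
  IntegerMatrix votes(n, n_class);
  IntegerVector oob_trees(n);
  std::vector<int> idx;
  std::vector<char> inbag(n);
  std::vector<int> feat_pool(X.ncol());
  std::vector<std::pair<double,int> > buf;
  buf.reserve(n);

  for (int t = 0; t < n_trees; ++t) {
    std::fill(inbag.begin(), inbag.end(), 0);
    idx.clear();
    for (int i = 0; i < n; ++i) {
      int k = (int)std::floor(unif_rand() * n);
      if (k >= n) k = n - 1;
      idx.push_back(k);
      inbag[k] = 1;
    }
    std::vector<Node> nodes;
    nodes.reserve(2 * n);
    grow_node(X, y, n_class, mtry, idx, 0, n, nodes, feat_pool, buf);
    for (int i = 0; i < n; ++i) {
      if (inbag[i]) continue;
      votes(i, predict_row(nodes, X, i))++;
      oob_trees[i]++;
    }
  }
  return List::create(_["votes"] = votes, _["oob_trees"] = oob_trees);
}
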