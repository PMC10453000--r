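#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Balanced random forest for binary (one-vs-rest) classification.
// - per-tree bootstrap: k draws with replacement from each class,
//   k = min(class sizes), so rare positives are not swamped
// - Gini-impurity splits over mtry randomly chosen features
// - trees grown until pure or node size < min_node
// - importance: Gini decrease weighted by node fraction, averaged over trees
// Uses R's RNG (unif_rand) so set.seed() makes training deterministic.

namespace {

struct Tree {
  std::vector<int> feature;       // split feature, -1 for leaf
  std::vector<double> threshold;  // go left if x <= threshold
  std::vector<int> left, right;
  std::vector<double> prob;       // class-1 fraction at the node
};

int irand(int n) {
  int v = static_cast<int>(unif_rand() * n);
  return v >= n ? n - 1 : v;
}

double gini(int n1, int n) {
  if (n == 0) return 0.0;
  double p = static_cast<double>(n1) / n;
  return 2.0 * p * (1.0 - p);
}

struct Builder {
  const NumericMatrix& X;
  const IntegerVector& y;
  int mtry, min_node;
  std::vector<double>& importance;
  Tree tree;
  int n_boot;

  Builder(const NumericMatrix& X_, const IntegerVector& y_, int mtry_,
          int min_node_, std::vector<double>& imp)
      : X(X_), y(y_), mtry(mtry_), min_node(min_node_), importance(imp),
        n_boot(0) {}

  int build(std::vector<int>& idx) {
    int node = static_cast<int>(tree.feature.size());
    int n = static_cast<int>(idx.size());
    int n1 = 0;
    for (int i : idx) n1 += y[i];
    tree.feature.push_back(-1);
    tree.threshold.push_back(0.0);
    tree.left.push_back(-1);
    tree.right.push_back(-1);
    tree.prob.push_back(n > 0 ? static_cast<double>(n1) / n : 0.5);
    if (n < 2 || n < min_node || n1 == 0 || n1 == n) return node;

    double g_parent = gini(n1, n);
    int p = X.ncol();
    // sample mtry distinct features
    std::vector<int> feats(p);
    for (int f = 0; f < p; ++f) feats[f] = f;
    int m = std::min(mtry, p);
    for (int f = 0; f < m; ++f) std::swap(feats[f], feats[f + irand(p - f)]);

    double best_dec = 1e-12;
    int best_f = -1;
    double best_thr = 0.0;
    std::vector<std::pair<double, int> > vals(n);
    for (int fi = 0; fi < m; ++fi) {
      int f = feats[fi];
      for (int k = 0; k < n; ++k)
        vals[k] = std::make_pair(X(idx[k], f), y[idx[k]]);
      std::sort(vals.begin(), vals.end());
      int left1 = 0;
      for (int k = 0; k < n - 1; ++k) {
        left1 += vals[k].second;
        if (vals[k].first == vals[k + 1].first) continue;
        int nl = k + 1, nr = n - nl;
        double dec = g_parent -
            (static_cast<double>(nl) / n) * gini(left1, nl) -
            (static_cast<double>(nr) / n) * gini(n1 - left1, nr);
        if (dec > best_dec) {
          best_dec = dec;
          best_f = f;
          best_thr = 0.5 * (vals[k].first + vals[k + 1].first);
        }
      }
    }
    if (best_f < 0) return node;  // no admissible split among sampled features

    std::vector<int> li, ri;
    li.reserve(n);
    ri.reserve(n);
    for (int i : idx)
      (X(i, best_f) <= best_thr ? li : ri).push_back(i);
    if (li.empty() || ri.empty()) return node;

    importance[best_f] += best_dec * (static_cast<double>(n) / n_boot);
    tree.feature[node] = best_f;
    tree.threshold[node] = best_thr;
    int l = build(li);
    tree.left[node] = l;
    int r = build(ri);
    tree.right[node] = r;
    return node;
  }
};

double predict_tree(const List& tr, const NumericMatrix& X, int row) {
  IntegerVector feature = tr["feature"];
  NumericVector threshold = tr["threshold"];
  IntegerVector left = tr["left"], right = tr["right"];
  NumericVector prob = tr["prob"];
  int node = 0;
  while (feature[node] >= 0) {
    node = (X(row, feature[node]) <= threshold[node]) ? left[node]
                                                      : right[node];
  }
  return prob[node];
}

}  // namespace

// [[Rcpp::export(name = ".rf_train")]]
List rf_train_cpp(NumericMatrix X, IntegerVector y, int ntree, int mtry,
                  int min_node) {
  int n = X.nrow(), p = X.ncol();
  if (y.size() != n) stop("length(y) != nrow(X)");
  std::vector<int> pos, neg;
  for (int i = 0; i < n; ++i) (y[i] == 1 ? pos : neg).push_back(i);
  if (pos.empty() || neg.empty()) stop("both classes must be present");
  int k = static_cast<int>(std::min(pos.size(), neg.size()));

  RNGScope scope;
  std::vector<double> importance(p, 0.0);
  List trees(ntree);
  for (int t = 0; t < ntree; ++t) {
    std::vector<int> idx;
    idx.reserve(2 * k);
    for (int d = 0; d < k; ++d) idx.push_back(pos[irand(pos.size())]);
    for (int d = 0; d < k; ++d) idx.push_back(neg[irand(neg.size())]);
    Builder b(X, y, mtry, min_node, importance);
    b.n_boot = 2 * k;
    b.build(idx);
    trees[t] = List::create(
        _["feature"] = IntegerVector(b.tree.feature.begin(),
                                     b.tree.feature.end()),
        _["threshold"] = NumericVector(b.tree.threshold.begin(),
                                       b.tree.threshold.end()),
        _["left"] = IntegerVector(b.tree.left.begin(), b.tree.left.end()),
        _["right"] = IntegerVector(b.tree.right.begin(), b.tree.right.end()),
        _["prob"] = NumericVector(b.tree.prob.begin(), b.tree.prob.end()));
  }
  NumericVector imp(importance.begin(), importance.end());
  for (int f = 0; f < p; ++f) imp[f] /= ntree;
  return List::create(_["trees"] = trees, _["importance"] = imp,
                      _["ntree"] = ntree, _["mtry"] = mtry);
}

// [[Rcpp::export(name = ".rf_predict")]]
NumericVector rf_predict_cpp(List forest, NumericMatrix X) {
  List trees = forest["trees"];
  int ntree = trees.size(), n = X.nrow();
  NumericVector score(n, 0.0);
  for (int t = 0; t < ntree; ++t) {
    List tr = trees[t];
    for (int i = 0; i < n; ++i)
      if (predict_tree(tr, X, i) > 0.5) score[i] += 1.0;
  }
  for (int i = 0; i < n; ++i) score[i] /= ntree;
  return score;
}
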