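#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Binary-classification random forest: bagged CART trees, Gini impurity,
// mtry features per split, mean-decrease-in-impurity importance.
// Uses R's RNG so results are reproducible under set.seed().

namespace {

struct Tree {
  std::vector<int> feature;      // split feature (0-based); -1 for leaf
  std::vector<double> threshold; // go left if x <= threshold
  std::vector<int> left;
  std::vector<int> right;
  std::vector<double> prob;      // leaf: P(y = 1)
};

inline int rand_below(int n) {
  int v;
  do {
    v = static_cast<int>(unif_rand() * n);
  } while (v >= n);
  return v;
}

inline double gini(double n1, double n) {
  if (n <= 0.0) return 0.0;
  double p = n1 / n;
  return 2.0 * p * (1.0 - p);
}

class Grower {
public:
  Grower(const NumericMatrix& X, const IntegerVector& y,
         int mtry, int min_node, int max_depth,
         std::vector<double>& importance)
    : X_(X), y_(y), mtry_(mtry), min_node_(min_node),
      max_depth_(max_depth), imp_(importance) {
    pool_.resize(X_.ncol());
    for (int j = 0; j < X_.ncol(); ++j) pool_[j] = j;
  }

  Tree grow(std::vector<int>& idx) {
    tree_ = Tree();
    n_root_ = static_cast<double>(idx.size());
    grow_node(idx, 0);
    return tree_;
  }

private:
  const NumericMatrix& X_;
  const IntegerVector& y_;
  int mtry_, min_node_, max_depth_;
  std::vector<double>& imp_;
  std::vector<int> pool_;
  Tree tree_;
  double n_root_;

  int make_leaf(double n1, double n) {
    tree_.feature.push_back(-1);
    tree_.threshold.push_back(0.0);
    tree_.left.push_back(-1);
    tree_.right.push_back(-1);
    tree_.prob.push_back(n > 0 ? n1 / n : 0.5);
    return static_cast<int>(tree_.feature.size()) - 1;
  }

  int grow_node(std::vector<int>& idx, int depth) {
    const int n = static_cast<int>(idx.size());
    int n1 = 0;
    for (int i : idx) n1 += y_[i];

    if (n1 == 0 || n1 == n || n < 2 * min_node_ || depth >= max_depth_)
      return make_leaf(n1, n);

    // sample mtry candidate features without replacement
    const int p = static_cast<int>(pool_.size());
    for (int j = 0; j < mtry_; ++j)
      std::swap(pool_[j], pool_[j + rand_below(p - j)]);

    const double g_parent = gini(n1, n);
    double best_gain = 1e-12;
    int best_f = -1;
    double best_thr = 0.0;

    std::vector<std::pair<double, int> > vals(n);
    for (int j = 0; j < mtry_; ++j) {
      const int f = pool_[j];
      for (int i = 0; i < n; ++i)
        vals[i] = std::make_pair(X_(idx[i], f), y_[idx[i]]);
      std::sort(vals.begin(), vals.end());
      int nl = 0, nl1 = 0;
      for (int i = 0; i < n - 1; ++i) {
        ++nl;
        nl1 += vals[i].second;
        if (vals[i].first == vals[i + 1].first) continue;
        if (nl < min_node_ || n - nl < min_node_) continue;
        double gain = g_parent
          - (nl / static_cast<double>(n)) * gini(nl1, nl)
          - ((n - nl) / static_cast<double>(n)) * gini(n1 - nl1, n - nl);
        if (gain > best_gain) {
          best_gain = gain;
          best_f = f;
          best_thr = 0.5 * (vals[i].first + vals[i + 1].first);
        }
      }
    }

    if (best_f < 0) return make_leaf(n1, n);

    imp_[best_f] += (n / n_root_) * best_gain;

    std::vector<int> lidx, ridx;
    lidx.reserve(n);
    ridx.reserve(n);
    for (int i : idx)
      (X_(i, best_f) <= best_thr ? lidx : ridx).push_back(i);

    const int node = make_leaf(n1, n); // reserve slot, then fill as internal
    tree_.feature[node] = best_f;
    tree_.threshold[node] = best_thr;
    const int l = grow_node(lidx, depth + 1);
    const int r = grow_node(ridx, depth + 1);
    tree_.left[node] = l;
    tree_.right[node] = r;
    return node;
  }
};

List tree_to_list(const Tree& t) {
  return List::create(
    Named("feature") = wrap(t.feature),
    Named("threshold") = wrap(t.threshold),
    Named("left") = wrap(t.left),
    Named("right") = wrap(t.right),
    Named("prob") = wrap(t.prob));
}

double tree_predict_one(const IntegerVector& feature,
                        const NumericVector& threshold,
                        const IntegerVector& left,
                        const IntegerVector& right,
                        const NumericVector& prob,
                        const NumericMatrix& X, int row) {
  int node = 0;
  while (feature[node] >= 0)
    node = (X(row, feature[node]) <= threshold[node]) ? left[node]
                                                      : right[node];
  return prob[node];
}

} // namespace

// [[Rcpp::export(name = ".rf_fit_cpp")]]
List rf_fit_cpp(NumericMatrix X, IntegerVector y, int n_trees, int mtry,
                int min_node, int max_depth) {
  const int n = X.nrow();
  std::vector<double> importance(X.ncol(), 0.0);
  Grower grower(X, y, mtry, min_node, max_depth, importance);
  List trees(n_trees);
  std::vector<int> idx(n);
  for (int t = 0; t < n_trees; ++t) {
    for (int i = 0; i < n; ++i) idx[i] = rand_below(n); // bootstrap
    trees[t] = tree_to_list(grower.grow(idx));
  }
  NumericVector imp = wrap(importance);
  imp = imp / n_trees;
  return List::create(Named("trees") = trees, Named("importance") = imp);
}

// [[Rcpp::export(name = ".rf_predict_cpp")]]
NumericVector rf_predict_cpp(List trees, NumericMatrix X) {
  const int n = X.nrow();
  const int T = trees.size();
  NumericVector out(n);
  for (int t = 0; t < T; ++t) {
    List tr = trees[t];
    IntegerVector feature = tr["feature"];
    NumericVector threshold = tr["threshold"];
    IntegerVector left = tr["left"];
    IntegerVector right = tr["right"];
    NumericVector prob = tr["prob"];
    for (int i = 0; i < n; ++i)
      out[i] += tree_predict_one(feature, threshold, left, right, prob, X, i);
  }
  return out / static_cast<double>(T);
}
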