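// Random-forest core: bagged CART trees with Gini splitting, per-feature
// mean-decrease-in-impurity importance and leaf-probability averaging.
// Uses R's RNG so forests are reproducible under set.seed().

#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

namespace {

struct Node {
  int feat;     // -1 for leaf
  double thr;
  int left, right;
  double prob;  // in-bag positive fraction at the node
};

struct BestSplit {
  int feat = -1;
  double thr = 0.0;
  double score = R_PosInf;  // nL*giniL + nR*giniR
};

double gini_counts(int pos, int n) {
  if (n == 0) return 0.0;
  double p = static_cast<double>(pos) / n;
  return 1.0 - p * p - (1.0 - p) * (1.0 - p);
}

// Partial Fisher-Yates draw of m feature indices out of p.
void sample_features(std::vector<int>& pool, int m, std::vector<int>& out) {
  int p = pool.size();
  for (int i = 0; i < m; ++i) {
    int j = i + static_cast<int>(unif_rand() * (p - i));
    if (j >= p) j = p - 1;
    std::swap(pool[i], pool[j]);
    out[i] = pool[i];
  }
}

class TreeBuilder {
public:
  TreeBuilder(const NumericMatrix& X, const IntegerVector& y, int mtry,
              int min_node, std::vector<double>& imp)
      : X_(X), y_(y), mtry_(mtry), min_node_(min_node), imp_(imp),
        pool_(X.ncol()), chosen_(mtry) {
    for (int f = 0; f < X.ncol(); ++f) pool_[f] = f;
  }

  int build(std::vector<int>& idx) { return grow(idx); }
  std::vector<Node> nodes;

private:
  const NumericMatrix& X_;
  const IntegerVector& y_;
  int mtry_, min_node_;
  std::vector<double>& imp_;
  std::vector<int> pool_, chosen_;

  int grow(std::vector<int>& idx) {
    int n = idx.size();
    int pos = 0;
    for (int i : idx) pos += y_[i];
    int me = nodes.size();
    nodes.push_back(Node{-1, 0.0, -1, -1, static_cast<double>(pos) / n});

    double g_here = gini_counts(pos, n);
    if (n < 2 * min_node_ || n < 2 || pos == 0 || pos == n) return me;

    sample_features(pool_, mtry_, chosen_);
    BestSplit best;
    std::vector<std::pair<double, int>> vals(n);
    for (int f : chosen_) {
      for (int i = 0; i < n; ++i) vals[i] = {X_(idx[i], f), y_[idx[i]]};
      std::sort(vals.begin(), vals.end());
      if (vals.front().first == vals.back().first) continue;
      int lpos = 0;
      for (int k = 0; k < n - 1; ++k) {
        lpos += vals[k].second;
        if (vals[k].first == vals[k + 1].first) continue;
        int nl = k + 1, nr = n - nl;
        if (nl < min_node_ || nr < min_node_) continue;
        double s = nl * gini_counts(lpos, nl) + nr * gini_counts(pos - lpos, nr);
        if (s < best.score) {
          best.score = s;
          best.feat = f;
          best.thr = 0.5 * (vals[k].first + vals[k + 1].first);
        }
      }
    }
    if (best.feat < 0) return me;

    imp_[best.feat] += n * g_here - best.score;

    std::vector<int> lidx, ridx;
    lidx.reserve(n);
    ridx.reserve(n);
    for (int i : idx) {
      if (X_(i, best.feat) <= best.thr) lidx.push_back(i);
      else ridx.push_back(i);
    }
    nodes[me].feat = best.feat;
    nodes[me].thr = best.thr;
    int l = grow(lidx);
    nodes[me].left = l;
    int r = grow(ridx);
    nodes[me].right = r;
    return me;
  }
};

double tree_prob(const NumericMatrix& tree, const NumericMatrix& X, int row) {
  int node = 0;
  while (tree(node, 0) >= 0) {
    int f = static_cast<int>(tree(node, 0));
    node = (X(row, f) <= tree(node, 1)) ? static_cast<int>(tree(node, 2))
                                        : static_cast<int>(tree(node, 3));
  }
  return tree(node, 4);
}

}  // namespace

// [[Rcpp::export(name = ".rf_fit_cpp")]]
List rf_fit_cpp(NumericMatrix X, IntegerVector y, int ntree, int mtry,
                int min_node) {
  int n = X.nrow(), p = X.ncol();
  if (mtry < 1) mtry = 1;
  if (mtry > p) mtry = p;
  std::vector<double> imp(p, 0.0);
  List trees(ntree);
  std::vector<int> boot(n);
  for (int t = 0; t < ntree; ++t) {
    for (int i = 0; i < n; ++i) {
      int j = static_cast<int>(unif_rand() * n);
      if (j >= n) j = n - 1;
      boot[i] = j;
    }
    TreeBuilder tb(X, y, mtry, min_node, imp);
    tb.build(boot);
    NumericMatrix tm(tb.nodes.size(), 5);
    for (size_t k = 0; k < tb.nodes.size(); ++k) {
      tm(k, 0) = tb.nodes[k].feat;
      tm(k, 1) = tb.nodes[k].thr;
      tm(k, 2) = tb.nodes[k].left;
      tm(k, 3) = tb.nodes[k].right;
      tm(k, 4) = tb.nodes[k].prob;
    }
    trees[t] = tm;
  }
  NumericVector importance(p);
  for (int f = 0; f < p; ++f) importance[f] = imp[f] / ntree;
  return List::create(_["trees"] = trees, _["importance"] = importance);
}

// [[Rcpp::export(name = ".rf_predict_cpp")]]
NumericVector rf_predict_cpp(List trees, NumericMatrix X) {
  int n = X.nrow(), ntree = trees.size();
  NumericVector out(n);
  for (int t = 0; t < ntree; ++t) {
    NumericMatrix tm = trees[t];
    for (int i = 0; i < n; ++i) out[i] += tree_prob(tm, X, i);
  }
  for (int i = 0; i < n; ++i) out[i] /= ntree;
  return out;
}
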