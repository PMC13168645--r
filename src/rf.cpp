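// Compact CART-ensemble Random Forest (bootstrap + per-node feature
// subsampling, Gini impurity). Self-contained because no RF package is
// available at run time; deterministic given `seed` via std::mt19937.
#include <Rcpp.h>
#include <random>
#include <algorithm>
#include <vector>
using namespace Rcpp;

namespace {

struct TreeNodes {
  std::vector<int> feature;    // -1 => leaf
  std::vector<double> split;   // threshold; go left if x <= split
  std::vector<int> left, right;
  std::vector<int> pred;       // 1-based class label at leaves, 0 elsewhere
};

int majority_class(const std::vector<int> &cnt) {
  int best = 0;
  for (size_t c = 1; c < cnt.size(); ++c)
    if (cnt[c] > cnt[best]) best = (int)c;  // strict > keeps lowest code on ties
  return best + 1;
}

double gini_from_counts(const std::vector<int> &cnt, int n) {
  if (n == 0) return 0.0;
  double g = 1.0;
  for (size_t c = 0; c < cnt.size(); ++c) {
    double p = (double)cnt[c] / n;
    g -= p * p;
  }
  return g;
}

struct NodeTask {
  int node_id;
  int depth;
  std::vector<int> idx;  // row indices of this node's sample
};

void grow_tree(const NumericMatrix &X, const IntegerVector &y, int n_classes,
               int mtry, int min_node, int max_depth, std::mt19937 &rng,
               TreeNodes &tree) {
  const int n = X.nrow(), p = X.ncol();
  std::uniform_int_distribution<int> row_draw(0, n - 1);

  // bootstrap sample
  std::vector<int> boot(n);
  for (int i = 0; i < n; ++i) boot[i] = row_draw(rng);

  std::vector<NodeTask> stack;
  tree.feature.push_back(-1); tree.split.push_back(0.0);
  tree.left.push_back(-1); tree.right.push_back(-1); tree.pred.push_back(0);
  stack.push_back({0, 0, boot});

  std::vector<int> feat_pool(p);
  for (int j = 0; j < p; ++j) feat_pool[j] = j;

  while (!stack.empty()) {
    NodeTask task = std::move(stack.back());
    stack.pop_back();
    std::vector<int> &idx = task.idx;
    const int nn = (int)idx.size();

    std::vector<int> cnt(n_classes, 0);
    for (int i : idx) cnt[y[i] - 1]++;
    int n_present = 0;
    for (int c = 0; c < n_classes; ++c) if (cnt[c] > 0) n_present++;

    bool make_leaf = (nn < 2 * min_node) || (n_present <= 1) ||
                     (task.depth >= max_depth);

    int best_feat = -1;
    double best_split = 0.0, best_score = gini_from_counts(cnt, nn);
    std::vector<int> order;

    if (!make_leaf) {
      // sample mtry features without replacement (partial Fisher-Yates)
      for (int j = 0; j < mtry; ++j) {
        std::uniform_int_distribution<int> d(j, p - 1);
        std::swap(feat_pool[j], feat_pool[d(rng)]);
      }
      double parent_gini = best_score;
      double best_gain = 1e-12;  // require strictly positive gain
      for (int j = 0; j < mtry; ++j) {
        int f = feat_pool[j];
        order = idx;
        std::sort(order.begin(), order.end(), [&](int a, int b) {
          return X(a, f) < X(b, f);
        });
        std::vector<int> lc(n_classes, 0), rc(cnt);
        for (int k = 0; k + 1 < nn; ++k) {
          int i = order[k];
          lc[y[i] - 1]++; rc[y[i] - 1]--;
          double xk = X(i, f), xk1 = X(order[k + 1], f);
          if (xk == xk1) continue;
          int nl = k + 1, nr = nn - nl;
          double g = (nl * gini_from_counts(lc, nl) +
                      nr * gini_from_counts(rc, nr)) / nn;
          double gain = parent_gini - g;
          if (gain > best_gain) {
            best_gain = gain;
            best_feat = f;
            best_split = xk + (xk1 - xk) / 2.0;
          }
        }
      }
      if (best_feat < 0) make_leaf = true;
    }

    if (make_leaf) {
      tree.pred[task.node_id] = majority_class(cnt);
      tree.feature[task.node_id] = -1;
      continue;
    }

    std::vector<int> lidx, ridx;
    for (int i : idx) {
      if (X(i, best_feat) <= best_split) lidx.push_back(i);
      else ridx.push_back(i);
    }
    // numerical safety: degenerate split => leaf
    if (lidx.empty() || ridx.empty()) {
      tree.pred[task.node_id] = majority_class(cnt);
      tree.feature[task.node_id] = -1;
      continue;
    }

    int lid = (int)tree.feature.size();
    tree.feature.push_back(-1); tree.split.push_back(0.0);
    tree.left.push_back(-1); tree.right.push_back(-1); tree.pred.push_back(0);
    int rid = (int)tree.feature.size();
    tree.feature.push_back(-1); tree.split.push_back(0.0);
    tree.left.push_back(-1); tree.right.push_back(-1); tree.pred.push_back(0);

    tree.feature[task.node_id] = best_feat;
    tree.split[task.node_id] = best_split;
    tree.left[task.node_id] = lid;
    tree.right[task.node_id] = rid;

    stack.push_back({lid, task.depth + 1, std::move(lidx)});
    stack.push_back({rid, task.depth + 1, std::move(ridx)});
  }
}

}  // namespace

// [[Rcpp::export]]
List rf_train_cpp(NumericMatrix X, IntegerVector y, int n_classes,
                  int n_trees, int mtry, int min_node, int max_depth,
                  int seed) {
  std::mt19937 rng((unsigned)seed);
  List forest(n_trees);
  for (int t = 0; t < n_trees; ++t) {
    TreeNodes tr;
    grow_tree(X, y, n_classes, mtry, min_node, max_depth, rng, tr);
    forest[t] = List::create(
        _["feature"] = wrap(tr.feature), _["split"] = wrap(tr.split),
        _["left"] = wrap(tr.left), _["right"] = wrap(tr.right),
        _["pred"] = wrap(tr.pred));
  }
  return forest;
}

// [[Rcpp::export]]
IntegerMatrix rf_votes_cpp(List forest, NumericMatrix X, int n_classes) {
  const int n = X.nrow(), T = forest.size();
  IntegerMatrix votes(n, n_classes);
  for (int t = 0; t < T; ++t) {
    List tr = forest[t];
    IntegerVector feature = tr["feature"];
    NumericVector split = tr["split"];
    IntegerVector left = tr["left"], right = tr["right"], pred = tr["pred"];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (feature[node] >= 0)
        node = (X(i, feature[node]) <= split[node]) ? left[node] : right[node];
      votes(i, pred[node] - 1)++;
    }
  }
  return votes;
}
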