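// Gradient-boosted decision trees for binary logistic classification,
// mirroring the standard XGBoost gbtree configuration: second-order
// Newton boosting, exact greedy split finding, L2 leaf regularisation
// (lambda), shrinkage (eta), early stopping on validation log loss, and
// per-feature gain importance. Deterministic: no row/column subsampling.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

struct Node {
  int feature = -1;       // -1 for leaves
  double threshold = 0.0; // go left when x < threshold
  int left = -1, right = -1;
  double value = 0.0;     // leaf weight (pre-shrinkage)
};

struct Tree {
  std::vector<Node> nodes;
  double predict_row(const double* x, int nrow, int row) const {
    int i = 0;
    while (nodes[i].feature >= 0) {
      double v = x[(size_t)nodes[i].feature * nrow + row];
      i = (v < nodes[i].threshold) ? nodes[i].left : nodes[i].right;
    }
    return nodes[i].value;
  }
};

struct SplitInfo {
  int feature = -1;
  double threshold = 0.0;
  double gain = 0.0;
  bool found = false;
};

static double leaf_objective(double G, double H, double lambda) {
  return -0.5 * G * G / (H + lambda);
}

// exact greedy split search over all features for the rows in idx
static SplitInfo find_split(const double* x, int nrow, int ncol,
                            const std::vector<int>& idx,
                            const std::vector<double>& grad,
                            const std::vector<double>& hess,
                            double lambda, double min_child_weight) {
  double G = 0.0, H = 0.0;
  for (int r : idx) { G += grad[r]; H += hess[r]; }
  double base = leaf_objective(G, H, lambda);
  SplitInfo best;
  std::vector<std::pair<double, int>> vals(idx.size());
  for (int f = 0; f < ncol; ++f) {
    const double* col = x + (size_t)f * nrow;
    for (size_t k = 0; k < idx.size(); ++k)
      vals[k] = {col[idx[k]], idx[k]};
    std::sort(vals.begin(), vals.end());
    double GL = 0.0, HL = 0.0;
    for (size_t k = 0; k + 1 < vals.size(); ++k) {
      GL += grad[vals[k].second];
      HL += hess[vals[k].second];
      if (vals[k].first == vals[k + 1].first) continue; // no cut here
      double GR = G - GL, HR = H - HL;
      if (HL < min_child_weight || HR < min_child_weight) continue;
      double gain = leaf_objective(GL, HL, lambda) +
                    leaf_objective(GR, HR, lambda) - base;
      gain = -gain; // objective decreases; report positive gain
      if (gain > best.gain + 1e-12) {
        best.found = true;
        best.gain = gain;
        best.feature = f;
        best.threshold = 0.5 * (vals[k].first + vals[k + 1].first);
      }
    }
  }
  return best;
}

static int build_node(Tree& tree, const double* x, int nrow, int ncol,
                      const std::vector<int>& idx,
                      const std::vector<double>& grad,
                      const std::vector<double>& hess,
                      int depth, int max_depth, double lambda,
                      double min_child_weight,
                      std::vector<double>& gain_sum,
                      std::vector<int>& gain_cnt) {
  int me = (int)tree.nodes.size();
  tree.nodes.push_back(Node());
  double G = 0.0, H = 0.0;
  for (int r : idx) { G += grad[r]; H += hess[r]; }
  if (depth >= max_depth || idx.size() < 2) {
    tree.nodes[me].value = -G / (H + lambda);
    return me;
  }
  SplitInfo s = find_split(x, nrow, ncol, idx, grad, hess, lambda,
                           min_child_weight);
  if (!s.found) {
    tree.nodes[me].value = -G / (H + lambda);
    return me;
  }
  gain_sum[s.feature] += s.gain;
  gain_cnt[s.feature] += 1;
  std::vector<int> li, ri;
  const double* col = x + (size_t)s.feature * nrow;
  for (int r : idx) (col[r] < s.threshold ? li : ri).push_back(r);
  tree.nodes[me].feature = s.feature;
  tree.nodes[me].threshold = s.threshold;
  int l = build_node(tree, x, nrow, ncol, li, grad, hess, depth + 1,
                     max_depth, lambda, min_child_weight, gain_sum, gain_cnt);
  int r = build_node(tree, x, nrow, ncol, ri, grad, hess, depth + 1,
                     max_depth, lambda, min_child_weight, gain_sum, gain_cnt);
  tree.nodes[me].left = l;
  tree.nodes[me].right = r;
  return me;
}

static double logloss(const std::vector<double>& margin,
                      const NumericVector& y) {
  double s = 0.0;
  for (int i = 0; i < y.size(); ++i) {
    double p = 1.0 / (1.0 + std::exp(-margin[i]));
    p = std::min(std::max(p, 1e-15), 1.0 - 1e-15);
    s += y[i] > 0.5 ? -std::log(p) : -std::log(1.0 - p);
  }
  return s / y.size();
}

static List tree_to_list(const Tree& t) {
  int n = (int)t.nodes.size();
  IntegerVector feature(n), left(n), right(n);
  NumericVector threshold(n), value(n);
  for (int i = 0; i < n; ++i) {
    feature[i] = t.nodes[i].feature;
    threshold[i] = t.nodes[i].threshold;
    left[i] = t.nodes[i].left;
    right[i] = t.nodes[i].right;
    value[i] = t.nodes[i].value;
  }
  return List::create(_["feature"] = feature, _["threshold"] = threshold,
                      _["left"] = left, _["right"] = right,
                      _["value"] = value);
}

// [[Rcpp::export(name = ".cpp_gboost_train")]]
List cpp_gboost_train(NumericMatrix X, NumericVector y,
                      NumericMatrix Xval, NumericVector yval,
                      int max_depth, double eta, int nrounds,
                      int early_stopping_rounds, double lambda,
                      double min_child_weight, double base_score) {
  int n = X.nrow(), p = X.ncol(), nv = Xval.nrow();
  if (y.size() != n) stop("feature matrix / label mismatch");
  if (nv > 0 && yval.size() != nv) stop("validation matrix / label mismatch");
  double base_margin = std::log(base_score / (1.0 - base_score));
  std::vector<double> margin(n, base_margin), vmargin(nv, base_margin);
  std::vector<double> grad(n), hess(n);
  std::vector<double> gain_sum(p, 0.0);
  std::vector<int> gain_cnt(p, 0);
  std::vector<Tree> trees;
  NumericVector eval_log;
  double best_loss = R_PosInf;
  int best_iter = 0, since_best = 0;
  std::vector<int> all_idx(n);
  for (int i = 0; i < n; ++i) all_idx[i] = i;
  for (int round = 0; round < nrounds; ++round) {
    for (int i = 0; i < n; ++i) {
      double pr = 1.0 / (1.0 + std::exp(-margin[i]));
      grad[i] = pr - y[i];
      hess[i] = std::max(pr * (1.0 - pr), 1e-16);
    }
    Tree t;
    build_node(t, X.begin(), n, p, all_idx, grad, hess, 0, max_depth,
               lambda, min_child_weight, gain_sum, gain_cnt);
    trees.push_back(t);
    for (int i = 0; i < n; ++i)
      margin[i] += eta * t.predict_row(X.begin(), n, i);
    if (nv > 0) {
      for (int i = 0; i < nv; ++i)
        vmargin[i] += eta * t.predict_row(Xval.begin(), nv, i);
      double loss = logloss(vmargin, yval);
      eval_log.push_back(loss);
      if (loss < best_loss - 1e-12) {
        best_loss = loss;
        best_iter = round + 1;
        since_best = 0;
      } else if (++since_best >= early_stopping_rounds) {
        break;
      }
    } else {
      eval_log.push_back(logloss(margin, y));
      best_iter = round + 1;
    }
  }
  List tl((int)trees.size());
  for (size_t i = 0; i < trees.size(); ++i) tl[i] = tree_to_list(trees[i]);
  return List::create(
      _["trees"] = tl, _["eval_log"] = eval_log,
      _["best_iteration"] = best_iter, _["best_loss"] = best_loss,
      _["gain_sum"] = NumericVector(gain_sum.begin(), gain_sum.end()),
      _["split_count"] = IntegerVector(gain_cnt.begin(), gain_cnt.end()),
      _["base_margin"] = base_margin, _["eta"] = eta);
}

// [[Rcpp::export(name = ".cpp_gboost_predict")]]
NumericVector cpp_gboost_predict(List trees, NumericMatrix X,
                                 double base_margin, double eta,
                                 int ntrees) {
  int n = X.nrow();
  NumericVector margin(n, base_margin);
  int use = std::min((int)trees.size(), ntrees);
  for (int k = 0; k < use; ++k) {
    List tl = trees[k];
    IntegerVector feature = tl["feature"], left = tl["left"],
                  right = tl["right"];
    NumericVector threshold = tl["threshold"], value = tl["value"];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (feature[node] >= 0) {
        double v = X((size_t)i, feature[node]);
        node = (v < threshold[node]) ? left[node] : right[node];
      }
      margin[i] += eta * value[node];
    }
  }
  for (int i = 0; i < n; ++i)
    margin[i] = 1.0 / (1.0 + std::exp(-margin[i]));
  return margin;
}
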