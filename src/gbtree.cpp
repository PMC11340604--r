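// Gradient-boosted decision trees with logistic loss.
//
// Exact greedy split finding; missing values (NA/NaN) are routed down a
// learned default direction chosen by gain, the same device XGBoost uses,
// so feature vectors with absent resources never need imputation.
// Optional per-feature monotone constraints are enforced by rejecting
// violating splits and propagating leaf-value bounds to children.
// Everything is deterministic: no subsampling, ties resolved by the first
// (lowest-index) feature and the left-most threshold.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
#include <limits>

using namespace Rcpp;

namespace {

struct Node {
  int feature;        // -1 for leaf
  double threshold;
  int default_left;   // 1: missing goes left
  int left, right;    // child node ids, -1 for leaf
  double value;       // leaf value (already scaled by eta)
  Node() : feature(-1), threshold(0.0), default_left(1),
           left(-1), right(-1), value(0.0) {}
};

struct Split {
  bool found;
  int feature;
  double threshold;
  bool default_left;
  double gain;
  double wl, wr;      // clamped child weights (pre-eta)
  Split() : found(false), feature(-1), threshold(0.0),
            default_left(true), gain(0.0), wl(0.0), wr(0.0) {}
};

inline double clampd(double x, double lo, double hi) {
  return std::max(lo, std::min(hi, x));
}

inline double leaf_score(double G, double H, double lambda) {
  return -G / (H + lambda);
}

inline double gain_term(double G, double H, double lambda) {
  return G * G / (H + lambda);
}

// Find the best split for the samples in `idx`.
Split best_split(const NumericMatrix& X,
                 const std::vector<double>& g,
                 const std::vector<double>& h,
                 const std::vector<int>& idx,
                 double lambda, double min_child_weight,
                 const IntegerVector& monotone,
                 double lb, double ub) {
  Split best;
  const int p = X.ncol();
  double G = 0.0, H = 0.0;
  for (int i : idx) { G += g[i]; H += h[i]; }
  const double parent_term = gain_term(G, H, lambda);

  std::vector<std::pair<double, int> > vals;
  vals.reserve(idx.size());

  for (int j = 0; j < p; ++j) {
    vals.clear();
    double Gmiss = 0.0, Hmiss = 0.0;
    for (int i : idx) {
      double x = X(i, j);
      if (std::isnan(x)) { Gmiss += g[i]; Hmiss += h[i]; }
      else vals.push_back(std::make_pair(x, i));
    }
    if (vals.size() < 2) continue;
    std::sort(vals.begin(), vals.end());
    const bool any_missing = (Hmiss > 0.0) || (Gmiss != 0.0);
    const int mono = (monotone.size() == p) ? monotone[j] : 0;

    // dir = 0: missing right; dir = 1: missing left
    for (int dir = 0; dir < (any_missing ? 2 : 1); ++dir) {
      double GL = dir ? Gmiss : 0.0;
      double HL = dir ? Hmiss : 0.0;
      for (size_t k = 0; k + 1 < vals.size(); ++k) {
        GL += g[vals[k].second];
        HL += h[vals[k].second];
        if (vals[k].first == vals[k + 1].first) continue;
        double GR = G - GL, HR = H - HL;
        if (HL < min_child_weight || HR < min_child_weight) continue;
        double wl = clampd(leaf_score(GL, HL, lambda), lb, ub);
        double wr = clampd(leaf_score(GR, HR, lambda), lb, ub);
        if (mono > 0 && wl > wr) continue;
        if (mono < 0 && wl < wr) continue;
        double gain = 0.5 * (gain_term(GL, HL, lambda) +
                             gain_term(GR, HR, lambda) - parent_term);
        if (gain > best.gain + 1e-12) {
          best.found = true;
          best.feature = j;
          best.threshold = 0.5 * (vals[k].first + vals[k + 1].first);
          best.default_left = (dir == 1);
          best.gain = gain;
          best.wl = wl;
          best.wr = wr;
        }
      }
    }
  }
  return best;
}

struct WorkItem {
  int node_id;
  std::vector<int> idx;
  int depth;
  double lb, ub;
};

}  // namespace

// [[Rcpp::export]]
List gbt_fit_cpp(NumericMatrix X, NumericVector y,
                 int nrounds, double eta, int max_depth,
                 double lambda, double min_child_weight,
                 IntegerVector monotone, double base_margin) {
  const int n = X.nrow();
  const double inf = std::numeric_limits<double>::infinity();
  std::vector<double> f(n, base_margin), g(n), h(n);
  List forest(nrounds);

  for (int round = 0; round < nrounds; ++round) {
    for (int i = 0; i < n; ++i) {
      double pr = 1.0 / (1.0 + std::exp(-f[i]));
      g[i] = pr - y[i];
      h[i] = std::max(pr * (1.0 - pr), 1e-16);
    }

    std::vector<Node> nodes;
    std::vector<std::vector<int> > leaf_members;
    std::vector<WorkItem> stack;

    WorkItem root;
    root.node_id = 0;
    root.idx.resize(n);
    for (int i = 0; i < n; ++i) root.idx[i] = i;
    root.depth = 0;
    root.lb = -inf;
    root.ub = inf;
    nodes.push_back(Node());
    stack.push_back(root);

    while (!stack.empty()) {
      WorkItem w = stack.back();
      stack.pop_back();
      Split s;
      if (w.depth < max_depth && (int)w.idx.size() >= 2) {
        s = best_split(X, g, h, w.idx, lambda, min_child_weight,
                       monotone, w.lb, w.ub);
      }
      if (!s.found) {
        double G = 0.0, H = 0.0;
        for (int i : w.idx) { G += g[i]; H += h[i]; }
        double val = clampd(leaf_score(G, H, lambda), w.lb, w.ub);
        nodes[w.node_id].feature = -1;
        nodes[w.node_id].value = eta * val;
        for (int i : w.idx) f[i] += eta * val;
        continue;
      }
      int lid = (int)nodes.size(); nodes.push_back(Node());
      int rid = (int)nodes.size(); nodes.push_back(Node());
      nodes[w.node_id].feature = s.feature;
      nodes[w.node_id].threshold = s.threshold;
      nodes[w.node_id].default_left = s.default_left ? 1 : 0;
      nodes[w.node_id].left = lid;
      nodes[w.node_id].right = rid;

      WorkItem wl, wr;
      wl.node_id = lid; wr.node_id = rid;
      wl.depth = wr.depth = w.depth + 1;
      wl.lb = w.lb; wl.ub = w.ub;
      wr.lb = w.lb; wr.ub = w.ub;
      const int mono = (monotone.size() == X.ncol()) ? monotone[s.feature] : 0;
      if (mono != 0) {
        double mid = 0.5 * (s.wl + s.wr);
        if (mono > 0) { wl.ub = std::min(wl.ub, mid); wr.lb = std::max(wr.lb, mid); }
        else          { wl.lb = std::max(wl.lb, mid); wr.ub = std::min(wr.ub, mid); }
      }
      for (int i : w.idx) {
        double x = X(i, s.feature);
        bool go_left = std::isnan(x) ? s.default_left : (x < s.threshold);
        if (go_left) wl.idx.push_back(i); else wr.idx.push_back(i);
      }
      stack.push_back(wr);
      stack.push_back(wl);
    }

    const int m = (int)nodes.size();
    IntegerVector feature(m), default_left(m), left(m), right(m);
    NumericVector threshold(m), value(m);
    for (int k = 0; k < m; ++k) {
      feature[k] = nodes[k].feature;
      threshold[k] = nodes[k].threshold;
      default_left[k] = nodes[k].default_left;
      left[k] = nodes[k].left;
      right[k] = nodes[k].right;
      value[k] = nodes[k].value;
    }
    forest[round] = List::create(
      Named("feature") = feature, Named("threshold") = threshold,
      Named("default_left") = default_left, Named("left") = left,
      Named("right") = right, Named("value") = value);
  }
  return forest;
}

namespace {

// Internal flat-forest fit over a row subset, used by the cross-validated
// feature-selection path to avoid R object churn across thousands of fits.
struct FlatTree {
  std::vector<Node> nodes;
};

std::vector<FlatTree> fit_forest(const NumericMatrix& X,
                                 const NumericVector& y,
                                 const std::vector<int>& rows,
                                 int nrounds, double eta, int max_depth,
                                 double lambda, double min_child_weight) {
  const int n = X.nrow();
  const double inf = std::numeric_limits<double>::infinity();
  IntegerVector mono(0);
  std::vector<double> f(n, 0.0), g(n), h(n);
  std::vector<FlatTree> forest;
  forest.reserve(nrounds);

  for (int round = 0; round < nrounds; ++round) {
    for (int i : rows) {
      double pr = 1.0 / (1.0 + std::exp(-f[i]));
      g[i] = pr - y[i];
      h[i] = std::max(pr * (1.0 - pr), 1e-16);
    }
    FlatTree tree;
    std::vector<WorkItem> stack;
    WorkItem root;
    root.node_id = 0;
    root.idx = rows;
    root.depth = 0;
    root.lb = -inf;
    root.ub = inf;
    tree.nodes.push_back(Node());
    stack.push_back(root);
    while (!stack.empty()) {
      WorkItem w = stack.back();
      stack.pop_back();
      Split s;
      if (w.depth < max_depth && (int)w.idx.size() >= 2) {
        s = best_split(X, g, h, w.idx, lambda, min_child_weight,
                       mono, -inf, inf);
      }
      if (!s.found) {
        double G = 0.0, H = 0.0;
        for (int i : w.idx) { G += g[i]; H += h[i]; }
        double val = leaf_score(G, H, lambda);
        tree.nodes[w.node_id].feature = -1;
        tree.nodes[w.node_id].value = eta * val;
        for (int i : w.idx) f[i] += eta * val;
        continue;
      }
      int lid = (int)tree.nodes.size(); tree.nodes.push_back(Node());
      int rid = (int)tree.nodes.size(); tree.nodes.push_back(Node());
      tree.nodes[w.node_id].feature = s.feature;
      tree.nodes[w.node_id].threshold = s.threshold;
      tree.nodes[w.node_id].default_left = s.default_left ? 1 : 0;
      tree.nodes[w.node_id].left = lid;
      tree.nodes[w.node_id].right = rid;
      WorkItem wl, wr;
      wl.node_id = lid; wr.node_id = rid;
      wl.depth = wr.depth = w.depth + 1;
      wl.lb = wr.lb = -inf; wl.ub = wr.ub = inf;
      for (int i : w.idx) {
        double x = X(i, s.feature);
        bool go_left = std::isnan(x) ? s.default_left : (x < s.threshold);
        if (go_left) wl.idx.push_back(i); else wr.idx.push_back(i);
      }
      stack.push_back(wr);
      stack.push_back(wl);
    }
    forest.push_back(tree);
  }
  return forest;
}

double predict_one(const std::vector<FlatTree>& forest,
                   const NumericMatrix& X, int i) {
  double margin = 0.0;
  for (const FlatTree& t : forest) {
    int k = 0;
    while (t.nodes[k].feature >= 0) {
      double x = X(i, t.nodes[k].feature);
      bool go_left = std::isnan(x) ? (t.nodes[k].default_left == 1)
                                   : (x < t.nodes[k].threshold);
      k = go_left ? t.nodes[k].left : t.nodes[k].right;
    }
    margin += t.nodes[k].value;
  }
  return 1.0 / (1.0 + std::exp(-margin));
}

double mcc_at_half(const std::vector<double>& truth,
                   const std::vector<double>& prob) {
  double tp = 0, fp = 0, tn = 0, fn = 0;
  for (size_t i = 0; i < truth.size(); ++i) {
    bool pos = prob[i] >= 0.5;
    if (pos && truth[i] >= 0.5) ++tp;
    else if (pos) ++fp;
    else if (truth[i] >= 0.5) ++fn;
    else ++tn;
  }
  double den = std::sqrt(tp + fp) * std::sqrt(tp + fn) *
               std::sqrt(tn + fp) * std::sqrt(tn + fn);
  if (den == 0.0) return 0.0;
  return (tp * tn - fp * fn) / den;
}

}  // namespace

// Mean cross-validated MCC for each candidate feature-index set.
// `fold` holds fold ids 1..k; `cand_sets` holds 1-based column indices.
// [[Rcpp::export]]
NumericVector gbt_cv_mcc_cpp(NumericMatrix X, NumericVector y,
                             IntegerVector fold, int k, List cand_sets,
                             int nrounds, double eta, int max_depth,
                             double lambda, double min_child_weight) {
  const int n = X.nrow();
  NumericVector out(cand_sets.size());
  for (int c = 0; c < cand_sets.size(); ++c) {
    IntegerVector cols = cand_sets[c];
    NumericMatrix sub(n, cols.size());
    for (int j = 0; j < cols.size(); ++j) {
      for (int i = 0; i < n; ++i) sub(i, j) = X(i, cols[j] - 1);
    }
    double acc = 0.0;
    for (int f = 1; f <= k; ++f) {
      std::vector<int> train;
      std::vector<int> test;
      for (int i = 0; i < n; ++i) {
        if (fold[i] == f) test.push_back(i); else train.push_back(i);
      }
      std::vector<FlatTree> forest = fit_forest(
          sub, y, train, nrounds, eta, max_depth, lambda,
          min_child_weight);
      std::vector<double> truth, prob;
      truth.reserve(test.size());
      prob.reserve(test.size());
      for (int i : test) {
        truth.push_back(y[i]);
        prob.push_back(predict_one(forest, sub, i));
      }
      acc += mcc_at_half(truth, prob);
    }
    out[c] = acc / k;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector gbt_predict_cpp(List forest, NumericMatrix X, double base_margin) {
  const int n = X.nrow();
  NumericVector out(n, base_margin);
  for (int t = 0; t < forest.size(); ++t) {
    List tree = forest[t];
    IntegerVector feature = tree["feature"];
    NumericVector threshold = tree["threshold"];
    IntegerVector default_left = tree["default_left"];
    IntegerVector left = tree["left"];
    IntegerVector right = tree["right"];
    NumericVector value = tree["value"];
    for (int i = 0; i < n; ++i) {
      int k = 0;
      while (feature[k] >= 0) {
        double x = X(i, feature[k]);
        bool go_left = std::isnan(x) ? (default_left[k] == 1)
                                     : (x < threshold[k]);
        k = go_left ? left[k] : right[k];
      }
      out[i] += value[k];
    }
  }
  return out;
}
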