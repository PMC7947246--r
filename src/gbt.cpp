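// Gradient-boosted regression trees for binary logistic loss, with exact
// greedy split finding over presorted feature columns, plus TreeSHAP
// (path-dependent Shapley attribution) for the fitted ensemble.
//
// Deliberately deterministic: no subsampling, no RNG; identical data and
// parameters give an identical ensemble.
#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

struct Tree {
  std::vector<int> feature;      // -1 for leaf
  std::vector<double> threshold; // go left if x < threshold
  std::vector<int> left, right;
  std::vector<double> value;     // leaf value (already scaled by eta)
  std::vector<double> cover;     // sum of hessian at node
};

struct Builder {
  const NumericMatrix& X;
  const std::vector<std::vector<int> >& order; // per-feature ascending index
  const std::vector<double>& g;
  const std::vector<double>& h;
  double lambda, eta, min_child_weight;
  int max_depth;
  std::vector<char> in_node;
  Tree tree;

  Builder(const NumericMatrix& X_, const std::vector<std::vector<int> >& ord,
          const std::vector<double>& g_, const std::vector<double>& h_,
          double lambda_, double eta_, double mcw, int md)
    : X(X_), order(ord), g(g_), h(h_), lambda(lambda_), eta(eta_),
      min_child_weight(mcw), max_depth(md), in_node(X_.nrow(), 0) {}

  int build(std::vector<int>& idx, int depth) {
    double G = 0, H = 0;
    for (int i : idx) { G += g[i]; H += h[i]; }
    int node = (int)tree.feature.size();
    tree.feature.push_back(-1);
    tree.threshold.push_back(0.0);
    tree.left.push_back(-1);
    tree.right.push_back(-1);
    tree.value.push_back(-eta * G / (H + lambda));
    tree.cover.push_back(H);
    if (depth >= max_depth || (int)idx.size() < 2) return node;

    double best_gain = 1e-12;
    int best_f = -1;
    double best_thr = 0.0;
    double parent_score = G * G / (H + lambda);
    for (int i : idx) in_node[i] = 1;
    int p = X.ncol();
    for (int f = 0; f < p; ++f) {
      const std::vector<int>& ord = order[f];
      double gl = 0, hl = 0;
      double prev_val = 0; bool have_prev = false;
      for (size_t k = 0; k < ord.size(); ++k) {
        int i = ord[k];
        if (!in_node[i]) continue;
        double v = X(i, f);
        if (have_prev && v > prev_val && hl >= min_child_weight &&
            (H - hl) >= min_child_weight) {
          double gain = gl * gl / (hl + lambda) +
                        (G - gl) * (G - gl) / (H - hl + lambda) - parent_score;
          if (gain > best_gain) {
            best_gain = gain; best_f = f; best_thr = (prev_val + v) / 2.0;
          }
        }
        gl += g[i]; hl += h[i];
        prev_val = v; have_prev = true;
      }
    }
    for (int i : idx) in_node[i] = 0;

    if (best_f < 0) return node;
    std::vector<int> li, ri;
    for (int i : idx) {
      if (X(i, best_f) < best_thr) li.push_back(i); else ri.push_back(i);
    }
    if (li.empty() || ri.empty()) return node;
    tree.feature[node] = best_f;
    tree.threshold[node] = best_thr;
    int l = build(li, depth + 1);
    int r = build(ri, depth + 1);
    tree.left[node] = l;
    tree.right[node] = r;
    return node;
  }
};

static double tree_predict_row(const Tree& t, const NumericMatrix& X, int i) {
  int node = 0;
  while (t.feature[node] >= 0) {
    node = (X(i, t.feature[node]) < t.threshold[node]) ? t.left[node]
                                                       : t.right[node];
  }
  return t.value[node];
}

static List tree_to_list(const Tree& t) {
  return List::create(_["feature"] = wrap(t.feature),
                      _["threshold"] = wrap(t.threshold),
                      _["left"] = wrap(t.left), _["right"] = wrap(t.right),
                      _["value"] = wrap(t.value), _["cover"] = wrap(t.cover));
}

static Tree tree_from_list(const List& l) {
  Tree t;
  t.feature = as<std::vector<int> >(l["feature"]);
  t.threshold = as<std::vector<double> >(l["threshold"]);
  t.left = as<std::vector<int> >(l["left"]);
  t.right = as<std::vector<int> >(l["right"]);
  t.value = as<std::vector<double> >(l["value"]);
  t.cover = as<std::vector<double> >(l["cover"]);
  return t;
}

static double auc_rank(const std::vector<double>& s, const IntegerVector& y) {
  int n = s.size();
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return s[a] < s[b]; });
  // midranks
  std::vector<double> rank(n);
  int i = 0;
  while (i < n) {
    int j = i;
    while (j + 1 < n && s[ord[j + 1]] == s[ord[i]]) ++j;
    double mr = (i + j) / 2.0 + 1.0;
    for (int k = i; k <= j; ++k) rank[ord[k]] = mr;
    i = j + 1;
  }
  double n1 = 0, sum1 = 0;
  for (int k = 0; k < n; ++k) if (y[k] == 1) { n1 += 1; sum1 += rank[k]; }
  double n0 = n - n1;
  if (n1 == 0 || n0 == 0) return NA_REAL;
  return (sum1 - n1 * (n1 + 1) / 2.0) / (n1 * n0);
}

// [[Rcpp::export]]
List gbt_train_cpp(NumericMatrix X, IntegerVector y, int nrounds,
                   int max_depth, double eta, double lambda,
                   double min_child_weight, double base_margin,
                   Nullable<NumericMatrix> Xval_ = R_NilValue,
                   Nullable<IntegerVector> yval_ = R_NilValue,
                   int early_stopping_rounds = 0) {
  int n = X.nrow(), p = X.ncol();
  std::vector<std::vector<int> > order(p);
  for (int f = 0; f < p; ++f) {
    order[f].resize(n);
    for (int i = 0; i < n; ++i) order[f][i] = i;
    NumericMatrix::Column col = X(_, f);
    std::stable_sort(order[f].begin(), order[f].end(),
                     [&](int a, int b) { return col[a] < col[b]; });
  }
  std::vector<double> margin(n, base_margin), g(n), h(n);
  bool has_val = Xval_.isNotNull() && yval_.isNotNull() &&
                 early_stopping_rounds > 0;
  NumericMatrix Xval;
  IntegerVector yval;
  std::vector<double> vmargin;
  if (has_val) {
    Xval = NumericMatrix(Xval_);
    yval = IntegerVector(yval_);
    vmargin.assign(Xval.nrow(), base_margin);
  }
  List trees;
  double best_auc = -1; int best_iter = -1, since_best = 0;
  for (int round = 0; round < nrounds; ++round) {
    for (int i = 0; i < n; ++i) {
      double pr = 1.0 / (1.0 + std::exp(-margin[i]));
      g[i] = pr - y[i];
      h[i] = std::max(pr * (1.0 - pr), 1e-16);
    }
    Builder b(X, order, g, h, lambda, eta, min_child_weight, max_depth);
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = i;
    b.build(idx, 0);
    for (int i = 0; i < n; ++i) margin[i] += tree_predict_row(b.tree, X, i);
    trees.push_back(tree_to_list(b.tree));
    if (has_val) {
      for (int i = 0; i < Xval.nrow(); ++i)
        vmargin[i] += tree_predict_row(b.tree, Xval, i);
      double a = auc_rank(vmargin, yval);
      if (a > best_auc + 1e-12) { best_auc = a; best_iter = round; since_best = 0; }
      else if (++since_best >= early_stopping_rounds) break;
    }
  }
  int keep = has_val && best_iter >= 0 ? best_iter + 1 : trees.size();
  List kept(keep);
  for (int i = 0; i < keep; ++i) kept[i] = trees[i];
  return List::create(_["trees"] = kept, _["base_margin"] = base_margin,
                      _["best_val_auc"] = has_val ? best_auc : NA_REAL);
}

// [[Rcpp::export]]
NumericVector gbt_predict_cpp(List trees, NumericMatrix X, double base_margin) {
  int n = X.nrow();
  NumericVector out(n, base_margin);
  for (int t = 0; t < trees.size(); ++t) {
    Tree tr = tree_from_list(trees[t]);
    for (int i = 0; i < n; ++i) out[i] += tree_predict_row(tr, X, i);
  }
  return out;
}

// ---- TreeSHAP (Lundberg & Lee path-dependent algorithm) ------------------

struct PathElem {
  int feature;
  double zero_frac, one_frac, pweight;
};

static void extend_path(std::vector<PathElem>& path, double pz, double po,
                        int pi) {
  int l = (int)path.size();
  PathElem e; e.feature = pi; e.zero_frac = pz; e.one_frac = po;
  e.pweight = (l == 0) ? 1.0 : 0.0;
  path.push_back(e);
  for (int i = l - 1; i >= 0; --i) {
    path[i + 1].pweight += po * path[i].pweight * (i + 1) / (double)(l + 1);
    path[i].pweight = pz * path[i].pweight * (l - i) / (double)(l + 1);
  }
}

static void unwind_path(std::vector<PathElem>& path, int i) {
  int l = (int)path.size() - 1;
  double n = path[l].pweight;
  double po = path[i].one_frac, pz = path[i].zero_frac;
  for (int j = l - 1; j >= 0; --j) {
    if (po != 0) {
      double t = path[j].pweight;
      path[j].pweight = n * (l + 1) / ((j + 1) * po);
      n = t - path[j].pweight * pz * (l - j) / (double)(l + 1);
    } else {
      path[j].pweight = path[j].pweight * (l + 1) / ((double)(l - j) * pz);
    }
  }
  for (int j = i; j < l; ++j) {
    path[j].feature = path[j + 1].feature;
    path[j].zero_frac = path[j + 1].zero_frac;
    path[j].one_frac = path[j + 1].one_frac;
  }
  path.pop_back();
}

static double unwound_sum(const std::vector<PathElem>& path, int i) {
  int l = (int)path.size() - 1;
  double po = path[i].one_frac, pz = path[i].zero_frac;
  double total = 0, n = path[l].pweight;
  if (po != 0) {
    for (int j = l - 1; j >= 0; --j) {
      double tmp = n / ((j + 1) * po);
      total += tmp;
      n = path[j].pweight - tmp * pz * (l - j);
    }
  } else {
    for (int j = l - 1; j >= 0; --j) {
      total += path[j].pweight / ((l - j) * pz);
    }
  }
  return total * (l + 1);
}

static void tree_shap_recurse(const Tree& t, const NumericMatrix& X, int row,
                              NumericVector phi, int node,
                              std::vector<PathElem> path, double pz, double po,
                              int pi) {
  extend_path(path, pz, po, pi);
  if (t.feature[node] < 0) {
    for (int i = 1; i < (int)path.size(); ++i) {
      double w = unwound_sum(path, i);
      phi[path[i].feature] +=
          w * (path[i].one_frac - path[i].zero_frac) * t.value[node];
    }
    return;
  }
  int f = t.feature[node];
  int hot = (X(row, f) < t.threshold[node]) ? t.left[node] : t.right[node];
  int cold = (hot == t.left[node]) ? t.right[node] : t.left[node];
  double iz = 1.0, io = 1.0;
  int k = -1;
  for (int i = 1; i < (int)path.size(); ++i) {
    if (path[i].feature == f) { k = i; break; }
  }
  if (k >= 0) {
    iz = path[k].zero_frac; io = path[k].one_frac;
    unwind_path(path, k);
  }
  double rj = t.cover[node];
  tree_shap_recurse(t, X, row, phi, hot, path,
                    iz * t.cover[hot] / rj, io, f);
  tree_shap_recurse(t, X, row, phi, cold, path,
                    iz * t.cover[cold] / rj, 0.0, f);
}

// [[Rcpp::export]]
NumericMatrix gbt_shap_cpp(List trees, NumericMatrix X) {
  int n = X.nrow(), p = X.ncol();
  NumericMatrix phi(n, p);
  for (int t = 0; t < trees.size(); ++t) {
    Tree tr = tree_from_list(trees[t]);
    for (int i = 0; i < n; ++i) {
      NumericVector row_phi = phi(i, _);
      std::vector<PathElem> path;
      tree_shap_recurse(tr, X, i, row_phi, 0, path, 1.0, 1.0, -1);
      phi(i, _) = row_phi;
    }
  }
  return phi;
}

// expected value of the ensemble (cover-weighted leaf mean), the SHAP base
// [[Rcpp::export]]
double gbt_expected_value_cpp(List trees) {
  double total = 0;
  for (int t = 0; t < trees.size(); ++t) {
    Tree tr = tree_from_list(trees[t]);
    std::vector<double> node_mean(tr.feature.size(), 0.0);
    for (int node = (int)tr.feature.size() - 1; node >= 0; --node) {
      if (tr.feature[node] < 0) node_mean[node] = tr.value[node];
      else {
        int l = tr.left[node], r = tr.right[node];
        node_mean[node] = (tr.cover[l] * node_mean[l] +
                           tr.cover[r] * node_mean[r]) / tr.cover[node];
      }
    }
    total += node_mean[0];
  }
  return total;
}
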