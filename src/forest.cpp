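// Weighted probability random forest: CART regression trees on a 0/1
// response, weighted bootstrap per tree, mtry feature subsampling.
// Self-contained because no forest package is available in the target
// library; parameters are fixed by the caller and documented there.

#include <Rcpp.h>
#include <random>
#include <vector>
#include <algorithm>

using namespace Rcpp;

struct Tree {
  // node arrays; leaf iff feature == -1
  std::vector<int> feature;
  std::vector<double> threshold;
  std::vector<int> left, right;
  std::vector<double> value;
};

static const int MAX_DEPTH = 30;

static int build_node(const NumericMatrix &X, const NumericVector &y,
                      const std::vector<int> &samples, int depth, int mtry,
                      int min_node, std::mt19937 &rng, Tree &tree) {
  const int node = static_cast<int>(tree.feature.size());
  tree.feature.push_back(-1);
  tree.threshold.push_back(0.0);
  tree.left.push_back(-1);
  tree.right.push_back(-1);

  const int n = static_cast<int>(samples.size());
  double sum = 0.0;
  for (int i : samples) sum += y[i];
  const double mean = sum / n;
  tree.value.push_back(mean);

  if (n < 2 * min_node || depth >= MAX_DEPTH) return node;
  bool pure = true;
  for (int i : samples) {
    if (y[i] != y[samples[0]]) { pure = false; break; }
  }
  if (pure) return node;

  const int p = X.ncol();
  std::vector<int> feats(p);
  for (int j = 0; j < p; ++j) feats[j] = j;
  std::shuffle(feats.begin(), feats.end(), rng);

  int best_feat = -1;
  double best_gain = -1.0, best_thr = 0.0;
  std::vector<int> ord(samples);
  std::vector<double> xv(n);

  for (int t = 0; t < std::min(mtry, p); ++t) {
    const int j = feats[t];
    for (int k = 0; k < n; ++k) xv[k] = X(samples[k], j);
    std::vector<int> idx(n);
    for (int k = 0; k < n; ++k) idx[k] = k;
    std::sort(idx.begin(), idx.end(),
              [&xv](int a, int b) { return xv[a] < xv[b]; });
    double sumL = 0.0;
    for (int k = 0; k < n - 1; ++k) {
      sumL += y[samples[idx[k]]];
      const int nL = k + 1, nR = n - nL;
      if (nL < min_node) continue;
      if (nR < min_node) break;
      if (xv[idx[k]] == xv[idx[k + 1]]) continue;  // no threshold between ties
      const double sumR = sum - sumL;
      const double gain = sumL * sumL / nL + sumR * sumR / nR;
      if (gain > best_gain) {
        best_gain = gain;
        best_feat = j;
        best_thr = 0.5 * (xv[idx[k]] + xv[idx[k + 1]]);
      }
    }
  }
  if (best_feat < 0) return node;
  // require an actual improvement over the parent node
  if (best_gain <= sum * sum / n + 1e-12) return node;

  std::vector<int> ls, rs;
  ls.reserve(n); rs.reserve(n);
  for (int i : samples) {
    if (X(i, best_feat) <= best_thr) ls.push_back(i); else rs.push_back(i);
  }
  if (ls.empty() || rs.empty()) return node;

  tree.feature[node] = best_feat;
  tree.threshold[node] = best_thr;
  const int l = build_node(X, y, ls, depth + 1, mtry, min_node, rng, tree);
  tree.left[node] = l;
  const int r = build_node(X, y, rs, depth + 1, mtry, min_node, rng, tree);
  tree.right[node] = r;
  return node;
}

static double predict_one(const Tree &tree, const NumericMatrix &X, int row) {
  int node = 0;
  while (tree.feature[node] >= 0) {
    node = (X(row, tree.feature[node]) <= tree.threshold[node])
             ? tree.left[node] : tree.right[node];
  }
  return tree.value[node];
}

// [[Rcpp::export(name = ".rf_grow")]]
List rf_grow(NumericMatrix X, NumericVector y, NumericVector w,
             int n_trees, int mtry, int min_node, int seed) {
  const int n = X.nrow();
  std::mt19937 rng(static_cast<unsigned>(seed));
  std::discrete_distribution<int> boot(w.begin(), w.end());
  List forest(n_trees);
  for (int t = 0; t < n_trees; ++t) {
    std::vector<int> samples(n);
    for (int k = 0; k < n; ++k) samples[k] = boot(rng);
    Tree tree;
    build_node(X, y, samples, 0, mtry, min_node, rng, tree);
    forest[t] = List::create(
        _["feature"] = IntegerVector(tree.feature.begin(), tree.feature.end()),
        _["threshold"] = NumericVector(tree.threshold.begin(),
                                       tree.threshold.end()),
        _["left"] = IntegerVector(tree.left.begin(), tree.left.end()),
        _["right"] = IntegerVector(tree.right.begin(), tree.right.end()),
        _["value"] = NumericVector(tree.value.begin(), tree.value.end()));
  }
  return forest;
}

// [[Rcpp::export(name = ".rf_predict")]]
NumericVector rf_predict(List forest, NumericMatrix X) {
  const int n = X.nrow();
  const int n_trees = forest.size();
  NumericVector out(n);
  for (int t = 0; t < n_trees; ++t) {
    List tl = forest[t];
    Tree tree;
    IntegerVector f = tl["feature"], l = tl["left"], r = tl["right"];
    NumericVector th = tl["threshold"], v = tl["value"];
    tree.feature.assign(f.begin(), f.end());
    tree.threshold.assign(th.begin(), th.end());
    tree.left.assign(l.begin(), l.end());
    tree.right.assign(r.begin(), r.end());
    tree.value.assign(v.begin(), v.end());
    for (int i = 0; i < n; ++i) out[i] += predict_one(tree, X, i);
  }
  return out / static_cast<double>(n_trees);
}
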