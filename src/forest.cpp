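// A compact probability random forest for binary outcomes.
//
// CART-style trees on bootstrap resamples, Gini splitting over mtry
// randomly drawn features, terminal-node class fractions averaged over
// trees as the predicted relapse probability, and out-of-bag (OOB)
// permutation importance (mean decrease in OOB accuracy). Deterministic
// given the seed. No pre-installed R forest implementation exists in the
// target environment, so the primitive is built here.

#define ARMA_NO_DEBUG
#include <RcppArmadillo.h>
#include <algorithm>
#include <vector>

#include "rng.h"
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct Forest {
  std::vector<int> feat;       // split feature per node, -1 for leaf
  std::vector<double> thr;     // split threshold (x <= thr goes left)
  std::vector<int> left, right;  // child node ids (absolute), -1 for leaf
  std::vector<double> prob;    // in-bag class-1 fraction at the node
  std::vector<int> offset;     // node id range per tree: [offset[t], offset[t+1])
};

// Grow one tree over in-bag indices idx[lo, hi); returns node id.
int grow(const arma::mat &X, const arma::ivec &y, std::vector<int> &idx,
         int lo, int hi, int mtry, int min_node, rrf::Rng &rng,
         std::vector<int> &featbuf, Forest &f, std::vector<int> &used) {
  const int n = hi - lo;
  int pos = 0;
  for (int i = lo; i < hi; ++i) pos += y[idx[i]];
  const int id = (int)f.feat.size();
  f.feat.push_back(-1);
  f.thr.push_back(0.0);
  f.left.push_back(-1);
  f.right.push_back(-1);
  f.prob.push_back((double)pos / n);

  if (n <= min_node || n < 2 || pos == 0 || pos == n) return id;

  // candidate features: partial Fisher-Yates over featbuf
  const int p = (int)featbuf.size();
  double best_score = ((double)pos * pos + (double)(n - pos) * (n - pos)) / n;
  best_score += 1e-12;
  int best_feat = -1;
  double best_thr = 0.0;

  static thread_local std::vector<std::pair<double, int>> vals;
  vals.resize(n);
  for (int k = 0; k < mtry && k < p; ++k) {
    int r = k + rng.unif_int(p - k);
    std::swap(featbuf[k], featbuf[r]);
    const int j = featbuf[k];
    for (int i = 0; i < n; ++i) {
      const int s = idx[lo + i];
      vals[i] = {X(s, j), y[s]};
    }
    std::sort(vals.begin(), vals.end());
    if (vals.front().first == vals.back().first) continue;
    int pl = 0;
    for (int i = 0; i < n - 1; ++i) {
      pl += vals[i].second;
      if (vals[i].first == vals[i + 1].first) continue;
      const int nl = i + 1, nr = n - nl;
      const int pr = pos - pl;
      double score = ((double)pl * pl + (double)(nl - pl) * (nl - pl)) / nl +
                     ((double)pr * pr + (double)(nr - pr) * (nr - pr)) / nr;
      if (score > best_score) {
        best_score = score;
        best_feat = j;
        best_thr = vals[i].first + 0.5 * (vals[i + 1].first - vals[i].first);
      }
    }
  }
  if (best_feat < 0) return id;

  // partition idx in place
  int mid = lo;
  for (int i = lo; i < hi; ++i)
    if (X(idx[i], best_feat) <= best_thr) std::swap(idx[i], idx[mid++]);

  f.feat[id] = best_feat;
  f.thr[id] = best_thr;
  used.push_back(best_feat);
  int l = grow(X, y, idx, lo, mid, mtry, min_node, rng, featbuf, f, used);
  int r = grow(X, y, idx, mid, hi, mtry, min_node, rng, featbuf, f, used);
  f.left[id] = l;
  f.right[id] = r;
  return id;
}

double tree_prob(const Forest &f, int node, const arma::mat &X, int row,
                 int perm_feat = -1, double perm_val = 0.0) {
  while (f.feat[node] >= 0) {
    double v = (f.feat[node] == perm_feat) ? perm_val : X(row, f.feat[node]);
    node = (v <= f.thr[node]) ? f.left[node] : f.right[node];
  }
  return f.prob[node];
}

}  // namespace

// [[Rcpp::export]]
List cpp_rf_fit(const arma::mat &X, const arma::ivec &y, int n_trees,
                int mtry, int min_node, double seed,
                bool compute_importance = true) {
  const int n = (int)X.n_rows, p = (int)X.n_cols;
  rrf::Rng seeder((uint64_t)seed);
  uint64_t sm = seeder.next();

  Forest f;
  f.offset.push_back(0);
  arma::vec oob_sum(n, arma::fill::zeros);
  arma::ivec oob_cnt(n, arma::fill::zeros);
  arma::vec imp(p, arma::fill::zeros);

  std::vector<int> idx(n), inbag(n), featbuf(p), used, oob;
  std::vector<double> permv;
  for (int t = 0; t < n_trees; ++t) {
    rrf::Rng rng(rrf::splitmix64(sm));
    std::fill(inbag.begin(), inbag.end(), 0);
    for (int i = 0; i < n; ++i) {
      int s = rng.unif_int(n);
      idx[i] = s;
      inbag[s]++;
    }
    for (int j = 0; j < p; ++j) featbuf[j] = j;
    used.clear();
    grow(X, y, idx, 0, n, mtry, min_node, rng, featbuf, f, used);
    f.offset.push_back((int)f.feat.size());
    const int root = f.offset[t];

    oob.clear();
    for (int i = 0; i < n; ++i)
      if (!inbag[i]) oob.push_back(i);
    if (oob.empty()) continue;

    int correct = 0;
    for (int i : oob) {
      double pr = tree_prob(f, root, X, i);
      oob_sum[i] += pr;
      oob_cnt[i]++;
      correct += ((pr > 0.5) ? 1 : 0) == y[i];
    }
    if (compute_importance && !used.empty()) {
      std::sort(used.begin(), used.end());
      used.erase(std::unique(used.begin(), used.end()), used.end());
      const int no = (int)oob.size();
      for (int j : used) {
        permv.resize(no);
        for (int i = 0; i < no; ++i) permv[i] = X(oob[i], j);
        for (int i = no - 1; i > 0; --i)
          std::swap(permv[i], permv[rng.unif_int(i + 1)]);
        int correct_perm = 0;
        for (int i = 0; i < no; ++i) {
          double pr = tree_prob(f, root, X, oob[i], j, permv[i]);
          correct_perm += ((pr > 0.5) ? 1 : 0) == y[oob[i]];
        }
        imp[j] += (double)(correct - correct_perm) / no;
      }
    }
  }

  arma::vec oob_pred(n);
  for (int i = 0; i < n; ++i)
    oob_pred[i] = oob_cnt[i] ? oob_sum[i] / oob_cnt[i] : NA_REAL;
  if (compute_importance) imp /= n_trees;

  return List::create(
      _["feat"] = IntegerVector(f.feat.begin(), f.feat.end()),
      _["thr"] = NumericVector(f.thr.begin(), f.thr.end()),
      _["left"] = IntegerVector(f.left.begin(), f.left.end()),
      _["right"] = IntegerVector(f.right.begin(), f.right.end()),
      _["prob"] = NumericVector(f.prob.begin(), f.prob.end()),
      _["offset"] = IntegerVector(f.offset.begin(), f.offset.end()),
      _["oob_pred"] = NumericVector(oob_pred.begin(), oob_pred.end()),
      _["importance"] = NumericVector(imp.begin(), imp.end()),
      _["n_features"] = p);
}

// [[Rcpp::export]]
NumericVector cpp_rf_predict(const List &forest, const arma::mat &X) {
  IntegerVector feat = forest["feat"], left = forest["left"],
                right = forest["right"], offset = forest["offset"];
  NumericVector thr = forest["thr"], prob = forest["prob"];
  const int n_trees = offset.size() - 1;
  const int n = (int)X.n_rows;
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double s = 0;
    for (int t = 0; t < n_trees; ++t) {
      int node = offset[t];
      while (feat[node] >= 0)
        node = (X(i, feat[node]) <= thr[node]) ? left[node] : right[node];
      s += prob[node];
    }
    out[i] = s / n_trees;
  }
  return out;
}
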