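// Gaussian gradient boosting with small regression trees.
// Trees are grown best-first with `tc` splits (so tc+1 terminal nodes, the
// usual "tree complexity" parameterization); each boosting step fits a tree
// to the current residuals of a bag-fraction subsample and shrinks the leaf
// means by the learning rate. Bagging uses R's RNG so set.seed() in R makes
// fits reproducible.
#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

struct Tree {
  std::vector<int> var;      // split variable, -1 = leaf
  std::vector<double> split;
  std::vector<int> left, right;
  std::vector<double> value; // leaf prediction (already scaled by lr)
};

struct SplitCand {
  int node;
  int var;
  double thresh;
  double gain;
  std::vector<int> obs;      // observation indices in this node
};

static bool best_split(const NumericMatrix& X, const std::vector<double>& r,
                       const std::vector<int>& obs, int min_obs,
                       int& bvar, double& bthresh, double& bgain) {
  int p = X.ncol();
  int m = (int)obs.size();
  if (m < 2 * min_obs) return false;
  double s = 0.0;
  for (int i = 0; i < m; i++) s += r[obs[i]];
  double base = s * s / m;
  bgain = 0.0; bvar = -1;
  std::vector<std::pair<double, double> > xy(m);
  for (int j = 0; j < p; j++) {
    for (int i = 0; i < m; i++)
      xy[i] = std::make_pair(X(obs[i], j), r[obs[i]]);
    std::sort(xy.begin(), xy.end());
    double sl = 0.0;
    for (int i = 0; i < m - 1; i++) {
      sl += xy[i].second;
      if (xy[i + 1].first <= xy[i].first) continue; // not a distinct cut
      int nl = i + 1, nr_ = m - nl;
      if (nl < min_obs || nr_ < min_obs) continue;
      double sr = s - sl;
      double gain = sl * sl / nl + sr * sr / nr_ - base;
      if (gain > bgain + 1e-12) {
        bgain = gain;
        bvar = j;
        bthresh = 0.5 * (xy[i].first + xy[i + 1].first);
      }
    }
  }
  return bvar >= 0;
}

// Grow one tree on residuals r over bagged obs; returns per-variable gain
// accumulation into var_gain. Leaf values scaled by lr.
static Tree grow_tree(const NumericMatrix& X, const std::vector<double>& r,
                      const std::vector<int>& bag_obs, int tc, double lr,
                      int min_obs, std::vector<double>& var_gain) {
  Tree t;
  t.var.push_back(-1); t.split.push_back(0.0);
  t.left.push_back(-1); t.right.push_back(-1); t.value.push_back(0.0);
  std::vector<SplitCand> cands;
  {
    SplitCand c; c.node = 0; c.obs = bag_obs;
    if (best_split(X, r, c.obs, min_obs, c.var, c.thresh, c.gain))
      cands.push_back(c);
  }
  // leaf means (over bagged obs) per node
  std::vector<std::vector<int> > node_obs(1, bag_obs);
  int splits = 0;
  while (splits < tc && !cands.empty()) {
    int bi = 0;
    for (int i = 1; i < (int)cands.size(); i++)
      if (cands[i].gain > cands[bi].gain) bi = i;
    SplitCand c = cands[bi];
    cands.erase(cands.begin() + bi);
    // perform split
    int nl = (int)t.var.size(), nr_ = nl + 1;
    t.var.push_back(-1); t.split.push_back(0.0);
    t.left.push_back(-1); t.right.push_back(-1); t.value.push_back(0.0);
    t.var.push_back(-1); t.split.push_back(0.0);
    t.left.push_back(-1); t.right.push_back(-1); t.value.push_back(0.0);
    t.var[c.node] = c.var; t.split[c.node] = c.thresh;
    t.left[c.node] = nl; t.right[c.node] = nr_;
    std::vector<int> lo, ro;
    for (size_t i = 0; i < c.obs.size(); i++) {
      if (X(c.obs[i], c.var) <= c.thresh) lo.push_back(c.obs[i]);
      else ro.push_back(c.obs[i]);
    }
    node_obs.resize(t.var.size());
    node_obs[nl] = lo; node_obs[nr_] = ro;
    var_gain[c.var] += c.gain;
    splits++;
    SplitCand cl; cl.node = nl; cl.obs = lo;
    if (best_split(X, r, cl.obs, min_obs, cl.var, cl.thresh, cl.gain))
      cands.push_back(cl);
    SplitCand cr; cr.node = nr_; cr.obs = ro;
    if (best_split(X, r, cr.obs, min_obs, cr.var, cr.thresh, cr.gain))
      cands.push_back(cr);
  }
  // set leaf values = lr * mean residual of bagged obs in leaf
  for (size_t nd = 0; nd < t.var.size(); nd++) {
    if (t.var[nd] >= 0) continue;
    const std::vector<int>& o = node_obs[nd];
    double s = 0.0;
    for (size_t i = 0; i < o.size(); i++) s += r[o[i]];
    t.value[nd] = o.empty() ? 0.0 : lr * s / o.size();
  }
  return t;
}

static double tree_pred(const Tree& t, const NumericMatrix& X, int row) {
  int nd = 0;
  while (t.var[nd] >= 0)
    nd = (X(row, t.var[nd]) <= t.split[nd]) ? t.left[nd] : t.right[nd];
  return t.value[nd];
}

static void bag_sample(int n, int k, std::vector<int>& out) {
  // partial Fisher-Yates using R's RNG
  std::vector<int> pool(n);
  for (int i = 0; i < n; i++) pool[i] = i;
  out.resize(k);
  for (int i = 0; i < k; i++) {
    int j = i + (int)std::floor(unif_rand() * (n - i));
    if (j >= n) j = n - 1;
    std::swap(pool[i], pool[j]);
    out[i] = pool[i];
  }
}

// Core boosting loop; optionally tracks predictions on a held-out set.
static List boost_core(const NumericMatrix& X, const NumericVector& y,
                       double lr, int tc, double bag, int n_trees,
                       int min_obs,
                       const NumericMatrix* Xtest, const NumericVector* ytest,
                       NumericVector* test_sse_path) {
  int n = X.nrow(), p = X.ncol();
  double init = mean(y);
  std::vector<double> F(n, init), r(n);
  int ntest = Xtest ? Xtest->nrow() : 0;
  std::vector<double> Ft(ntest, init);
  std::vector<double> var_gain(p, 0.0);
  std::vector<Tree> trees;
  trees.reserve(n_trees);
  int nbag = std::max(2 * min_obs, (int)std::floor(bag * n));
  if (nbag > n) nbag = n;
  std::vector<int> bag_obs;
  for (int m = 0; m < n_trees; m++) {
    for (int i = 0; i < n; i++) r[i] = y[i] - F[i];
    bag_sample(n, nbag, bag_obs);
    Tree t = grow_tree(X, r, bag_obs, tc, lr, min_obs, var_gain);
    for (int i = 0; i < n; i++) F[i] += tree_pred(t, X, i);
    if (Xtest) {
      double sse = 0.0;
      for (int i = 0; i < ntest; i++) {
        Ft[i] += tree_pred(t, *Xtest, i);
        double e = (*ytest)[i] - Ft[i];
        sse += e * e;
      }
      (*test_sse_path)[m] = sse;
    }
    trees.push_back(t);
  }
  // flatten
  int total_nodes = 0;
  for (size_t i = 0; i < trees.size(); i++) total_nodes += trees[i].var.size();
  IntegerVector var(total_nodes), left(total_nodes), right(total_nodes);
  NumericVector split(total_nodes), value(total_nodes);
  IntegerVector offset(trees.size() + 1);
  int k = 0;
  for (size_t i = 0; i < trees.size(); i++) {
    offset[i] = k;
    const Tree& t = trees[i];
    int base = k;
    for (size_t nd = 0; nd < t.var.size(); nd++) {
      var[k] = t.var[nd]; split[k] = t.split[nd];
      // children stored as global node indices into the flattened arrays
      left[k] = t.left[nd] >= 0 ? base + t.left[nd] : -1;
      right[k] = t.right[nd] >= 0 ? base + t.right[nd] : -1;
      value[k] = t.value[nd];
      k++;
    }
  }
  offset[trees.size()] = k;
  NumericVector fitted(n);
  for (int i = 0; i < n; i++) fitted[i] = F[i];
  NumericVector gains(p);
  for (int j = 0; j < p; j++) gains[j] = var_gain[j];
  return List::create(_["init"] = init, _["var"] = var, _["split"] = split,
                      _["left"] = left, _["right"] = right,
                      _["value"] = value, _["offset"] = offset,
                      _["fitted"] = fitted, _["gains"] = gains,
                      _["n_trees"] = (int)trees.size());
}

// [[Rcpp::export]]
List cpp_boost_fit(NumericMatrix X, NumericVector y, double lr, int tc,
                   double bag, int n_trees, int min_obs = 5) {
  return boost_core(X, y, lr, tc, bag, n_trees, min_obs, NULL, NULL, NULL);
}

// Ten-fold-style CV path: for each fold, boost on the remainder and record
// held-out SSE after each tree. Returns the summed held-out SSE path and the
// held-out null SSE (train-fold means as predictor).
// [[Rcpp::export]]
List cpp_boost_cv(NumericMatrix X, NumericVector y, IntegerVector fold,
                  double lr, int tc, double bag, int max_trees,
                  int min_obs = 5) {
  int n = X.nrow(), p = X.ncol();
  int K = max(fold);
  NumericVector cv_sse(max_trees);
  double null_sse = 0.0;
  for (int k = 1; k <= K; k++) {
    std::vector<int> tr, te;
    for (int i = 0; i < n; i++) (fold[i] == k ? te : tr).push_back(i);
    if (te.empty() || (int)tr.size() < 2 * min_obs) continue;
    NumericMatrix Xtr((int)tr.size(), p), Xte((int)te.size(), p);
    NumericVector ytr((int)tr.size()), yte((int)te.size());
    for (size_t i = 0; i < tr.size(); i++) {
      ytr[i] = y[tr[i]];
      for (int j = 0; j < p; j++) Xtr(i, j) = X(tr[i], j);
    }
    for (size_t i = 0; i < te.size(); i++) {
      yte[i] = y[te[i]];
      for (int j = 0; j < p; j++) Xte(i, j) = X(te[i], j);
    }
    double mtr = mean(ytr);
    for (int i = 0; i < (int)te.size(); i++) {
      double e = yte[i] - mtr;
      null_sse += e * e;
    }
    NumericVector path(max_trees);
    boost_core(Xtr, ytr, lr, tc, bag, max_trees, min_obs, &Xte, &yte, &path);
    for (int m = 0; m < max_trees; m++) cv_sse[m] += path[m];
  }
  return List::create(_["cv_sse"] = cv_sse, _["null_sse"] = null_sse);
}

// [[Rcpp::export]]
NumericVector cpp_boost_predict(double init, IntegerVector var,
                                NumericVector split, IntegerVector left,
                                IntegerVector right, NumericVector value,
                                IntegerVector offset, int n_trees,
                                NumericMatrix X) {
  int n = X.nrow();
  NumericVector out(n, init);
  for (int t = 0; t < n_trees; t++) {
    int base = offset[t];
    for (int i = 0; i < n; i++) {
      int nd = base;
      while (var[nd] >= 0)
        nd = (X(i, var[nd]) <= split[nd]) ? left[nd] : right[nd];
      out[i] += value[nd];
    }
  }
  return out;
}

// Partial dependence by brute force: average prediction over the training
// rows with predictor j clamped to each grid value.
// [[Rcpp::export]]
NumericVector cpp_boost_pd(double init, IntegerVector var, NumericVector split,
                           IntegerVector left, IntegerVector right,
                           NumericVector value, IntegerVector offset,
                           int n_trees, NumericMatrix X, int j,
                           NumericVector grid) {
  int n = X.nrow();
  NumericVector out(grid.size());
  NumericMatrix Xc = clone(X);
  for (int g = 0; g < grid.size(); g++) {
    for (int i = 0; i < n; i++) Xc(i, j) = grid[g];
    double s = 0.0;
    for (int i = 0; i < n; i++) {
      double f = init;
      for (int t = 0; t < n_trees; t++) {
        int nd = offset[t];
        while (var[nd] >= 0)
          nd = (Xc(i, var[nd]) <= split[nd]) ? left[nd] : right[nd];
        f += value[nd];
      }
      s += f;
    }
    out[g] = s / n;
  }
  return out;
}
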