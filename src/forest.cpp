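#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Regression random forest with out-of-bag bookkeeping and Breiman-Cutler
// permutation importance. All randomness is drawn from R's RNG so that
// set.seed() in R makes fits byte-reproducible.

struct Tree {
  std::vector<int> var;      // split predictor, -1 for leaf
  std::vector<double> split; // threshold: x <= split goes left
  std::vector<int> left, right;
  std::vector<double> value; // leaf mean
};

static int ri(int n) { // uniform integer in [0, n)
  int v = (int)(unif_rand() * n);
  return v >= n ? n - 1 : v;
}

static void grow_node(Tree& tr, const arma::mat& X, const arma::vec& y,
                      std::vector<int>& rows, int lo, int hi, int node,
                      int mtry, int min_node) {
  const int n = hi - lo;
  double sum = 0.0, ss = 0.0;
  for (int i = lo; i < hi; ++i) { sum += y(rows[i]); ss += y(rows[i]) * y(rows[i]); }
  const double mean = sum / n;
  tr.value[node] = mean;
  if (n < min_node || ss - sum * mean <= 1e-12) return;

  const int p = X.n_cols;
  // sample mtry candidate predictors without replacement (partial Fisher-Yates)
  std::vector<int> cand(p);
  for (int j = 0; j < p; ++j) cand[j] = j;
  int m = std::min(mtry, p);
  for (int j = 0; j < m; ++j) std::swap(cand[j], cand[j + ri(p - j)]);

  double best_gain = 1e-12;
  int best_var = -1;
  double best_split = 0.0;
  std::vector<int> ord(rows.begin() + lo, rows.begin() + hi);
  for (int c = 0; c < m; ++c) {
    const int j = cand[c];
    std::sort(ord.begin(), ord.end(),
              [&](int a, int b) { return X(a, j) < X(b, j); });
    double sl = 0.0;
    for (int i = 0; i < n - 1; ++i) {
      sl += y(ord[i]);
      if (X(ord[i + 1], j) <= X(ord[i], j)) continue; // tied values
      const int nl = i + 1, nr = n - nl;
      const double sr = sum - sl;
      const double gain = sl * sl / nl + sr * sr / nr - sum * mean;
      if (gain > best_gain) {
        best_gain = gain;
        best_var = j;
        best_split = 0.5 * (X(ord[i], j) + X(ord[i + 1], j));
      }
    }
  }
  if (best_var < 0) return;

  // partition rows[lo:hi) in place
  int mid = lo;
  for (int i = lo; i < hi; ++i)
    if (X(rows[i], best_var) <= best_split) std::swap(rows[i], rows[mid++]);
  if (mid == lo || mid == hi) return; // numeric degeneracy guard

  tr.var[node] = best_var;
  tr.split[node] = best_split;
  int l = (int)tr.var.size();
  tr.var.push_back(-1); tr.split.push_back(0.0);
  tr.left.push_back(-1); tr.right.push_back(-1); tr.value.push_back(0.0);
  int r = (int)tr.var.size();
  tr.var.push_back(-1); tr.split.push_back(0.0);
  tr.left.push_back(-1); tr.right.push_back(-1); tr.value.push_back(0.0);
  tr.left[node] = l;
  tr.right[node] = r;
  grow_node(tr, X, y, rows, lo, mid, l, mtry, min_node);
  grow_node(tr, X, y, rows, mid, hi, r, mtry, min_node);
}

static double predict_row(const Tree& tr, const arma::mat& X, int i,
                          int perm_var = -1, double perm_val = 0.0) {
  int node = 0;
  while (tr.var[node] >= 0) {
    const int j = tr.var[node];
    const double x = (j == perm_var) ? perm_val : X(i, j);
    node = (x <= tr.split[node]) ? tr.left[node] : tr.right[node];
  }
  return tr.value[node];
}

static Tree unpack_tree(const List& tl) {
  Tree tr;
  tr.var = as<std::vector<int>>(tl["var"]);
  tr.split = as<std::vector<double>>(tl["split"]);
  tr.left = as<std::vector<int>>(tl["left"]);
  tr.right = as<std::vector<int>>(tl["right"]);
  tr.value = as<std::vector<double>>(tl["value"]);
  return tr;
}

// [[Rcpp::export(name = ".rf_fit_cpp")]]
List rf_fit_cpp(const arma::mat& X, const arma::vec& y, int n_trees,
                int mtry, int min_node, bool replace, int sampsize) {
  RNGScope scope;
  const int n = X.n_rows;
  List trees(n_trees);
  arma::imat inbag(n, n_trees, arma::fill::zeros);
  arma::vec oob_sum(n, arma::fill::zeros);
  arma::ivec oob_n(n, arma::fill::zeros);

  std::vector<int> pool(n);
  for (int t = 0; t < n_trees; ++t) {
    std::vector<int> rows;
    rows.reserve(sampsize);
    if (replace) {
      for (int i = 0; i < sampsize; ++i) rows.push_back(ri(n));
    } else {
      for (int i = 0; i < n; ++i) pool[i] = i;
      for (int i = 0; i < sampsize; ++i) {
        std::swap(pool[i], pool[i + ri(n - i)]);
        rows.push_back(pool[i]);
      }
    }
    for (int i : rows) inbag(i, t) += 1;

    Tree tr;
    tr.var.assign(1, -1); tr.split.assign(1, 0.0);
    tr.left.assign(1, -1); tr.right.assign(1, -1); tr.value.assign(1, 0.0);
    grow_node(tr, X, y, rows, 0, (int)rows.size(), 0, mtry, min_node);
    for (int i = 0; i < n; ++i)
      if (inbag(i, t) == 0) {
        oob_sum(i) += predict_row(tr, X, i);
        oob_n(i) += 1;
      }
    trees[t] = List::create(Named("var") = tr.var, Named("split") = tr.split,
                            Named("left") = tr.left, Named("right") = tr.right,
                            Named("value") = tr.value);
  }
  arma::vec oob_pred(n);
  for (int i = 0; i < n; ++i)
    oob_pred(i) = oob_n(i) > 0 ? oob_sum(i) / oob_n(i) : NA_REAL;
  return List::create(Named("trees") = trees, Named("inbag") = inbag,
                      Named("oob_pred") = oob_pred);
}

// [[Rcpp::export(name = ".rf_predict_cpp")]]
arma::vec rf_predict_cpp(const List& trees, const arma::mat& X) {
  const int n = X.n_rows, T = trees.size();
  arma::vec out(n, arma::fill::zeros);
  for (int t = 0; t < T; ++t) {
    Tree tr = unpack_tree(trees[t]);
    for (int i = 0; i < n; ++i) out(i) += predict_row(tr, X, i);
  }
  return out / T;
}

// Breiman-Cutler permutation VIMP: per tree, increase in OOB mean squared
// error after permuting one predictor over that tree's OOB rows; averaged
// over trees. Returns the per-predictor mean and its standard error over
// trees.
// [[Rcpp::export(name = ".rf_vimp_cpp")]]
List rf_vimp_cpp(const List& trees, const arma::imat& inbag,
                 const arma::mat& X, const arma::vec& y) {
  RNGScope scope;
  const int n = X.n_rows, p = X.n_cols, T = trees.size();
  arma::mat imp(T, p, arma::fill::value(NA_REAL));
  std::vector<int> oob;
  std::vector<double> perm;
  for (int t = 0; t < T; ++t) {
    Tree tr = unpack_tree(trees[t]);
    oob.clear();
    for (int i = 0; i < n; ++i) if (inbag(i, t) == 0) oob.push_back(i);
    const int no = (int)oob.size();
    if (no < 2) continue;
    double err0 = 0.0;
    for (int i : oob) {
      const double d = y(i) - predict_row(tr, X, i);
      err0 += d * d;
    }
    err0 /= no;
    for (int j = 0; j < p; ++j) {
      perm.resize(no);
      for (int k = 0; k < no; ++k) perm[k] = X(oob[k], j);
      for (int k = no - 1; k > 0; --k) std::swap(perm[k], perm[ri(k + 1)]);
      double errp = 0.0;
      for (int k = 0; k < no; ++k) {
        const double d = y(oob[k]) - predict_row(tr, X, oob[k], j, perm[k]);
        errp += d * d;
      }
      imp(t, j) = errp / no - err0;
    }
  }
  arma::vec mean_imp(p), se_imp(p);
  for (int j = 0; j < p; ++j) {
    arma::vec col = imp.col(j);
    arma::vec ok = col(arma::find_finite(col));
    mean_imp(j) = arma::mean(ok);
    se_imp(j) = ok.n_elem > 1 ? arma::stddev(ok) / std::sqrt((double)ok.n_elem)
                              : NA_REAL;
  }
  return List::create(Named("vimp") = mean_imp, Named("se") = se_imp);
}
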