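// Small-n regression random forest recording every split, used as the
// per-SNP engine of the gradient-forest turnover model. Bootstrap of rows,
// mtry predictors tried per node, nodes with more than min_node cases are
// split at the midpoint maximising the reduction in residual sum of
// squares. Out-of-bag predictions give R2; out-of-bag permutation of one
// predictor at a time gives importance. Uses R's RNG so results are fixed
// by set.seed() on the R side.

#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

namespace {

struct Forest {
  // flattened tree nodes across the whole forest; tree t owns
  // [tree_off[t], tree_off[t+1])
  std::vector<int> var, left, right;
  std::vector<double> thr, val;
  std::vector<int> tree_off;
};

inline int rand_int(int n) {  // uniform on 0..n-1 via R RNG
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

int predict_node(const Forest& f, int node, const double* xrow, int p,
                 const NumericMatrix& X, int row, int perm_var,
                 double perm_val) {
  // descend from `node`; if perm_var >= 0 use perm_val for that predictor
  while (f.var[node] >= 0) {
    double x = (f.var[node] == perm_var) ? perm_val
                                         : X(row, f.var[node]);
    node = (x <= f.thr[node]) ? f.left[node] : f.right[node];
  }
  return node;
}

}  // namespace

// [[Rcpp::export]]
List gf_forest_cpp(NumericMatrix X, NumericVector y, int ntree, int mtry,
                   int min_node) {
  const int n = X.nrow(), p = X.ncol();
  if (mtry < 1) mtry = 1;
  if (mtry > p) mtry = p;

  Forest forest;
  forest.tree_off.push_back(0);
  std::vector<double> split_var, split_thr, split_imp;

  std::vector<double> oob_sum(n, 0.0);
  std::vector<int> oob_cnt(n, 0);
  std::vector<double> imp(p, 0.0);
  std::vector<int> imp_trees(p, 0);

  std::vector<int> idx(n), inbag(n);
  std::vector<int> cand(p);
  std::vector<std::pair<double, double>> buf(n);  // (x, y) pairs for sorting
  std::vector<int> oob_rows, perm;

  for (int t = 0; t < ntree; ++t) {
    std::fill(inbag.begin(), inbag.end(), 0);
    for (int i = 0; i < n; ++i) {
      int k = rand_int(n);
      idx[i] = k;
      inbag[k]++;
    }

    // iterative tree construction over segments of idx
    struct Task { int lo, hi, node; };
    std::vector<Task> stack;
    // create root placeholder
    auto new_node = [&]() {
      forest.var.push_back(-1);
      forest.thr.push_back(0.0);
      forest.left.push_back(-1);
      forest.right.push_back(-1);
      forest.val.push_back(0.0);
      return (int)forest.var.size() - 1;
    };
    int root = new_node();
    stack.push_back({0, n, root});

    while (!stack.empty()) {
      Task tk = stack.back();
      stack.pop_back();
      int m = tk.hi - tk.lo;
      double sum = 0.0, ss = 0.0;
      for (int i = tk.lo; i < tk.hi; ++i) sum += y[idx[i]];
      double mean = sum / m;
      for (int i = tk.lo; i < tk.hi; ++i) {
        double d = y[idx[i]] - mean;
        ss += d * d;
      }
      forest.val[tk.node] = mean;
      if (m <= min_node || ss <= 1e-12) continue;

      // choose mtry candidate predictors (partial Fisher-Yates)
      for (int j = 0; j < p; ++j) cand[j] = j;
      int best_var = -1;
      double best_crit = sum * sum / m, best_thr = 0.0;
      for (int j = 0; j < mtry; ++j) {
        int pick = j + rand_int(p - j);
        std::swap(cand[j], cand[pick]);
        int v = cand[j];
        for (int i = 0; i < m; ++i) {
          int r = idx[tk.lo + i];
          buf[i] = {X(r, v), y[r]};
        }
        std::sort(buf.begin(), buf.begin() + m);
        double sl = 0.0;
        for (int i = 0; i < m - 1; ++i) {
          sl += buf[i].second;
          if (buf[i + 1].first <= buf[i].first) continue;  // tie on x
          double sr = sum - sl;
          double crit = sl * sl / (i + 1) + sr * sr / (m - i - 1);
          if (crit > best_crit + 1e-12) {
            best_crit = crit;
            best_var = v;
            best_thr = 0.5 * (buf[i].first + buf[i + 1].first);
          }
        }
      }
      if (best_var < 0) continue;  // no usable split among candidates

      double improvement = best_crit - sum * sum / m;  // SS reduction
      split_var.push_back(best_var + 1);               // 1-based for R
      split_thr.push_back(best_thr);
      split_imp.push_back(improvement);

      // partition idx segment
      int i = tk.lo, j2 = tk.hi - 1;
      while (i <= j2) {
        if (X(idx[i], best_var) <= best_thr) {
          ++i;
        } else {
          std::swap(idx[i], idx[j2]);
          --j2;
        }
      }
      int mid = i;
      int lnode = new_node(), rnode = new_node();
      forest.var[tk.node] = best_var;
      forest.thr[tk.node] = best_thr;
      forest.left[tk.node] = lnode;
      forest.right[tk.node] = rnode;
      stack.push_back({tk.lo, mid, lnode});
      stack.push_back({mid, tk.hi, rnode});
    }
    forest.tree_off.push_back((int)forest.var.size());

    // out-of-bag predictions and permutation importance for this tree
    oob_rows.clear();
    for (int i = 0; i < n; ++i)
      if (inbag[i] == 0) oob_rows.push_back(i);
    int no = (int)oob_rows.size();
    if (no == 0) continue;
    double mse = 0.0;
    std::vector<double> pred(no);
    for (int k = 0; k < no; ++k) {
      int r = oob_rows[k];
      int leaf = predict_node(forest, root, nullptr, p, X, r, -1, 0.0);
      pred[k] = forest.val[leaf];
      oob_sum[r] += pred[k];
      oob_cnt[r]++;
      double d = pred[k] - y[r];
      mse += d * d;
    }
    mse /= no;
    perm.resize(no);
    for (int v = 0; v < p; ++v) {
      for (int k = 0; k < no; ++k) perm[k] = k;
      for (int k = no - 1; k > 0; --k) std::swap(perm[k], perm[rand_int(k + 1)]);
      double mse_p = 0.0;
      for (int k = 0; k < no; ++k) {
        int r = oob_rows[k];
        double pv = X(oob_rows[perm[k]], v);
        int leaf = predict_node(forest, root, nullptr, p, X, r, v, pv);
        double d = forest.val[leaf] - y[r];
        mse_p += d * d;
      }
      mse_p /= no;
      imp[v] += (mse_p - mse);
      imp_trees[v]++;
    }
  }

  NumericVector oob_pred(n, NA_REAL);
  double err = 0.0, tot = 0.0, ybar = 0.0;
  int covered = 0;
  for (int i = 0; i < n; ++i)
    if (oob_cnt[i] > 0) {
      oob_pred[i] = oob_sum[i] / oob_cnt[i];
      ybar += y[i];
      covered++;
    }
  double r2 = NA_REAL;
  if (covered > 1) {
    ybar /= covered;
    for (int i = 0; i < n; ++i)
      if (oob_cnt[i] > 0) {
        err += (oob_pred[i] - y[i]) * (oob_pred[i] - y[i]);
        tot += (y[i] - ybar) * (y[i] - ybar);
      }
    r2 = (tot > 0) ? 1.0 - err / tot : NA_REAL;
  }

  NumericVector importance(p);
  for (int v = 0; v < p; ++v)
    importance[v] = imp_trees[v] > 0 ? imp[v] / imp_trees[v] : 0.0;

  NumericMatrix splits((int)split_var.size(), 3);
  for (int s = 0; s < (int)split_var.size(); ++s) {
    splits(s, 0) = split_var[s];
    splits(s, 1) = split_thr[s];
    splits(s, 2) = split_imp[s];
  }
  colnames(splits) = CharacterVector::create("var", "threshold", "improvement");

  return List::create(_["r2"] = r2, _["importance"] = importance,
                      _["splits"] = splits, _["oob_pred"] = oob_pred);
}
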