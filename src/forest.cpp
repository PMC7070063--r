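#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Random-forest regression with bootstrap resampling and per-node feature
// subsampling; out-of-bag predictions are accumulated per training row.
// Uses R's RNG so that set.seed() in R makes runs reproducible.

namespace {

struct Node {
  int feature = -1;
  double thresh = 0.0;
  int left = -1, right = -1;
  double value = 0.0;
  bool is_leaf = true;
};

int rand_int(int n) {  // uniform on 0..n-1 via R RNG
  int k = (int)(unif_rand() * n);
  return (k >= n) ? n - 1 : k;
}

void build(std::vector<Node>& nodes, int nd, std::vector<int>& rows, int lo,
           int hi, const NumericMatrix& X, const NumericVector& y, int mtry,
           int min_node, int depth, int max_depth, std::vector<int>& feats) {
  const int cnt = hi - lo;
  double sum = 0.0;
  for (int k = lo; k < hi; ++k) sum += y[rows[k]];
  nodes[nd].value = sum / cnt;
  if (cnt <= min_node || depth >= max_depth) return;

  // sample mtry features without replacement (partial Fisher-Yates)
  const int p = X.ncol();
  for (int j = 0; j < p; ++j) feats[j] = j;
  int best_feature = -1;
  double best_thresh = 0.0, best_gain = 1e-12;
  const double baseT = sum * sum / cnt;
  std::vector<int> idx(rows.begin() + lo, rows.begin() + hi);
  for (int t = 0; t < mtry && t < p; ++t) {
    const int pickj = t + rand_int(p - t);
    std::swap(feats[t], feats[pickj]);
    const int j = feats[t];
    std::sort(idx.begin(), idx.end(), [&](int a, int b) {
      return X(a, j) < X(b, j);
    });
    double sumL = 0.0;
    for (int k = 0; k < cnt - 1; ++k) {
      sumL += y[idx[k]];
      const double x0 = X(idx[k], j), x1 = X(idx[k + 1], j);
      if (x1 <= x0) continue;
      const int cntL = k + 1, cntR = cnt - cntL;
      const double sumR = sum - sumL;
      const double gain = sumL * sumL / cntL + sumR * sumR / cntR - baseT;
      if (gain > best_gain) {
        best_gain = gain;
        best_feature = j;
        best_thresh = 0.5 * (x0 + x1);
      }
    }
  }
  if (best_feature < 0) return;

  // partition rows[lo:hi] in place
  int mid = lo;
  for (int k = lo; k < hi; ++k) {
    if (X(rows[k], best_feature) <= best_thresh) {
      std::swap(rows[k], rows[mid]);
      ++mid;
    }
  }
  if (mid == lo || mid == hi) return;  // numerically degenerate

  const int li = (int)nodes.size(), ri = li + 1;
  nodes[nd].is_leaf = false;
  nodes[nd].feature = best_feature;
  nodes[nd].thresh = best_thresh;
  nodes[nd].left = li;
  nodes[nd].right = ri;
  nodes.push_back(Node());
  nodes.push_back(Node());
  build(nodes, li, rows, lo, mid, X, y, mtry, min_node, depth + 1, max_depth,
        feats);
  build(nodes, ri, rows, mid, hi, X, y, mtry, min_node, depth + 1, max_depth,
        feats);
}

double predict_row(const std::vector<Node>& nodes, const NumericMatrix& X,
                   int row) {
  int nd = 0;
  while (!nodes[nd].is_leaf) {
    nd = (X(row, nodes[nd].feature) <= nodes[nd].thresh) ? nodes[nd].left
                                                         : nodes[nd].right;
  }
  return nodes[nd].value;
}

}  // namespace

// [[Rcpp::export(name = ".rf_oob")]]
List rf_oob(NumericMatrix X, NumericVector y, int n_trees, int mtry,
            int min_node, int max_depth) {
  const int n = X.nrow();
  if (y.size() != n) stop("length(y) != nrow(X)");
  if (n_trees < 1) stop("n_trees must be >= 1");

  std::vector<double> oob_sum(n, 0.0);
  std::vector<int> oob_cnt(n, 0);
  std::vector<int> inbag(n), rows;
  std::vector<int> feats(X.ncol());
  NumericVector yb(n);

  for (int t = 0; t < n_trees; ++t) {
    std::fill(inbag.begin(), inbag.end(), 0);
    rows.resize(n);
    for (int i = 0; i < n; ++i) {
      const int k = rand_int(n);
      rows[i] = k;
      ++inbag[k];
    }
    std::vector<Node> nodes(1);
    build(nodes, 0, rows, 0, n, X, y, mtry, min_node, 0, max_depth, feats);
    for (int i = 0; i < n; ++i) {
      if (inbag[i] == 0) {
        oob_sum[i] += predict_row(nodes, X, i);
        ++oob_cnt[i];
      }
    }
  }

  NumericVector pred(n);
  IntegerVector cnt(n);
  for (int i = 0; i < n; ++i) {
    cnt[i] = oob_cnt[i];
    pred[i] = (oob_cnt[i] > 0) ? oob_sum[i] / oob_cnt[i] : NA_REAL;
  }
  return List::create(_["oob"] = pred, _["n_oob_trees"] = cnt);
}
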