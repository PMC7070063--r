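#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Stagewise gradient boosting with squared-error loss and small regression
// trees grown best-first to a fixed number of splits ("interaction depth").
// No row or feature subsampling: deterministic given the data.

namespace {

struct Node {
  int feature = -1;
  double thresh = 0.0;
  int left = -1, right = -1;
  double value = 0.0;
  bool is_leaf = true;
};

struct Split {
  int node = -1;
  int feature = -1;
  double thresh = 0.0;
  double gain = -1.0;
};

// Best split of the rows currently assigned to `node`, scanning each
// feature in presorted order. Hot path: raw pointers throughout.
Split best_split(int node, const double* X, int n, int p,
                 const std::vector<double>& r,
                 const std::vector<std::vector<int> >& sorted,
                 const std::vector<int>& leaf_of, int min_obs) {
  double sumT = 0.0;
  int cntT = 0;
  for (int i = 0; i < n; ++i) {
    if (leaf_of[i] == node) { sumT += r[i]; ++cntT; }
  }
  Split best;
  best.node = node;
  if (cntT < 2 * min_obs) return best;
  const double baseT = sumT * sumT / cntT;
  const double* rr = r.data();
  const int* lf = leaf_of.data();
  for (int j = 0; j < p; ++j) {
    const double* xj = X + (size_t)n * j;
    const int* ord = sorted[j].data();
    double sumL = 0.0;
    int cntL = 0;
    double prev_x = 0.0;
    bool have_prev = false;
    for (int k = 0; k < n; ++k) {
      const int i = ord[k];
      if (lf[i] != node) continue;
      const double x = xj[i];
      if (have_prev && x > prev_x && cntL >= min_obs &&
          (cntT - cntL) >= min_obs) {
        const double sumR = sumT - sumL;
        const int cntR = cntT - cntL;
        const double gain =
            sumL * sumL / cntL + sumR * sumR / cntR - baseT;
        if (gain > best.gain) {
          best.gain = gain;
          best.feature = j;
          best.thresh = 0.5 * (prev_x + x);
        }
      }
      sumL += rr[i];
      ++cntL;
      prev_x = x;
      have_prev = true;
    }
  }
  return best;
}

// Best splits of two sibling leaves computed in one pass over the
// presorted feature columns.
void best_split_pair(int nodeA, int nodeB, const double* X, int n, int p,
                     const std::vector<double>& r,
                     const std::vector<std::vector<int> >& sorted,
                     const std::vector<int>& leaf_of, int min_obs,
                     Split& outA, Split& outB) {
  double sumTA = 0.0, sumTB = 0.0;
  int cntTA = 0, cntTB = 0;
  for (int i = 0; i < n; ++i) {
    if (leaf_of[i] == nodeA) { sumTA += r[i]; ++cntTA; }
    else if (leaf_of[i] == nodeB) { sumTB += r[i]; ++cntTB; }
  }
  outA = Split(); outA.node = nodeA;
  outB = Split(); outB.node = nodeB;
  const bool doA = cntTA >= 2 * min_obs, doB = cntTB >= 2 * min_obs;
  if (!doA && !doB) return;
  const double baseA = doA ? sumTA * sumTA / cntTA : 0.0;
  const double baseB = doB ? sumTB * sumTB / cntTB : 0.0;
  const double* rr = r.data();
  const int* lf = leaf_of.data();
  for (int j = 0; j < p; ++j) {
    const double* xj = X + (size_t)n * j;
    const int* ord = sorted[j].data();
    double sumLA = 0.0, sumLB = 0.0, prevA = 0.0, prevB = 0.0;
    int cntLA = 0, cntLB = 0;
    bool haveA = false, haveB = false;
    for (int k = 0; k < n; ++k) {
      const int i = ord[k];
      const int l = lf[i];
      if (l == nodeA) {
        const double x = xj[i];
        if (doA && haveA && x > prevA && cntLA >= min_obs &&
            (cntTA - cntLA) >= min_obs) {
          const double sumR = sumTA - sumLA;
          const int cntR = cntTA - cntLA;
          const double gain = sumLA * sumLA / cntLA + sumR * sumR / cntR - baseA;
          if (gain > outA.gain) {
            outA.gain = gain; outA.feature = j; outA.thresh = 0.5 * (prevA + x);
          }
        }
        sumLA += rr[i]; ++cntLA; prevA = x; haveA = true;
      } else if (l == nodeB) {
        const double x = xj[i];
        if (doB && haveB && x > prevB && cntLB >= min_obs &&
            (cntTB - cntLB) >= min_obs) {
          const double sumR = sumTB - sumLB;
          const int cntR = cntTB - cntLB;
          const double gain = sumLB * sumLB / cntLB + sumR * sumR / cntR - baseB;
          if (gain > outB.gain) {
            outB.gain = gain; outB.feature = j; outB.thresh = 0.5 * (prevB + x);
          }
        }
        sumLB += rr[i]; ++cntLB; prevB = x; haveB = true;
      }
    }
  }
}

int traverse(const std::vector<Node>& nodes, const double* X, int n, int row) {
  int nd = 0;
  while (!nodes[nd].is_leaf) {
    const double x = X[(size_t)n * nodes[nd].feature + row];
    nd = (x <= nodes[nd].thresh) ? nodes[nd].left : nodes[nd].right;
  }
  return nd;
}

}  // namespace

// [[Rcpp::export(name = ".gbm_boost")]]
List gbm_boost(NumericMatrix Xtr, NumericVector y, NumericMatrix Xte,
               int n_trees, double shrinkage, int interaction_depth,
               int min_obs) {
  const int n = Xtr.nrow(), p = Xtr.ncol(), m = Xte.nrow();
  if (y.size() != n) stop("length(y) != nrow(Xtr)");
  if (min_obs < 1) stop("min_obs must be >= 1");
  const double* X = REAL(Xtr);
  const double* Xt = REAL(Xte);

  // presort feature columns once
  std::vector<std::vector<int> > sorted(p);
  for (int j = 0; j < p; ++j) {
    std::vector<int>& ord = sorted[j];
    ord.resize(n);
    for (int i = 0; i < n; ++i) ord[i] = i;
    const double* xj = X + (size_t)n * j;
    std::stable_sort(ord.begin(), ord.end(), [&](int a, int b) {
      return xj[a] < xj[b];
    });
  }

  double f0 = 0.0;
  for (int i = 0; i < n; ++i) f0 += y[i];
  f0 /= n;

  std::vector<double> F_tr(n, f0), F_te(m, f0), r(n);
  std::vector<int> leaf_of(n);

  for (int t = 0; t < n_trees; ++t) {
    for (int i = 0; i < n; ++i) r[i] = y[i] - F_tr[i];

    std::vector<Node> nodes(1);
    std::fill(leaf_of.begin(), leaf_of.end(), 0);
    std::vector<Split> cand;
    cand.push_back(best_split(0, X, n, p, r, sorted, leaf_of, min_obs));

    for (int s = 0; s < interaction_depth; ++s) {
      int pick = -1;
      double gbest = 1e-12;
      for (size_t c = 0; c < cand.size(); ++c) {
        if (cand[c].gain > gbest) { gbest = cand[c].gain; pick = (int)c; }
      }
      if (pick < 0) break;
      Split sp = cand[pick];
      cand.erase(cand.begin() + pick);
      const int li = (int)nodes.size(), ri = li + 1;
      nodes[sp.node].is_leaf = false;
      nodes[sp.node].feature = sp.feature;
      nodes[sp.node].thresh = sp.thresh;
      nodes[sp.node].left = li;
      nodes[sp.node].right = ri;
      nodes.push_back(Node());
      nodes.push_back(Node());
      const double* xs = X + (size_t)n * sp.feature;
      for (int i = 0; i < n; ++i) {
        if (leaf_of[i] == sp.node)
          leaf_of[i] = (xs[i] <= sp.thresh) ? li : ri;
      }
      if (s + 1 < interaction_depth) {  // children only if splits remain
        Split ca, cb;
        best_split_pair(li, ri, X, n, p, r, sorted, leaf_of, min_obs, ca, cb);
        cand.push_back(ca);
        cand.push_back(cb);
      }
    }

    // leaf means of residuals
    std::vector<double> sum(nodes.size(), 0.0);
    std::vector<int> cnt(nodes.size(), 0);
    for (int i = 0; i < n; ++i) { sum[leaf_of[i]] += r[i]; ++cnt[leaf_of[i]]; }
    for (size_t nd = 0; nd < nodes.size(); ++nd) {
      if (nodes[nd].is_leaf && cnt[nd] > 0) nodes[nd].value = sum[nd] / cnt[nd];
    }

    for (int i = 0; i < n; ++i)
      F_tr[i] += shrinkage * nodes[leaf_of[i]].value;
    for (int i = 0; i < m; ++i)
      F_te[i] += shrinkage * nodes[traverse(nodes, Xt, m, i)].value;
  }

  return List::create(_["train"] = NumericVector(F_tr.begin(), F_tr.end()),
                      _["test"] = NumericVector(F_te.begin(), F_te.end()));
}
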