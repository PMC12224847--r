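#include <Rcpp.h>
#include <random>
#include <vector>
#include <algorithm>
#include <numeric>
using namespace Rcpp;

// Compact CART used by the native random-forest and gradient-boosting
// learners. Criterion is Gini impurity (y holds class indices 0..K-1) or
// squared error (y numeric, K = 1). Splits are binary on numeric features;
// thresholds are midpoints between adjacent distinct values.

namespace {

struct TreeBuf {
  std::vector<int> feat, left, right;
  std::vector<double> thr;
  std::vector<std::vector<double>> value; // leaf/node value (K per node)
  std::vector<double> imp;                // impurity-decrease per feature
};

struct Grower {
  const NumericMatrix& X;
  const NumericVector& y;
  int K;
  bool gini;
  int mtry, max_depth, min_node;
  std::mt19937 rng;
  TreeBuf out;
  std::vector<int> featpool;

  Grower(const NumericMatrix& X_, const NumericVector& y_, int K_, bool gini_,
         int mtry_, int max_depth_, int min_node_, unsigned seed)
      : X(X_), y(y_), K(K_), gini(gini_), mtry(mtry_), max_depth(max_depth_),
        min_node(min_node_), rng(seed), featpool(X_.ncol()) {
    std::iota(featpool.begin(), featpool.end(), 0);
    out.imp.assign(X_.ncol(), 0.0);
  }

  std::vector<double> node_value(const std::vector<int>& idx) const {
    std::vector<double> v(gini ? K : 1, 0.0);
    if (gini) {
      for (int i : idx) v[(int)y[i]] += 1.0;
      for (double& p : v) p /= idx.size();
    } else {
      double s = 0.0;
      for (int i : idx) s += y[i];
      v[0] = s / idx.size();
    }
    return v;
  }

  // impurity * n for a node described by class counts / sums
  double impurity_n(const std::vector<double>& cnt, double n, double sum,
                    double sum2) const {
    if (gini) {
      double s = 0.0;
      for (double c : cnt) s += c * c;
      return n - s / n; // n * (1 - sum p^2)
    }
    return sum2 - sum * sum / n; // SSE
  }

  int grow(std::vector<int>& idx, int depth) {
    int node = (int)out.feat.size();
    out.feat.push_back(-1);
    out.thr.push_back(0.0);
    out.left.push_back(-1);
    out.right.push_back(-1);
    out.value.push_back(node_value(idx));

    int n = (int)idx.size();
    if (depth >= max_depth || n < 2 * min_node) return node;

    // parent impurity
    std::vector<double> cnt(gini ? K : 0, 0.0);
    double sum = 0.0, sum2 = 0.0;
    for (int i : idx) {
      if (gini) cnt[(int)y[i]] += 1.0;
      sum += y[i];
      sum2 += y[i] * y[i];
    }
    double imp_parent = impurity_n(cnt, n, sum, sum2);
    if (imp_parent <= 1e-12) return node;

    std::shuffle(featpool.begin(), featpool.end(), rng);
    int ntry = std::min(mtry, (int)featpool.size());

    double best_gain = 1e-10;
    int best_f = -1, best_pos = -1;
    std::vector<int> ord(idx), best_ord;
    for (int t = 0; t < ntry; ++t) {
      int f = featpool[t];
      std::sort(ord.begin(), ord.end(), [&](int a, int b) {
        return X(a, f) < X(b, f);
      });
      std::vector<double> lcnt(gini ? K : 0, 0.0);
      double lsum = 0.0, lsum2 = 0.0;
      for (int p = 0; p < n - 1; ++p) {
        int i = ord[p];
        if (gini) lcnt[(int)y[i]] += 1.0;
        lsum += y[i];
        lsum2 += y[i] * y[i];
        int nl = p + 1, nr = n - nl;
        if (nl < min_node || nr < min_node) continue;
        if (X(ord[p + 1], f) <= X(i, f)) continue; // tie, no valid threshold
        std::vector<double> rcnt;
        if (gini) {
          rcnt = cnt;
          for (int k = 0; k < K; ++k) rcnt[k] -= lcnt[k];
        }
        double gain = imp_parent -
                      impurity_n(lcnt, nl, lsum, lsum2) -
                      impurity_n(rcnt, nr, sum - lsum, sum2 - lsum2);
        if (gain > best_gain) {
          best_gain = gain;
          best_f = f;
          best_pos = p;
          best_ord = ord;
        }
      }
    }
    if (best_f < 0) return node;

    double thr = 0.5 * (X(best_ord[best_pos], best_f) +
                        X(best_ord[best_pos + 1], best_f));
    std::vector<int> lidx(best_ord.begin(), best_ord.begin() + best_pos + 1);
    std::vector<int> ridx(best_ord.begin() + best_pos + 1, best_ord.end());
    out.imp[best_f] += best_gain;
    out.feat[node] = best_f;
    out.thr[node] = thr;
    out.left[node] = grow(lidx, depth + 1);
    out.right[node] = grow(ridx, depth + 1);
    return node;
  }
};

} // namespace

// [[Rcpp::export(name = ".grow_tree_cpp")]]
List grow_tree_cpp(NumericMatrix X, NumericVector y, int K, bool gini,
                   IntegerVector sample_idx, int mtry, int max_depth,
                   int min_node, int seed) {
  Grower gr(X, y, K, gini, mtry, max_depth, min_node,
            static_cast<unsigned>(seed));
  std::vector<int> idx(sample_idx.begin(), sample_idx.end());
  gr.grow(idx, 0);
  int nn = (int)gr.out.feat.size();
  int vk = gini ? K : 1;
  NumericMatrix val(nn, vk);
  for (int i = 0; i < nn; ++i)
    for (int k = 0; k < vk; ++k) val(i, k) = gr.out.value[i][k];
  return List::create(
      _["feat"] = IntegerVector(gr.out.feat.begin(), gr.out.feat.end()),
      _["thr"] = NumericVector(gr.out.thr.begin(), gr.out.thr.end()),
      _["left"] = IntegerVector(gr.out.left.begin(), gr.out.left.end()),
      _["right"] = IntegerVector(gr.out.right.begin(), gr.out.right.end()),
      _["value"] = val,
      _["importance"] = NumericVector(gr.out.imp.begin(), gr.out.imp.end()));
}

// [[Rcpp::export(name = ".predict_tree_cpp")]]
NumericMatrix predict_tree_cpp(List tree, NumericMatrix X) {
  IntegerVector feat = tree["feat"], left = tree["left"], right = tree["right"];
  NumericVector thr = tree["thr"];
  NumericMatrix val = tree["value"];
  int n = X.nrow(), vk = val.ncol();
  NumericMatrix out(n, vk);
  for (int i = 0; i < n; ++i) {
    int node = 0;
    while (feat[node] >= 0)
      node = (X(i, feat[node]) <= thr[node]) ? left[node] : right[node];
    for (int k = 0; k < vk; ++k) out(i, k) = val(node, k);
  }
  return out;
}
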