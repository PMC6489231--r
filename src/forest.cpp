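// Bagged regression forest with out-of-bag prediction and out-of-bag
// permutation variable importance.
//
// Deliberately self-contained and deterministic: a splitmix64 generator
// seeded per tree makes results identical across platforms and thread
// counts (fitting is sequential; parallel callers shard by gene with
// derived seeds). CART variance-reduction splits, bootstrap samples of
// size n, `mtry` features tried per split, leaves hold >= min_leaf
// bootstrap observations.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cstdint>
#include <limits>
#include <cmath>

using namespace Rcpp;

namespace {

struct SplitMix {
  uint64_t s;
  explicit SplitMix(uint64_t seed) : s(seed) {}
  uint64_t next() {
    uint64_t z = (s += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  // modulo bias is negligible for the sizes used here and keeps the
  // stream implementation-independent
  int below(int n) { return static_cast<int>(next() % static_cast<uint64_t>(n)); }
};

struct Tree {
  std::vector<int> feature;      // -1 for leaf
  std::vector<double> threshold; // go left if x <= threshold
  std::vector<int> left, right;
  std::vector<double> value;     // leaf mean
  std::vector<bool> used;        // feature used anywhere in this tree

  int new_node() {
    feature.push_back(-1);
    threshold.push_back(0.0);
    left.push_back(-1);
    right.push_back(-1);
    value.push_back(0.0);
    return static_cast<int>(feature.size()) - 1;
  }

  double predict(const NumericMatrix& X, int row, int swap_feature,
                 double swap_value) const {
    int node = 0;
    while (feature[node] >= 0) {
      double v = (feature[node] == swap_feature)
                     ? swap_value
                     : X(row, feature[node]);
      node = (v <= threshold[node]) ? left[node] : right[node];
    }
    return value[node];
  }
};

struct Builder {
  const double* X;  // column-major n x p
  const double* y;
  int n_rows, min_leaf, mtry, p;
  SplitMix& rng;
  Tree& tree;
  std::vector<int> feat_pool;                   // for sampling mtry features
  std::vector<std::pair<double, double>> buf;   // (x value, y value)
  std::vector<int> samples;                     // bootstrap; partitioned in place
  const std::vector<double>* bin_lo = nullptr;  // per-feature low value,
  const std::vector<double>* bin_hi = nullptr;  // NaN when not binary

  Builder(const double* X_, const double* y_, int n_rows_, int p_,
          int min_leaf_, int mtry_, SplitMix& rng_, Tree& tree_)
      : X(X_), y(y_), n_rows(n_rows_), min_leaf(min_leaf_), mtry(mtry_),
        p(p_), rng(rng_), tree(tree_) {
    feat_pool.resize(p);
    for (int j = 0; j < p; ++j) feat_pool[j] = j;
    buf.reserve(n_rows);
  }

  // builds the subtree over samples[lo, hi)
  int build(int lo, int hi) {
    int node = tree.new_node();
    int n = hi - lo;
    double sum = 0.0;
    for (int k = lo; k < hi; ++k) sum += y[samples[k]];
    tree.value[node] = sum / n;
    if (n < 2 * min_leaf) return node;

    // draw mtry distinct candidate features (partial Fisher-Yates)
    for (int k = 0; k < mtry; ++k) {
      int j = k + rng.below(p - k);
      std::swap(feat_pool[k], feat_pool[j]);
    }

    int best_f = -1;
    double best_gain = -1.0, best_thr = 0.0;
    double parent_score = sum * sum / n;

    for (int k = 0; k < mtry; ++k) {
      int f = feat_pool[k];
      const double* col = X + static_cast<size_t>(f) * n_rows;
      double blo = (*bin_lo)[f];
      if (blo == blo) {  // binary feature: counting pass, no sort
        double sum_left = 0.0;
        int nl = 0;
        for (int q = lo; q < hi; ++q) {
          if (col[samples[q]] == blo) {
            sum_left += y[samples[q]];
            ++nl;
          }
        }
        int nr = n - nl;
        if (nl < min_leaf || nr < min_leaf) continue;
        double sum_right = sum - sum_left;
        double gain = sum_left * sum_left / nl + sum_right * sum_right / nr -
                      parent_score;
        if (gain > best_gain) {
          best_gain = gain;
          best_f = f;
          best_thr = blo + 0.5 * ((*bin_hi)[f] - blo);
        }
        continue;
      }
      buf.clear();
      for (int q = lo; q < hi; ++q) buf.emplace_back(col[samples[q]], y[samples[q]]);
      std::sort(buf.begin(), buf.end());
      if (buf.front().first == buf.back().first) continue;  // constant here
      double sum_left = 0.0;
      for (int i = 0; i < n - min_leaf; ++i) {
        sum_left += buf[i].second;
        int nl = i + 1;
        if (nl < min_leaf) continue;
        double xv = buf[i].first, xn = buf[i + 1].first;
        if (xv == xn) continue;  // no cut between equal values
        double sum_right = sum - sum_left;
        int nr = n - nl;
        double gain = sum_left * sum_left / nl + sum_right * sum_right / nr -
                      parent_score;
        if (gain > best_gain) {
          best_gain = gain;
          best_f = f;
          best_thr = xv + 0.5 * (xn - xv);
        }
      }
    }

    if (best_f < 0 || best_gain <= 0.0) return node;

    const double* bcol = X + static_cast<size_t>(best_f) * n_rows;
    double thr = best_thr;
    int mid = static_cast<int>(
        std::partition(samples.begin() + lo, samples.begin() + hi,
                       [&](int i) { return bcol[i] <= thr; }) -
        samples.begin());
    if (mid - lo < min_leaf || hi - mid < min_leaf) return node;

    tree.feature[node] = best_f;
    tree.threshold[node] = best_thr;
    tree.used[best_f] = true;
    tree.left[node] = build(lo, mid);
    tree.right[node] = build(mid, hi);
    return node;
  }
};

}  // namespace

// [[Rcpp::export(name = ".rf_fit_cpp")]]
List rf_fit_cpp(NumericMatrix X, NumericVector y, int ntree, int min_leaf,
                int mtry, double seed, bool importance) {
  int n = X.nrow(), p = X.ncol();
  if (n == 0 || p == 0) stop("empty feature matrix");
  if (mtry < 1) mtry = 1;
  if (mtry > p) mtry = p;

  NumericVector oob_sum(n, 0.0);
  IntegerVector oob_cnt(n, 0);
  NumericVector imp_sum(p, 0.0), imp_sumsq(p, 0.0);

  // precompute which features are binary (exactly two distinct values)
  std::vector<double> bin_lo(p, std::numeric_limits<double>::quiet_NaN()),
      bin_hi(p, std::numeric_limits<double>::quiet_NaN());
  {
    const double* xp = REAL(X);
    for (int f = 0; f < p; ++f) {
      const double* col = xp + static_cast<size_t>(f) * n;
      double v0 = col[0], v1 = std::numeric_limits<double>::quiet_NaN();
      bool binary = true;
      for (int i = 1; i < n; ++i) {
        double v = col[i];
        if (v == v0 || v == v1) continue;
        if (v1 != v1) { v1 = v; continue; }
        binary = false;
        break;
      }
      if (binary && v1 == v1) {
        bin_lo[f] = std::min(v0, v1);
        bin_hi[f] = std::max(v0, v1);
      }
    }
  }

  std::vector<char> inbag(n);
  std::vector<int> oob_idx;
  std::vector<double> oob_base;
  std::vector<int> perm;

  for (int t = 0; t < ntree; ++t) {
    SplitMix rng(static_cast<uint64_t>(seed) * 2654435761ULL +
                 static_cast<uint64_t>(t) + 1ULL);
    std::fill(inbag.begin(), inbag.end(), 0);
    Tree tree;
    tree.used.assign(p, false);
    Builder b(REAL(X), REAL(y), n, p, min_leaf, mtry, rng, tree);
    b.bin_lo = &bin_lo;
    b.bin_hi = &bin_hi;
    b.samples.resize(n);
    for (int i = 0; i < n; ++i) {
      int j = rng.below(n);
      b.samples[i] = j;
      inbag[j] = 1;
    }
    b.build(0, n);

    oob_idx.clear();
    for (int i = 0; i < n; ++i)
      if (!inbag[i]) oob_idx.push_back(i);
    int m = static_cast<int>(oob_idx.size());

    oob_base.resize(m);
    double mse_base = 0.0;
    for (int k = 0; k < m; ++k) {
      int i = oob_idx[k];
      double pred = tree.predict(X, i, -1, 0.0);
      oob_base[k] = pred;
      oob_sum[i] += pred;
      oob_cnt[i] += 1;
      double e = pred - y[i];
      mse_base += e * e;
    }
    if (m > 0) mse_base /= m;

    if (importance && m > 1) {
      perm.resize(m);
      for (int k = 0; k < m; ++k) perm[k] = oob_idx[k];
      for (int f = 0; f < p; ++f) {
        if (!tree.used[f]) continue;  // unused feature: exact zero increase
        // fresh permutation of the OOB rows for this feature
        for (int k = m - 1; k > 0; --k) {
          int j = rng.below(k + 1);
          std::swap(perm[k], perm[j]);
        }
        double mse_perm = 0.0;
        for (int k = 0; k < m; ++k) {
          int i = oob_idx[k];
          double pred = tree.predict(X, i, f, X(perm[k], f));
          double e = pred - y[i];
          mse_perm += e * e;
        }
        mse_perm /= m;
        double d = mse_perm - mse_base;
        imp_sum[f] += d;
        imp_sumsq[f] += d * d;
      }
    }
  }

  NumericVector oob_pred(n);
  for (int i = 0; i < n; ++i)
    oob_pred[i] = oob_cnt[i] > 0 ? oob_sum[i] / oob_cnt[i] : NA_REAL;

  NumericVector imp_mean(p), imp_sd(p);
  for (int f = 0; f < p; ++f) {
    double mean = imp_sum[f] / ntree;
    imp_mean[f] = mean;
    double var = ntree > 1
                     ? (imp_sumsq[f] - ntree * mean * mean) / (ntree - 1)
                     : 0.0;
    imp_sd[f] = var > 0 ? std::sqrt(var) : 0.0;
  }

  return List::create(_["oob_pred"] = oob_pred, _["oob_count"] = oob_cnt,
                      _["imp_mean"] = imp_mean, _["imp_sd"] = imp_sd);
}
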