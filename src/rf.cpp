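// Regression random forest with per-feature importance, built for the
// all-relevant feature-selection loop.  CART-style trees on bootstrap
// samples; variance impurity (sum of squared errors).  Importances:
//   - gini: total SSE decrease attributed to a feature, averaged over trees
//   - permutation (raw): mean increase in out-of-bag MSE when the feature's
//     OOB values are permuted, unscaled
// Bias-corrected impurity is assembled at the R level from permuted
// pseudo-variables and reuses the plain impurity accumulator here.
//
// Determinism contract: identical (X, y, hyperparameters, seed) give
// bit-identical importances on the same platform.  All randomness flows
// from one std::mt19937 seeded once per forest.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <random>
#include <cstdint>

using namespace Rcpp;

namespace {

struct Node {
  int var;        // split variable, -1 for leaf
  double split;   // go left if x <= split
  int left, right;
  double pred;    // leaf prediction (node mean)
};

inline int rnd_below(std::mt19937 &rng, int n) {
  return static_cast<int>(rng() % static_cast<uint32_t>(n));
}

class TreeBuilder {
public:
  // xcol: column-major contiguous copy of X (n rows), ycol: response copy
  TreeBuilder(const std::vector<double> &xcol, const std::vector<double> &y,
              int n, int p, int mtry, int min_node, std::mt19937 &rng,
              std::vector<double> &imp_acc)
      : x_(xcol), y_(y), n_(n), p_(p), mtry_(mtry), min_node_(min_node),
        rng_(rng), imp_(imp_acc), feat_pool_(p_), is_binary_(p_) {
    for (int j = 0; j < p_; ++j) feat_pool_[j] = j;
    // all columns arrive as small non-negative integers (0/1 indicators or
    // rank-transformed continuous values); record the domain size per
    // column for the counting-sort split search
    domain_.resize(p_);
    int maxdom = 2;
    for (int j = 0; j < p_; ++j) {
      const double *xj = &x_[static_cast<size_t>(j) * n_];
      double mx = 0.0;
      for (int i = 0; i < n_; ++i) mx = std::max(mx, xj[i]);
      domain_[j] = static_cast<int>(mx) + 1;
      is_binary_[j] = domain_[j] <= 2;
      maxdom = std::max(maxdom, domain_[j]);
    }
    bsum_.assign(maxdom, 0.0);
    bcnt_.assign(maxdom, 0);
  }

  std::vector<Node> nodes;
  std::vector<int> used_vars;  // unique split variables of this tree

  void build(std::vector<int> &idx) {
    used_flag_.assign(p_, 0);
    nodes.clear();
    used_vars.clear();
    grow(idx, 0, static_cast<int>(idx.size()));
    for (int j = 0; j < p_; ++j)
      if (used_flag_[j]) used_vars.push_back(j);
  }

  inline double xv(int row, int col) const {
    return x_[static_cast<size_t>(col) * n_ + row];
  }

  double predict(int row) const {
    int k = 0;
    while (nodes[k].var >= 0)
      k = (xv(row, nodes[k].var) <= nodes[k].split) ? nodes[k].left
                                                    : nodes[k].right;
    return nodes[k].pred;
  }

  // Predict with feature `var` read from a substitute row (OOB permutation).
  double predict_sub(int row, int var, int sub_row) const {
    int k = 0;
    while (nodes[k].var >= 0) {
      const int v = nodes[k].var;
      const double x = (v == var) ? xv(sub_row, v) : xv(row, v);
      k = (x <= nodes[k].split) ? nodes[k].left : nodes[k].right;
    }
    return nodes[k].pred;
  }

private:
  const std::vector<double> &x_;
  const std::vector<double> &y_;
  const int n_, p_, mtry_, min_node_;
  std::mt19937 &rng_;
  std::vector<double> &imp_;
  std::vector<int> feat_pool_;
  std::vector<int> domain_;
  std::vector<char> is_binary_;
  std::vector<char> used_flag_;
  std::vector<double> bsum_;            // counting-sort accumulators
  std::vector<int> bcnt_;
  std::vector<std::pair<double, double>> buf_;  // (x, y) for split search

  // Grow the subtree over idx[lo, hi); returns node index.
  int grow(std::vector<int> &idx, int lo, int hi) {
    const int n = hi - lo;
    double sum = 0.0, sumsq = 0.0;
    for (int i = lo; i < hi; ++i) {
      const double v = y_[idx[i]];
      sum += v;
      sumsq += v * v;
    }
    const double mean = sum / n;
    const double sse = sumsq - sum * sum / n;

    const int self = static_cast<int>(nodes.size());
    nodes.push_back({-1, 0.0, -1, -1, mean});
    if (n < 2 * min_node_ || sse <= 1e-12) return self;

    // sample mtry candidate features without replacement
    int best_var = -1, pool_n = p_;
    double best_dec = 0.0, best_split = 0.0;
    for (int t = 0; t < mtry_ && pool_n > 0; ++t, --pool_n) {
      const int r = rnd_below(rng_, pool_n);
      const int j = feat_pool_[r];
      std::swap(feat_pool_[r], feat_pool_[pool_n - 1]);

      const double *xj = &x_[static_cast<size_t>(j) * n_];
      if (is_binary_[j]) {
        double sum1 = 0.0;
        int n1 = 0;
        for (int i = lo; i < hi; ++i) {
          const int row = idx[i];
          if (xj[row] == 1.0) {
            sum1 += y_[row];
            ++n1;
          }
        }
        if (n1 == 0 || n1 == n) continue;
        const double sum0 = sum - sum1;
        const int n0 = n - n1;
        const double dec =
            sum0 * sum0 / n0 + sum1 * sum1 / n1 - sum * sum / n;
        if (dec > best_dec) {
          best_dec = dec;
          best_var = j;
          best_split = 0.5;
        }
        continue;
      }

      const int dom = domain_[j];
      if (n * 4 >= dom) {
        // counting sort over the column's integer domain
        for (int i = lo; i < hi; ++i) {
          const int v = static_cast<int>(xj[idx[i]]);
          bsum_[v] += y_[idx[i]];
          ++bcnt_[v];
        }
        double lsum = 0.0;
        int nl = 0, prev = -1;
        for (int v = 0; v < dom; ++v) {
          if (!bcnt_[v]) continue;
          if (prev >= 0 && nl > 0 && nl < n) {
            const int nr = n - nl;
            const double rsum = sum - lsum;
            const double dec =
                lsum * lsum / nl + rsum * rsum / nr - sum * sum / n;
            if (dec > best_dec) {
              best_dec = dec;
              best_var = j;
              best_split = prev + 0.5 * (v - prev);
            }
          }
          lsum += bsum_[v];
          nl += bcnt_[v];
          prev = v;
          bsum_[v] = 0.0;
          bcnt_[v] = 0;
        }
        continue;
      }

      buf_.resize(n);
      for (int i = 0; i < n; ++i) {
        const int row = idx[lo + i];
        buf_[i] = {xj[row], y_[row]};
      }
      std::sort(buf_.begin(), buf_.end());
      if (buf_.front().first == buf_.back().first) continue;  // constant

      double lsum = 0.0;
      for (int i = 0; i < n - 1; ++i) {
        lsum += buf_[i].second;
        if (buf_[i].first == buf_[i + 1].first) continue;
        const int nl = i + 1, nr = n - nl;
        const double rsum = sum - lsum;
        const double dec =
            lsum * lsum / nl + rsum * rsum / nr - sum * sum / n;
        if (dec > best_dec) {
          best_dec = dec;
          best_var = j;
          best_split = buf_[i].first +
                       0.5 * (buf_[i + 1].first - buf_[i].first);
        }
      }
    }
    if (best_var < 0) return self;

    imp_[best_var] += best_dec;
    used_flag_[best_var] = 1;

    // in-place partition of idx[lo, hi)
    int mid = lo;
    const double *xb = &x_[static_cast<size_t>(best_var) * n_];
    for (int i = lo; i < hi; ++i)
      if (xb[idx[i]] <= best_split) std::swap(idx[i], idx[mid++]);
    // numeric safety: a midpoint between distinct values always separates
    if (mid == lo || mid == hi) return self;

    nodes[self].var = best_var;
    nodes[self].split = best_split;
    nodes[self].left = grow(idx, lo, mid);
    nodes[self].right = grow(idx, mid, hi);
    return self;
  }
};

}  // namespace

// [[Rcpp::export(name = ".rf_forest_cpp")]]
List rf_forest_cpp(NumericMatrix X, NumericVector y, int n_trees, int mtry,
                   int min_node, int seed, bool permutation) {
  const int n = X.nrow(), p = X.ncol();
  std::mt19937 rng(static_cast<uint32_t>(seed));

  std::vector<double> xcol(X.begin(), X.end());  // column-major copy
  // CART trees are invariant to monotone transforms of a feature, so each
  // non-binary column is replaced by its (tie-aware) rank.  Small integer
  // domains admit a counting-sort split search in the builder.
  {
    std::vector<int> ord(n);
    for (int j = 0; j < p; ++j) {
      double *xj = &xcol[static_cast<size_t>(j) * n];
      bool bin = true;
      for (int i = 0; i < n && bin; ++i) bin = (xj[i] == 0.0 || xj[i] == 1.0);
      if (bin) continue;
      for (int i = 0; i < n; ++i) ord[i] = i;
      std::sort(ord.begin(), ord.end(),
                [&](int a, int b) { return xj[a] < xj[b]; });
      std::vector<double> rk(n);
      int r = 0;
      rk[ord[0]] = 0;
      for (int i = 1; i < n; ++i) {
        if (xj[ord[i]] != xj[ord[i - 1]]) ++r;
        rk[ord[i]] = r;
      }
      std::copy(rk.begin(), rk.end(), xj);
    }
  }
  std::vector<double> yv(y.begin(), y.end());
  std::vector<double> gini(p, 0.0), perm(p, 0.0);
  std::vector<int> idx, oob, perm_map, inbag(n);
  TreeBuilder tree(xcol, yv, n, p, mtry, min_node, rng, gini);

  for (int t = 0; t < n_trees; ++t) {
    std::fill(inbag.begin(), inbag.end(), 0);
    idx.resize(n);
    for (int i = 0; i < n; ++i) {
      const int r = rnd_below(rng, n);
      idx[i] = r;
      inbag[r]++;
    }
    tree.build(idx);

    if (!permutation) continue;
    oob.clear();
    for (int i = 0; i < n; ++i)
      if (!inbag[i]) oob.push_back(i);
    const int m = static_cast<int>(oob.size());
    if (m < 2) continue;

    double mse0 = 0.0;
    for (int i = 0; i < m; ++i) {
      const double e = tree.predict(oob[i]) - yv[oob[i]];
      mse0 += e * e;
    }
    mse0 /= m;

    perm_map.resize(m);
    for (const int j : tree.used_vars) {
      for (int i = 0; i < m; ++i) perm_map[i] = i;
      for (int i = m - 1; i > 0; --i)
        std::swap(perm_map[i], perm_map[rnd_below(rng, i + 1)]);
      double mse1 = 0.0;
      for (int i = 0; i < m; ++i) {
        const double e =
            tree.predict_sub(oob[i], j, oob[perm_map[i]]) - yv[oob[i]];
        mse1 += e * e;
      }
      perm[j] += mse1 / m - mse0;
    }
  }

  NumericVector g(p), pr(p);
  for (int j = 0; j < p; ++j) {
    g[j] = gini[j] / n_trees;
    pr[j] = perm[j] / n_trees;
  }
  return List::create(_["gini"] = g, _["permutation"] = pr);
}
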