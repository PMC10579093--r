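// Gradient-boosted decision trees with exact greedy split search,
// second-order (Newton) boosting on the binary logistic objective,
// per-tree column subsampling, and exact per-tree Shapley attributions
// (subset enumeration over each tree's used features with cover-weighted
// conditional expectations). Trees are shallow (depth <= 3 in the default
// configuration), so a tree uses at most 2^depth - 1 distinct features and
// exhaustive subset enumeration is cheap and exact.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
#include <algorithm>

using namespace Rcpp;

namespace {

struct Tree {
  // flat arrays; feature == -1 marks a leaf
  std::vector<int> feature;
  std::vector<double> thr;
  std::vector<int> left, right;
  std::vector<double> value;  // leaf value (already scaled by eta)
  std::vector<double> cover;  // sum of hessian-weights of training rows
};

inline double sigmoid(double z) { return 1.0 / (1.0 + std::exp(-z)); }

// deterministic 32-bit generator (xorshift) so results do not depend on the
// platform's std:: distributions
struct XorShift {
  uint32_t s;
  explicit XorShift(uint32_t seed) : s(seed ? seed : 0x9E3779B9u) {}
  uint32_t next() {
    uint32_t x = s;
    x ^= x << 13; x ^= x >> 17; x ^= x << 5;
    return s = x;
  }
  // integer in [0, n)
  uint32_t below(uint32_t n) { return next() % n; }
};

struct Builder {
  const NumericMatrix& X;
  const std::vector<double>& g;
  const std::vector<double>& h;
  const std::vector<std::vector<int> >& order;  // per-feature sorted row ids
  const std::vector<int>& feats;                // column-subsampled features
  int max_depth;
  double gamma_, lambda_, min_child_weight, eta;
  std::vector<uint8_t> in_node;
  Tree tree;

  Builder(const NumericMatrix& X_, const std::vector<double>& g_,
          const std::vector<double>& h_,
          const std::vector<std::vector<int> >& order_,
          const std::vector<int>& feats_, int max_depth_, double gamma__,
          double lambda__, double mcw_, double eta_)
      : X(X_), g(g_), h(h_), order(order_), feats(feats_),
        max_depth(max_depth_), gamma_(gamma__), lambda_(lambda__),
        min_child_weight(mcw_), eta(eta_), in_node(X_.nrow(), 0) {}

  int new_node() {
    tree.feature.push_back(-1);
    tree.thr.push_back(0.0);
    tree.left.push_back(-1);
    tree.right.push_back(-1);
    tree.value.push_back(0.0);
    tree.cover.push_back(0.0);
    return (int)tree.feature.size() - 1;
  }

  int build(const std::vector<int>& rows, int depth) {
    int id = new_node();
    double G = 0.0, H = 0.0;
    for (int i : rows) { G += g[i]; H += h[i]; }
    tree.cover[id] = H;
    if (depth >= max_depth || rows.size() < 2) {
      tree.value[id] = -eta * G / (H + lambda_);
      return id;
    }
    // exact greedy split search over the subsampled features
    double best_gain = 0.0, best_thr = 0.0;
    int best_feat = -1;
    const double parent_score = G * G / (H + lambda_);
    for (int i : rows) in_node[i] = 1;
    for (int j : feats) {
      double GL = 0.0, HL = 0.0;
      double prev = 0.0;
      bool have_prev = false;
      for (int i : order[j]) {
        if (!in_node[i]) continue;
        double x = X(i, j);
        if (have_prev && x > prev) {
          double HR = H - HL;
          if (HL >= min_child_weight && HR >= min_child_weight) {
            double GR = G - GL;
            double gain = 0.5 * (GL * GL / (HL + lambda_) +
                                 GR * GR / (HR + lambda_) - parent_score) -
                          gamma_;
            if (gain > best_gain + 1e-12) {
              best_gain = gain;
              best_feat = j;
              best_thr = 0.5 * (prev + x);
            }
          }
        }
        GL += g[i]; HL += h[i];
        prev = x; have_prev = true;
      }
    }
    for (int i : rows) in_node[i] = 0;
    if (best_feat < 0) {
      tree.value[id] = -eta * G / (H + lambda_);
      return id;
    }
    std::vector<int> lrows, rrows;
    lrows.reserve(rows.size()); rrows.reserve(rows.size());
    for (int i : rows) {
      if (X(i, best_feat) < best_thr) lrows.push_back(i); else rrows.push_back(i);
    }
    tree.feature[id] = best_feat;
    tree.thr[id] = best_thr;
    tree.left[id] = build(lrows, depth + 1);
    tree.right[id] = build(rrows, depth + 1);
    return id;
  }
};

double predict_tree(const Tree& t, const NumericMatrix& X, int i) {
  int node = 0;
  while (t.feature[node] >= 0) {
    node = (X(i, t.feature[node]) < t.thr[node]) ? t.left[node] : t.right[node];
  }
  return t.value[node];
}

Tree tree_from_list(const List& tl) {
  Tree t;
  IntegerVector f = tl["feature"], l = tl["left"], r = tl["right"];
  NumericVector th = tl["thr"], v = tl["value"], c = tl["cover"];
  t.feature.assign(f.begin(), f.end());
  t.left.assign(l.begin(), l.end());
  t.right.assign(r.begin(), r.end());
  t.thr.assign(th.begin(), th.end());
  t.value.assign(v.begin(), v.end());
  t.cover.assign(c.begin(), c.end());
  return t;
}

// cover-weighted conditional expectation of the tree output given the
// features in subset S (bit mask over `used`) fixed at x's values
double eval_subset(const Tree& t, int node, const NumericMatrix& X, int i,
                   uint32_t mask, const std::vector<int>& featpos) {
  int f = t.feature[node];
  if (f < 0) return t.value[node];
  int pos = featpos[f];
  if (mask & (1u << pos)) {
    int nxt = (X(i, f) < t.thr[node]) ? t.left[node] : t.right[node];
    return eval_subset(t, nxt, X, i, mask, featpos);
  }
  double cl = t.cover[t.left[node]], cr = t.cover[t.right[node]];
  double tot = cl + cr;
  if (tot <= 0) return t.value[node];
  return (cl * eval_subset(t, t.left[node], X, i, mask, featpos) +
          cr * eval_subset(t, t.right[node], X, i, mask, featpos)) / tot;
}

void used_features(const Tree& t, std::vector<int>& used,
                   std::vector<int>& featpos, int p) {
  used.clear();
  featpos.assign(p, -1);
  for (size_t n = 0; n < t.feature.size(); ++n) {
    int f = t.feature[n];
    if (f >= 0 && featpos[f] < 0) {
      featpos[f] = (int)used.size();
      used.push_back(f);
    }
  }
}

const double FACT[9] = {1, 1, 2, 6, 24, 120, 720, 5040, 40320};

}  // namespace

// [[Rcpp::export(name = ".gbt_fit_cpp")]]
List gbt_fit_cpp(NumericMatrix X, NumericVector y, NumericVector w,
                 int nrounds, int max_depth, double eta, double colsample,
                 double gamma, double lambda, double min_child_weight,
                 double base_margin, int seed) {
  const int n = X.nrow(), p = X.ncol();
  if (n < 2) stop("need at least two rows");
  // presort each column once
  std::vector<std::vector<int> > order(p);
  for (int j = 0; j < p; ++j) {
    order[j].resize(n);
    for (int i = 0; i < n; ++i) order[j][i] = i;
    const int jj = j;
    std::stable_sort(order[j].begin(), order[j].end(),
                     [&X, jj](int a, int b) { return X(a, jj) < X(b, jj); });
  }
  std::vector<double> margin(n, base_margin), g(n), h(n);
  std::vector<int> allrows(n);
  for (int i = 0; i < n; ++i) allrows[i] = i;
  XorShift rng((uint32_t)seed);
  int k = std::max(1, (int)std::lround(colsample * p));
  List trees(nrounds);
  std::vector<int> featpool(p);
  for (int j = 0; j < p; ++j) featpool[j] = j;
  for (int round = 0; round < nrounds; ++round) {
    for (int i = 0; i < n; ++i) {
      double pr = sigmoid(margin[i]);
      g[i] = (pr - y[i]) * w[i];
      h[i] = std::max(pr * (1.0 - pr), 1e-16) * w[i];
    }
    // column subsample: partial Fisher-Yates
    std::vector<int> feats(featpool);
    for (int j = 0; j < k; ++j) {
      int r = j + (int)rng.below((uint32_t)(p - j));
      std::swap(feats[j], feats[r]);
    }
    feats.resize(k);
    std::sort(feats.begin(), feats.end());
    Builder b(X, g, h, order, feats, max_depth, gamma, lambda,
              min_child_weight, eta);
    b.build(allrows, 0);
    for (int i = 0; i < n; ++i) margin[i] += predict_tree(b.tree, X, i);
    trees[round] = List::create(
        _["feature"] = IntegerVector(b.tree.feature.begin(), b.tree.feature.end()),
        _["thr"] = NumericVector(b.tree.thr.begin(), b.tree.thr.end()),
        _["left"] = IntegerVector(b.tree.left.begin(), b.tree.left.end()),
        _["right"] = IntegerVector(b.tree.right.begin(), b.tree.right.end()),
        _["value"] = NumericVector(b.tree.value.begin(), b.tree.value.end()),
        _["cover"] = NumericVector(b.tree.cover.begin(), b.tree.cover.end()));
  }
  return List::create(_["trees"] = trees, _["base_margin"] = base_margin,
                      _["nfeat"] = p);
}

// [[Rcpp::export(name = ".gbt_predict_cpp")]]
NumericVector gbt_predict_cpp(List model, NumericMatrix X) {
  List trees = model["trees"];
  double base = as<double>(model["base_margin"]);
  const int n = X.nrow();
  NumericVector out(n, base);
  for (int t = 0; t < trees.size(); ++t) {
    Tree tr = tree_from_list(trees[t]);
    for (int i = 0; i < n; ++i) out[i] += predict_tree(tr, X, i);
  }
  return out;
}

// Exact Shapley values per sample on the margin scale. Returns an
// n x (p + 1) matrix; the last column is the expected value (bias) so that
// rowSums(out) equals the predicted margin exactly.
// [[Rcpp::export(name = ".gbt_shap_cpp")]]
NumericMatrix gbt_shap_cpp(List model, NumericMatrix X) {
  List trees = model["trees"];
  double base = as<double>(model["base_margin"]);
  const int n = X.nrow(), p = X.ncol();
  NumericMatrix out(n, p + 1);
  std::vector<int> used, featpos;
  std::vector<double> v;
  for (int t = 0; t < trees.size(); ++t) {
    Tree tr = tree_from_list(trees[t]);
    used_features(tr, used, featpos, p);
    const int u = (int)used.size();
    const uint32_t nsub = 1u << u;
    v.assign(nsub, 0.0);
    for (int i = 0; i < n; ++i) {
      for (uint32_t S = 0; S < nsub; ++S)
        v[S] = eval_subset(tr, 0, X, i, S, featpos);
      out(i, p) += v[0];
      for (int a = 0; a < u; ++a) {
        uint32_t bit = 1u << a;
        double phi = 0.0;
        for (uint32_t S = 0; S < nsub; ++S) {
          if (S & bit) continue;
          int s = __builtin_popcount(S);
          double wgt = FACT[s] * FACT[u - s - 1] / FACT[u];
          phi += wgt * (v[S | bit] - v[S]);
        }
        out(i, used[a]) += phi;
      }
    }
  }
  for (int i = 0; i < n; ++i) out(i, p) += base;
  return out;
}

// Exact Shapley interaction values per sample (Shapley-Taylor style split:
// off-diagonal pair (i,j) gets half of the pairwise interaction index each
// way; diagonal is the remainder so rows sum to the Shapley value and the
// whole matrix sums to margin - base). Returns a p x p x n array.
// [[Rcpp::export(name = ".gbt_shap_inter_cpp")]]
NumericVector gbt_shap_inter_cpp(List model, NumericMatrix X) {
  List trees = model["trees"];
  const int n = X.nrow(), p = X.ncol();
  NumericVector out(Dimension(p, p, n));
  std::vector<int> used, featpos;
  std::vector<double> v;
  for (int t = 0; t < trees.size(); ++t) {
    Tree tr = tree_from_list(trees[t]);
    used_features(tr, used, featpos, p);
    const int u = (int)used.size();
    const uint32_t nsub = 1u << u;
    v.assign(nsub, 0.0);
    for (int i = 0; i < n; ++i) {
      for (uint32_t S = 0; S < nsub; ++S)
        v[S] = eval_subset(tr, 0, X, i, S, featpos);
      double* slab = &out[(size_t)i * p * p];
      // Shapley values per used feature (for the diagonal remainder)
      for (int a = 0; a < u; ++a) {
        uint32_t abit = 1u << a;
        double phi = 0.0;
        for (uint32_t S = 0; S < nsub; ++S) {
          if (S & abit) continue;
          int s = __builtin_popcount(S);
          phi += FACT[s] * FACT[u - s - 1] / FACT[u] * (v[S | abit] - v[S]);
        }
        slab[(size_t)used[a] * p + used[a]] += phi;
      }
      if (u >= 2) {
        for (int a = 0; a < u; ++a) {
          for (int b = a + 1; b < u; ++b) {
            uint32_t abit = 1u << a, bbit = 1u << b;
            double inter = 0.0;
            for (uint32_t S = 0; S < nsub; ++S) {
              if (S & (abit | bbit)) continue;
              int s = __builtin_popcount(S);
              double wgt = FACT[s] * FACT[u - s - 2] / FACT[u - 1];
              inter += wgt * (v[S | abit | bbit] - v[S | abit] -
                              v[S | bbit] + v[S]);
            }
            int fa = used[a], fb = used[b];
            slab[(size_t)fa * p + fb] += 0.5 * inter;
            slab[(size_t)fb * p + fa] += 0.5 * inter;
            slab[(size_t)fa * p + fa] -= 0.5 * inter;
            slab[(size_t)fb * p + fb] -= 0.5 * inter;
          }
        }
      }
    }
  }
  return out;
}

// Sample entropy (Richman & Moorman): -log(A/B) with B the number of
// template pairs of length m within Chebyshev tolerance r and A the same
// for length m + 1. Self-matches excluded. Returns NA when A or B is zero
// (entropy undefined); a constant series gives 0.
// [[Rcpp::export(name = ".sampen_cpp")]]
double sampen_cpp(NumericVector x, int m, double r) {
  const int n = x.size();
  const int N = n - m;  // number of (m+1)-length templates = n - m
  if (N < 2) return NA_REAL;
  long long A = 0, B = 0;
  for (int i = 0; i < N; ++i) {
    for (int j = i + 1; j < N; ++j) {
      double d = 0.0;
      for (int k = 0; k < m; ++k) {
        double dd = std::fabs(x[i + k] - x[j + k]);
        if (dd > d) d = dd;
      }
      if (d <= r) {
        ++B;
        double dd = std::fabs(x[i + m] - x[j + m]);
        if (std::max(d, dd) <= r) ++A;
      }
    }
  }
  if (B == 0 || A == 0) return NA_REAL;
  return -std::log((double)A / (double)B);
}
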