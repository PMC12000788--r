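// Native tree-ensemble primitives: a single CART-style regression tree
// learner with three growth policies (depth-wise for bagged forests,
// leaf-wise for LightGBM-style boosting, oblivious/symmetric levels for
// CatBoost-style boosting), prediction, path-dependent TreeSHAP, and
// sample entropy for minute-level heart-rate series.
//
// The learner minimises weighted squared error with optional Newton
// (gradient/hessian) leaf values, which covers both class-probability
// bagging (hessian = 1, leaf = mean of 0/1 labels, equivalent to Gini)
// and logistic-loss boosting (y = residual, hessian = p(1-p)).

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <queue>
#include <random>
#include <vector>

using namespace Rcpp;

namespace {

struct Tree {
  std::vector<int> feature;      // -1 for leaves
  std::vector<double> threshold; // x <= threshold -> left
  std::vector<int> left, right;
  std::vector<double> value;     // Newton value G/(H+lambda), all nodes
  std::vector<double> cover;     // training rows routed through node
};

struct Split {
  int feat = -1;
  double thr = 0.0;
  double gain = -1.0;
};

struct Problem {
  const NumericMatrix& X;
  const NumericVector& g; // gradient / response
  const NumericVector& h; // hessian / weights
  double lambda;
  int min_leaf;
};

double node_value(const Problem& p, const std::vector<int>& rows) {
  double G = 0.0, H = 0.0;
  for (int r : rows) { G += p.g[r]; H += p.h[r]; }
  if (H + p.lambda <= 0.0) return 0.0;
  return G / (H + p.lambda);
}

double score(double G, double H, double lambda) {
  return (H + lambda > 0.0) ? G * G / (H + lambda) : 0.0;
}

// Best split for one node over a sampled feature subset.
Split best_split(const Problem& p, const std::vector<int>& rows,
                 const std::vector<int>& feats) {
  Split best;
  const int n = static_cast<int>(rows.size());
  if (n < 2 * p.min_leaf) return best;
  double G = 0.0, H = 0.0;
  for (int r : rows) { G += p.g[r]; H += p.h[r]; }
  const double parent = score(G, H, p.lambda);

  std::vector<std::pair<double, int>> vals(n);
  for (int f : feats) {
    for (int i = 0; i < n; ++i) vals[i] = {p.X(rows[i], f), rows[i]};
    std::sort(vals.begin(), vals.end());
    if (vals.front().first == vals.back().first) continue;
    double GL = 0.0, HL = 0.0;
    for (int i = 0; i < n - 1; ++i) {
      GL += p.g[vals[i].second];
      HL += p.h[vals[i].second];
      if (vals[i].first == vals[i + 1].first) continue;
      const int nl = i + 1, nr = n - nl;
      if (nl < p.min_leaf || nr < p.min_leaf) continue;
      const double gain =
          score(GL, HL, p.lambda) + score(G - GL, H - HL, p.lambda) - parent;
      if (gain > best.gain + 1e-12) {
        best.gain = gain;
        best.feat = f;
        best.thr = 0.5 * (vals[i].first + vals[i + 1].first);
      }
    }
  }
  if (best.gain <= 1e-10) best.feat = -1;
  return best;
}

std::vector<int> sample_feats(int p, int mtry, std::mt19937& rng) {
  std::vector<int> all(p);
  for (int i = 0; i < p; ++i) all[i] = i;
  if (mtry >= p) return all;
  for (int i = 0; i < mtry; ++i) {
    std::uniform_int_distribution<int> d(i, p - 1);
    std::swap(all[i], all[d(rng)]);
  }
  all.resize(mtry);
  return all;
}

int add_node(Tree& t, const Problem& p, const std::vector<int>& rows) {
  t.feature.push_back(-1);
  t.threshold.push_back(0.0);
  t.left.push_back(-1);
  t.right.push_back(-1);
  t.value.push_back(node_value(p, rows));
  t.cover.push_back(static_cast<double>(rows.size()));
  return static_cast<int>(t.feature.size()) - 1;
}

void partition(const Problem& p, const std::vector<int>& rows, int feat,
               double thr, std::vector<int>& lo, std::vector<int>& hi) {
  for (int r : rows) (p.X(r, feat) <= thr ? lo : hi).push_back(r);
}

struct Open {
  int id;
  int depth;
  std::vector<int> rows;
  Split best;
};

void grow_depthwise(Tree& t, const Problem& p, std::vector<int> rows,
                    int max_depth, int mtry, std::mt19937& rng) {
  std::vector<Open> stack;
  int root = add_node(t, p, rows);
  stack.push_back({root, 0, std::move(rows), Split()});
  while (!stack.empty()) {
    Open nd = std::move(stack.back());
    stack.pop_back();
    if (nd.depth >= max_depth) continue;
    Split s = best_split(p, nd.rows, sample_feats(p.X.ncol(), mtry, rng));
    if (s.feat < 0) continue;
    std::vector<int> lo, hi;
    partition(p, nd.rows, s.feat, s.thr, lo, hi);
    t.feature[nd.id] = s.feat;
    t.threshold[nd.id] = s.thr;
    int l = add_node(t, p, lo), r = add_node(t, p, hi);
    t.left[nd.id] = l;
    t.right[nd.id] = r;
    stack.push_back({l, nd.depth + 1, std::move(lo), Split()});
    stack.push_back({r, nd.depth + 1, std::move(hi), Split()});
  }
}

void grow_leafwise(Tree& t, const Problem& p, std::vector<int> rows,
                   int max_depth, int max_leaves, int mtry,
                   std::mt19937& rng) {
  std::vector<Open> open;
  int root = add_node(t, p, rows);
  Open o{root, 0, std::move(rows), Split()};
  o.best = best_split(p, o.rows, sample_feats(p.X.ncol(), mtry, rng));
  open.push_back(std::move(o));
  int n_leaves = 1;
  while (n_leaves < max_leaves) {
    int pick = -1;
    double g = 0.0;
    for (size_t i = 0; i < open.size(); ++i)
      if (open[i].best.feat >= 0 && open[i].best.gain > g) {
        g = open[i].best.gain;
        pick = static_cast<int>(i);
      }
    if (pick < 0) break;
    Open nd = std::move(open[pick]);
    open.erase(open.begin() + pick);
    std::vector<int> lo, hi;
    partition(p, nd.rows, nd.best.feat, nd.best.thr, lo, hi);
    t.feature[nd.id] = nd.best.feat;
    t.threshold[nd.id] = nd.best.thr;
    int l = add_node(t, p, lo), r = add_node(t, p, hi);
    t.left[nd.id] = l;
    t.right[nd.id] = r;
    ++n_leaves;
    for (int child = 0; child < 2; ++child) {
      Open c{child == 0 ? l : r, nd.depth + 1,
             child == 0 ? std::move(lo) : std::move(hi), Split()};
      if (c.depth < max_depth)
        c.best = best_split(p, c.rows, sample_feats(p.X.ncol(), mtry, rng));
      open.push_back(std::move(c));
    }
  }
}

// Symmetric (oblivious) levels: one shared (feature, threshold) per depth,
// chosen by summed gain across the level, using quantised candidate cuts.
void grow_oblivious(Tree& t, const Problem& p, std::vector<int> rows,
                    int max_depth, int mtry, std::mt19937& rng) {
  const int nbin = 32;
  int root = add_node(t, p, rows);
  std::vector<std::pair<int, std::vector<int>>> level;
  level.push_back({root, std::move(rows)});
  for (int depth = 0; depth < max_depth; ++depth) {
    std::vector<int> feats = sample_feats(p.X.ncol(), mtry, rng);
    int best_f = -1;
    double best_thr = 0.0, best_gain = 1e-10;
    const int n_leaves = static_cast<int>(level.size());
    for (int f : feats) {
      // candidate cuts: quantiles of pooled values at this level
      std::vector<double> pool;
      for (auto& nd : level)
        for (int r : nd.second) pool.push_back(p.X(r, f));
      if (pool.empty()) continue;
      std::sort(pool.begin(), pool.end());
      std::vector<double> cuts;
      for (int b = 1; b < nbin; ++b) {
        double q = pool[static_cast<size_t>(
            std::min<double>(pool.size() - 1.0,
                             std::floor(b * pool.size() /
                                        static_cast<double>(nbin))))];
        if (cuts.empty() || q > cuts.back()) cuts.push_back(q);
      }
      if (!cuts.empty() && cuts.back() >= pool.back()) cuts.pop_back();
      if (cuts.empty()) continue;
      const int nc = static_cast<int>(cuts.size());
      // histogram accumulation: one pass over rows per leaf, then a
      // prefix scan yields the summed gain for every cut at once
      std::vector<double> gain(nc, 0.0);
      for (auto& nd : level) {
        std::vector<double> hg(nc + 1, 0.0), hh(nc + 1, 0.0);
        double G = 0.0, H = 0.0;
        for (int r : nd.second) {
          const double v = p.X(r, f);
          int b = static_cast<int>(
              std::upper_bound(cuts.begin(), cuts.end(), v) - cuts.begin());
          hg[b] += p.g[r];
          hh[b] += p.h[r];
          G += p.g[r];
          H += p.h[r];
        }
        const double parent = score(G, H, p.lambda);
        double GL = 0.0, HL = 0.0;
        for (int c = 0; c < nc; ++c) {
          GL += hg[c];
          HL += hh[c];
          gain[c] += score(GL, HL, p.lambda) +
                     score(G - GL, H - HL, p.lambda) - parent;
        }
      }
      for (int c = 0; c < nc; ++c)
        if (gain[c] > best_gain) {
          best_gain = gain[c];
          best_f = f;
          best_thr = cuts[c];
        }
    }
    (void)n_leaves;
    if (best_f < 0) break;
    std::vector<std::pair<int, std::vector<int>>> next;
    for (auto& nd : level) {
      std::vector<int> lo, hi;
      partition(p, nd.second, best_f, best_thr, lo, hi);
      t.feature[nd.first] = best_f;
      t.threshold[nd.first] = best_thr;
      int l = add_node(t, p, lo), r = add_node(t, p, hi);
      // empty child keeps the parent's value so predictions stay defined;
      // epsilon cover keeps TreeSHAP's cover ratios finite
      if (lo.empty()) { t.value[l] = t.value[nd.first]; t.cover[l] = 1e-9; }
      if (hi.empty()) { t.value[r] = t.value[nd.first]; t.cover[r] = 1e-9; }
      t.left[nd.first] = l;
      t.right[nd.first] = r;
      next.push_back({l, std::move(lo)});
      next.push_back({r, std::move(hi)});
    }
    level = std::move(next);
  }
}

List tree_to_list(const Tree& t) {
  return List::create(_["feature"] = wrap(t.feature),
                      _["threshold"] = wrap(t.threshold),
                      _["left"] = wrap(t.left), _["right"] = wrap(t.right),
                      _["value"] = wrap(t.value),
                      _["cover"] = wrap(t.cover));
}

Tree tree_from_list(const List& l) {
  Tree t;
  t.feature = as<std::vector<int>>(l["feature"]);
  t.threshold = as<std::vector<double>>(l["threshold"]);
  t.left = as<std::vector<int>>(l["left"]);
  t.right = as<std::vector<int>>(l["right"]);
  t.value = as<std::vector<double>>(l["value"]);
  t.cover = as<std::vector<double>>(l["cover"]);
  return t;
}

} // namespace

// [[Rcpp::export(name = ".fit_tree_cpp")]]
List fit_tree_cpp(NumericMatrix X, NumericVector g, NumericVector h,
                  IntegerVector rows, int max_depth, int max_leaves,
                  int min_leaf, int mtry, double lambda, int growth,
                  int seed) {
  Problem p{X, g, h, lambda, min_leaf};
  std::mt19937 rng(static_cast<unsigned>(seed));
  std::vector<int> rws(rows.begin(), rows.end());
  Tree t;
  if (growth == 0)
    grow_depthwise(t, p, std::move(rws), max_depth, mtry, rng);
  else if (growth == 1)
    grow_leafwise(t, p, std::move(rws), max_depth, max_leaves, mtry, rng);
  else
    grow_oblivious(t, p, std::move(rws), max_depth, mtry, rng);
  return tree_to_list(t);
}

// [[Rcpp::export(name = ".predict_tree_cpp")]]
NumericVector predict_tree_cpp(List tree, NumericMatrix X) {
  Tree t = tree_from_list(tree);
  const int n = X.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    int j = 0;
    while (t.feature[j] >= 0)
      j = (X(i, t.feature[j]) <= t.threshold[j]) ? t.left[j] : t.right[j];
    out[i] = t.value[j];
  }
  return out;
}

namespace {

struct PathElem {
  int d;
  double z, o, w;
};

void extend_path(std::vector<PathElem>& m, double pz, double po, int pi) {
  const int l = static_cast<int>(m.size());
  m.push_back({pi, pz, po, l == 0 ? 1.0 : 0.0});
  for (int i = l - 1; i >= 0; --i) {
    m[i + 1].w += po * m[i].w * (i + 1) / static_cast<double>(l + 1);
    m[i].w = pz * m[i].w * (l - i) / static_cast<double>(l + 1);
  }
}

double unwound_sum(const std::vector<PathElem>& m, int i) {
  const int L = static_cast<int>(m.size());
  double n = m[L - 1].w, total = 0.0;
  const double o = m[i].o, z = m[i].z;
  for (int j = L - 2; j >= 0; --j) {
    if (o != 0.0) {
      const double nw = n * L / ((j + 1) * o);
      total += nw;
      n = m[j].w - nw * z * (L - 1 - j) / static_cast<double>(L);
    } else {
      total += m[j].w * L / (z * (L - 1 - j));
    }
  }
  return total;
}

void unwind_path(std::vector<PathElem>& m, int i) {
  const int L = static_cast<int>(m.size());
  double n = m[L - 1].w;
  const double o = m[i].o, z = m[i].z;
  for (int j = L - 2; j >= 0; --j) {
    if (o != 0.0) {
      const double t = m[j].w;
      m[j].w = n * L / ((j + 1) * o);
      n = t - m[j].w * z * (L - 1 - j) / static_cast<double>(L);
    } else {
      m[j].w = m[j].w * L / (z * (L - 1 - j));
    }
  }
  for (int j = i; j < L - 1; ++j) {
    m[j].d = m[j + 1].d;
    m[j].z = m[j + 1].z;
    m[j].o = m[j + 1].o;
  }
  m.pop_back();
}

void shap_recurse(const Tree& t, const NumericMatrix& X, int row,
                  std::vector<double>& phi, int node,
                  std::vector<PathElem> m, double pz, double po, int pi) {
  extend_path(m, pz, po, pi);
  if (t.feature[node] < 0) {
    for (int i = 1; i < static_cast<int>(m.size()); ++i)
      phi[m[i].d] += unwound_sum(m, i) * (m[i].o - m[i].z) * t.value[node];
    return;
  }
  const int f = t.feature[node];
  const int a = t.left[node], b = t.right[node];
  const bool goes_left = X(row, f) <= t.threshold[node];
  const int hot = goes_left ? a : b, cold = goes_left ? b : a;
  double iz = 1.0, io = 1.0;
  for (int k = 1; k < static_cast<int>(m.size()); ++k)
    if (m[k].d == f) {
      iz = m[k].z;
      io = m[k].o;
      unwind_path(m, k);
      break;
    }
  const double rj = t.cover[node];
  shap_recurse(t, X, row, phi, hot, m, iz * t.cover[hot] / rj, io, f);
  shap_recurse(t, X, row, phi, cold, m, iz * t.cover[cold] / rj, 0.0, f);
}

} // namespace

// Path-dependent TreeSHAP: returns n x p matrix of contributions in the
// tree's output space; rowSums(phi) + expected_value == prediction.
// [[Rcpp::export(name = ".tree_shap_cpp")]]
NumericMatrix tree_shap_cpp(List tree, NumericMatrix X) {
  Tree t = tree_from_list(tree);
  const int n = X.nrow(), p = X.ncol();
  NumericMatrix out(n, p);
  for (int i = 0; i < n; ++i) {
    std::vector<double> phi(p, 0.0);
    std::vector<PathElem> m;
    shap_recurse(t, X, i, phi, 0, m, 1.0, 1.0, -1);
    for (int j = 0; j < p; ++j) out(i, j) = phi[j];
  }
  return out;
}

// Cover-weighted expectation of the tree output (SHAP base value).
// [[Rcpp::export(name = ".tree_expected_cpp")]]
double tree_expected_cpp(List tree) {
  Tree t = tree_from_list(tree);
  double tot = 0.0, acc = 0.0;
  for (size_t j = 0; j < t.feature.size(); ++j)
    if (t.feature[j] < 0) {
      tot += t.cover[j];
      acc += t.cover[j] * t.value[j];
    }
  return tot > 0.0 ? acc / tot : 0.0;
}

// Sample entropy SampEn(m, r) with Chebyshev distance, self-matches
// excluded; returns NA when no length-m matches exist, 0 for constant
// series (A == B).
// [[Rcpp::export(name = ".sample_entropy_cpp")]]
double sample_entropy_cpp(NumericVector x, int m, double r) {
  const int n = x.size();
  if (n < m + 2) return NA_REAL;
  long long A = 0, B = 0;
  for (int i = 0; i < n - m; ++i) {
    for (int j = i + 1; j < n - m; ++j) {
      bool match = true;
      for (int k = 0; k < m; ++k)
        if (std::fabs(x[i + k] - x[j + k]) > r) {
          match = false;
          break;
        }
      if (!match) continue;
      ++B;
      if (std::fabs(x[i + m] - x[j + m]) <= r) ++A;
    }
  }
  if (B == 0) return NA_REAL;
  if (A == 0) return R_PosInf; // -log(0): no template extends within r
  return -std::log(static_cast<double>(A) / static_cast<double>(B));
}
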