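// Regression random forest with out-of-bag permutation variable importance
// and empirical permutation-null p-values.  Trees are CART-style
// variance-reduction trees, unpruned, with a minimum leaf size; each tree is
// grown on a bootstrap sample and evaluated on its out-of-bag (OOB) cases.
// Everything is deterministic given the seed (own 64-bit RNG stream, no
// dependence on R's RNG or on std::distribution implementations).

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <algorithm>
#include <cmath>
#include <limits>

using namespace Rcpp;

// splitmix64: small, portable, deterministic
struct Rng {
  uint64_t state;
  explicit Rng(uint64_t seed) : state(seed + 0x9E3779B97f4A7C15ULL) {}
  uint64_t next() {
    uint64_t z = (state += 0x9E3779B97f4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  int below(int n) { return (int)(next() % (uint64_t)n); }
  // in-place Fisher-Yates
  void shuffle(std::vector<int>& v) {
    for (int i = (int)v.size() - 1; i > 0; --i) std::swap(v[i], v[below(i + 1)]);
  }
};

struct Tree {
  std::vector<int> var;      // split variable, -1 for leaf
  std::vector<double> split; // split threshold (x <= split goes left)
  std::vector<int> left, right;
  std::vector<double> value; // leaf prediction (node mean)
};

struct NodeJob { int node, start, end; };

static void grow_tree(const NumericMatrix& X, const NumericVector& y,
                      std::vector<int>& idx, int mtry, int min_leaf,
                      Rng& rng, Tree& tr) {
  const int p = X.ncol();
  std::vector<int> vars(p);
  for (int j = 0; j < p; ++j) vars[j] = j;
  std::vector<std::pair<double, double> > buf; // (x, y) within a node

  std::vector<NodeJob> stack;
  tr.var.push_back(-1); tr.split.push_back(0.0);
  tr.left.push_back(-1); tr.right.push_back(-1); tr.value.push_back(0.0);
  stack.push_back(NodeJob{0, 0, (int)idx.size()});

  while (!stack.empty()) {
    NodeJob jb = stack.back(); stack.pop_back();
    const int n = jb.end - jb.start;
    double sum = 0.0;
    for (int k = jb.start; k < jb.end; ++k) sum += y[idx[k]];
    const double mean = sum / n;
    tr.value[jb.node] = mean;
    if (n < 2 * min_leaf) continue;
    double ss = 0.0;
    for (int k = jb.start; k < jb.end; ++k) {
      const double d = y[idx[k]] - mean;
      ss += d * d;
    }
    if (ss <= 1e-12) continue;

    // sample mtry candidate variables (partial Fisher-Yates)
    for (int j = 0; j < mtry; ++j) std::swap(vars[j], vars[j + rng.below(p - j)]);

    int best_var = -1; double best_split = 0.0, best_gain = 1e-12;
    for (int j = 0; j < mtry; ++j) {
      const int v = vars[j];
      buf.clear();
      for (int k = jb.start; k < jb.end; ++k) {
        buf.push_back(std::make_pair(X(idx[k], v), y[idx[k]]));
      }
      std::sort(buf.begin(), buf.end());
      if (buf.front().first == buf.back().first) continue;
      double sl = 0.0;
      for (int k = 0; k + 1 < n; ++k) {
        sl += buf[k].second;
        const int nl = k + 1, nr = n - nl;
        if (nl < min_leaf) continue;
        if (nr < min_leaf) break;
        if (buf[k].first == buf[k + 1].first) continue; // no boundary here
        const double sr = sum - sl;
        const double gain = sl * sl / nl + sr * sr / nr - sum * sum / n;
        if (gain > best_gain) {
          best_gain = gain;
          best_var = v;
          best_split = 0.5 * (buf[k].first + buf[k + 1].first);
        }
      }
    }
    if (best_var < 0) continue;

    // partition idx[start, end) by the chosen split (stable)
    std::vector<int> lo, hi;
    for (int k = jb.start; k < jb.end; ++k) {
      if (X(idx[k], best_var) <= best_split) lo.push_back(idx[k]);
      else hi.push_back(idx[k]);
    }
    for (size_t k = 0; k < lo.size(); ++k) idx[jb.start + k] = lo[k];
    for (size_t k = 0; k < hi.size(); ++k) idx[jb.start + lo.size() + k] = hi[k];

    const int li = (int)tr.var.size();
    tr.var.push_back(-1); tr.split.push_back(0.0);
    tr.left.push_back(-1); tr.right.push_back(-1); tr.value.push_back(0.0);
    const int ri = (int)tr.var.size();
    tr.var.push_back(-1); tr.split.push_back(0.0);
    tr.left.push_back(-1); tr.right.push_back(-1); tr.value.push_back(0.0);
    tr.var[jb.node] = best_var;
    tr.split[jb.node] = best_split;
    tr.left[jb.node] = li;
    tr.right[jb.node] = ri;
    stack.push_back(NodeJob{li, jb.start, jb.start + (int)lo.size()});
    stack.push_back(NodeJob{ri, jb.start + (int)lo.size(), jb.end});
  }
}

static List tree_to_list(const Tree& tr) {
  return List::create(_["var"] = wrap(tr.var), _["split"] = wrap(tr.split),
                      _["left"] = wrap(tr.left), _["right"] = wrap(tr.right),
                      _["value"] = wrap(tr.value));
}

static Tree tree_from_list(const List& l) {
  Tree tr;
  tr.var = as<std::vector<int> >(l["var"]);
  tr.split = as<std::vector<double> >(l["split"]);
  tr.left = as<std::vector<int> >(l["left"]);
  tr.right = as<std::vector<int> >(l["right"]);
  tr.value = as<std::vector<double> >(l["value"]);
  return tr;
}

// route one row through a tree; variable pvar (if >= 0) takes value pval
static inline double route(const Tree& tr, const NumericMatrix& X, int row,
                           int pvar, double pval) {
  int node = 0;
  while (tr.var[node] >= 0) {
    const int v = tr.var[node];
    const double x = (v == pvar) ? pval : X(row, v);
    node = (x <= tr.split[node]) ? tr.left[node] : tr.right[node];
  }
  return tr.value[node];
}

// [[Rcpp::export]]
List rf_fit_cpp(NumericMatrix X, NumericVector y, int ntree, int mtry,
                int min_leaf, double seed) {
  const int n = X.nrow();
  Rng rng((uint64_t)seed);
  List trees(ntree);
  IntegerMatrix inbag(n, ntree);
  std::vector<int> idx;
  for (int t = 0; t < ntree; ++t) {
    idx.clear();
    for (int k = 0; k < n; ++k) {
      const int j = rng.below(n);
      idx.push_back(j);
      inbag(j, t)++;
    }
    Tree tr;
    grow_tree(X, y, idx, mtry, min_leaf, rng, tr);
    trees[t] = tree_to_list(tr);
  }
  return List::create(_["trees"] = trees, _["inbag"] = inbag);
}

// [[Rcpp::export]]
NumericMatrix rf_predict_cpp(List trees, NumericMatrix X, bool per_tree) {
  const int n = X.nrow(), T = trees.size();
  if (per_tree) {
    NumericMatrix out(n, T);
    for (int t = 0; t < T; ++t) {
      Tree tr = tree_from_list(trees[t]);
      for (int i = 0; i < n; ++i) out(i, t) = route(tr, X, i, -1, 0.0);
    }
    return out;
  }
  NumericMatrix out(n, 1);
  for (int t = 0; t < T; ++t) {
    Tree tr = tree_from_list(trees[t]);
    for (int i = 0; i < n; ++i) out(i, 0) += route(tr, X, i, -1, 0.0);
  }
  for (int i = 0; i < n; ++i) out(i, 0) /= T;
  return out;
}

// OOB ensemble prediction (NaN for rows in every bag)
// [[Rcpp::export]]
NumericVector rf_oob_predict_cpp(List trees, IntegerMatrix inbag,
                                 NumericMatrix X) {
  const int n = X.nrow(), T = trees.size();
  NumericVector sum(n), cnt(n);
  for (int t = 0; t < T; ++t) {
    Tree tr = tree_from_list(trees[t]);
    for (int i = 0; i < n; ++i) {
      if (inbag(i, t) == 0) {
        sum[i] += route(tr, X, i, -1, 0.0);
        cnt[i] += 1.0;
      }
    }
  }
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = cnt[i] > 0 ? sum[i] / cnt[i] : NA_REAL;
  return out;
}

struct Forest {
  std::vector<Tree> trees;
  std::vector<std::vector<int> > oob; // OOB row indices per tree
};

static Forest load_forest(const List& trees, const IntegerMatrix& inbag) {
  Forest f;
  const int T = trees.size(), n = inbag.nrow();
  f.trees.reserve(T);
  f.oob.resize(T);
  for (int t = 0; t < T; ++t) {
    f.trees.push_back(tree_from_list(trees[t]));
    for (int i = 0; i < n; ++i) if (inbag(i, t) == 0) f.oob[t].push_back(i);
  }
  return f;
}

// Prediction of one tree for one row as a step function of variable v's
// value (all other coordinates fixed at the row's values).  Built by
// descending the tree, branching both ways at v-splits; left-first DFS
// yields the value segments in increasing v order.  Evaluating a
// permutation then costs a short scan instead of a full traversal.
struct PathFn {
  std::vector<double> breaks; // segment upper bounds, except the last (+inf)
  std::vector<double> vals;   // breaks.size() + 1 leaf values
  double eval(double x) const {
    size_t k = 0;
    while (k < breaks.size() && x > breaks[k]) ++k;
    return vals[k];
  }
};

static void build_pathfn(const Tree& tr, const NumericMatrix& X, int row,
                         int v, PathFn& pf) {
  struct Seg { int node; double hi; double lo; };
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<Seg> st;
  st.push_back(Seg{0, INF, -INF});
  pf.breaks.clear(); pf.vals.clear();
  while (!st.empty()) {
    Seg s = st.back(); st.pop_back();
    int node = s.node;
    while (tr.var[node] >= 0 && tr.var[node] != v) {
      node = (X(row, tr.var[node]) <= tr.split[node]) ? tr.left[node]
                                                      : tr.right[node];
    }
    if (tr.var[node] < 0) {
      if (!pf.vals.empty()) pf.breaks.push_back(s.lo); // previous seg's bound
      pf.vals.push_back(tr.value[node]);
      continue;
    }
    const double sp = tr.split[node];
    // push right first so the left (smaller v) branch is processed first
    if (sp < s.hi) st.push_back(Seg{tr.right[node], s.hi, std::max(s.lo, sp)});
    if (s.lo < sp) st.push_back(Seg{tr.left[node], std::min(s.hi, sp), s.lo});
  }
}

// mean over trees of the OOB MSE when variable `var` carries the values
// assigned by `perm` (row i reads X(perm[i], var)); perm == identity gives
// the baseline OOB error
static double mean_oob_mse(const Forest& f, const NumericMatrix& X,
                           const NumericVector& y, int var,
                           const std::vector<int>& perm) {
  double acc = 0.0;
  int used = 0;
  for (size_t t = 0; t < f.trees.size(); ++t) {
    const std::vector<int>& oob = f.oob[t];
    if (oob.empty()) continue;
    double mse = 0.0;
    for (size_t k = 0; k < oob.size(); ++k) {
      const int i = oob[k];
      const double pred = (var >= 0)
        ? route(f.trees[t], X, i, var, X(perm[i], var))
        : route(f.trees[t], X, i, -1, 0.0);
      const double d = y[i] - pred;
      mse += d * d;
    }
    acc += mse / oob.size();
    ++used;
  }
  return used > 0 ? acc / used : NA_REAL;
}

// Observed permutation importance and empirical permutation-null p-values.
// Observed importance of a variable: one random global permutation of the
// variable; the increase in per-tree OOB MSE over the unpermuted baseline,
// averaged over trees.  Null draws repeat the procedure comparing two fresh
// independent permutations; under the null hypothesis the identity
// assignment is exchangeable with any permutation, so
// p = (1 + #{null >= observed}) / (n_null + 1) is a valid permutation p.
// [[Rcpp::export]]
List rf_importance_cpp(List trees, IntegerMatrix inbag, NumericMatrix X,
                       NumericVector y, IntegerVector vars, int n_null,
                       double seed) {
  const int n = X.nrow(), nv = vars.size();
  Forest f = load_forest(trees, inbag);
  const int T = (int)f.trees.size();
  Rng rng((uint64_t)seed);
  std::vector<int> id(n), pa(n), pb(n);
  for (int i = 0; i < n; ++i) id[i] = i;

  int used = 0;
  for (int t = 0; t < T; ++t) if (!f.oob[t].empty()) ++used;

  NumericVector observed(nv), pval(nv);
  NumericMatrix nulls(n_null, nv);
  std::vector<std::vector<PathFn> > pf(T);
  std::vector<double> base(T), xv(n);
  std::vector<char> active(T);

  for (int j = 0; j < nv; ++j) {
    const int v = vars[j];
    for (int i = 0; i < n; ++i) xv[i] = X(i, v);
    // per-(tree, OOB row) step functions of the v value, and per-tree
    // baseline OOB MSE at the original values
    for (int t = 0; t < T; ++t) {
      const std::vector<int>& oob = f.oob[t];
      pf[t].resize(oob.size());
      bool any = false;
      double mse = 0.0;
      for (size_t k = 0; k < oob.size(); ++k) {
        build_pathfn(f.trees[t], X, oob[k], v, pf[t][k]);
        if (!pf[t][k].breaks.empty()) any = true;
        const double d = y[oob[k]] - pf[t][k].eval(xv[oob[k]]);
        mse += d * d;
      }
      base[t] = oob.empty() ? 0.0 : mse / oob.size();
      active[t] = any ? 1 : 0; // trees with no reachable v-split never change
    }
    // mean over trees of (OOB MSE under the assignment - baseline OOB MSE)
    // NB: inactive trees contribute exactly 0
    #define EVAL_DIFF(perm, out) do {                                   \
      double acc = 0.0;                                                 \
      for (int t = 0; t < T; ++t) {                                     \
        if (!active[t] || f.oob[t].empty()) continue;                   \
        const std::vector<int>& oob = f.oob[t];                         \
        double mse = 0.0;                                               \
        for (size_t k = 0; k < oob.size(); ++k) {                       \
          const double d = y[oob[k]] - pf[t][k].eval(xv[(perm)[oob[k]]]); \
          mse += d * d;                                                 \
        }                                                               \
        acc += mse / oob.size() - base[t];                              \
      }                                                                 \
      (out) = acc / used;                                               \
    } while (0)

    pa = id; rng.shuffle(pa);
    double obs; EVAL_DIFF(pa, obs);
    int ge = 0;
    for (int r = 0; r < n_null; ++r) {
      pa = id; rng.shuffle(pa);
      pb = id; rng.shuffle(pb);
      double da, db;
      EVAL_DIFF(pa, da);
      EVAL_DIFF(pb, db);
      const double d = da - db;
      nulls(r, j) = d;
      if (d >= obs) ++ge;
    }
    #undef EVAL_DIFF
    observed[j] = obs;
    pval[j] = (1.0 + ge) / (n_null + 1.0);
  }
  return List::create(_["observed"] = observed, _["pvalue"] = pval,
                      _["nulls"] = nulls);
}

// step-function-based evaluation of an explicit assignment; must agree
// exactly with the direct-traversal route (cross-checked in the tests)
// [[Rcpp::export]]
double rf_perm_importance_fast_cpp(List trees, IntegerMatrix inbag,
                                   NumericMatrix X, NumericVector y, int var,
                                   IntegerVector perm) {
  const int n = X.nrow();
  Forest f = load_forest(trees, inbag);
  const int T = (int)f.trees.size();
  int used = 0;
  for (int t = 0; t < T; ++t) if (!f.oob[t].empty()) ++used;
  double acc = 0.0;
  PathFn pfn;
  for (int t = 0; t < T; ++t) {
    const std::vector<int>& oob = f.oob[t];
    if (oob.empty()) continue;
    double mse = 0.0, mse0 = 0.0;
    for (size_t k = 0; k < oob.size(); ++k) {
      const int i = oob[k];
      build_pathfn(f.trees[t], X, i, var, pfn);
      double d = y[i] - pfn.eval(X(perm[i] - 1, var));
      mse += d * d;
      d = y[i] - pfn.eval(X(i, var));
      mse0 += d * d;
    }
    acc += (mse - mse0) / oob.size();
  }
  return used > 0 ? acc / used : NA_REAL;
}

// importance for an explicitly supplied assignment (1-based permutation);
// used by tests (identity => exactly 0) and by the multi-permutation
// importance estimate
// [[Rcpp::export]]
double rf_perm_importance_cpp(List trees, IntegerMatrix inbag,
                              NumericMatrix X, NumericVector y, int var,
                              IntegerVector perm) {
  const int n = X.nrow();
  Forest f = load_forest(trees, inbag);
  std::vector<int> id(n), pm(n);
  for (int i = 0; i < n; ++i) id[i] = i;
  for (int i = 0; i < n; ++i) pm[i] = perm[i] - 1;
  return mean_oob_mse(f, X, y, var, pm) - mean_oob_mse(f, X, y, -1, id);
}
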