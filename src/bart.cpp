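#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Flat tree representation shared with the R side:
// a numeric matrix with columns (var, split, value, left, right).
// var == 0 marks a leaf; left/right are 1-based row indices (0 = none).
// Observations with x[, var] <= split route left.

struct Tree {
  std::vector<int> var;     // 0 = leaf, else 1-based column of X
  std::vector<double> split;
  std::vector<double> value;
  std::vector<int> left, right, parent, depth; // 0-based indices, -1 = none

  int size() const { return (int) var.size(); }
  bool is_leaf(int i) const { return var[i] == 0; }
  bool is_nog(int i) const { // internal node with two leaf children
    return !is_leaf(i) && is_leaf(left[i]) && is_leaf(right[i]);
  }
};

static Tree tree_from_matrix(const NumericMatrix& m) {
  Tree t;
  int k = m.nrow();
  t.var.resize(k); t.split.resize(k); t.value.resize(k);
  t.left.resize(k); t.right.resize(k); t.parent.assign(k, -1); t.depth.assign(k, 0);
  for (int i = 0; i < k; ++i) {
    t.var[i] = (int) m(i, 0);
    t.split[i] = m(i, 1);
    t.value[i] = m(i, 2);
    t.left[i] = (int) m(i, 3) - 1;
    t.right[i] = (int) m(i, 4) - 1;
  }
  for (int i = 0; i < k; ++i) {
    if (t.var[i] != 0) {
      t.parent[t.left[i]] = i;
      t.parent[t.right[i]] = i;
    }
  }
  // depths via parent links (root is row 0)
  for (int i = 1; i < k; ++i) {
    int d = 0, p = t.parent[i];
    while (p >= 0) { ++d; p = t.parent[p]; }
    t.depth[i] = d;
  }
  return t;
}

static NumericMatrix tree_to_matrix(const Tree& t) {
  // compact: drop detached nodes by re-indexing reachable nodes from root
  int k = t.size();
  std::vector<int> newid(k, -1);
  std::vector<int> order;
  order.reserve(k);
  std::vector<int> stack;
  stack.push_back(0);
  while (!stack.empty()) {
    int i = stack.back(); stack.pop_back();
    newid[i] = (int) order.size();
    order.push_back(i);
    if (!t.is_leaf(i)) { stack.push_back(t.right[i]); stack.push_back(t.left[i]); }
  }
  int k2 = (int) order.size();
  NumericMatrix m(k2, 5);
  for (int j = 0; j < k2; ++j) {
    int i = order[j];
    m(j, 0) = t.var[i];
    m(j, 1) = t.split[i];
    m(j, 2) = t.value[i];
    m(j, 3) = t.is_leaf(i) ? 0 : newid[t.left[i]] + 1;
    m(j, 4) = t.is_leaf(i) ? 0 : newid[t.right[i]] + 1;
  }
  colnames(m) = CharacterVector::create("var", "split", "value", "left", "right");
  return m;
}

// rebuild a tree in compact preorder layout (drops detached nodes). Node
// iteration order feeds proposal selection and leaf redraws, so updates must
// run on a canonical layout to be reproducible across storage schemes.
static void normalize_tree(Tree& t) {
  Tree out;
  std::vector<std::pair<int, int>> stack; // (old index, new parent)
  stack.push_back({0, -1});
  std::vector<int> newid(t.size(), -1);
  std::vector<int> order;
  while (!stack.empty()) {
    auto pr = stack.back(); stack.pop_back();
    int i = pr.first;
    newid[i] = (int) order.size();
    order.push_back(i);
    if (!t.is_leaf(i)) { stack.push_back({t.right[i], i});
                         stack.push_back({t.left[i], i}); }
  }
  int k = (int) order.size();
  out.var.resize(k); out.split.resize(k); out.value.resize(k);
  out.left.assign(k, -1); out.right.assign(k, -1);
  out.parent.assign(k, -1); out.depth.assign(k, 0);
  for (int j = 0; j < k; ++j) {
    int i = order[j];
    out.var[j] = t.var[i];
    out.split[j] = t.split[i];
    out.value[j] = t.value[i];
    if (!t.is_leaf(i)) { out.left[j] = newid[t.left[i]];
                         out.right[j] = newid[t.right[i]]; }
  }
  for (int j = 0; j < k; ++j) if (out.var[j] != 0) {
    out.parent[out.left[j]] = j;
    out.parent[out.right[j]] = j;
    out.depth[out.left[j]] = out.depth[j] + 1;
    out.depth[out.right[j]] = out.depth[j] + 1;
  }
  t = out;
}

// covariate accessor: plain column-major R matrix, or a transposed copy
// (observation-contiguous) used by the persistent ensemble for locality
struct XAcc {
  const double* d;
  int n, p;
  bool transposed;
  inline double operator()(int i, int j) const {
    return transposed ? d[(size_t) i * p + j] : d[(size_t) j * n + i];
  }
};

static XAcc acc_of(const NumericMatrix& X) {
  XAcc a; a.d = &X[0]; a.n = X.nrow(); a.p = X.ncol(); a.transposed = false;
  return a;
}

static int route(const Tree& t, const XAcc& X, int obs, int from = 0) {
  int node = from;
  while (!t.is_leaf(node))
    node = (X(obs, t.var[node] - 1) <= t.split[node]) ? t.left[node] : t.right[node];
  return node;
}

// integrated leaf likelihood, terms that do not cancel between competing
// partitions of the same observation set:
//   0.5 * log(sigma^2 / (sigma^2 + n sigma_mu^2))
//     + sigma_mu^2 s^2 / (2 sigma^2 (sigma^2 + n sigma_mu^2))
static double mll_core(double n, double s, double sig2, double smu2) {
  if (n <= 0.0) return 0.0;
  double denom = sig2 + n * smu2;
  return 0.5 * std::log(sig2 / denom) + smu2 * s * s / (2.0 * sig2 * denom);
}

static double p_split(int depth, double alpha, double beta) {
  return alpha * std::pow(1.0 + depth, -beta);
}

struct LeafStats {
  std::vector<int> leaf_of;          // per-obs leaf node index
  std::vector<double> n, s;          // per-node counts / residual sums
};

static LeafStats compute_stats(const Tree& t, const XAcc& X,
                               const std::vector<double>& r) {
  LeafStats st;
  int n = (int) r.size(), k = t.size();
  st.leaf_of.resize(n);
  st.n.assign(k, 0.0);
  st.s.assign(k, 0.0);
  for (int i = 0; i < n; ++i) {
    int leaf = route(t, X, i);
    st.leaf_of[i] = leaf;
    st.n[leaf] += 1.0;
    st.s[leaf] += r[i];
  }
  return st;
}

static void collect(const Tree& t, bool leaves_only, int max_depth,
                    std::vector<int>& out, int kind) {
  // kind 0: growable leaves, 1: nog nodes, 2: internal nodes
  out.clear();
  for (int i = 0; i < t.size(); ++i) {
    if (t.parent[i] < 0 && i != 0) continue; // detached
    bool reachable = (i == 0);
    if (!reachable) { // check chain to root
      int p = i;
      while (t.parent[p] >= 0) p = t.parent[p];
      reachable = (p == 0);
    }
    if (!reachable) continue;
    if (kind == 0 && t.is_leaf(i) && (max_depth <= 0 || t.depth[i] < max_depth))
      out.push_back(i);
    else if (kind == 1 && t.is_nog(i))
      out.push_back(i);
    else if (kind == 2 && !t.is_leaf(i))
      out.push_back(i);
  }
  (void) leaves_only;
}

// One Metropolis-Hastings update of a single tree against partial residuals r,
// followed by a conjugate redraw of all leaf values. Returns 1 if the
// topology proposal was accepted, 0 otherwise. fit is overwritten with the
// tree's new per-observation contribution.
static int update_one_tree(Tree& t, const XAcc& X, const List& cutpoints,
                           const std::vector<double>& r, double sigma, double sigma_mu,
                           double alpha, double beta,
                           double p_grow, double p_prune,
                           int max_depth, bool prior_only,
                           std::vector<double>& fit) {
  int nobs = (int) r.size();
  double sig2 = sigma * sigma, smu2 = sigma_mu * sigma_mu;
  normalize_tree(t);
  LeafStats st = compute_stats(t, X, r);

  // splittable predictors (nonempty cutpoint grids)
  std::vector<int> splittable;
  for (int v = 0; v < cutpoints.size(); ++v)
    if (Rf_length(cutpoints[v]) > 0) splittable.push_back(v);
  int V = (int) splittable.size();

  int accepted = 0;
  double u_move = unif_rand();
  std::vector<int> pool;

  if (V > 0 && u_move < p_grow) {
    collect(t, true, max_depth, pool, 0); // growable leaves
    int G = (int) pool.size();
    if (G > 0) {
      int leaf = pool[(int) std::floor(unif_rand() * G)];
      int v = splittable[(int) std::floor(unif_rand() * V)];
      NumericVector cuts = cutpoints[v];
      double c = cuts[(int) std::floor(unif_rand() * cuts.size())];
      // partition the leaf's observations
      double nl = 0, sl = 0, nr = 0, sr = 0;
      for (int i = 0; i < nobs; ++i) {
        if (st.leaf_of[i] != leaf) continue;
        if (X(i, v) <= c) { nl += 1; sl += r[i]; } else { nr += 1; sr += r[i]; }
      }
      if (nl > 0 && nr > 0) {
        int d = t.depth[leaf];
        double psd = p_split(d, alpha, beta), psd1 = p_split(d + 1, alpha, beta);
        double loglik = prior_only ? 0.0 :
          mll_core(nl, sl, sig2, smu2) + mll_core(nr, sr, sig2, smu2) -
          mll_core(nl + nr, sl + sr, sig2, smu2);
        // uniform rule-choice terms cancel between prior and proposal
        double logprior = std::log(psd) + 2.0 * std::log(1.0 - psd1) - std::log(1.0 - psd);
        int nog_after; // reverse PRUNE selects among nog nodes of the grown tree
        {
          std::vector<int> nogs;
          collect(t, false, 0, nogs, 1);
          int cnt = (int) nogs.size() + 1;
          int p = t.parent[leaf];
          if (p >= 0 && t.is_nog(p)) cnt -= 1;
          nog_after = cnt;
        }
        double logq = std::log(p_prune) - std::log((double) nog_after)
                    - std::log(p_grow) + std::log((double) G);
        if (std::log(unif_rand()) < loglik + logprior + logq) {
          int k = t.size();
          t.var.push_back(0); t.split.push_back(0.0); t.value.push_back(0.0);
          t.left.push_back(-1); t.right.push_back(-1);
          t.parent.push_back(leaf); t.depth.push_back(d + 1);
          t.var.push_back(0); t.split.push_back(0.0); t.value.push_back(0.0);
          t.left.push_back(-1); t.right.push_back(-1);
          t.parent.push_back(leaf); t.depth.push_back(d + 1);
          t.var[leaf] = v + 1; t.split[leaf] = c;
          t.left[leaf] = k; t.right[leaf] = k + 1;
          accepted = 1;
        }
      }
    }
  } else if (u_move < p_grow + p_prune) {
    collect(t, false, 0, pool, 1); // nog nodes
    int NG = (int) pool.size();
    if (NG > 0) {
      int node = pool[(int) std::floor(unif_rand() * NG)];
      int l = t.left[node], rr = t.right[node];
      double nl = st.n[l], sl = st.s[l], nr = st.n[rr], sr = st.s[rr];
      int d = t.depth[node];
      double psd = p_split(d, alpha, beta), psd1 = p_split(d + 1, alpha, beta);
      double loglik = prior_only ? 0.0 :
        mll_core(nl + nr, sl + sr, sig2, smu2) -
        mll_core(nl, sl, sig2, smu2) - mll_core(nr, sr, sig2, smu2);
      double logprior = -(std::log(psd) + 2.0 * std::log(1.0 - psd1) - std::log(1.0 - psd));
      // growable-leaf count of the pruned tree (reverse GROW selection)
      std::vector<int> grw;
      collect(t, true, max_depth, grw, 0);
      int G_after = (int) grw.size() + 1;
      if (max_depth <= 0 || d + 1 < max_depth) G_after -= 2;
      double logq = std::log(p_grow) - std::log((double) G_after)
                  - std::log(p_prune) + std::log((double) NG);
      if (std::log(unif_rand()) < loglik + logprior + logq) {
        t.var[node] = 0; t.left[node] = -1; t.right[node] = -1;
        t.parent[l] = -2; t.parent[rr] = -2; // detach
        accepted = 1;
      }
    }
  } else if (V > 0) {
    collect(t, false, 0, pool, 2); // internal nodes
    int NI = (int) pool.size();
    if (NI > 0) {
      int node = pool[(int) std::floor(unif_rand() * NI)];
      int v = splittable[(int) std::floor(unif_rand() * V)];
      NumericVector cuts = cutpoints[v];
      double c = cuts[(int) std::floor(unif_rand() * cuts.size())];
      // observations currently reaching `node`: those whose leaf lies under it
      std::vector<int> subleaves;
      { std::vector<int> stck; stck.push_back(node);
        while (!stck.empty()) {
          int x = stck.back(); stck.pop_back();
          if (t.is_leaf(x)) subleaves.push_back(x);
          else { stck.push_back(t.left[x]); stck.push_back(t.right[x]); }
        } }
      std::vector<bool> under(t.size(), false);
      for (int x : subleaves) under[x] = true;
      double old_ll = 0.0;
      if (!prior_only)
        for (int x : subleaves) old_ll += mll_core(st.n[x], st.s[x], sig2, smu2);
      int old_var = t.var[node]; double old_split = t.split[node];
      t.var[node] = v + 1; t.split[node] = c;
      std::vector<double> nn(t.size(), 0.0), ss(t.size(), 0.0);
      for (int i = 0; i < nobs; ++i) {
        if (!under[st.leaf_of[i]]) continue;
        int lf = route(t, X, i, node);
        nn[lf] += 1.0; ss[lf] += r[i];
      }
      bool ok = true;
      double new_ll = 0.0;
      for (int x : subleaves) {
        if (nn[x] <= 0) { ok = false; break; }
        if (!prior_only) new_ll += mll_core(nn[x], ss[x], sig2, smu2);
      }
      // uniform rule prior and uniform proposal cancel exactly
      if (ok && std::log(unif_rand()) < new_ll - old_ll) {
        accepted = 1;
      } else {
        t.var[node] = old_var; t.split[node] = old_split;
      }
    }
  }

  // conjugate leaf redraw and fit refresh (routing unchanged on rejection)
  LeafStats st2 = accepted ? compute_stats(t, X, r) : st;
  for (int i = 0; i < t.size(); ++i) {
    if (t.parent[i] == -2 || !t.is_leaf(i)) continue;
    if (i != 0) { // skip detached
      int p = i; bool reach = false;
      while (p >= 0) { if (p == 0) { reach = true; break; } p = t.parent[p]; }
      if (!reach) continue;
    }
    if (prior_only) {
      t.value[i] = norm_rand() * sigma_mu;
    } else {
      double prec = st2.n[i] / sig2 + 1.0 / smu2;
      double mean = (st2.s[i] / sig2) / prec;
      t.value[i] = mean + norm_rand() / std::sqrt(prec);
    }
  }
  for (int i = 0; i < nobs; ++i) fit[i] = t.value[st2.leaf_of[i]];
  return accepted;
}

// [[Rcpp::export(name = ".bart_sweep_cpp")]]
List bart_sweep_cpp(List trees, NumericMatrix tree_fits, NumericMatrix X,
                    List cutpoints, NumericVector y_working,
                    double sigma, double sigma_mu, double alpha, double beta,
                    double p_grow, double p_prune,
                    int max_depth, bool prior_only, int only_tree) {
  int n = X.nrow(), m = trees.size();
  XAcc xa = acc_of(X);
  NumericMatrix fits = clone(tree_fits);
  List out_trees = clone(trees);
  std::vector<double> total(n, 0.0);
  for (int j = 0; j < m; ++j)
    for (int i = 0; i < n; ++i) total[i] += fits(i, j);
  int accepts = 0;
  std::vector<double> r(n), fit(n);
  int j0 = (only_tree > 0) ? only_tree - 1 : 0;
  int j1 = (only_tree > 0) ? only_tree : m;
  for (int j = j0; j < j1; ++j) {
    Tree t = tree_from_matrix(out_trees[j]);
    for (int i = 0; i < n; ++i) r[i] = y_working[i] - (total[i] - fits(i, j));
    accepts += update_one_tree(t, xa, cutpoints, r, sigma, sigma_mu, alpha,
                               beta, p_grow, p_prune, max_depth, prior_only,
                               fit);
    for (int i = 0; i < n; ++i) {
      total[i] += fit[i] - fits(i, j);
      fits(i, j) = fit[i];
    }
    out_trees[j] = tree_to_matrix(t);
  }
  return List::create(_["trees"] = out_trees, _["tree_fits"] = fits,
                      _["total_fit"] = NumericVector(total.begin(), total.end()),
                      _["accepts"] = accepts);
}

// Persistent ensemble used inside chain runs: identical update logic, no
// per-sweep conversion between R matrices and the C++ tree structures. The
// R-side wrapper guarantees the same RNG consumption order as the
// value-semantics path, so both produce identical chains for a given seed.
struct BartState {
  std::vector<Tree> trees;
  std::vector<std::vector<double>> fits;
  std::vector<double> total;
  std::vector<double> Xt; // transposed (observation-contiguous) covariates
  int n, p;
  List cutpoints;
  XAcc acc() const {
    XAcc a; a.d = Xt.data(); a.n = n; a.p = p; a.transposed = true;
    return a;
  }
};

// [[Rcpp::export(name = ".bart_state_new")]]
SEXP bart_state_new(List trees, NumericMatrix X, List cutpoints) {
  BartState* st = new BartState();
  st->cutpoints = cutpoints;
  int n = X.nrow(), m = trees.size();
  st->n = n; st->p = X.ncol();
  st->Xt.resize((size_t) n * st->p);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < st->p; ++j)
      st->Xt[(size_t) i * st->p + j] = X(i, j);
  st->total.assign(n, 0.0);
  XAcc xa = st->acc();
  for (int j = 0; j < m; ++j) {
    Tree t = tree_from_matrix(trees[j]);
    std::vector<double> f(n);
    for (int i = 0; i < n; ++i) f[i] = t.value[route(t, xa, i)];
    for (int i = 0; i < n; ++i) st->total[i] += f[i];
    st->trees.push_back(t);
    st->fits.push_back(f);
  }
  return XPtr<BartState>(st, true);
}

// [[Rcpp::export(name = ".bart_state_sweep")]]
int bart_state_sweep(SEXP ptr, NumericVector y_working, double sigma,
                     double sigma_mu, double alpha, double beta,
                     double p_grow, double p_prune, int max_depth,
                     bool prior_only) {
  XPtr<BartState> st(ptr);
  int n = st->n, m = (int) st->trees.size();
  int accepts = 0;
  XAcc xa = st->acc();
  // refresh the running total from the per-tree fits so that long chains
  // stay bit-identical with the value-semantics sweep
  std::fill(st->total.begin(), st->total.end(), 0.0);
  for (int j = 0; j < m; ++j)
    for (int i = 0; i < n; ++i) st->total[i] += st->fits[j][i];
  std::vector<double> r(n), fit(n);
  for (int j = 0; j < m; ++j) {
    for (int i = 0; i < n; ++i)
      r[i] = y_working[i] - (st->total[i] - st->fits[j][i]);
    accepts += update_one_tree(st->trees[j], xa, st->cutpoints, r, sigma,
                               sigma_mu, alpha, beta, p_grow, p_prune,
                               max_depth, prior_only, fit);
    for (int i = 0; i < n; ++i) {
      st->total[i] += fit[i] - st->fits[j][i];
      st->fits[j][i] = fit[i];
    }
  }
  return accepts;
}

// [[Rcpp::export(name = ".bart_state_total")]]
NumericVector bart_state_total(SEXP ptr) {
  XPtr<BartState> st(ptr);
  return NumericVector(st->total.begin(), st->total.end());
}

// [[Rcpp::export(name = ".bart_state_predict")]]
NumericVector bart_state_predict(SEXP ptr, NumericMatrix Xnew) {
  XPtr<BartState> st(ptr);
  int n = Xnew.nrow();
  XAcc xa = acc_of(Xnew);
  NumericVector out(n);
  for (const Tree& t : st->trees)
    for (int i = 0; i < n; ++i) out[i] += t.value[route(t, xa, i)];
  return out;
}

// [[Rcpp::export(name = ".bart_state_trees")]]
List bart_state_trees(SEXP ptr) {
  XPtr<BartState> st(ptr);
  List out(st->trees.size());
  for (int j = 0; j < (int) st->trees.size(); ++j)
    out[j] = tree_to_matrix(st->trees[j]);
  return out;
}

// [[Rcpp::export(name = ".bart_predict_cpp")]]
NumericVector bart_predict_cpp(List trees, NumericMatrix X) {
  int n = X.nrow(), m = trees.size();
  XAcc xa = acc_of(X);
  NumericVector out(n);
  for (int j = 0; j < m; ++j) {
    Tree t = tree_from_matrix(trees[j]);
    for (int i = 0; i < n; ++i) out[i] += t.value[route(t, xa, i)];
  }
  return out;
}
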