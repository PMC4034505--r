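// Minimal random forest for binary classification of the 20 amino-acid
// "samples", purpose-built so that permutation variable importance can be
// computed from per-tree out-of-bag misclassification COUNTS with explicit,
// reproducible bootstraps and permutations:
//
//   VIM(x_i) = (1/ntree) * sum_t ( err.OOB~_t - err.OOB_t )
//
// where err.OOB~_t counts OOB misclassifications of tree t after permuting
// variable i's OOB values and err.OOB_t counts them unpermuted.  All
// randomness flows from a user seed + stream counter through a splitmix64 /
// xorshift64* generator, independent of R's RNG, so results are
// bit-reproducible across platforms.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <algorithm>

using namespace Rcpp;

namespace {

inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

struct Rng {
  uint64_t state;
  Rng(double seed, double stream) {
    uint64_t a = splitmix64(static_cast<uint64_t>(seed));
    uint64_t b = splitmix64(static_cast<uint64_t>(stream) ^ 0xA5A5A5A5A5A5A5A5ULL);
    state = splitmix64(a ^ (b << 1));
    if (state == 0) state = 0x1234567887654321ULL;
  }
  uint64_t next() {
    uint64_t x = state;
    x ^= x >> 12;
    x ^= x << 25;
    x ^= x >> 27;
    state = x;
    return x * 0x2545F4914F6CDD1DULL;
  }
  // uniform integer in [0, n)
  int unif_int(int n) { return static_cast<int>(next() % static_cast<uint64_t>(n)); }
  // partial Fisher-Yates: first k of a shuffle of 0..n-1
  void sample_k(int n, int k, std::vector<int> &out) {
    std::vector<int> pool(n);
    for (int i = 0; i < n; ++i) pool[i] = i;
    out.resize(k);
    for (int i = 0; i < k; ++i) {
      int j = i + unif_int(n - i);
      std::swap(pool[i], pool[j]);
      out[i] = pool[i];
    }
  }
  void shuffle(std::vector<int> &v) {
    for (int i = static_cast<int>(v.size()) - 1; i > 0; --i) {
      int j = unif_int(i + 1);
      std::swap(v[i], v[j]);
    }
  }
};

struct Tree {
  std::vector<int> var;      // split variable, -1 at leaves
  std::vector<double> thr;   // split threshold (x <= thr goes left)
  std::vector<int> left, right;
  std::vector<int> pred;     // leaf class, -1 at internal nodes
};

int majority(int n0, int n1, int tie_class) {
  if (n1 > n0) return 1;
  if (n0 > n1) return 0;
  return tie_class;
}

// grow a CART tree to purity on the in-bag sample (indices with repetition)
int grow_node(Tree &tree, const NumericMatrix &X, const IntegerVector &y,
              std::vector<int> idx, int mtry, int tie_class, Rng &rng) {
  const int m = X.ncol();
  const int nn = static_cast<int>(idx.size());
  int n1 = 0;
  for (int i : idx) n1 += y[i];
  const int n0 = nn - n1;

  int node = static_cast<int>(tree.var.size());
  tree.var.push_back(-1);
  tree.thr.push_back(0.0);
  tree.left.push_back(-1);
  tree.right.push_back(-1);
  tree.pred.push_back(majority(n0, n1, tie_class));
  if (n0 == 0 || n1 == 0 || nn < 2) return node;

  const double parent = nn - (static_cast<double>(n0) * n0 +
                              static_cast<double>(n1) * n1) / nn;
  std::vector<int> cand;
  rng.sample_k(m, std::min(mtry, m), cand);

  double best_score = parent - 1e-9;
  int best_var = -1;
  double best_thr = 0.0;

  std::vector<int> ord(nn);
  std::vector<double> xv(nn);
  for (int v : cand) {
    for (int i = 0; i < nn; ++i) xv[i] = X(idx[i], v);
    for (int i = 0; i < nn; ++i) ord[i] = i;
    std::sort(ord.begin(), ord.end(), [&](int a, int b) { return xv[a] < xv[b]; });
    int l0 = 0, l1 = 0;
    for (int i = 0; i < nn - 1; ++i) {
      int s = ord[i];
      if (y[idx[s]] == 1) ++l1; else ++l0;
      if (xv[ord[i + 1]] <= xv[s]) continue;  // no distinct cut here
      const int nl = i + 1, nr = nn - nl;
      const int r0 = n0 - l0, r1 = n1 - l1;
      const double score =
        (nl - (static_cast<double>(l0) * l0 + static_cast<double>(l1) * l1) / nl) +
        (nr - (static_cast<double>(r0) * r0 + static_cast<double>(r1) * r1) / nr);
      if (score < best_score - 1e-12) {
        best_score = score;
        best_var = v;
        best_thr = (xv[s] + xv[ord[i + 1]]) / 2.0;
      }
    }
  }
  if (best_var < 0) return node;  // no improving split among candidates

  std::vector<int> lidx, ridx;
  for (int i : idx) {
    if (X(i, best_var) <= best_thr) lidx.push_back(i); else ridx.push_back(i);
  }
  tree.var[node] = best_var;
  tree.thr[node] = best_thr;
  tree.pred[node] = -1;
  tree.left[node] = grow_node(tree, X, y, lidx, mtry, tie_class, rng);
  tree.right[node] = grow_node(tree, X, y, ridx, mtry, tie_class, rng);
  return node;
}

int predict_one(const Tree &t, const NumericMatrix &X, int i,
                int perm_var = -1, double perm_val = 0.0) {
  int node = 0;
  while (t.var[node] >= 0) {
    double x = (t.var[node] == perm_var) ? perm_val : X(i, t.var[node]);
    node = (x <= t.thr[node]) ? t.left[node] : t.right[node];
  }
  return t.pred[node];
}

// stratified bootstrap: within each class, draw with replacement as many
// samples as the class holds
void stratified_bootstrap(const IntegerVector &y, Rng &rng,
                          std::vector<int> &idx, std::vector<int> &counts) {
  const int n = y.size();
  std::vector<int> c0, c1;
  for (int i = 0; i < n; ++i) (y[i] == 1 ? c1 : c0).push_back(i);
  idx.clear();
  counts.assign(n, 0);
  for (size_t k = 0; k < c0.size(); ++k) {
    int i = c0[rng.unif_int(static_cast<int>(c0.size()))];
    idx.push_back(i);
    ++counts[i];
  }
  for (size_t k = 0; k < c1.size(); ++k) {
    int i = c1[rng.unif_int(static_cast<int>(c1.size()))];
    idx.push_back(i);
    ++counts[i];
  }
}

struct Forest {
  std::vector<Tree> trees;
  std::vector<std::vector<int>> inbag;  // per tree, per sample counts
};

void grow_forest(Forest &f, const NumericMatrix &X, const IntegerVector &y,
                 int ntree, int mtry, int tie_class, Rng &rng,
                 const IntegerMatrix *fixed_inbag) {
  const int n = X.nrow();
  f.trees.resize(ntree);
  f.inbag.resize(ntree);
  for (int t = 0; t < ntree; ++t) {
    std::vector<int> idx, counts;
    if (fixed_inbag) {
      counts.assign(n, 0);
      idx.clear();
      for (int i = 0; i < n; ++i) {
        counts[i] = (*fixed_inbag)(i, t);
        for (int r = 0; r < counts[i]; ++r) idx.push_back(i);
      }
    } else {
      stratified_bootstrap(y, rng, idx, counts);
    }
    if (idx.empty()) stop("tree %d has an empty in-bag sample", t + 1);
    grow_node(f.trees[t], X, y, idx, mtry, tie_class, rng);
    f.inbag[t] = counts;
  }
}

// Eq.-style VIM: mean over trees of (permuted - unpermuted) OOB
// misclassification counts.  If `perms` is supplied it must give, for every
// tree, a list of 1-based permutations of that tree's OOB positions (OOB
// samples taken in ascending row order), one per variable.
NumericVector forest_vim(const Forest &f, const NumericMatrix &X,
                         const IntegerVector &y, Rng &rng,
                         const List *perms) {
  const int n = X.nrow(), m = X.ncol();
  const int ntree = static_cast<int>(f.trees.size());
  std::vector<double> acc(m, 0.0);

  for (int t = 0; t < ntree; ++t) {
    const Tree &tree = f.trees[t];
    std::vector<int> oob;
    for (int i = 0; i < n; ++i) if (f.inbag[t][i] == 0) oob.push_back(i);
    if (oob.empty()) continue;
    const int no = static_cast<int>(oob.size());

    int err_base = 0;
    for (int i : oob) if (predict_one(tree, X, i) != y[i]) ++err_base;

    // variables actually used in this tree; others contribute exactly zero
    std::vector<bool> used(m, false);
    for (size_t k = 0; k < tree.var.size(); ++k) {
      if (tree.var[k] >= 0) used[tree.var[k]] = true;
    }
    std::vector<int> perm(no);
    for (int v = 0; v < m; ++v) {
      if (!used[v]) continue;
      if (perms) {
        List tp = (*perms)[t];
        IntegerVector pv = tp[v];
        if (pv.size() != no) stop("permutation for tree %d, variable %d must have length %d",
                                  t + 1, v + 1, no);
        for (int k = 0; k < no; ++k) perm[k] = pv[k] - 1;
      } else {
        for (int k = 0; k < no; ++k) perm[k] = k;
        rng.shuffle(perm);
      }
      int err_perm = 0;
      for (int k = 0; k < no; ++k) {
        const int i = oob[k];
        const double pval = X(oob[perm[k]], v);
        if (predict_one(tree, X, i, v, pval) != y[i]) ++err_perm;
      }
      acc[v] += err_perm - err_base;
    }
  }
  NumericVector out(m);
  for (int v = 0; v < m; ++v) out[v] = acc[v] / ntree;
  return out;
}

// ensemble OOB error in percent: majority vote over trees holding the sample
// out of bag; samples never OOB are excluded from the denominator
double forest_oob_error(const Forest &f, const NumericMatrix &X,
                        const IntegerVector &y, int tie_class) {
  const int n = X.nrow();
  const int ntree = static_cast<int>(f.trees.size());
  int wrong = 0, eval = 0;
  for (int i = 0; i < n; ++i) {
    int v0 = 0, v1 = 0;
    for (int t = 0; t < ntree; ++t) {
      if (f.inbag[t][i] != 0) continue;
      if (predict_one(f.trees[t], X, i) == 1) ++v1; else ++v0;
    }
    if (v0 + v1 == 0) continue;
    ++eval;
    if (majority(v0, v1, tie_class) != y[i]) ++wrong;
  }
  if (eval == 0) return NA_REAL;
  return 100.0 * wrong / eval;
}

List forest_to_list(const Forest &f) {
  const int ntree = static_cast<int>(f.trees.size());
  List trees(ntree);
  for (int t = 0; t < ntree; ++t) {
    const Tree &tr = f.trees[t];
    trees[t] = List::create(
      _["var"] = IntegerVector(tr.var.begin(), tr.var.end()),
      _["thr"] = NumericVector(tr.thr.begin(), tr.thr.end()),
      _["left"] = IntegerVector(tr.left.begin(), tr.left.end()),
      _["right"] = IntegerVector(tr.right.begin(), tr.right.end()),
      _["pred"] = IntegerVector(tr.pred.begin(), tr.pred.end()));
  }
  const int n = f.inbag.empty() ? 0 : static_cast<int>(f.inbag[0].size());
  IntegerMatrix inbag(n, ntree);
  for (int t = 0; t < ntree; ++t)
    for (int i = 0; i < n; ++i) inbag(i, t) = f.inbag[t][i];
  return List::create(_["trees"] = trees, _["inbag"] = inbag);
}

Forest forest_from_list(const List &trees, const IntegerMatrix &inbag) {
  Forest f;
  const int ntree = trees.size();
  f.trees.resize(ntree);
  f.inbag.resize(ntree);
  for (int t = 0; t < ntree; ++t) {
    List tr = trees[t];
    IntegerVector var = tr["var"], left = tr["left"], right = tr["right"],
                  pred = tr["pred"];
    NumericVector thr = tr["thr"];
    Tree &x = f.trees[t];
    x.var.assign(var.begin(), var.end());
    x.thr.assign(thr.begin(), thr.end());
    x.left.assign(left.begin(), left.end());
    x.right.assign(right.begin(), right.end());
    x.pred.assign(pred.begin(), pred.end());
    f.inbag[t].resize(inbag.nrow());
    for (int i = 0; i < inbag.nrow(); ++i) f.inbag[t][i] = inbag(i, t);
  }
  return f;
}

void check_xy(const NumericMatrix &X, const IntegerVector &y) {
  if (X.nrow() != y.size()) stop("X and y sizes disagree");
  int n1 = 0;
  for (int i = 0; i < y.size(); ++i) {
    if (y[i] != 0 && y[i] != 1) stop("y must be 0/1");
    n1 += y[i];
  }
  if (n1 == 0 || n1 == y.size()) stop("degenerate labels: only one class present");
}

}  // namespace

// [[Rcpp::export]]
List cpp_grow_forest(NumericMatrix X, IntegerVector y, int ntree, int mtry,
                     double seed, double stream, int tie_class,
                     Nullable<IntegerMatrix> inbag = R_NilValue) {
  check_xy(X, y);
  Rng rng(seed, stream);
  Forest f;
  if (inbag.isNotNull()) {
    IntegerMatrix ib(inbag);
    if (ib.nrow() != X.nrow() || ib.ncol() != ntree)
      stop("inbag must be an n x ntree count matrix");
    grow_forest(f, X, y, ntree, mtry, tie_class, rng, &ib);
  } else {
    grow_forest(f, X, y, ntree, mtry, tie_class, rng, nullptr);
  }
  return forest_to_list(f);
}

// [[Rcpp::export]]
IntegerMatrix cpp_predict_trees(List trees, IntegerMatrix inbag, NumericMatrix X) {
  Forest f = forest_from_list(trees, inbag);
  const int n = X.nrow(), ntree = static_cast<int>(f.trees.size());
  IntegerMatrix out(n, ntree);
  for (int t = 0; t < ntree; ++t)
    for (int i = 0; i < n; ++i) out(i, t) = predict_one(f.trees[t], X, i);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_forest_vim(List trees, IntegerMatrix inbag, NumericMatrix X,
                             IntegerVector y, double seed, double stream,
                             Nullable<List> perms = R_NilValue) {
  Forest f = forest_from_list(trees, inbag);
  Rng rng(seed, stream);
  if (perms.isNotNull()) {
    List p(perms);
    if (p.size() != static_cast<int>(f.trees.size()))
      stop("perms must have one element per tree");
    return forest_vim(f, X, y, rng, &p);
  }
  return forest_vim(f, X, y, rng, nullptr);
}

// [[Rcpp::export]]
double cpp_forest_oob_error(List trees, IntegerMatrix inbag, NumericMatrix X,
                            IntegerVector y, int tie_class) {
  Forest f = forest_from_list(trees, inbag);
  return forest_oob_error(f, X, y, tie_class);
}

// Repeated trials batched in C++: each trial grows a fresh forest from the
// (seed, stream0 + trial) stream and computes VIM for every variable.
// [[Rcpp::export]]
NumericMatrix cpp_vim_trials(NumericMatrix X, IntegerVector y, int ntree,
                             int mtry, int n_trials, double seed,
                             double stream0, int tie_class) {
  check_xy(X, y);
  NumericMatrix out(n_trials, X.ncol());
  for (int trial = 0; trial < n_trials; ++trial) {
    Rng rng(seed, stream0 + trial);
    Forest f;
    grow_forest(f, X, y, ntree, mtry, tie_class, rng, nullptr);
    NumericVector v = forest_vim(f, X, y, rng, nullptr);
    for (int j = 0; j < X.ncol(); ++j) out(trial, j) = v[j];
    if (trial % 64 == 63) Rcpp::checkUserInterrupt();
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_oob_error_trials(NumericMatrix X, IntegerVector y, int ntree,
                                   int mtry, int n_trials, double seed,
                                   double stream0, int tie_class) {
  check_xy(X, y);
  NumericVector out(n_trials);
  for (int trial = 0; trial < n_trials; ++trial) {
    Rng rng(seed, stream0 + trial);
    Forest f;
    grow_forest(f, X, y, ntree, mtry, tie_class, rng, nullptr);
    out[trial] = forest_oob_error(f, X, y, tie_class);
    if (trial % 64 == 63) Rcpp::checkUserInterrupt();
  }
  return out;
}
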