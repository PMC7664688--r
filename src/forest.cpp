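#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <random>
#include <cmath>
using namespace Rcpp;

// Minimal CART random forest for classification (gini splits, bootstrap,
// out-of-bag error, impurity and permutation importance). Written for the
// feature-selection wrappers in this package; the installed R stack carries
// no random-forest implementation.

struct Tree {
  std::vector<int> feat;     // -1 for leaf
  std::vector<double> thr;
  std::vector<int> left, right;
  std::vector<int> pred;     // leaf majority class
};

static inline double gini_from_counts(const std::vector<int>& c, int n) {
  if (n == 0) return 0.0;
  double g = 1.0;
  for (size_t k = 0; k < c.size(); ++k) {
    double p = (double)c[k] / n;
    g -= p * p;
  }
  return g;
}

struct Builder {
  const NumericMatrix& X;
  const IntegerVector& y;
  int K, mtry, min_node, max_depth;
  std::mt19937& rng;
  Tree tree;
  std::vector<double>& imp_gini; // accumulated across trees
  std::vector<char>& used;       // features used by this tree

  Builder(const NumericMatrix& X_, const IntegerVector& y_, int K_, int mtry_,
          int min_node_, int max_depth_, std::mt19937& rng_,
          std::vector<double>& ig, std::vector<char>& us)
    : X(X_), y(y_), K(K_), mtry(mtry_), min_node(min_node_),
      max_depth(max_depth_), rng(rng_), imp_gini(ig), used(us) {}

  int make_leaf(const std::vector<int>& idx) {
    std::vector<int> cnt(K, 0);
    for (int i : idx) cnt[y[i]]++;
    int best = 0;
    for (int k = 1; k < K; ++k) if (cnt[k] > cnt[best]) best = k;
    tree.feat.push_back(-1); tree.thr.push_back(0.0);
    tree.left.push_back(-1); tree.right.push_back(-1);
    tree.pred.push_back(best);
    return (int)tree.feat.size() - 1;
  }

  int build(std::vector<int>& idx, int depth) {
    int n = (int)idx.size();
    std::vector<int> cnt(K, 0);
    for (int i : idx) cnt[y[i]]++;
    int nonzero = 0;
    for (int k = 0; k < K; ++k) if (cnt[k] > 0) ++nonzero;
    if (n < 2 * min_node || nonzero <= 1 || depth >= max_depth)
      return make_leaf(idx);

    double g_parent = gini_from_counts(cnt, n);
    int p = X.ncol();
    // sample mtry features without replacement (partial Fisher-Yates)
    std::vector<int> feats(p);
    for (int j = 0; j < p; ++j) feats[j] = j;
    int m = std::min(mtry, p);
    for (int j = 0; j < m; ++j) {
      std::uniform_int_distribution<int> U(j, p - 1);
      std::swap(feats[j], feats[U(rng)]);
    }

    double best_gain = 1e-12;
    int best_f = -1, best_split_pos = -1;
    double best_thr = 0.0;
    std::vector<int> ord(idx);

    for (int j = 0; j < m; ++j) {
      int f = feats[j];
      std::sort(ord.begin(), ord.end(), [&](int a, int b) {
        double xa = X(a, f), xb = X(b, f);
        if (xa != xb) return xa < xb;
        return a < b;
      });
      std::vector<int> cl(K, 0);
      std::vector<int> cr(cnt);
      for (int s = 0; s < n - 1; ++s) {
        int yi = y[ord[s]];
        cl[yi]++; cr[yi]--;
        double xv = X(ord[s], f), xnext = X(ord[s + 1], f);
        if (xv == xnext) continue;
        int nl = s + 1, nr = n - nl;
        if (nl < min_node || nr < min_node) continue;
        double g = g_parent
          - ((double)nl / n) * gini_from_counts(cl, nl)
          - ((double)nr / n) * gini_from_counts(cr, nr);
        if (g > best_gain) {
          best_gain = g; best_f = f; best_thr = 0.5 * (xv + xnext);
          best_split_pos = s;
        }
      }
    }

    if (best_f < 0) return make_leaf(idx);

    imp_gini[best_f] += n * best_gain;
    used[best_f] = 1;

    std::vector<int> li, ri;
    li.reserve(n); ri.reserve(n);
    for (int i : idx) {
      if (X(i, best_f) <= best_thr) li.push_back(i); else ri.push_back(i);
    }
    if (li.empty() || ri.empty()) return make_leaf(idx);

    int node = (int)tree.feat.size();
    tree.feat.push_back(best_f); tree.thr.push_back(best_thr);
    tree.left.push_back(-1); tree.right.push_back(-1);
    tree.pred.push_back(-1);
    int L = build(li, depth + 1);
    int R = build(ri, depth + 1);
    tree.left[node] = L; tree.right[node] = R;
    (void)best_split_pos;
    return node;
  }
};

static inline int tree_predict_row(const Tree& t, const NumericMatrix& X,
                                   int row, const int* perm_map, int perm_f) {
  int node = 0;
  while (t.feat[node] >= 0) {
    int f = t.feat[node];
    int r = (perm_map != nullptr && f == perm_f) ? perm_map[row] : row;
    node = (X(r, f) <= t.thr[node]) ? t.left[node] : t.right[node];
  }
  return t.pred[node];
}

// `group`: 0-based group id per row. The bootstrap resamples groups, not
// rows, and OOB rows are those of never-drawn groups — so importance and
// OOB error measure generalization across groups (questions), matching the
// grouping discipline of the outer cross-validation. With one row per group
// this reduces to the ordinary bootstrap.
// [[Rcpp::export]]
List rf_fit_cpp(NumericMatrix X, IntegerVector y, int nclass, int ntree,
                int mtry, int min_node, int max_depth, bool perm_importance,
                IntegerVector group, int seed) {
  int n = X.nrow(), p = X.ncol();
  std::mt19937 rng((unsigned)seed);
  std::vector<double> imp_gini(p, 0.0), imp_perm(p, 0.0), imp_perm2(p, 0.0);
  IntegerMatrix oob_votes(n, nclass);
  std::vector<Tree> forest;
  forest.reserve(ntree);

  int ngroup = 0;
  for (int i = 0; i < n; ++i) ngroup = std::max(ngroup, group[i] + 1);
  std::vector<std::vector<int>> rows_of(ngroup);
  for (int i = 0; i < n; ++i) rows_of[group[i]].push_back(i);
  std::uniform_int_distribution<int> Ug(0, ngroup - 1);

  for (int t = 0; t < ntree; ++t) {
    std::vector<char> inbag(n, 0);
    std::vector<int> idx;
    idx.reserve(n);
    for (int g = 0; g < ngroup; ++g) {
      int gs = Ug(rng);
      for (int i : rows_of[gs]) {
        idx.push_back(i);
        inbag[i] = 1;
      }
    }
    std::vector<char> used(p, 0);
    Builder b(X, y, nclass, mtry, min_node, max_depth, rng, imp_gini, used);
    b.build(idx, 0);
    Tree& tr = b.tree;

    std::vector<int> oob;
    for (int i = 0; i < n; ++i) if (!inbag[i]) oob.push_back(i);
    int correct = 0;
    for (int i : oob) {
      int c = tree_predict_row(tr, X, i, nullptr, -1);
      oob_votes(i, c)++;
      if (c == y[i]) ++correct;
    }

    if (perm_importance && !oob.empty()) {
      int no = (int)oob.size();
      std::vector<int> perm_map(n, 0);
      std::vector<int> shuffled(oob);
      for (int f = 0; f < p; ++f) {
        if (!used[f]) continue;
        for (int q = no - 1; q > 0; --q) {
          std::uniform_int_distribution<int> Uq(0, q);
          std::swap(shuffled[q], shuffled[Uq(rng)]);
        }
        for (int q = 0; q < no; ++q) perm_map[oob[q]] = shuffled[q];
        int cperm = 0;
        for (int i : oob)
          if (tree_predict_row(tr, X, i, perm_map.data(), f) == y[i]) ++cperm;
        double v = (double)(correct - cperm) / no;
        imp_perm[f] += v;
        imp_perm2[f] += v * v;
      }
    }
    forest.push_back(std::move(tr));
  }

  // OOB error from accumulated votes (samples never OOB are skipped)
  int miss = 0, counted = 0;
  IntegerVector oob_pred(n, NA_INTEGER);
  for (int i = 0; i < n; ++i) {
    int tot = 0, best = 0;
    for (int k = 0; k < nclass; ++k) {
      tot += oob_votes(i, k);
      if (oob_votes(i, k) > oob_votes(i, best)) best = k;
    }
    if (tot > 0) {
      ++counted;
      oob_pred[i] = best;
      if (best != y[i]) ++miss;
    }
  }
  double oob_err = counted > 0 ? (double)miss / counted : NA_REAL;

  List trees(forest.size());
  for (size_t t = 0; t < forest.size(); ++t) {
    const Tree& tr = forest[t];
    trees[t] = List::create(
      _["feat"] = IntegerVector(tr.feat.begin(), tr.feat.end()),
      _["thr"] = NumericVector(tr.thr.begin(), tr.thr.end()),
      _["left"] = IntegerVector(tr.left.begin(), tr.left.end()),
      _["right"] = IntegerVector(tr.right.begin(), tr.right.end()),
      _["pred"] = IntegerVector(tr.pred.begin(), tr.pred.end()));
  }
  // mean, and z-score (mean / sd over trees; trees not using a feature
  // contribute 0, matching the usual convention)
  NumericVector perm_mean(p), perm_z(p);
  for (int f = 0; f < p; ++f) {
    double m = imp_perm[f] / ntree;
    double v = imp_perm2[f] / ntree - m * m;
    perm_mean[f] = m;
    perm_z[f] = (v > 1e-300) ? m / std::sqrt(v / ntree) : 0.0;
  }

  return List::create(
    _["trees"] = trees,
    _["oob_error"] = oob_err,
    _["oob_pred"] = oob_pred,
    _["importance_gini"] = NumericVector(imp_gini.begin(), imp_gini.end()),
    _["importance_perm"] = perm_mean,
    _["importance_perm_z"] = perm_z);
}

// [[Rcpp::export]]
IntegerMatrix rf_predict_cpp(List trees, NumericMatrix X, int nclass) {
  int n = X.nrow(), nt = trees.size();
  IntegerMatrix votes(n, nclass);
  for (int t = 0; t < nt; ++t) {
    List tl = trees[t];
    Tree tr;
    IntegerVector feat = tl["feat"], left = tl["left"], right = tl["right"],
      pred = tl["pred"];
    NumericVector thr = tl["thr"];
    tr.feat.assign(feat.begin(), feat.end());
    tr.thr.assign(thr.begin(), thr.end());
    tr.left.assign(left.begin(), left.end());
    tr.right.assign(right.begin(), right.end());
    tr.pred.assign(pred.begin(), pred.end());
    for (int i = 0; i < n; ++i)
      votes(i, tree_predict_row(tr, X, i, nullptr, -1))++;
  }
  return votes;
}
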