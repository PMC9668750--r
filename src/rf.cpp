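// Random forest classifier and repeated cross-validated AUC.
//
// Implemented from first principles because the classifier is the core of the
// prioritization method: CART trees with Gini impurity, bootstrap resampling,
// mtry features per node, class probability = mean over trees of the leaf
// class-1 fraction. All randomness comes from a self-contained splitmix64
// generator so that results are bit-identical across platforms for a given
// seed, independent of R's RNG state.
//
// Sample sizes here are tiny (tens of cells per neighbourhood or subsample)
// but the number of forests is huge (one per fold per repeat per barcode),
// so the hot path avoids allocation and re-sorting where possible.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// RNG: splitmix64, bounded ints by rejection (implementation-defined
// std::uniform_int_distribution is avoided on purpose).

static inline uint64_t sm64_next(uint64_t &state) {
  state += 0x9E3779B97F4A7C15ULL;
  uint64_t z = state;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

static inline uint32_t rng_int(uint64_t &state, uint32_t n) {
  // uniform on [0, n): multiply-shift (bias < n / 2^32, immaterial here,
  // and division-free which matters in the tree-growing hot path)
  return (uint32_t)(((sm64_next(state) >> 32) * (uint64_t)n) >> 32);
}

static inline uint64_t fnv1a64(const std::string &s) {
  uint64_t h = 0xcbf29ce484222325ULL;
  for (unsigned char c : s) {
    h ^= (uint64_t)c;
    h *= 0x100000001b3ULL;
  }
  return h;
}

// Derive a child RNG state from a base seed and a string identifier.
// Used for per-unit (cell type / barcode) streams: stable under reordering.
static inline uint64_t derive_state(double seed, const std::string &id) {
  uint64_t s = (uint64_t)(int64_t)seed;
  s ^= fnv1a64(id);
  // one scramble round so nearby seeds decorrelate
  sm64_next(s);
  return s;
}

// [[Rcpp::export(name = ".derive_seed_cpp")]]
double derive_seed_cpp(double seed, std::string id) {
  uint64_t s = derive_state(seed, id);
  uint64_t v = sm64_next(s);
  // 31-bit non-negative value, safe for set.seed()
  return (double)(v >> 33);
}

// ---------------------------------------------------------------------------
// AUC with midrank tie handling (Mann-Whitney; each tied pair credits 0.5).

static double auc_midrank(const std::vector<double> &score,
                          const std::vector<int> &label) {
  const int n = (int)score.size();
  int n1 = 0;
  for (int i = 0; i < n; i++) n1 += label[i];
  const int n0 = n - n1;
  if (n1 == 0 || n0 == 0) return NA_REAL;
  std::vector<int> ord(n);
  for (int i = 0; i < n; i++) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    return score[a] < score[b];
  });
  double ranksum1 = 0.0;
  int i = 0;
  while (i < n) {
    int j = i;
    while (j + 1 < n && score[ord[j + 1]] == score[ord[i]]) j++;
    double midrank = 0.5 * ((i + 1) + (j + 1));
    for (int t = i; t <= j; t++)
      if (label[ord[t]] == 1) ranksum1 += midrank;
    i = j + 1;
  }
  return (ranksum1 - 0.5 * (double)n1 * (n1 + 1)) / ((double)n1 * (double)n0);
}

// [[Rcpp::export(name = ".auc_cpp")]]
double auc_cpp(NumericVector score, IntegerVector label) {
  std::vector<double> s(score.begin(), score.end());
  std::vector<int> l(label.begin(), label.end());
  return auc_midrank(s, l);
}

// ---------------------------------------------------------------------------
// Trees. No depth cap; a node is split while it is impure and holds at least
// min_node_size samples (the probability-forest convention: terminal nodes
// may be smaller, and their class fractions are the tree's probabilities).

struct Tree {
  std::vector<int> feature;     // -1 for leaf
  std::vector<double> threshold;
  std::vector<int> left, right;
  std::vector<double> prob;     // leaf class-1 fraction
};

// Pre-ranked dataset: for each feature, dense value ranks over all samples
// (ties share a rank) plus the value at each rank. Split search at a node is
// then a counting sort into rank buckets instead of a per-node sort.
struct Dataset {
  int n, p;
  std::vector<double> x;        // column-major values: x[f*n + s]
  std::vector<uint16_t> rank;   // rank[f*n + s] in [0, nrank[f])
  std::vector<double> rankval;  // rankval[f*n + r], valid for r < nrank[f]
  std::vector<int> nrank;
  std::vector<double> recip;    // recip[i] = 1/i, i in 1..n

  void init(const double *X, int n_, int p_) {
    n = n_; p = p_;
    if (n > 65535) stop("too many observations for one forest");
    x.assign(X, X + (size_t)n * p);
    rank.resize((size_t)n * p);
    rankval.resize((size_t)n * p);
    nrank.resize(p);
    recip.resize((size_t)n + 1);
    recip[0] = 0.0;
    for (int i = 1; i <= n; i++) recip[i] = 1.0 / (double)i;
    std::vector<int> ord(n);
    for (int f = 0; f < p; f++) {
      const double *xf = x.data() + (size_t)f * n;
      for (int i = 0; i < n; i++) ord[i] = i;
      std::sort(ord.begin(), ord.end(), [&](int a, int b) {
        return xf[a] < xf[b];
      });
      int r = -1;
      double prev = 0.0;
      for (int i = 0; i < n; i++) {
        if (r < 0 || xf[ord[i]] != prev) {
          r++;
          prev = xf[ord[i]];
          rankval[(size_t)f * n + r] = prev;
        }
        rank[(size_t)f * n + ord[i]] = (uint16_t)r;
      }
      nrank[f] = r + 1;
    }
  }
};

struct Workspace {
  std::vector<int> work;        // bootstrap occurrences, partitioned in place
  std::vector<int> featbuf;     // feature indices for mtry sampling
  std::vector<int> bk;          // rank buckets, class counts packed c0 + (c1<<16)
  std::vector<int> pinc;        // per-sample packed increment 1 + (y<<16)
  std::vector<int> touched;     // ranks touched while filling buckets
  std::vector<int> stack_node, stack_lo, stack_hi, stack_c1;
};

static void build_tree(const Dataset &ds, const int *y,
                       int n_train, const int *train_idx,
                       int mtry, int min_node_size, uint64_t &rng,
                       Tree &tree, Workspace &ws) {
  const int n = ds.n, p = ds.p;
  // cap so that small training sets (small k windows) still grow trees:
  // the root must always be splittable when it is impure
  if (min_node_size > n_train / 2) min_node_size = n_train / 2;
  if (min_node_size < 2) min_node_size = 2;
  tree.feature.clear(); tree.threshold.clear();
  tree.left.clear(); tree.right.clear(); tree.prob.clear();

  // bootstrap: n_train draws with replacement from train_idx
  ws.work.resize(n_train);
  for (int i = 0; i < n_train; i++)
    ws.work[i] = train_idx[rng_int(rng, (uint32_t)n_train)];

  if ((int)ws.featbuf.size() != p) {
    ws.featbuf.resize(p);
    for (int f = 0; f < p; f++) ws.featbuf[f] = f;
  }
  if ((int)ws.bk.size() != n) {
    ws.bk.assign(n, 0);
    ws.touched.assign(n, 0);
  }
  if ((int)ws.pinc.size() != n) {
    ws.pinc.resize(n);
    for (int s = 0; s < n; s++) ws.pinc[s] = 1 + (y[s] << 16);
  }

  int root_c1 = 0;
  for (int i = 0; i < n_train; i++) root_c1 += y[ws.work[i]];

  // root
  tree.feature.push_back(-1); tree.threshold.push_back(0.0);
  tree.left.push_back(-1); tree.right.push_back(-1); tree.prob.push_back(0.0);
  ws.stack_node.clear(); ws.stack_lo.clear(); ws.stack_hi.clear();
  ws.stack_c1.clear();
  ws.stack_node.push_back(0); ws.stack_lo.push_back(0);
  ws.stack_hi.push_back(n_train); ws.stack_c1.push_back(root_c1);

  while (!ws.stack_node.empty()) {
    int node = ws.stack_node.back(); ws.stack_node.pop_back();
    int lo = ws.stack_lo.back(); ws.stack_lo.pop_back();
    int hi = ws.stack_hi.back(); ws.stack_hi.pop_back();
    int c1 = ws.stack_c1.back(); ws.stack_c1.pop_back();
    int m = hi - lo;

    tree.prob[node] = (double)c1 / (double)m;
    // leaf if pure or below the minimal size to attempt a split
    // (probability-forest convention: terminal nodes may be smaller)
    if (c1 == 0 || c1 == m || m < min_node_size || m < 2) continue;

    // Split scoring is division-free: minimize the weighted child impurity
    //   l1*(nl-l1)/nl + r1*(nr-r1)/nr   (Gini up to the constant 2/m)
    // using a precomputed reciprocal table.
    const double parent_w = (double)c1 * (double)(m - c1) * ds.recip[m];
    double best_w = parent_w - 1e-9;
    int best_f = -1, best_l1 = 0, best_nl = 0;
    double best_thr = 0.0;

    // sample mtry features without replacement (partial Fisher-Yates on a
    // persistent pool; swaps keep the pool a permutation, which suffices)
    for (int t = 0; t < mtry; t++) {
      int rswap = t + (int)rng_int(rng, (uint32_t)(p - t));
      std::swap(ws.featbuf[t], ws.featbuf[rswap]);
      const int f = ws.featbuf[t];
      const uint16_t *rk = ds.rank.data() + (size_t)f * n;
      const double *rv = ds.rankval.data() + (size_t)f * n;

      // counting sort into rank buckets (class counts packed into one int),
      // tracking the rank span so the scan can stay tight
      int rmin = n, rmax = 0;
      for (int i = lo; i < hi; i++) {
        int s = ws.work[i];
        int r = rk[s];
        ws.bk[r] += ws.pinc[s];
        if (r < rmin) rmin = r;
        if (r > rmax) rmax = r;
      }

      if (rmin == rmax) {          // constant within the node
        ws.bk[rmin] = 0;           // clear the bucket before moving on
        continue;
      }

      // scan ranks in value order; every boundary in the span is evaluated
      // (at an unoccupied rank the running counts — hence the impurity —
      // equal those of the previous occupied boundary, so extra evaluations
      // are redundant but harmless, and the loop stays branch-free)
      int b0 = ws.bk[rmin];
      ws.bk[rmin] = 0;
      int l1 = b0 >> 16, l0 = (b0 & 0xffff) - l1;
      for (int r = rmin + 1; r <= rmax; r++) {
        int b = ws.bk[r];
        ws.bk[r] = 0;
        int nl = l0 + l1, nrem = m - nl;
        int r1 = c1 - l1;
        double w = (double)l1 * (double)l0 * ds.recip[nl] +
                   (double)r1 * (double)(nrem - r1) * ds.recip[nrem];
        if (w < best_w) {
          best_w = w;
          best_f = f;
          best_l1 = l1;
          best_nl = nl;
          best_thr = 0.5 * (rv[r - 1] + rv[r]);
        }
        int c1b = b >> 16;
        l0 += (b & 0xffff) - c1b; l1 += c1b;
      }
    }

    if (best_f < 0) continue;  // no informative split among candidates: leaf

    // partition work[lo,hi) by x < thr
    const double *xf = ds.x.data() + (size_t)best_f * n;
    int i = lo, j = hi - 1;
    while (i <= j) {
      if (xf[ws.work[i]] < best_thr) { i++; }
      else { std::swap(ws.work[i], ws.work[j]); j--; }
    }
    int mid = i;
    if (mid == lo || mid == hi) continue;  // numeric edge case: leaf

    int lnode = (int)tree.feature.size();
    tree.feature.push_back(-1); tree.threshold.push_back(0.0);
    tree.left.push_back(-1); tree.right.push_back(-1); tree.prob.push_back(0.0);
    int rnode = (int)tree.feature.size();
    tree.feature.push_back(-1); tree.threshold.push_back(0.0);
    tree.left.push_back(-1); tree.right.push_back(-1); tree.prob.push_back(0.0);

    tree.feature[node] = best_f;
    tree.threshold[node] = best_thr;
    tree.left[node] = lnode;
    tree.right[node] = rnode;

    // class-1 counts of the children are known from the chosen split;
    // recount only if midpoint rounding made the partition disagree
    if (mid - lo != best_nl) {
      best_l1 = 0;
      for (int t = lo; t < mid; t++) best_l1 += y[ws.work[t]];
    }
    ws.stack_node.push_back(lnode); ws.stack_lo.push_back(lo);
    ws.stack_hi.push_back(mid); ws.stack_c1.push_back(best_l1);
    ws.stack_node.push_back(rnode); ws.stack_lo.push_back(mid);
    ws.stack_hi.push_back(hi); ws.stack_c1.push_back(c1 - best_l1);
  }
}

static inline double tree_predict(const Tree &tree, const double *X, int n,
                                  int sample) {
  int node = 0;
  while (tree.feature[node] >= 0) {
    double v = X[(size_t)tree.feature[node] * n + sample];
    node = (v < tree.threshold[node]) ? tree.left[node] : tree.right[node];
  }
  return tree.prob[node];
}

// forest probability for one sample
static double forest_predict(const std::vector<Tree> &forest, const double *X,
                             int n, int sample) {
  double acc = 0.0;
  for (const Tree &t : forest) acc += tree_predict(t, X, n, sample);
  return acc / (double)forest.size();
}

// ---------------------------------------------------------------------------
// Stratified fold assignment. Within each class, indices are shuffled and
// dealt round-robin; class c starts dealing at fold (c mod n_folds), so a
// 20/20 two-class sample under 3 folds yields fold sizes {14, 13, 13}.

static void stratified_folds(const std::vector<int> &y, int n_folds,
                             uint64_t &rng, std::vector<int> &fold) {
  const int n = (int)y.size();
  fold.assign(n, 0);
  for (int cls = 0; cls <= 1; cls++) {
    std::vector<int> idx;
    for (int i = 0; i < n; i++)
      if (y[i] == cls) idx.push_back(i);
    for (int i = (int)idx.size() - 1; i > 0; i--) {
      int j = (int)rng_int(rng, (uint32_t)(i + 1));
      std::swap(idx[i], idx[j]);
    }
    for (size_t t = 0; t < idx.size(); t++)
      fold[idx[t]] = (int)((t + cls) % (size_t)n_folds);
  }
}

// [[Rcpp::export(name = ".stratified_folds_cpp")]]
IntegerVector stratified_folds_cpp(IntegerVector y, int n_folds, double seed) {
  std::vector<int> yv(y.begin(), y.end());
  uint64_t rng = derive_state(seed, "folds");
  std::vector<int> fold;
  stratified_folds(yv, n_folds, rng, fold);
  return IntegerVector(fold.begin(), fold.end());  // 0-based
}

// ---------------------------------------------------------------------------
// Repeated stratified k-fold CV AUC. Returns one AUC per repeat: the mean of
// per-fold AUCs (folds whose test split is single-class yield NA and are
// dropped from the mean).

// [[Rcpp::export(name = ".rf_cv_auc_cpp")]]
NumericVector rf_cv_auc_cpp(NumericMatrix X, IntegerVector y, int n_folds,
                            int n_trees, int n_repeats, int mtry,
                            int min_node_size, double seed) {
  const int n = X.nrow(), p = X.ncol();
  std::vector<double> xv(X.begin(), X.end());  // column-major already
  std::vector<int> yv(y.begin(), y.end());
  if (mtry < 1) mtry = 1;
  if (mtry > p) mtry = p;

  uint64_t rng = (uint64_t)(int64_t)seed;
  sm64_next(rng);

  Dataset ds;
  ds.init(xv.data(), n, p);

  NumericVector out(n_repeats);
  std::vector<int> fold, train_idx, test_idx;
  std::vector<Tree> forest((size_t)n_trees);
  Workspace ws;
  std::vector<double> scores;
  std::vector<int> labels;

  for (int rep = 0; rep < n_repeats; rep++) {
    stratified_folds(yv, n_folds, rng, fold);
    double fold_sum = 0.0;
    int fold_cnt = 0;
    for (int f = 0; f < n_folds; f++) {
      train_idx.clear(); test_idx.clear();
      for (int i = 0; i < n; i++)
        (fold[i] == f ? test_idx : train_idx).push_back(i);
      if (train_idx.empty() || test_idx.empty()) continue;
      for (int t = 0; t < n_trees; t++)
        build_tree(ds, yv.data(), (int)train_idx.size(),
                   train_idx.data(), mtry, min_node_size, rng,
                   forest[(size_t)t], ws);
      scores.clear(); labels.clear();
      for (int i : test_idx) {
        scores.push_back(forest_predict(forest, xv.data(), n, i));
        labels.push_back(yv[i]);
      }
      double a = auc_midrank(scores, labels);
      if (!ISNAN(a)) { fold_sum += a; fold_cnt++; }
    }
    out[rep] = fold_cnt > 0 ? fold_sum / fold_cnt : NA_REAL;
  }
  return out;
}

// [[Rcpp::export(name = ".rf_fit_predict_cpp")]]
NumericVector rf_fit_predict_cpp(NumericMatrix Xtrain, IntegerVector ytrain,
                                 NumericMatrix Xtest, int n_trees, int mtry,
                                 int min_node_size, double seed) {
  const int ntr = Xtrain.nrow(), p = Xtrain.ncol(), nte = Xtest.nrow();
  if (Xtest.ncol() != p) stop("train and test feature counts differ");
  if (mtry < 1) mtry = 1;
  if (mtry > p) mtry = p;

  // stack train and test into one column-major block so trees index one array
  std::vector<double> xv((size_t)(ntr + nte) * p);
  for (int f = 0; f < p; f++) {
    for (int i = 0; i < ntr; i++)
      xv[(size_t)f * (ntr + nte) + i] = Xtrain(i, f);
    for (int i = 0; i < nte; i++)
      xv[(size_t)f * (ntr + nte) + ntr + i] = Xtest(i, f);
  }
  std::vector<int> yv(ntr + nte, 0);
  for (int i = 0; i < ntr; i++) yv[i] = ytrain[i];

  uint64_t rng = (uint64_t)(int64_t)seed;
  sm64_next(rng);

  Dataset ds;
  ds.init(xv.data(), ntr + nte, p);

  std::vector<int> train_idx(ntr);
  for (int i = 0; i < ntr; i++) train_idx[i] = i;
  std::vector<Tree> forest((size_t)n_trees);
  Workspace ws;
  for (int t = 0; t < n_trees; t++)
    build_tree(ds, yv.data(), ntr, train_idx.data(),
               mtry, min_node_size, rng, forest[(size_t)t], ws);

  NumericVector out(nte);
  for (int i = 0; i < nte; i++)
    out[i] = forest_predict(forest, xv.data(), ntr + nte, ntr + i);
  return out;
}
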