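// Gini-split classification forest with per-node weighted candidate-feature
// sampling. Trees are fully deterministic given (seed, tree index): each tree
// owns an independent xoshiro256++ substream, so results do not depend on R's
// RNG state or on execution order.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cstdint>
#include <cmath>

using namespace Rcpp;

namespace {

// splitmix64 used only for seeding the per-tree streams
inline uint64_t splitmix64(uint64_t &x) {
  x += 0x9E3779B97F4A7C15ULL;
  uint64_t z = x;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Xoshiro {
  uint64_t s[4];
  Xoshiro(uint64_t seed, uint64_t stream) {
    uint64_t x = seed * 0x9E3779B97F4A7C15ULL + stream;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(x);
  }
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform in [0, 1), 53-bit resolution, platform independent
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
};

// n * Gini(a, b) for a two-class node: n(1 - (a/n)^2 - (b/n)^2) = 2ab/n
inline double gini_times_n(double a, double b) {
  double n = a + b;
  return n > 0.0 ? 2.0 * a * b / n : 0.0;
}

// Weighted sampling of distinct feature indices without replacement, each
// successive draw proportional to the remaining probabilities. Implemented as
// proportional draws WITH replacement where duplicates are redrawn (the
// conditional law of the next new index is exactly proportional to the
// remaining mass, so the scheme is identical in distribution), with an exact
// renormalized fallback when rejections pile up on concentrated weights.
struct CandidateSampler {
  int p = 0;
  double total = 0.0;
  std::vector<double> w, cum;
  std::vector<int> nonzero;

  void init(const NumericVector &probs) {
    p = probs.size();
    w.assign(probs.begin(), probs.end());
    cum.resize(p);
    nonzero.clear();
    double acc = 0.0;
    for (int j = 0; j < p; ++j) {
      if (w[j] > 0.0) nonzero.push_back(j);
      acc += w[j];
      cum[j] = acc;
    }
    total = acc;
  }

  void draw_exact(Xoshiro &rng, int k, std::vector<int> &out,
                  std::vector<int> &mark, int epoch) const {
    while ((int)out.size() < k) {
      double tot = 0.0;
      for (int j : nonzero) if (mark[j] != epoch) tot += w[j];
      double u = rng.unif() * tot, acc = 0.0;
      int pick = -1;
      for (int j : nonzero) {
        if (mark[j] == epoch) continue;
        acc += w[j];
        if (acc > u) { pick = j; break; }
      }
      if (pick < 0) {  // float-edge guard: take last unmarked
        for (int t = (int)nonzero.size() - 1; t >= 0; --t)
          if (mark[nonzero[t]] != epoch) { pick = nonzero[t]; break; }
      }
      mark[pick] = epoch;
      out.push_back(pick);
    }
  }

  // out is sorted ascending (deterministic candidate evaluation order)
  void draw(Xoshiro &rng, int mtry, std::vector<int> &out,
            std::vector<int> &mark, int epoch) const {
    int k = std::min<int>(mtry, (int)nonzero.size());
    out.clear();
    if (k == (int)nonzero.size()) { out = nonzero; return; }
    int rejects = 0, cap = 100 + 20 * k;
    while ((int)out.size() < k) {
      double u = rng.unif() * total;
      int j = (int)(std::upper_bound(cum.begin(), cum.end(), u) - cum.begin());
      if (j >= p) j = p - 1;
      if (mark[j] == epoch) {
        if (++rejects > cap) { draw_exact(rng, k, out, mark, epoch); break; }
        continue;
      }
      mark[j] = epoch;
      out.push_back(j);
    }
    std::sort(out.begin(), out.end());
  }
};

struct TreeOut {
  std::vector<int> feat, left, right, c0, c1;
  std::vector<double> thr;
  int add_node() {
    feat.push_back(-1); thr.push_back(0.0);
    left.push_back(-1); right.push_back(-1);
    c0.push_back(0); c1.push_back(0);
    return (int)feat.size() - 1;
  }
};

struct Group { double v; double n0, n1; };

void build_one_tree(const double *X, int n, const int *y,
                    const CandidateSampler &smp, Xoshiro &rng,
                    int mtry, int min_node_size, bool bootstrap,
                    TreeOut &tree, std::vector<double> &imp,
                    std::vector<int> &mark, int &epoch) {
  std::vector<int> idx(n);
  if (bootstrap) {
    for (int i = 0; i < n; ++i) {
      int r = (int)(rng.unif() * n);
      idx[i] = r >= n ? n - 1 : r;
    }
  } else {
    for (int i = 0; i < n; ++i) idx[i] = i;
  }

  struct Item { int node, s, e; };
  std::vector<Item> stack;
  stack.push_back({tree.add_node(), 0, n});

  std::vector<int> cand;
  std::vector<std::pair<double, int>> nz;
  std::vector<Group> groups;

  while (!stack.empty()) {
    Item it = stack.back();
    stack.pop_back();
    int nn = it.e - it.s, c0 = 0, c1 = 0;
    for (int i = it.s; i < it.e; ++i) (y[idx[i]] ? c1 : c0)++;
    tree.c0[it.node] = c0;
    tree.c1[it.node] = c1;
    if (c0 == 0 || c1 == 0 || nn < 2 || nn <= min_node_size) continue;

    ++epoch;
    smp.draw(rng, mtry, cand, mark, epoch);

    int best_f = -1;
    double best_thr = 0.0, best_dec = 1e-12;
    double parent = gini_times_n(c0, c1);

    for (int f : cand) {
      const double *col = X + (size_t)f * n;
      int z0 = 0, z1 = 0;
      nz.clear();
      for (int i = it.s; i < it.e; ++i) {
        double v = col[idx[i]];
        if (v == 0.0) (y[idx[i]] ? z1 : z0)++;
        else nz.push_back({v, y[idx[i]]});
      }
      if (nz.empty()) continue;  // constant zero in this node
      std::sort(nz.begin(), nz.end());

      // distinct-value groups in ascending order, zero block slotted between
      // negatives and positives (count matrices make the zero path dominant)
      groups.clear();
      bool zdone = (z0 + z1) == 0;
      size_t i2 = 0;
      while (i2 < nz.size()) {
        if (!zdone && nz[i2].first > 0.0) {
          groups.push_back({0.0, (double)z0, (double)z1});
          zdone = true;
          continue;
        }
        double v = nz[i2].first;
        int a = 0, b = 0;
        while (i2 < nz.size() && nz[i2].first == v) {
          (nz[i2].second ? b : a)++;
          ++i2;
        }
        groups.push_back({v, (double)a, (double)b});
      }
      if (!zdone) groups.push_back({0.0, (double)z0, (double)z1});
      if (groups.size() < 2) continue;

      double l0 = 0.0, l1 = 0.0;
      for (size_t g = 0; g + 1 < groups.size(); ++g) {
        l0 += groups[g].n0;
        l1 += groups[g].n1;
        double r0 = c0 - l0, r1 = c1 - l1;
        double dec = parent - gini_times_n(l0, l1) - gini_times_n(r0, r1);
        // strict > keeps the lowest feature (ascending candidate order) and
        // the lowest threshold (ascending scan) on exact ties
        if (dec > best_dec) {
          best_dec = dec;
          best_f = f;
          best_thr = (groups[g].v + groups[g + 1].v) / 2.0;
        }
      }
    }

    if (best_f < 0) continue;  // no candidate with positive impurity decrease
    imp[best_f] += best_dec / n;  // (n_node/n)[G - weighted child G]

    const double *col = X + (size_t)best_f * n;
    double thr = best_thr;
    auto mid = std::partition(idx.begin() + it.s, idx.begin() + it.e,
                              [col, thr](int r) { return col[r] <= thr; });
    int nleft = (int)(mid - (idx.begin() + it.s));
    int li = tree.add_node(), ri = tree.add_node();
    tree.feat[it.node] = best_f;
    tree.thr[it.node] = best_thr;
    tree.left[it.node] = li;
    tree.right[it.node] = ri;
    stack.push_back({li, it.s, it.s + nleft});
    stack.push_back({ri, it.s + nleft, it.e});
  }
}

inline int tree_vote(const IntegerVector &feat, const NumericVector &thr,
                     const IntegerVector &left, const IntegerVector &right,
                     const IntegerVector &c0, const IntegerVector &c1,
                     const double *x, int n, int nsamp, int i) {
  int node = 0;
  while (feat[node] >= 0) {
    double v = x[(size_t)feat[node] * nsamp + i];
    node = (v <= thr[node]) ? left[node] : right[node];
  }
  return c1[node] > c0[node] ? 1 : 0;  // leaf tie -> negative
  (void)n;
}

}  // namespace

// [[Rcpp::export]]
List rf_fit_cpp(NumericMatrix X, IntegerVector y, NumericVector probs,
                int n_trees, int mtry, int min_node_size, bool bootstrap,
                double seed) {
  int n = X.nrow(), p = X.ncol();
  CandidateSampler smp;
  smp.init(probs);
  if (smp.nonzero.empty()) stop("all candidate probabilities are zero");

  std::vector<double> imp(p, 0.0);
  std::vector<int> mark(p, -1);
  int epoch = 0;
  List trees(n_trees);
  const double *Xp = REAL(X);
  std::vector<int> yv(y.begin(), y.end());

  for (int t = 0; t < n_trees; ++t) {
    Xoshiro rng((uint64_t)seed, (uint64_t)t + 1);
    TreeOut tr;
    build_one_tree(Xp, n, yv.data(), smp, rng, mtry, min_node_size,
                   bootstrap, tr, imp, mark, epoch);
    trees[t] = List::create(
        _["feature"] = IntegerVector(tr.feat.begin(), tr.feat.end()),
        _["threshold"] = NumericVector(tr.thr.begin(), tr.thr.end()),
        _["left"] = IntegerVector(tr.left.begin(), tr.left.end()),
        _["right"] = IntegerVector(tr.right.begin(), tr.right.end()),
        _["count0"] = IntegerVector(tr.c0.begin(), tr.c0.end()),
        _["count1"] = IntegerVector(tr.c1.begin(), tr.c1.end()));
  }
  for (int j = 0; j < p; ++j) imp[j] /= n_trees;
  return List::create(_["trees"] = trees,
                      _["importance"] = NumericVector(imp.begin(), imp.end()));
}

// [[Rcpp::export]]
IntegerMatrix rf_predict_votes_cpp(List trees, NumericMatrix X) {
  int nsamp = X.nrow(), n_trees = trees.size();
  IntegerMatrix votes(nsamp, n_trees);
  const double *Xp = REAL(X);
  for (int t = 0; t < n_trees; ++t) {
    List tr = trees[t];
    IntegerVector feat = tr["feature"], left = tr["left"], right = tr["right"],
                  c0 = tr["count0"], c1 = tr["count1"];
    NumericVector thr = tr["threshold"];
    for (int i = 0; i < nsamp; ++i)
      votes(i, t) = tree_vote(feat, thr, left, right, c0, c1, Xp, 0, nsamp, i);
  }
  return votes;
}

// [[Rcpp::export]]
IntegerVector rf_sample_candidates_cpp(NumericVector probs, int mtry,
                                       double seed) {
  CandidateSampler smp;
  smp.init(probs);
  if (smp.nonzero.empty()) stop("all candidate probabilities are zero");
  Xoshiro rng((uint64_t)seed, 1);
  std::vector<int> mark(probs.size(), -1), out;
  int epoch = 1;
  smp.draw(rng, mtry, out, mark, epoch);
  IntegerVector res(out.size());
  for (size_t i = 0; i < out.size(); ++i) res[i] = out[i] + 1;
  return res;
}
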