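#include <Rcpp.h>
#include <random>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Minimal random forest for multiclass classification: bagged CART trees,
// Gini impurity splits on a random feature subset per node, majority vote
// with ties broken toward the lowest class index. Self-contained because no
// tree/forest package ships with the target environment. Deterministic given
// the seed (std::mt19937 is fully specified by the standard).

namespace {

struct Node {
  int feat = -1;       // -1 => leaf
  double thr = 0.0;
  int left = -1, right = -1;
  int pred = 0;
};

struct Tree {
  std::vector<Node> nodes;

  int predict(const NumericMatrix& X, int row) const {
    int cur = 0;
    while (nodes[cur].feat >= 0) {
      cur = (X(row, nodes[cur].feat) <= nodes[cur].thr) ? nodes[cur].left
                                                        : nodes[cur].right;
    }
    return nodes[cur].pred;
  }
};

class Builder {
public:
  Builder(const NumericMatrix& X, const IntegerVector& y, int nclass,
          int mtry, int min_node, std::mt19937& rng)
      : X_(X), y_(y), nclass_(nclass), mtry_(mtry), min_node_(min_node),
        rng_(rng) {}

  Tree build(std::vector<int>& idx) {
    Tree t;
    grow(t, idx, 0, (int)idx.size());
    return t;
  }

private:
  const NumericMatrix& X_;
  const IntegerVector& y_;
  int nclass_, mtry_, min_node_;
  std::mt19937& rng_;

  int majority(const std::vector<int>& counts) const {
    int best = 0;
    for (int c = 1; c < nclass_; ++c)
      if (counts[c] > counts[best]) best = c;
    return best;
  }

  int grow(Tree& t, std::vector<int>& idx, int lo, int hi) {
    std::vector<int> counts(nclass_, 0);
    for (int i = lo; i < hi; ++i) counts[y_[idx[i]]]++;
    int n = hi - lo;
    int node_id = (int)t.nodes.size();
    t.nodes.push_back(Node());

    int nonzero = 0;
    for (int c = 0; c < nclass_; ++c) nonzero += counts[c] > 0;
    if (n <= min_node_ || nonzero <= 1) {
      t.nodes[node_id].pred = majority(counts);
      return node_id;
    }

    int p = X_.ncol();
    // sample mtry features without replacement (partial Fisher-Yates)
    std::vector<int> feats(p);
    for (int j = 0; j < p; ++j) feats[j] = j;
    int m = std::min(mtry_, p);
    for (int j = 0; j < m; ++j) {
      std::uniform_int_distribution<int> U(j, p - 1);
      std::swap(feats[j], feats[U(rng_)]);
    }

    double best_gain = 0.0, best_thr = 0.0;
    int best_feat = -1;
    double parent_imp = 0.0;
    for (int c = 0; c < nclass_; ++c) {
      double f = (double)counts[c] / n;
      parent_imp += f * (1.0 - f);
    }

    std::vector<int> ord(idx.begin() + lo, idx.begin() + hi);
    std::vector<int> lc(nclass_);
    for (int jj = 0; jj < m; ++jj) {
      int f = feats[jj];
      std::sort(ord.begin(), ord.end(), [&](int a, int b) {
        return X_(a, f) < X_(b, f);
      });
      std::fill(lc.begin(), lc.end(), 0);
      int nl = 0;
      for (int i = 0; i + 1 < n; ++i) {
        lc[y_[ord[i]]]++;
        nl++;
        if (X_(ord[i], f) == X_(ord[i + 1], f)) continue; // no cut here
        int nr = n - nl;
        double gl = 0.0, gr = 0.0;
        for (int c = 0; c < nclass_; ++c) {
          double fl = (double)lc[c] / nl;
          double fr = (double)(counts[c] - lc[c]) / nr;
          gl += fl * (1.0 - fl);
          gr += fr * (1.0 - fr);
        }
        double gain = parent_imp - ((double)nl / n) * gl - ((double)nr / n) * gr;
        if (gain > best_gain + 1e-12) {
          best_gain = gain;
          best_feat = f;
          best_thr = 0.5 * (X_(ord[i], f) + X_(ord[i + 1], f));
        }
      }
    }

    if (best_feat < 0) {
      t.nodes[node_id].pred = majority(counts);
      return node_id;
    }

    // partition idx[lo, hi) around the split, preserving relative order
    std::stable_partition(idx.begin() + lo, idx.begin() + hi, [&](int a) {
      return X_(a, best_feat) <= best_thr;
    });
    int mid = lo;
    while (mid < hi && X_(idx[mid], best_feat) <= best_thr) ++mid;
    if (mid == lo || mid == hi) { // numeric degeneracy
      t.nodes[node_id].pred = majority(counts);
      return node_id;
    }
    t.nodes[node_id].feat = best_feat;
    t.nodes[node_id].thr = best_thr;
    int l = grow(t, idx, lo, mid);
    int r = grow(t, idx, mid, hi);
    t.nodes[node_id].left = l;
    t.nodes[node_id].right = r;
    return node_id;
  }
};

} // namespace

// [[Rcpp::export]]
IntegerVector rf_fit_predict_cpp(NumericMatrix Xtr, IntegerVector ytr,
                                 NumericMatrix Xte, int nclass, int ntree,
                                 int mtry, int min_node, int seed) {
  int n = Xtr.nrow(), nte = Xte.nrow();
  if (n < 1) stop("empty training set");
  std::mt19937 rng((unsigned)seed);
  std::uniform_int_distribution<int> boot(0, n - 1);

  std::vector<std::vector<int>> votes(nte, std::vector<int>(nclass, 0));
  std::vector<int> idx(n);
  for (int b = 0; b < ntree; ++b) {
    for (int i = 0; i < n; ++i) idx[i] = boot(rng);
    Builder bl(Xtr, ytr, nclass, mtry, min_node, rng);
    Tree t = bl.build(idx);
    for (int i = 0; i < nte; ++i) votes[i][t.predict(Xte, i)]++;
  }
  IntegerVector out(nte);
  for (int i = 0; i < nte; ++i) {
    int best = 0;
    for (int c = 1; c < nclass; ++c)
      if (votes[i][c] > votes[i][best]) best = c;
    out[i] = best;
  }
  return out;
}
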