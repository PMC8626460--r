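// Exact interventional Shapley attribution for boosted-tree ensembles.
//
// For one instance x, one background row z and one tree, the coalition game
// is v(S) = f(composite), where the composite takes x's value on features in
// S and z's value elsewhere. Each leaf turns this into an AND-game over the
// features split on along its path: the leaf is reached iff every feature
// that must carry x's value is in S (set D) and every feature that must
// carry z's value is out of S (set E); a feature failing under both values
// kills the leaf. The Shapley value of such an indicator game is closed
// form: with p = |D|, q = |E|, k = p + q,
//   phi_j = (p-1)! (k-p)! / k!            for j in D,
//   phi_j = -p! (k-p-1)! / k!             for j in E,
// and 0 elsewhere. Summing leaf_value * phi over leaves and averaging over
// background rows gives the exact interventional Shapley vector; summing
// over j recovers f(x) - E_z f(z) (local accuracy) by construction.
//
// Because a path of length L admits only 2^L distinct per-node routing
// patterns, background rows are collapsed into pattern counts per leaf and
// the per-pattern attributions are precomputed, making the per-instance
// cost O(trees * leaves * depth), independent of background size.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Node {
  int feature;   // -1 for leaf
  double thr;
  int yes, no, miss;
  double value;
};

struct Tree {
  std::vector<Node> nodes;
};

// one root-to-leaf path
struct LeafPath {
  double value;
  std::vector<int> node_feature;   // feature split on at each path node
  std::vector<double> node_thr;
  std::vector<bool> miss_yes;      // missing routes to yes-child?
  std::vector<bool> toward_yes;    // leaf lies in the yes subtree?
  std::vector<int> uniq_feat;      // unique features on the path
  std::vector<int> feat_slot;      // path position -> index into uniq_feat
  // precomputed attribution per x-routing pattern (filled later):
  // contrib[amask * uniq_feat.size() + u]
  std::vector<double> contrib;
};

// Split comparisons are made in single precision, matching the boosting
// backend's float32 storage of both feature values and thresholds.
inline bool goes_yes(double v, double thr) {
  return (float)v < (float)thr;
}

inline bool routes_toward(double v, double thr, bool miss_yes, bool toward_yes) {
  bool go_yes = ISNAN(v) ? miss_yes : goes_yes(v, thr);
  return go_yes == toward_yes;
}

std::vector<Tree> build_trees(const IntegerVector& feature,
                              const NumericVector& threshold,
                              const IntegerVector& yes,
                              const IntegerVector& no,
                              const IntegerVector& miss,
                              const NumericVector& value,
                              const IntegerVector& offset) {
  int n_tree = offset.size() - 1;
  std::vector<Tree> trees(n_tree);
  for (int t = 0; t < n_tree; ++t) {
    int a = offset[t], b = offset[t + 1];
    trees[t].nodes.resize(b - a);
    for (int i = a; i < b; ++i) {
      Node& nd = trees[t].nodes[i - a];
      nd.feature = feature[i];
      nd.thr = threshold[i];
      nd.yes = yes[i];
      nd.no = no[i];
      nd.miss = miss[i];
      nd.value = value[i];
    }
  }
  return trees;
}

double traverse(const Tree& tr, const double* x, int n, int stride) {
  int id = 0;
  while (tr.nodes[id].feature >= 0) {
    const Node& nd = tr.nodes[id];
    double v = x[(size_t)nd.feature * stride];
    bool go_yes = ISNAN(v) ? (nd.miss == nd.yes) : goes_yes(v, nd.thr);
    id = go_yes ? nd.yes : nd.no;
  }
  (void)n;
  return tr.nodes[id].value;
}

void collect_leaves(const Tree& tr, int id, LeafPath cur,
                    std::vector<LeafPath>& out) {
  const Node& nd = tr.nodes[id];
  if (nd.feature < 0) {
    cur.value = nd.value;
    out.push_back(cur);
    return;
  }
  if ((int)cur.node_feature.size() >= 12)
    stop("tree depth exceeds the supported limit (12) for exact attribution");
  LeafPath l = cur, r = cur;
  l.node_feature.push_back(nd.feature);
  l.node_thr.push_back(nd.thr);
  l.miss_yes.push_back(nd.miss == nd.yes);
  l.toward_yes.push_back(true);
  r.node_feature.push_back(nd.feature);
  r.node_thr.push_back(nd.thr);
  r.miss_yes.push_back(nd.miss == nd.yes);
  r.toward_yes.push_back(false);
  collect_leaves(tr, nd.yes, l, out);
  collect_leaves(tr, nd.no, r, out);
}

}  // namespace

// [[Rcpp::export]]
NumericVector cpp_predict_margin(const NumericMatrix& X,
                                 const IntegerVector& feature,
                                 const NumericVector& threshold,
                                 const IntegerVector& yes,
                                 const IntegerVector& no,
                                 const IntegerVector& missing,
                                 const NumericVector& value,
                                 const IntegerVector& offset,
                                 bool float_acc = false) {
  std::vector<Tree> trees =
      build_trees(feature, threshold, yes, no, missing, value, offset);
  int n = X.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    const double* row = &X(i, 0);
    if (float_acc) {
      // replicate the backend's single-precision accumulation order, for
      // bit-faithful round-trip checks against the fitted booster
      float m = 0;
      for (size_t t = 0; t < trees.size(); ++t)
        m += (float)traverse(trees[t], row, X.ncol(), n);
      out[i] = m;
    } else {
      double m = 0;
      for (size_t t = 0; t < trees.size(); ++t)
        m += traverse(trees[t], row, X.ncol(), n);
      out[i] = m;
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_tree_shapley(const NumericMatrix& X,
                               const NumericMatrix& Z,
                               const IntegerVector& feature,
                               const NumericVector& threshold,
                               const IntegerVector& yes,
                               const IntegerVector& no,
                               const IntegerVector& missing,
                               const NumericVector& value,
                               const IntegerVector& offset) {
  std::vector<Tree> trees =
      build_trees(feature, threshold, yes, no, missing, value, offset);
  const int n = X.nrow(), d = X.ncol(), B = Z.nrow();
  if (B < 1) stop("background set must contain at least one row");
  NumericMatrix phi(n, d);

  std::vector<double> fact(16, 1.0);
  for (int i = 1; i < 16; ++i) fact[i] = fact[i - 1] * i;

  for (size_t t = 0; t < trees.size(); ++t) {
    std::vector<LeafPath> leaves;
    collect_leaves(trees[t], 0, LeafPath(), leaves);

    for (LeafPath& lf : leaves) {
      const int L = lf.node_feature.size();
      lf.feat_slot.resize(L);
      for (int j = 0; j < L; ++j) {
        int f = lf.node_feature[j];
        int slot = -1;
        for (size_t u = 0; u < lf.uniq_feat.size(); ++u)
          if (lf.uniq_feat[u] == f) { slot = (int)u; break; }
        if (slot < 0) {
          slot = (int)lf.uniq_feat.size();
          lf.uniq_feat.push_back(f);
        }
        lf.feat_slot[j] = slot;
      }
    }

    // background routing-pattern counts per leaf
    std::vector<std::vector<int>> bcount(leaves.size());
    for (size_t li = 0; li < leaves.size(); ++li)
      bcount[li].assign(1 << leaves[li].node_feature.size(), 0);
    for (int b = 0; b < B; ++b) {
      for (size_t li = 0; li < leaves.size(); ++li) {
        const LeafPath& lf = leaves[li];
        int mask = 0;
        for (size_t j = 0; j < lf.node_feature.size(); ++j) {
          double v = Z(b, lf.node_feature[j]);
          if (routes_toward(v, lf.node_thr[j], lf.miss_yes[j], lf.toward_yes[j]))
            mask |= (1 << j);
        }
        bcount[li][mask]++;
      }
    }

    // precompute per-leaf attribution for every x-routing pattern
    for (size_t li = 0; li < leaves.size(); ++li) {
      LeafPath& lf = leaves[li];
      const int L = lf.node_feature.size();
      const int U = lf.uniq_feat.size();
      const int M = 1 << L;
      lf.contrib.assign((size_t)M * U, 0.0);
      const int full = M - 1;
      for (int amask = 0; amask < M; ++amask) {
        for (int bmask = 0; bmask < M; ++bmask) {
          int cnt = bcount[li][bmask];
          if (cnt == 0) continue;
          // per unique feature: does x (resp. z) satisfy all its conditions?
          int a_ok = 0, b_ok = 0;  // bitmasks over slots
          a_ok = b_ok = (1 << U) - 1;
          for (int j = 0; j < L; ++j) {
            if (!(amask & (1 << j))) a_ok &= ~(1 << lf.feat_slot[j]);
            if (!(bmask & (1 << j))) b_ok &= ~(1 << lf.feat_slot[j]);
          }
          bool dead = false;
          int p = 0, q = 0;
          for (int u = 0; u < U; ++u) {
            bool a = a_ok & (1 << u), b = b_ok & (1 << u);
            if (!a && !b) { dead = true; break; }
            if (a && !b) ++p;
            if (!a && b) ++q;
          }
          if (dead) continue;
          int k = p + q;
          if (k == 0) continue;  // leaf reached regardless: no attribution
          double wD = (p > 0) ? fact[p - 1] * fact[k - p] / fact[k] : 0.0;
          double wE = (q > 0) ? fact[p] * fact[k - p - 1] / fact[k] : 0.0;
          double scale = lf.value * (double)cnt / (double)B;
          for (int u = 0; u < U; ++u) {
            bool a = a_ok & (1 << u), b = b_ok & (1 << u);
            if (a && !b) lf.contrib[(size_t)amask * U + u] += scale * wD;
            else if (!a && b) lf.contrib[(size_t)amask * U + u] -= scale * wE;
          }
          (void)full;
        }
      }
    }

    // per-instance accumulation
    for (int i = 0; i < n; ++i) {
      for (size_t li = 0; li < leaves.size(); ++li) {
        const LeafPath& lf = leaves[li];
        const int L = lf.node_feature.size();
        const int U = lf.uniq_feat.size();
        int amask = 0;
        for (int j = 0; j < L; ++j) {
          double v = X(i, lf.node_feature[j]);
          if (routes_toward(v, lf.node_thr[j], lf.miss_yes[j], lf.toward_yes[j]))
            amask |= (1 << j);
        }
        const double* c = &lf.contrib[(size_t)amask * U];
        for (int u = 0; u < U; ++u) phi(i, lf.uniq_feat[u]) += c[u];
      }
    }
  }
  return phi;
}
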