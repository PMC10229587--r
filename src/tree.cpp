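#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Weighted regression tree used inside the boosting relevance machinery.
// Splits are chosen greedily to maximise the weighted between-child
// improvement  s2 = wL*wR/(wL+wR) * (meanL - meanR)^2,  which equals the
// reduction in weighted squared error from fitting separate constants to
// the two daughter regions.  Each internal node records the split variable
// and its s2 so that per-variable relevance can be tallied afterwards.

namespace {

struct Node {
  int var;       // 0-based split variable, -1 for leaf
  double thr;
  double imp;    // s2 improvement at this node
  double value;  // weighted mean response of the node
  int left, right;
  int n;
};

class Grower {
public:
  Grower(const NumericMatrix& X, const NumericVector& y, const NumericVector& w,
         int max_depth, int min_leaf)
    : X_(X), y_(y), w_(w), max_depth_(max_depth), min_leaf_(min_leaf) {}

  std::vector<Node> nodes;

  int grow(std::vector<int>& idx, int depth) {
    double wsum = 0.0, wysum = 0.0;
    for (size_t a = 0; a < idx.size(); ++a) {
      wsum += w_[idx[a]];
      wysum += w_[idx[a]] * y_[idx[a]];
    }
    double node_val = wsum > 0.0 ? wysum / wsum : 0.0;
    int me = (int)nodes.size();
    Node nd; nd.var = -1; nd.thr = NA_REAL; nd.imp = 0.0;
    nd.value = node_val; nd.left = -1; nd.right = -1; nd.n = (int)idx.size();
    nodes.push_back(nd);

    if (depth >= max_depth_ || (int)idx.size() < 2 * min_leaf_ || wsum <= 0.0)
      return me;

    const int p = X_.ncol();
    double best_s2 = 0.0, best_thr = 0.0;
    int best_var = -1;
    std::vector<int> ord(idx);

    for (int j = 0; j < p; ++j) {
      std::sort(ord.begin(), ord.end(),
                [&](int a, int b) { return X_(a, j) < X_(b, j); });
      double wl = 0.0, wyl = 0.0;
      for (size_t k = 0; k + 1 < ord.size(); ++k) {
        int i = ord[k];
        wl += w_[i];
        wyl += w_[i] * y_[i];
        int nl = (int)(k + 1), nr = (int)(ord.size() - k - 1);
        if (nl < min_leaf_ || nr < min_leaf_) continue;
        double xk = X_(i, j), xk1 = X_(ord[k + 1], j);
        if (!(xk1 > xk)) continue;  // tied values: not a valid cut point
        double wr = wsum - wl, wyr = wysum - wyl;
        if (wl <= 0.0 || wr <= 0.0) continue;
        double d = wyl / wl - wyr / wr;
        double s2 = wl * wr / (wl + wr) * d * d;
        if (s2 > best_s2) {
          best_s2 = s2;
          best_var = j;
          best_thr = 0.5 * (xk + xk1);
        }
      }
    }
    if (best_var < 0) return me;

    std::vector<int> li, ri;
    li.reserve(idx.size()); ri.reserve(idx.size());
    for (size_t a = 0; a < idx.size(); ++a) {
      if (X_(idx[a], best_var) <= best_thr) li.push_back(idx[a]);
      else ri.push_back(idx[a]);
    }
    if ((int)li.size() < min_leaf_ || (int)ri.size() < min_leaf_) return me;

    nodes[me].var = best_var;
    nodes[me].thr = best_thr;
    nodes[me].imp = best_s2;
    int l = grow(li, depth + 1);
    nodes[me].left = l;
    int r = grow(ri, depth + 1);
    nodes[me].right = r;
    return me;
  }

private:
  const NumericMatrix& X_;
  const NumericVector& y_;
  const NumericVector& w_;
  int max_depth_, min_leaf_;
};

}  // namespace

// [[Rcpp::export]]
List fit_wls_tree_cpp(NumericMatrix X, NumericVector y, NumericVector w,
                      int max_depth, int min_leaf) {
  int n = X.nrow();
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  Grower g(X, y, w, max_depth, min_leaf);
  g.grow(idx, 0);
  int m = (int)g.nodes.size();
  IntegerVector var(m), left(m), right(m), nn(m);
  NumericVector thr(m), imp(m), value(m);
  for (int i = 0; i < m; ++i) {
    var[i] = g.nodes[i].var;
    thr[i] = g.nodes[i].thr;
    imp[i] = g.nodes[i].imp;
    value[i] = g.nodes[i].value;
    left[i] = g.nodes[i].left;
    right[i] = g.nodes[i].right;
    nn[i] = g.nodes[i].n;
  }
  return List::create(_["var"] = var, _["threshold"] = thr,
                      _["improvement"] = imp, _["value"] = value,
                      _["left"] = left, _["right"] = right, _["n"] = nn);
}

// [[Rcpp::export]]
NumericVector predict_wls_tree_cpp(IntegerVector var, NumericVector thr,
                                   NumericVector value, IntegerVector left,
                                   IntegerVector right, NumericMatrix X) {
  int n = X.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    int node = 0;
    while (var[node] >= 0)
      node = (X(i, var[node]) <= thr[node]) ? left[node] : right[node];
    out[i] = value[node];
  }
  return out;
}
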