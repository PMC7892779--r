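// Hot loops shared by the filtering and clustering code: a direct-form-II
// transposed IIR pass (called twice by the zero-phase wrapper) and
// connected-component labelling of suprathreshold (electrode, time) masks
// under spatio-temporal adjacency.
#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// One IIR pass down the columns of x. a and b must have equal length with
// a[0] == 1. Initial filter state is zi * x(0, j) per column (steady-state
// scaling computed by the R wrapper), which removes startup transients for
// signals that begin near a constant level.
// [[Rcpp::export]]
NumericMatrix iir_filter_cpp(NumericMatrix x, NumericVector b, NumericVector a,
                             NumericVector zi) {
  const int T = x.nrow(), m = x.ncol(), nord = zi.size();
  if (b.size() != nord + 1 || a.size() != nord + 1)
    stop("coefficient length must equal length(zi) + 1");
  NumericMatrix y(T, m);
  std::vector<double> z(nord);
  for (int j = 0; j < m; ++j) {
    for (int i = 0; i < nord; ++i) z[i] = zi[i] * x(0, j);
    for (int t = 0; t < T; ++t) {
      const double xt = x(t, j);
      const double yt = b[0] * xt + z[0];
      for (int i = 0; i < nord - 1; ++i)
        z[i] = b[i + 1] * xt + z[i + 1] - a[i + 1] * yt;
      z[nord - 1] = b[nord] * xt - a[nord] * yt;
      y(t, j) = yt;
    }
  }
  return y;
}

static inline void push_if(std::vector<int> &stack, IntegerMatrix &lab,
                           const LogicalMatrix &mask, int e, int t, int E,
                           int cur) {
  if (mask(e, t) && lab(e, t) == 0) {
    lab(e, t) = cur;
    stack.push_back(e + t * E);
  }
}

// Label connected components of a logical (electrode x time) mask. Two
// points are adjacent iff same electrode and |t1 - t2| == 1, or same time
// and the electrodes are neighbours in `adj` (a list of 1-based integer
// vectors, one per electrode row). Returns 0 for sub-threshold points and
// 1..n_clusters otherwise.
// [[Rcpp::export]]
IntegerMatrix label_clusters_cpp(LogicalMatrix mask, List adj) {
  const int E = mask.nrow(), T = mask.ncol();
  if (adj.size() != E) stop("adjacency list length must match electrode count");
  std::vector<std::vector<int> > nb(E);
  for (int e = 0; e < E; ++e) {
    IntegerVector v = adj[e];
    nb[e].assign(v.begin(), v.end());
  }
  IntegerMatrix lab(E, T);
  std::vector<int> stack;
  int cur = 0;
  for (int t = 0; t < T; ++t) {
    for (int e = 0; e < E; ++e) {
      if (!mask(e, t) || lab(e, t) != 0) continue;
      ++cur;
      lab(e, t) = cur;
      stack.push_back(e + t * E);
      while (!stack.empty()) {
        const int idx = stack.back();
        stack.pop_back();
        const int ee = idx % E, tt = idx / E;
        if (tt > 0) push_if(stack, lab, mask, ee, tt - 1, E, cur);
        if (tt < T - 1) push_if(stack, lab, mask, ee, tt + 1, E, cur);
        for (size_t q = 0; q < nb[ee].size(); ++q)
          push_if(stack, lab, mask, nb[ee][q] - 1, tt, E, cur);
      }
    }
  }
  return lab;
}

// Maximum cluster sum of `stat` over connected components of `mask`
// (adjacency as above). Returns 0 when the mask is empty, matching the
// "no cluster" convention of the permutation null.
// [[Rcpp::export]]
double max_cluster_sum_cpp(LogicalMatrix mask, NumericMatrix stat, List adj) {
  const int E = mask.nrow(), T = mask.ncol();
  if (stat.nrow() != E || stat.ncol() != T) stop("mask/stat shape mismatch");
  if (adj.size() != E) stop("adjacency list length must match electrode count");
  std::vector<std::vector<int> > nb(E);
  for (int e = 0; e < E; ++e) {
    IntegerVector v = adj[e];
    nb[e].assign(v.begin(), v.end());
  }
  IntegerMatrix lab(E, T);
  std::vector<int> stack;
  int cur = 0;
  double best = 0.0;
  for (int t = 0; t < T; ++t) {
    for (int e = 0; e < E; ++e) {
      if (!mask(e, t) || lab(e, t) != 0) continue;
      ++cur;
      lab(e, t) = cur;
      stack.push_back(e + t * E);
      double s = 0.0;
      while (!stack.empty()) {
        const int idx = stack.back();
        stack.pop_back();
        const int ee = idx % E, tt = idx / E;
        s += stat(ee, tt);
        if (tt > 0) push_if(stack, lab, mask, ee, tt - 1, E, cur);
        if (tt < T - 1) push_if(stack, lab, mask, ee, tt + 1, E, cur);
        for (size_t q = 0; q < nb[ee].size(); ++q)
          push_if(stack, lab, mask, nb[ee][q] - 1, tt, E, cur);
      }
      if (s > best) best = s;
    }
  }
  return best;
}
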