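#include <Rcpp.h>
using namespace Rcpp;

// Felsenstein pruning for the symmetric k-state Mk model, vectorised over
// site patterns.  Branch lengths are expected substitutions per character
// (total leaving rate 1), so
//   P_same(v) = 1/k + (k-1)/k * exp(-v k/(k-1))
//   P_diff(v) = 1/k -   1/k  * exp(-v k/(k-1))
// Root state frequencies are uniform 1/k.  Missing tips (NA) contribute
// all-ones partials.
//
// Partials are stored pattern-major (node -> state -> pattern rows of
// length npat) so every inner loop is a sequential pass; this is the hot
// path of the tip-dating MCMC.
//
// edge:      2-column integer matrix, 1-based ape numbering (tips 1..ntip,
//            root ntip+1)
// postorder: edge row indices (1-based) in child-before-parent order
// patterns:  ntip x npat integer matrix of states 0..k-1, NA = missing
//
// Returns the per-pattern likelihoods (not logged).
// [[Rcpp::export]]
NumericVector mk_pattern_lik(IntegerMatrix edge, NumericVector edge_len,
                             IntegerVector postorder, int ntip, int nnode,
                             IntegerMatrix patterns, int k) {
  const int nedge = edge.nrow();
  const int npat = patterns.ncol();
  const int nnodes_all = ntip + nnode;
  const double kk = (double)k;
  const size_t row = (size_t)npat;

  std::vector<double> partial((size_t)nnodes_all * k * row);
  std::vector<double> sums(row);

  // tips: indicator partials (all ones when missing)
  for (int i = 0; i < ntip; ++i) {
    double* base = &partial[(size_t)i * k * row];
    for (int s = 0; s < npat; ++s) {
      int st = patterns(i, s);
      for (int j = 0; j < k; ++j)
        base[j * row + s] = (st == NA_INTEGER) ? 1.0 : (st == j ? 1.0 : 0.0);
    }
  }
  for (size_t i = (size_t)ntip * k * row; i < partial.size(); ++i)
    partial[i] = 1.0;

  for (int ei = 0; ei < nedge; ++ei) {
    int e = postorder[ei] - 1;
    double ex = std::exp(-edge_len[e] * kk / (kk - 1.0));
    double pd = 1.0 / kk - ex / kk;
    double dlt = ex;  // p_same - p_diff
    double* ch = &partial[(size_t)(edge(e, 1) - 1) * k * row];
    double* par = &partial[(size_t)(edge(e, 0) - 1) * k * row];
    for (int s = 0; s < npat; ++s) sums[s] = 0.0;
    for (int j = 0; j < k; ++j) {
      const double* cj = ch + j * row;
      for (int s = 0; s < npat; ++s) sums[s] += cj[s];
    }
    for (int j = 0; j < k; ++j) {
      const double* cj = ch + j * row;
      double* pj = par + j * row;
      for (int s = 0; s < npat; ++s)
        pj[s] *= pd * sums[s] + dlt * cj[s];
    }
  }

  NumericVector out(npat);
  const double* root = &partial[(size_t)ntip * k * row];
  for (int s = 0; s < npat; ++s) {
    double lik = 0.0;
    for (int j = 0; j < k; ++j) lik += root[j * row + s];
    out[s] = lik / kk;
  }
  return out;
}
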