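#include <Rcpp.h>
using namespace Rcpp;

// Hot loops of the im2col convolution path. Both kernels preserve the
// exact element order of the R reference implementation (gather in
// index order; scatter-accumulate sequentially over kernel-position
// blocks), so results are bit-identical to the pure-R path.

// out[k] = x[idx[k] - 1]
// [[Rcpp::export]]
NumericVector gather_idx(NumericVector x, IntegerVector idx) {
  R_xlen_t n = idx.size();
  NumericVector out(no_init(n));
  const double* xp = REAL(x);
  const int* ip = INTEGER(idx);
  double* op = REAL(out);
  for (R_xlen_t k = 0; k < n; ++k) op[k] = xp[ip[k] - 1];
  return out;
}

// out[idx[k] - 1] += d[k], processed in storage order
// [[Rcpp::export]]
NumericVector scatter_add(NumericVector d, IntegerVector idx,
                          int out_len) {
  NumericVector out(out_len);            // zero-initialised
  R_xlen_t n = idx.size();
  const double* dp = REAL(d);
  const int* ip = INTEGER(idx);
  double* op = REAL(out);
  for (R_xlen_t k = 0; k < n; ++k) op[ip[k] - 1] += dp[k];
  return out;
}
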