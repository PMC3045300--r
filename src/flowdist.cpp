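#include <Rcpp.h>
using namespace Rcpp;

// Distances from every flowgram to every candidate perfect flowgram.
//
// bins: N x M matrix of 0-based intensity bin indices.
// runs: P x M matrix of candidate homopolymer run lengths per flow.
// dmat: n_bins x (max_run + 1) table of per-signal distances d(f | n);
//       runs beyond max_run use the last column.
// Returns the N x P matrix of length-normalised total distances
// d'(f, U) = sum_i d(f_i | u_i) / M.
// [[Rcpp::export]]
NumericMatrix flow_dist_mat(const IntegerMatrix bins, const IntegerMatrix runs,
                            const NumericMatrix dmat) {
  const int N = bins.nrow(), M = bins.ncol(), P = runs.nrow();
  const int maxrun = dmat.ncol() - 1;
  if (runs.ncol() != M) stop("flowgram and candidate flow counts differ");
  NumericMatrix out(N, P);
  for (int k = 0; k < P; ++k) {
    for (int m = 0; m < M; ++m) {
      int n = runs(k, m);
      if (n > maxrun) n = maxrun;
      const double *col = &dmat(0, n);
      for (int i = 0; i < N; ++i) {
        out(i, k) += col[bins(i, m)];
      }
    }
    for (int i = 0; i < N; ++i) out(i, k) /= M;
  }
  return out;
}
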