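#include <Rcpp.h>
using namespace Rcpp;

// Census of maximal diagonal line segments in the recurrence matrix of the
// embedded state sequence `x` (rows = states). Recurrence between states i
// and k iff squared Euclidean distance <= eps^2. Only offsets k >= 1 are
// scanned (upper triangle; a Theiler window of 1 excludes the main
// diagonal, and the matrix is symmetric). Returns counts[len] = number of
// maximal runs of exactly `len` recurrent cells along any diagonal, for
// len = 1..M (only len >= jmin is of interest downstream, but shorter runs
// are returned too so callers can inspect the full distribution).
// [[Rcpp::export]]
IntegerVector rqa_census_cpp(NumericMatrix x, double eps, int jmin) {
  const int M = x.nrow(), m = x.ncol();
  const double eps2 = eps * eps;
  IntegerVector counts(M); // counts[len - 1] = #maximal runs of length len
  for (int k = 1; k < M; ++k) {
    int run = 0;
    for (int i = 0; i + k < M; ++i) {
      double d2 = 0.0;
      for (int c = 0; c < m; ++c) {
        const double diff = x(i, c) - x(i + k, c);
        d2 += diff * diff;
      }
      if (d2 <= eps2) {
        ++run;
      } else if (run > 0) {
        ++counts[run - 1];
        run = 0;
      }
    }
    if (run > 0) ++counts[run - 1];
  }
  (void)jmin; // filtering by minimum length happens in R
  return counts;
}
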