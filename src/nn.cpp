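#include <Rcpp.h>
using namespace Rcpp;

// Exhaustive O(n*m) nearest-neighbour scan, any dimension. Serves as the
// independent oracle for the kd-tree route and as the small-instance
// fallback. Ties resolve to the lowest reference index.

// [[Rcpp::export(name = ".nn_brute_cpp")]]
IntegerVector nn_brute_cpp(NumericMatrix query, NumericMatrix ref) {
  const int n = query.nrow(), m = ref.nrow(), d = query.ncol();
  if (m == 0) stop("reference point set is empty");
  if (ref.ncol() != d) stop("dimension mismatch");
  IntegerVector idx(n);
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    int bj = 0;
    for (int j = 0; j < m; ++j) {
      double s = 0.0;
      for (int k = 0; k < d; ++k) {
        const double t = query(i, k) - ref(j, k);
        s += t * t;
      }
      if (s < best) { best = s; bj = j; }
    }
    idx[i] = bj + 1;
  }
  return idx;
}
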