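#include <Rcpp.h>
using namespace Rcpp;

// Fisher-Yates shuffle of the rows within every column, each column drawing
// its own permutation from R's RNG stream. Operates in place: callers that
// need to keep the input must pass a copy. Because the permutations come from
// the R RNG, resetting the seed and calling again reproduces them exactly,
// which is how the same per-timepoint permutations are applied to the
// broadband and narrowband matrices without storing them.
// [[Rcpp::export]]
void shuffle_columns_inplace(NumericMatrix X) {
  const int n = X.nrow(), T = X.ncol();
  RNGScope scope;
  for (int t = 0; t < T; ++t) {
    double *col = &X(0, t);
    for (int i = n - 1; i > 0; --i) {
      int j = static_cast<int>(unif_rand() * (i + 1));
      if (j > i) j = i;
      const double tmp = col[i];
      col[i] = col[j];
      col[j] = tmp;
    }
  }
}

// Subtract each row's mean, in place.
// [[Rcpp::export]]
void center_rows_inplace(NumericMatrix X) {
  const int n = X.nrow(), T = X.ncol();
  std::vector<double> mean(n, 0.0);
  for (int t = 0; t < T; ++t) {
    const double *col = &X(0, t);
    for (int i = 0; i < n; ++i) mean[i] += col[i];
  }
  for (int i = 0; i < n; ++i) mean[i] /= T;
  for (int t = 0; t < T; ++t) {
    double *col = &X(0, t);
    for (int i = 0; i < n; ++i) col[i] -= mean[i];
  }
}
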