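#include <Rcpp.h>
using namespace Rcpp;

// Permutation null scores for the BASE statistic.
//
// dSorted: directional differentiation values sorted descending (the
//   observed sort order pi); f0: its cumulative fraction.  Each of the K
//   draws shuffles the weight vector b uniformly (Fisher-Yates driven by
//   R's RNG, so set.seed() in R makes the draws reproducible) and returns
//   delta* = max_i [f1*(i) - f0(i)].
//
// A permutation whose weight total sum(dSorted * b) is zero carries no
// weight on differentiated genes; its score is defined as 0, matching the
// degenerate-case convention of the R code.

// [[Rcpp::export(name = ".permNullScores")]]
NumericVector permNullScores(NumericVector dSorted, NumericVector b,
                             NumericVector f0, int K) {
  const int n = dSorted.size();
  if (b.size() != n || f0.size() != n)
    stop("dSorted, b and f0 must have equal length");
  if (K < 1) stop("K must be >= 1");
  NumericVector out(K);
  std::vector<double> bp(b.begin(), b.end());
  for (int k = 0; k < K; ++k) {
    for (int i = n - 1; i > 0; --i) {
      int j = static_cast<int>(unif_rand() * (i + 1));
      if (j > i) j = i;  // guard against unif_rand() == 1.0
      std::swap(bp[i], bp[j]);
    }
    double tot = 0.0;
    for (int i = 0; i < n; ++i) tot += dSorted[i] * bp[i];
    if (tot <= 0.0) { out[k] = 0.0; continue; }
    double cum = 0.0, best = R_NegInf;
    for (int i = 0; i < n; ++i) {
      cum += dSorted[i] * bp[i];
      const double gap = cum / tot - f0[i];
      if (gap > best) best = gap;
    }
    out[k] = best;
  }
  return out;
}
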