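#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Weighted Kolmogorov-Smirnov enrichment scores from hit positions.
//
// w:   non-negative hit weights along the ranked list (already raised to the
//      weight exponent), length N.
// pos: k x nsets integer matrix of 1-based hit positions into the ranked
//      list; columns need not be sorted.
//
// For each column: hits advance the running sum by w[q]/sum(w[hits]), misses
// retreat by 1/(N - k); the score is the running-sum deviation of maximal
// absolute value (ties between equal positive and negative deviations take
// the positive one). If all hit weights are zero the hits advance uniformly
// by 1/k.
// [[Rcpp::export(name = ".cppEsSets")]]
NumericVector cppEsSets(NumericVector w, IntegerMatrix pos) {
  const int N = w.size();
  const int k = pos.nrow();
  const int nsets = pos.ncol();
  if (k <= 0 || k >= N) stop("set size must be in [1, N - 1]");
  NumericVector es(nsets);
  std::vector<int> q(k);
  const double missStep = 1.0 / double(N - k);
  for (int s = 0; s < nsets; ++s) {
    for (int j = 0; j < k; ++j) {
      int p = pos(j, s);
      if (p < 1 || p > N) stop("hit position out of range");
      q[j] = p;
    }
    std::sort(q.begin(), q.end());
    double NR = 0.0;
    for (int j = 0; j < k; ++j) NR += w[q[j] - 1];
    double cum = 0.0, maxdev = 0.0, mindev = 0.0;
    for (int j = 0; j < k; ++j) {
      double before = cum - (double(q[j] - (j + 1))) * missStep;
      if (before < mindev) mindev = before;
      cum += (NR > 0.0) ? w[q[j] - 1] / NR : 1.0 / double(k);
      double after = cum - (double(q[j] - (j + 1))) * missStep;
      if (after > maxdev) maxdev = after;
      if (after < mindev) mindev = after;
    }
    // ties (to numerical tolerance) between the positive and negative
    // extremes resolve to the positive deviation
    es[s] = (maxdev + 1e-12 >= -mindev) ? maxdev : mindev;
  }
  return es;
}
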