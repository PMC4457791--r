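#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// k-NN majority vote for two-class problems. Labels are integers (1 or 2);
// ties (even k) are broken toward `tieLabel`. Distances are squared
// Euclidean; neighbour order among exactly equal distances follows the
// training-row order (stable), matching a stable R-side sort.
// [[Rcpp::export(name = ".knnVote")]]
IntegerVector knn_vote(NumericMatrix trainX, IntegerVector trainY,
                       NumericMatrix testX, int k, int tieLabel) {
  const int nTr = trainX.nrow(), nTe = testX.nrow(), p = trainX.ncol();
  if (k < 1 || k > nTr) stop("invalid k");
  IntegerVector out(nTe);
  std::vector<std::pair<double, int> > d(nTr);
  for (int i = 0; i < nTe; ++i) {
    for (int j = 0; j < nTr; ++j) {
      double s = 0.0;
      for (int c = 0; c < p; ++c) {
        const double diff = testX(i, c) - trainX(j, c);
        s += diff * diff;
      }
      d[j] = std::make_pair(s, j);
    }
    std::partial_sort(d.begin(), d.begin() + k, d.end());
    int n1 = 0;
    for (int j = 0; j < k; ++j) if (trainY[d[j].second] == 1) ++n1;
    const int n2 = k - n1;
    out[i] = (n1 > n2) ? 1 : (n2 > n1 ? 2 : tieLabel);
  }
  return out;
}
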