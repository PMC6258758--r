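#include <Rcpp.h>
using namespace Rcpp;

// Accumulate weighted-LD contributions C[i,j] of intra-chromosome site
// pairs into genetic-distance bins. `C` holds the delta-scaled genotype
// covariances for one chromosome, sites sorted by genetic position `gpos`
// (Morgans); bins are `bin_width` wide up to `max_d` (also Morgans).
// [[Rcpp::export]]
List ld_pair_bins(NumericMatrix C, NumericVector gpos, double bin_width,
                  double max_d) {
  int S = C.ncol();
  int nbins = (int)std::ceil(max_d / bin_width + 1e-9);
  NumericVector sums(nbins);
  NumericVector counts(nbins);
  for (int i = 0; i < S; ++i) {
    for (int j = i + 1; j < S; ++j) {
      double d = gpos[j] - gpos[i];
      if (d > max_d) break;
      double v = C(i, j);
      if (ISNAN(v)) continue;
      int b = (int)(d / bin_width);
      if (b >= nbins) continue;
      sums[b] += v;
      counts[b] += 1.0;
    }
  }
  return List::create(_["sums"] = sums, _["counts"] = counts);
}
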