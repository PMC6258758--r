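#include <Rcpp.h>
using namespace Rcpp;

// g generations of haploid Wright-Fisher random mating with crossover as a
// Poisson process of rate 1/Morgan. Haplotype and founder-ancestry arrays
// are sites x N with sites sorted by (chromosome, genetic position);
// `chrom_start` holds 0-based first-site offsets per chromosome plus a
// terminal S. Uses R's RNG for reproducibility.
// [[Rcpp::export]]
List wf_admix(IntegerMatrix founders_h, IntegerMatrix founders_a,
              NumericVector gpos, IntegerVector chrom_start,
              NumericVector chrom_len, int g, int n_out) {
  int S = founders_h.nrow(), N = founders_h.ncol();
  int n_chrom = chrom_len.size();
  IntegerMatrix h0 = clone(founders_h), a0 = clone(founders_a);
  IntegerMatrix h1(S, N), a1(S, N);
  RNGScope scope;
  for (int gen = 0; gen < g; ++gen) {
    for (int i = 0; i < N; ++i) {
      for (int c = 0; c < n_chrom; ++c) {
        // parents drawn per chromosome: in the large-population limit the
        // chromosomes of one individual descend from effectively
        // independent lineages, which keeps per-chromosome statistics
        // independent (the assumption behind chromosome-level jackknives)
        int p1 = (int)(unif_rand() * N);
        int p2 = (int)(unif_rand() * (N - 1));
        if (p2 >= p1) p2 += 1;
        int lo = chrom_start[c], hi = chrom_start[c + 1];
        int k = (int)R::rpois(chrom_len[c]);
        bool take1 = unif_rand() < 0.5;
        if (k == 0) {
          int src = take1 ? p1 : p2;
          for (int s = lo; s < hi; ++s) {
            h1(s, i) = h0(s, src);
            a1(s, i) = a0(s, src);
          }
        } else {
          std::vector<double> brk(k);
          for (int b = 0; b < k; ++b) brk[b] = unif_rand() * chrom_len[c];
          std::sort(brk.begin(), brk.end());
          int b = 0;
          bool cur = take1;
          for (int s = lo; s < hi; ++s) {
            while (b < k && gpos[s] >= brk[b]) { cur = !cur; ++b; }
            int src = cur ? p1 : p2;
            h1(s, i) = h0(s, src);
            a1(s, i) = a0(s, src);
          }
        }
      }
    }
    std::swap(h0, h1);
    std::swap(a0, a1);
  }
  // sample n_out haplotypes without replacement from the final population
  IntegerMatrix out_h(S, n_out), out_a(S, n_out);
  std::vector<int> idx(N);
  for (int i = 0; i < N; ++i) idx[i] = i;
  for (int i = 0; i < n_out; ++i) {
    int j = i + (int)(unif_rand() * (N - i));
    std::swap(idx[i], idx[j]);
    for (int s = 0; s < S; ++s) {
      out_h(s, i) = h0(s, idx[i]);
      out_a(s, i) = a0(s, idx[i]);
    }
  }
  return List::create(_["haps"] = out_h, _["ancestry"] = out_a);
}
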