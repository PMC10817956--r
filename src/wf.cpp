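// Wright-Fisher reproduction kernel: each offspring haplotype is a
// recombinant mosaic of one random parent's two haplotypes, crossovers
// Poisson(rec * L) with uniform breakpoints. Haplotypes are matrix COLUMNS
// (sites x haplotypes) so each gamete is contiguous in memory. Uses R's RNG
// so runs are reproducible under set.seed().

#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// [[Rcpp::export(name = ".wf_reproduce_cpp")]]
IntegerMatrix wf_reproduce_cpp(const IntegerMatrix& H,
                               const NumericVector& pos,
                               double L, double rec,
                               Nullable<NumericVector> weights) {
  const int S = H.nrow();
  const int nh = H.ncol();
  const int N = nh / 2;
  IntegerMatrix child(S, nh);

  std::vector<double> cw;
  bool weighted = weights.isNotNull();
  if (weighted) {
    NumericVector w(weights);
    if ((int) w.size() != N) stop("weights must have one entry per parent");
    cw.resize(N);
    double acc = 0.0;
    for (int i = 0; i < N; ++i) { acc += w[i]; cw[i] = acc; }
    if (acc <= 0) stop("non-positive total parent weight");
  }

  const int* hp = INTEGER(H);
  int* cp = INTEGER(child);
  std::vector<double> bp;
  for (int g = 0; g < nh; ++g) {
    int par;
    if (weighted) {
      double u = unif_rand() * cw[N - 1];
      par = (int) (std::lower_bound(cw.begin(), cw.end(), u) - cw.begin());
      if (par >= N) par = N - 1;
    } else {
      par = (int) (unif_rand() * N);
      if (par >= N) par = N - 1;
    }
    int h0 = (unif_rand() < 0.5) ? 0 : 1;
    int k = (int) R::rpois(rec * L);
    int* out = cp + (size_t) g * S;
    const int* c0 = hp + (size_t) (2 * par) * S;
    const int* c1 = c0 + S;
    if (k == 0 || S == 0) {
      const int* src = h0 ? c1 : c0;
      std::copy(src, src + S, out);
    } else {
      bp.resize(k);
      for (int i = 0; i < k; ++i) bp[i] = unif_rand() * L;
      std::sort(bp.begin(), bp.end());
      // positions are kept ascending, so the mosaic is a sequence of
      // contiguous runs copied whole from alternating parental haplotypes
      int j0 = 0;
      int h = h0;
      for (int i = 0; i <= k; ++i) {
        int j1 = (i < k)
          ? (int) (std::upper_bound(pos.begin(), pos.end(), bp[i]) -
                   pos.begin())
          : S;
        if (j1 > j0) {
          const int* src = (h & 1) ? c1 : c0;
          std::copy(src + j0, src + j1, out + j0);
          j0 = j1;
        }
        ++h;
      }
    }
  }
  return child;
}
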