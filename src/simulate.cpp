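#include <Rcpp.h>
using namespace Rcpp;

// Forward Monte-Carlo simulator of the generative process, used as an
// independent oracle for the exact chain. Each offspring is sampled by
// explicit lineage: with probability c it copies the full diploid
// genotype of one uniformly chosen parent; otherwise it unites two
// gametes, each being a uniformly chosen allele of a uniformly chosen
// parent (with replacement, so selfing happens at rate 1/N). Every
// transmitted allele then mutates (a <-> A) independently with
// probability mu. This never goes through the mixture/multinomial
// algebra of the exact transition law, which is the point.
//
// Individuals are held as allele pairs (0 = a, 1 = A). Uses R's RNG, so
// set.seed() on the R side makes runs reproducible.
//
// Returns an (n_generations + 1) x 3 integer matrix of genotypic states
// (n_aa, n_aA, n_AA), generation 0 first.
// [[Rcpp::export]]
IntegerMatrix simulate_chain_cpp(int N, double c, double mu,
                                 IntegerVector initial, int n_generations) {
  RNGScope scope;
  std::vector<int> a1(N), a2(N), b1(N), b2(N);
  // unpack initial state (n_aa, n_aA, n_AA) into individuals
  int k = 0;
  for (int i = 0; i < initial[0]; ++i, ++k) { a1[k] = 0; a2[k] = 0; }
  for (int i = 0; i < initial[1]; ++i, ++k) { a1[k] = 0; a2[k] = 1; }
  for (int i = 0; i < initial[2]; ++i, ++k) { a1[k] = 1; a2[k] = 1; }
  IntegerMatrix states(n_generations + 1, 3);
  for (int g = 0; g <= n_generations; ++g) {
    int naa = 0, naA = 0, nAA = 0;
    for (int i = 0; i < N; ++i) {
      int s = a1[i] + a2[i];
      if (s == 0) ++naa; else if (s == 1) ++naA; else ++nAA;
    }
    states(g, 0) = naa; states(g, 1) = naA; states(g, 2) = nAA;
    if (g == n_generations) break;
    for (int i = 0; i < N; ++i) {
      int x, y;
      if (unif_rand() < c) {                       // clonal copy
        int p = (int)(unif_rand() * N); if (p == N) p = N - 1;
        x = a1[p]; y = a2[p];
      } else {                                     // random union of gametes
        int p = (int)(unif_rand() * N); if (p == N) p = N - 1;
        x = (unif_rand() < 0.5) ? a1[p] : a2[p];
        int q = (int)(unif_rand() * N); if (q == N) q = N - 1;
        y = (unif_rand() < 0.5) ? a1[q] : a2[q];
      }
      if (mu > 0 && unif_rand() < mu) x = 1 - x;   // reciprocal mutation
      if (mu > 0 && unif_rand() < mu) y = 1 - y;
      b1[i] = x; b2[i] = y;
    }
    a1.swap(b1); a2.swap(b2);
    if ((g & 4095) == 0) Rcpp::checkUserInterrupt();
  }
  return states;
}
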