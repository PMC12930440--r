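#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Permuted overlap counts: draws n_perm uniform random subsets of size
// n_draw from a universe of size n_universe (partial Fisher-Yates against
// R's RNG, so results are reproducible under set.seed) and counts how many
// drawn elements fall in B.
// [[Rcpp::export]]
IntegerVector perm_overlap_counts(int n_universe, int n_draw,
                                  LogicalVector in_b, int n_perm) {
  if (n_universe < 0 || n_draw < 0 || n_draw > n_universe)
    stop("need 0 <= n_draw <= n_universe");
  if (in_b.size() != n_universe)
    stop("in_b must have length n_universe");
  if (n_perm < 1)
    stop("n_perm must be >= 1");
  std::vector<int> idx(n_universe);
  std::vector<int> swapped(n_draw);
  for (int i = 0; i < n_universe; ++i) idx[i] = i;
  IntegerVector out(n_perm);
  for (int p = 0; p < n_perm; ++p) {
    int hits = 0;
    for (int j = 0; j < n_draw; ++j) {
      int k = j + static_cast<int>(unif_rand() * (n_universe - j));
      if (k >= n_universe) k = n_universe - 1;  // guard the unif_rand()==1 edge
      std::swap(idx[j], idx[k]);
      swapped[j] = k;
      if (in_b[idx[j]]) ++hits;
    }
    // undo the swaps in reverse so idx is the identity again
    for (int j = n_draw - 1; j >= 0; --j) std::swap(idx[j], idx[swapped[j]]);
    out[p] = hits;
  }
  return out;
}
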