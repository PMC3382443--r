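#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Exhaustive maximal-clique oracle for graphs with n <= 25 vertices.
// Subsets are bitmasks; S is a clique iff S \ {lowest bit v} is a clique
// and adj[v] contains S \ {v} (dynamic programme over all 2^n subsets).
// A clique is maximal iff no outside vertex is adjacent to all of S.
// Returns the maximal cliques as integer bitmasks (bit i = vertex i+1).
// [[Rcpp::export]]
IntegerVector bf_maximal_masks(IntegerVector adj, int n) {
  if (n < 0 || n > 25) stop("brute-force oracle guard: n must be <= 25");
  if (n == 0) return IntegerVector(0);
  const size_t total = 1ULL << n;
  std::vector<unsigned char> isclq(total, 0);
  isclq[0] = 1;
  std::vector<int> out;
  for (size_t s = 1; s < total; ++s) {
    const unsigned int v = __builtin_ctzll(s);
    const size_t rest = s & (s - 1);
    if (isclq[rest] && ((static_cast<size_t>(adj[v]) & rest) == rest)) {
      isclq[s] = 1;
      bool maximal = true;
      for (int u = 0; u < n; ++u) {
        if (s & (1ULL << u)) continue;
        if ((static_cast<size_t>(adj[u]) & s) == s) { maximal = false; break; }
      }
      if (maximal) out.push_back(static_cast<int>(s));
    }
  }
  return IntegerVector(out.begin(), out.end());
}
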