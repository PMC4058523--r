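#include <Rcpp.h>
#include <unordered_set>
#include <vector>
using namespace Rcpp;

// Degree-preserving null for the exclusive-target count alpha on a directed
// bipartite miRNA -> gene edge set. A single Markov chain of checkerboard
// swaps runs over the edge list: two edges (m1,g1), (m2,g2) with m1 != m2,
// g1 != g2 and neither (m1,g2) nor (m2,g1) present are rewired to
// (m1,g2), (m2,g1). Each swap leaves every miRNA out-degree and every gene
// in-degree unchanged. After every `attemptsPerSample` attempts the chain is
// sampled: alpha (number of targets with in-degree 1) is recorded per miRNA.
// Gene endpoints per sample can be returned for degree audits. Uses R's RNG,
// so results are reproducible under set.seed().
// [[Rcpp::export]]
List rewire_alpha_null(IntegerVector mEnd, IntegerVector gEnd,
                       int nMir, int nGene, int nPerm,
                       int attemptsPerSample, bool returnGeneEnds) {
  const int E = mEnd.size();
  if (gEnd.size() != E) stop("endpoint vectors differ in length");
  std::vector<int> m(E), g(E);
  std::unordered_set<long long> edges;
  edges.reserve(2 * E);
  auto key = [&](int mm, int gg) {
    return (long long)mm * (long long)nGene + gg;
  };
  for (int e = 0; e < E; ++e) {
    m[e] = mEnd[e] - 1;
    g[e] = gEnd[e] - 1;
    if (m[e] < 0 || m[e] >= nMir || g[e] < 0 || g[e] >= nGene)
      stop("endpoint index out of range");
    if (!edges.insert(key(m[e], g[e])).second)
      stop("duplicate edge in input");
  }

  IntegerMatrix alpha(nMir, nPerm);
  IntegerMatrix ge = returnGeneEnds ? IntegerMatrix(E, nPerm)
                                    : IntegerMatrix(0, 0);
  std::vector<int> indeg(nGene);
  double accepted = 0;

  for (int p = 0; p < nPerm; ++p) {
    for (int a = 0; a < attemptsPerSample; ++a) {
      int i = (int)(unif_rand() * E); if (i >= E) i = E - 1;
      int j = (int)(unif_rand() * E); if (j >= E) j = E - 1;
      if (i == j) continue;
      if (m[i] == m[j] || g[i] == g[j]) continue;
      if (edges.count(key(m[i], g[j])) || edges.count(key(m[j], g[i])))
        continue;
      edges.erase(key(m[i], g[i]));
      edges.erase(key(m[j], g[j]));
      std::swap(g[i], g[j]);
      edges.insert(key(m[i], g[i]));
      edges.insert(key(m[j], g[j]));
      accepted += 1;
    }
    std::fill(indeg.begin(), indeg.end(), 0);
    for (int e = 0; e < E; ++e) ++indeg[g[e]];
    for (int e = 0; e < E; ++e)
      if (indeg[g[e]] == 1) ++alpha(m[e], p);
    if (returnGeneEnds)
      for (int e = 0; e < E; ++e) ge(e, p) = g[e] + 1;
  }
  return List::create(_["alpha"] = alpha, _["accepted"] = accepted,
                      _["gene_ends"] = ge);
}
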