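#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// Scan the rank-rank threshold grid for every edge and return the cell
// with the minimal upper-tail hypergeometric overlap p-value.
//
// pos_hi / pos_lo: n x E integer matrices; column e holds, for each rank
// k under gene 1's ordering, the rank of that sample under gene 2's
// ordering (1-based), for the concordant-high and concordant-low
// orderings respectively.
//
// Log p-values are memoised in a dense (i, j, o) table shared across
// edges and tails; entries are filled lazily with R::phyper. Ties in
// log p are broken towards smaller i + j, then the concordant-high tail.
// [[Rcpp::export]]
List rrho_scan_cpp(IntegerMatrix pos_hi, IntegerMatrix pos_lo,
                   int imin, int imax, int step, bool both_tails) {
  const int n = pos_hi.nrow();
  const int E = pos_hi.ncol();
  if (imin < 1) imin = 1;
  if (imax > n) imax = n;

  // lazy cache only for moderate n (dense table is (n+1)^3 doubles)
  const bool use_cache = n <= 256;
  const std::size_t np1 = static_cast<std::size_t>(n) + 1;
  static std::vector<double> cache;      // reused across calls for same n
  static std::size_t cache_n = 0;
  if (use_cache) {
    if (cache_n != np1) {
      cache.assign(np1 * np1 * np1, NA_REAL);
      cache_n = np1;
    } else {
      // keep prior entries; the table depends only on n
    }
  }

  IntegerVector best_i(E), best_j(E), best_o(E), best_tail(E);
  NumericVector best_p(E);
  std::vector<int> ov(n + 1);

  for (int e = 0; e < E; ++e) {
    double blogp = R_PosInf;
    int bi = 0, bj = 0, bo = 0, btail = 0;
    const int ntails = both_tails ? 2 : 1;
    for (int tail = 1; tail <= ntails; ++tail) {
      const int* pos = (tail == 1) ? &pos_hi(0, e) : &pos_lo(0, e);
      std::fill(ov.begin(), ov.end(), 0);
      // ov[j] after processing prefix length i equals |top_i(g1) ∩ top_j(g2)|
      for (int i = 1; i <= imax; ++i) {
        const int p = pos[i - 1];
        for (int j = p; j <= n; ++j) ov[j] += 1;
        if (i < imin || ((i - imin) % step) != 0) continue;
        for (int j = imin; j <= imax; j += step) {
          const int o = ov[j];
          double lp;
          if (use_cache) {
            const std::size_t idx =
              (static_cast<std::size_t>(i) * np1 + j) * np1 + o;
            lp = cache[idx];
            if (ISNA(lp)) {
              lp = R::phyper(o - 1, i, n - i, j, 0, 1);
              cache[idx] = lp;
            }
          } else {
            lp = R::phyper(o - 1, i, n - i, j, 0, 1);
          }
          if (lp < blogp ||
              (lp == blogp && (i + j < bi + bj ||
                               (i + j == bi + bj && tail < btail)))) {
            blogp = lp; bi = i; bj = j; bo = o; btail = tail;
          }
        }
      }
    }
    best_i[e] = bi; best_j[e] = bj; best_o[e] = bo; best_tail[e] = btail;
    best_p[e] = std::exp(blogp);
  }
  return List::create(_["i"] = best_i, _["j"] = best_j, _["overlap"] = best_o,
                      _["tail"] = best_tail, _["p"] = best_p);
}
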