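#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Collapsed Gibbs sweeps for the finite Bernoulli mixture over binary
// edge-by-sample membership rows. Component rates (Beta(alpha/2, alpha/2))
// and mixture weights (symmetric Dirichlet, total concentration beta) are
// integrated out; only the per-edge labels are sampled.
//
// Conditional for edge j and component k (up to a constant):
//   log w_k = log(n_k + beta/K) - S*log(alpha + n_k)
//           + sum_i log(alpha/2 + c0_ki)            [all samples]
//           + sum_{i in ones(j)} [log(alpha/2 + c1_ki) - log(alpha/2 + c0_ki)]
// with counts excluding edge j. The all-sample term (plus the n_k prior
// terms) is cached per component ("base") and refreshed only for the two
// components an update touches; logs of integer-offset counts come from
// lookup tables. Sample counts are stored sample-major (c1t[i*K + k]) so
// the hot loop over components is contiguous.
//
// x: E x S integer 0/1 matrix. Uses R's RNG (seed via set.seed()).
// Returns the E x K matrix of post-burn-in label counts and, optionally,
// the full post-burn-in label history.
// [[Rcpp::export]]
List gibbs_sweeps_cpp(IntegerMatrix x, int K, double alpha, double beta_total,
                      int n_sweeps, int n_burnin, IntegerVector s_init,
                      bool keep_history) {
  const int E = x.nrow(), S = x.ncol();
  const double a2 = alpha / 2.0;

  std::vector< std::vector<int> > ones(E);
  for (int j = 0; j < E; ++j)
    for (int i = 0; i < S; ++i)
      if (x(j, i) == 1) ones[j].push_back(i);

  // log tables over integer counts 0..E
  std::vector<double> lt(E + 1), lprior(E + 1), ldenom(E + 1);
  for (int c = 0; c <= E; ++c) {
    lt[c] = std::log(a2 + c);
    lprior[c] = std::log(beta_total / K + c);
    ldenom[c] = std::log(alpha + c);
  }

  std::vector<int> s(E), nk(K, 0), c1t(static_cast<size_t>(S) * K, 0);
  for (int j = 0; j < E; ++j) {
    s[j] = s_init[j] - 1;
    nk[s[j]] += 1;
    for (int i : ones[j]) c1t[static_cast<size_t>(i) * K + s[j]] += 1;
  }

  // base[k] = lprior[nk] - S*ldenom[nk] + sum_i lt[nk - c1_ki]
  std::vector<double> base(K);
  auto refresh_base = [&](int k) {
    double t = 0.0;
    const int n = nk[k];
    for (int i = 0; i < S; ++i) t += lt[n - c1t[static_cast<size_t>(i) * K + k]];
    base[k] = lprior[n] - S * ldenom[n] + t;
  };
  for (int k = 0; k < K; ++k) refresh_base(k);

  const int n_kept = n_sweeps - n_burnin;
  IntegerMatrix counts(E, K);
  IntegerMatrix history(keep_history ? E : 1, keep_history ? n_kept : 1);
  std::vector<double> lw(K);

  for (int sweep = 0; sweep < n_sweeps; ++sweep) {
    for (int j = 0; j < E; ++j) {
      const int kold = s[j];
      nk[kold] -= 1;
      for (int i : ones[j]) c1t[static_cast<size_t>(i) * K + kold] -= 1;
      refresh_base(kold);

      for (int k = 0; k < K; ++k) lw[k] = base[k];
      for (int i : ones[j]) {
        const int* row = &c1t[static_cast<size_t>(i) * K];
        for (int k = 0; k < K; ++k) {
          const int c1 = row[k];
          lw[k] += lt[c1] - lt[nk[k] - c1];
        }
      }
      double mx = lw[0];
      for (int k = 1; k < K; ++k) if (lw[k] > mx) mx = lw[k];
      double tot = 0.0;
      for (int k = 0; k < K; ++k) { lw[k] = std::exp(lw[k] - mx); tot += lw[k]; }
      const double u = unif_rand() * tot;
      int knew = K - 1;
      double acc = 0.0;
      for (int k = 0; k < K; ++k) { acc += lw[k]; if (u <= acc) { knew = k; break; } }

      s[j] = knew;
      nk[knew] += 1;
      for (int i : ones[j]) c1t[static_cast<size_t>(i) * K + knew] += 1;
      refresh_base(knew);
    }
    if (sweep >= n_burnin) {
      for (int j = 0; j < E; ++j) counts(j, s[j]) += 1;
      if (keep_history)
        for (int j = 0; j < E; ++j) history(j, sweep - n_burnin) = s[j] + 1;
    }
  }

  IntegerVector s_last(E);
  for (int j = 0; j < E; ++j) s_last[j] = s[j] + 1;
  List out = List::create(_["counts"] = counts, _["last"] = s_last);
  if (keep_history) out["history"] = history;
  return out;
}
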