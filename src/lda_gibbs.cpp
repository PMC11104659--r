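#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Small deterministic RNG (xorshift64*) so sampling is reproducible and
// independent of R's global RNG state.
struct XRng {
  uint64_t s;
  explicit XRng(uint64_t seed) : s(seed ? seed : 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {
    s ^= s >> 12; s ^= s << 25; s ^= s >> 27;
    return s * 0x2545F4914F6CDD1DULL;
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  int sample_cum(const std::vector<double>& cum) {
    double u = unif() * cum.back();
    int lo = 0, hi = (int)cum.size() - 1;
    while (lo < hi) {
      int mid = (lo + hi) / 2;
      if (cum[mid] < u) lo = mid + 1; else hi = mid;
    }
    return lo;
  }
};

// Collapsed Gibbs sampler for latent Dirichlet allocation.
// docs: list of integer vectors of 0-based term indices.
// Returns averaged phi (K x V), theta (D x K), final assignments and the
// final topic-word count matrix for conservation checks.
// [[Rcpp::export(name = ".lda_gibbs_cpp", rng = false)]]
List lda_gibbs_cpp(List docs, int V, int K, double alpha, double beta,
                   int iterations, int burn_in, int thin, int seed) {
  int D = docs.size();
  std::vector<std::vector<int>> w(D), z(D);
  for (int d = 0; d < D; ++d) {
    IntegerVector dv = docs[d];
    w[d].assign(dv.begin(), dv.end());
    z[d].resize(dv.size());
  }
  std::vector<int> nkw((size_t)K * V, 0), nk(K, 0);
  std::vector<std::vector<int>> ndk(D, std::vector<int>(K, 0));
  XRng rng((uint64_t)seed * 2862933555777941757ULL + 3037000493ULL);

  // random initial assignments
  for (int d = 0; d < D; ++d) {
    for (size_t i = 0; i < w[d].size(); ++i) {
      int k = (int)(rng.unif() * K);
      if (k == K) k = K - 1;
      z[d][i] = k;
      nkw[(size_t)k * V + w[d][i]]++; nk[k]++; ndk[d][k]++;
    }
  }

  NumericMatrix phi_acc(K, V), theta_acc(D, K);
  int n_samples = 0;
  std::vector<double> cum(K);
  double Vbeta = V * beta;

  for (int it = 1; it <= iterations; ++it) {
    for (int d = 0; d < D; ++d) {
      std::vector<int>& wd = w[d];
      std::vector<int>& zd = z[d];
      std::vector<int>& nd = ndk[d];
      for (size_t i = 0; i < wd.size(); ++i) {
        int word = wd[i], k = zd[i];
        nkw[(size_t)k * V + word]--; nk[k]--; nd[k]--;
        double run = 0.0;
        for (int t = 0; t < K; ++t) {
          run += (nd[t] + alpha) * (nkw[(size_t)t * V + word] + beta) /
                 (nk[t] + Vbeta);
          cum[t] = run;
        }
        int knew = rng.sample_cum(cum);
        zd[i] = knew;
        nkw[(size_t)knew * V + word]++; nk[knew]++; nd[knew]++;
      }
    }
    if (it > burn_in && ((it - burn_in) % thin == 0)) {
      ++n_samples;
      for (int k = 0; k < K; ++k) {
        double denom = nk[k] + Vbeta;
        for (int v = 0; v < V; ++v)
          phi_acc(k, v) += (nkw[(size_t)k * V + v] + beta) / denom;
      }
      for (int d = 0; d < D; ++d) {
        double denom = (double)w[d].size() + K * alpha;
        for (int k = 0; k < K; ++k)
          theta_acc(d, k) += (ndk[d][k] + alpha) / denom;
      }
    }
  }
  if (n_samples == 0) {  // no post-burn-in samples: use the final state
    ++n_samples;
    for (int k = 0; k < K; ++k) {
      double denom = nk[k] + Vbeta;
      for (int v = 0; v < V; ++v)
        phi_acc(k, v) += (nkw[(size_t)k * V + v] + beta) / denom;
    }
    for (int d = 0; d < D; ++d) {
      double denom = (double)w[d].size() + K * alpha;
      for (int k = 0; k < K; ++k)
        theta_acc(d, k) += (ndk[d][k] + alpha) / denom;
    }
  }
  for (int k = 0; k < K; ++k)
    for (int v = 0; v < V; ++v) phi_acc(k, v) /= n_samples;
  for (int d = 0; d < D; ++d)
    for (int k = 0; k < K; ++k) theta_acc(d, k) /= n_samples;

  List zs(D);
  IntegerMatrix nkw_out(K, V);
  for (int k = 0; k < K; ++k)
    for (int v = 0; v < V; ++v) nkw_out(k, v) = nkw[(size_t)k * V + v];
  for (int d = 0; d < D; ++d) zs[d] = IntegerVector(z[d].begin(), z[d].end());

  return List::create(_["phi"] = phi_acc, _["theta"] = theta_acc,
                      _["assignments"] = zs, _["nkw"] = nkw_out,
                      _["n_samples"] = n_samples);
}

// Fold-in sampling for held-out documents: phi fixed, only document-topic
// counts resampled. Returns theta' (D x K).
// [[Rcpp::export(name = ".lda_foldin_cpp", rng = false)]]
NumericMatrix lda_foldin_cpp(List docs, NumericMatrix phi, double alpha,
                             int iterations, int seed) {
  int D = docs.size(), K = phi.nrow();
  XRng rng((uint64_t)seed * 6364136223846793005ULL + 1442695040888963407ULL);
  NumericMatrix theta(D, K);
  std::vector<double> cum(K);
  for (int d = 0; d < D; ++d) {
    IntegerVector dv = docs[d];
    int n = dv.size();
    std::vector<int> zd(n), nd(K, 0);
    for (int i = 0; i < n; ++i) {
      int k = (int)(rng.unif() * K);
      if (k == K) k = K - 1;
      zd[i] = k; nd[k]++;
    }
    for (int it = 0; it < iterations; ++it) {
      for (int i = 0; i < n; ++i) {
        int word = dv[i], k = zd[i];
        nd[k]--;
        double run = 0.0;
        for (int t = 0; t < K; ++t) {
          run += (nd[t] + alpha) * phi(t, word);
          cum[t] = run;
        }
        int knew = rng.sample_cum(cum);
        zd[i] = knew; nd[knew]++;
      }
    }
    double denom = n + K * alpha;
    for (int k = 0; k < K; ++k) theta(d, k) = (nd[k] + alpha) / denom;
  }
  return theta;
}
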