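#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

namespace {

struct XRng {
  uint64_t s;
  explicit XRng(uint64_t seed) : s(seed ? seed : 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {
    s ^= s >> 12; s ^= s << 25; s ^= s >> 27;
    return s * 0x2545F4914F6CDD1DULL;
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  int below(int n) { return (int)(unif() * n) % n; }
};

inline double sigmoid(double x) {
  if (x > 8.0) return 1.0;
  if (x < -8.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

}  // namespace

// Skip-gram with negative sampling, single-threaded and deterministic.
// docs: list of integer vectors of 0-based word ids; counts: unigram
// frequencies (length V). Negative samples follow unigram^0.75.
// Learning rate decays linearly over all (epoch, token) steps.
// Returns input/output matrices (V x dim) and mean loss per epoch.
// [[Rcpp::export(name = ".sgns_train_cpp", rng = false)]]
List sgns_train_cpp(List docs, IntegerVector counts, int dim, int window,
                    int negatives, int epochs, double lr, int seed) {
  int V = counts.size();
  int D = docs.size();
  XRng rng((uint64_t)seed * 0x9E3779B97F4A7C15ULL + 12345ULL);

  // cumulative unigram^0.75 table for negative sampling
  std::vector<double> neg_cum(V);
  double run = 0.0;
  for (int v = 0; v < V; ++v) {
    run += std::pow((double)counts[v], 0.75);
    neg_cum[v] = run;
  }
  auto sample_negative = [&]() {
    double u = rng.unif() * neg_cum.back();
    int lo = 0, hi = V - 1;
    while (lo < hi) {
      int mid = (lo + hi) / 2;
      if (neg_cum[mid] < u) lo = mid + 1; else hi = mid;
    }
    return lo;
  };

  std::vector<double> syn0((size_t)V * dim), syn1((size_t)V * dim, 0.0);
  for (size_t i = 0; i < syn0.size(); ++i)
    syn0[i] = (rng.unif() - 0.5) / dim;

  long long total_tokens = 0;
  for (int d = 0; d < D; ++d) total_tokens += ((IntegerVector)docs[d]).size();
  long long total_steps = (long long)epochs * std::max(1LL, total_tokens);
  long long step = 0;

  NumericVector epoch_loss(epochs);
  std::vector<double> grad(dim);

  for (int ep = 0; ep < epochs; ++ep) {
    double loss = 0.0;
    long long n_pairs = 0;
    for (int d = 0; d < D; ++d) {
      IntegerVector dv = docs[d];
      int n = dv.size();
      for (int i = 0; i < n; ++i, ++step) {
        double alpha = lr * (1.0 - (double)step / (double)total_steps);
        if (alpha < lr * 1e-4) alpha = lr * 1e-4;
        int reduced = rng.below(window) ;  // dynamic window, word2vec style
        int lo = i - window + reduced, hi = i + window - reduced;
        if (lo < 0) lo = 0;
        if (hi > n - 1) hi = n - 1;
        int center = dv[i];
        double* vc = &syn0[(size_t)center * dim];
        for (int j = lo; j <= hi; ++j) {
          if (j == i) continue;
          int ctx = dv[j];
          std::fill(grad.begin(), grad.end(), 0.0);
          for (int s = 0; s <= negatives; ++s) {
            int target; double label;
            if (s == 0) { target = ctx; label = 1.0; }
            else {
              target = sample_negative();
              if (target == ctx) continue;
              label = 0.0;
            }
            double* ut = &syn1[(size_t)target * dim];
            double dot = 0.0;
            for (int c = 0; c < dim; ++c) dot += vc[c] * ut[c];
            double pred = sigmoid(dot);
            double g = (label - pred) * alpha;
            loss += label > 0.5 ? -std::log(std::max(pred, 1e-10))
                                : -std::log(std::max(1.0 - pred, 1e-10));
            for (int c = 0; c < dim; ++c) grad[c] += g * ut[c];
            for (int c = 0; c < dim; ++c) ut[c] += g * vc[c];
          }
          for (int c = 0; c < dim; ++c) vc[c] += grad[c];
          ++n_pairs;
        }
      }
    }
    epoch_loss[ep] = n_pairs > 0 ? loss / n_pairs : 0.0;
  }

  NumericMatrix input(V, dim), output(V, dim);
  for (int v = 0; v < V; ++v)
    for (int c = 0; c < dim; ++c) {
      input(v, c) = syn0[(size_t)v * dim + c];
      output(v, c) = syn1[(size_t)v * dim + c];
    }
  return List::create(_["input"] = input, _["output"] = output,
                      _["epoch_loss"] = epoch_loss);
}
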