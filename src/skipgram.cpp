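#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

// Deterministic xorshift64* generator so that training with a fixed seed is
// bit-reproducible across platforms, independent of R's RNG state.
static inline uint64_t xorshift_next(uint64_t &s) {
  s ^= s << 13;
  s ^= s >> 7;
  s ^= s << 17;
  return s * UINT64_C(2685821657736338717);
}

static inline double runif01(uint64_t &s) {
  return (xorshift_next(s) >> 11) * (1.0 / 9007199254740992.0); // 2^53
}

static inline double sigmoid(double x) {
  if (x > 30.0) return 1.0;
  if (x < -30.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

// Skip-gram with negative sampling.
//
// sentences: list of integer vectors, 1-based vocabulary indices (OOV removed)
// counts:    corpus frequency per vocabulary word (descending-frequency order)
// Training follows the reference formulation: noise distribution is the
// unigram distribution raised to 0.75; the per-position window radius is
// sampled uniformly from [1, window]; frequent words are discarded with
// probability max(0, 1 - sqrt(t / f)); the learning rate decays linearly to
// a floor of alpha0 * 1e-4. Input vectors are initialised uniformly on
// (-0.5/dim, 0.5/dim); output vectors start at zero. Single-threaded.
// [[Rcpp::export]]
List sg_train_cpp(List sentences, NumericVector counts, int dim, int window,
                  int negative, double subsample, int epochs, double alpha0,
                  int seed) {
  const int V = counts.size();
  if (V < 1) stop("empty vocabulary");
  uint64_t rng = static_cast<uint64_t>(seed) * UINT64_C(6364136223846793005) +
                 UINT64_C(1442695040888963407);
  if (rng == 0) rng = UINT64_C(88172645463325252);

  NumericMatrix W(V, dim), Wp(V, dim);
  for (int v = 0; v < V; ++v)
    for (int d = 0; d < dim; ++d)
      W(v, d) = (runif01(rng) - 0.5) / dim;

  double total = 0.0;
  for (int v = 0; v < V; ++v) total += counts[v];

  // cumulative noise distribution: unigram^0.75
  std::vector<double> noise_cum(V);
  double z = 0.0;
  for (int v = 0; v < V; ++v) {
    z += std::pow(counts[v], 0.75);
    noise_cum[v] = z;
  }
  for (int v = 0; v < V; ++v) noise_cum[v] /= z;

  std::vector<double> discard(V, 0.0);
  if (subsample > 0) {
    for (int v = 0; v < V; ++v) {
      double f = counts[v] / total;
      double p = 1.0 - std::sqrt(subsample / f);
      discard[v] = p > 0.0 ? p : 0.0;
    }
  }

  long long n_tokens = 0;
  const int S = sentences.size();
  for (int i = 0; i < S; ++i) n_tokens += as<IntegerVector>(sentences[i]).size();
  const double train_total = static_cast<double>(n_tokens) * epochs + 1.0;
  const double alpha_min = alpha0 * 1e-4;

  std::vector<double> neu1e(dim);
  std::vector<int> kept;
  long long processed = 0;

  for (int ep = 0; ep < epochs; ++ep) {
    for (int si = 0; si < S; ++si) {
      IntegerVector sen = sentences[si];
      kept.clear();
      for (int i = 0; i < sen.size(); ++i) {
        ++processed;
        int w = sen[i] - 1;
        if (w < 0 || w >= V) stop("word index out of range");
        if (discard[w] > 0.0 && runif01(rng) < discard[w]) continue;
        kept.push_back(w);
      }
      double alpha = alpha0 * (1.0 - processed / train_total);
      if (alpha < alpha_min) alpha = alpha_min;
      const int n = static_cast<int>(kept.size());
      for (int t = 0; t < n; ++t) {
        int radius = 1 + static_cast<int>(runif01(rng) * window);
        if (radius > window) radius = window;
        for (int j = t - radius; j <= t + radius; ++j) {
          if (j == t || j < 0 || j >= n) continue;
          const int input = kept[j]; // context word carries the input vector
          std::fill(neu1e.begin(), neu1e.end(), 0.0);
          for (int k = 0; k <= negative; ++k) {
            int target;
            double label;
            if (k == 0) {
              target = kept[t];
              label = 1.0;
            } else {
              double u = runif01(rng);
              int lo = 0, hi = V - 1;
              while (lo < hi) {
                int mid = (lo + hi) / 2;
                if (noise_cum[mid] < u) lo = mid + 1; else hi = mid;
              }
              target = lo;
              if (target == kept[t]) continue;
              label = 0.0;
            }
            double dot = 0.0;
            for (int d = 0; d < dim; ++d) dot += W(input, d) * Wp(target, d);
            double g = (label - sigmoid(dot)) * alpha;
            for (int d = 0; d < dim; ++d) {
              neu1e[d] += g * Wp(target, d);
              Wp(target, d) += g * W(input, d);
            }
          }
          for (int d = 0; d < dim; ++d) W(input, d) += neu1e[d];
        }
      }
    }
  }
  return List::create(Named("input") = W, Named("output") = Wp);
}
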