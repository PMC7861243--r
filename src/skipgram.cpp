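// Skip-gram with negative sampling (SGNS), single-threaded and seeded so a
// rerun with the same corpus, hyperparameters and seed is bit-identical.
#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

// xorshift64* PRNG: self-contained so results do not depend on R's RNG kind
static inline uint64_t next_rand(uint64_t &s) {
  s ^= s >> 12;
  s ^= s << 25;
  s ^= s >> 27;
  return s * 2685821657736338717ULL;
}

static inline double unif01(uint64_t &s) {
  return (next_rand(s) >> 11) * (1.0 / 9007199254740992.0);
}

// sample a word index from the unigram^0.75 distribution via binary search
// over the cumulative weight table
static inline int sample_negative(const std::vector<double> &cum,
                                  uint64_t &s) {
  double u = unif01(s) * cum.back();
  int lo = 0, hi = (int)cum.size() - 1;
  while (lo < hi) {
    int mid = (lo + hi) / 2;
    if (cum[mid] < u) lo = mid + 1; else hi = mid;
  }
  return lo;
}

// [[Rcpp::export]]
NumericMatrix sgns_train_cpp(List docs, int vocab_size, NumericVector counts,
                             int dim, int epochs, int window, int negative,
                             double alpha0, double alpha_min, double seed) {
  std::vector<std::vector<int>> corpus;
  corpus.reserve(docs.size());
  double total_words = 0;
  for (int i = 0; i < docs.size(); ++i) {
    IntegerVector d = docs[i];
    corpus.emplace_back(d.begin(), d.end());
    total_words += d.size();
  }
  uint64_t rng = (uint64_t)seed;
  if (rng == 0) rng = 88172645463325252ULL;

  std::vector<double> cum(vocab_size);
  double acc = 0;
  for (int i = 0; i < vocab_size; ++i) {
    acc += std::pow(counts[i], 0.75);
    cum[i] = acc;
  }

  std::vector<double> syn0((size_t)vocab_size * dim);
  std::vector<double> syn1((size_t)vocab_size * dim, 0.0);
  for (size_t i = 0; i < syn0.size(); ++i)
    syn0[i] = (unif01(rng) - 0.5) / dim;

  std::vector<double> neu1e(dim);
  const double grand_total = total_words * epochs;
  double processed = 0;

  for (int ep = 0; ep < epochs; ++ep) {
    Rcpp::checkUserInterrupt();
    for (size_t di = 0; di < corpus.size(); ++di) {
      const std::vector<int> &sen = corpus[di];
      const int n = (int)sen.size();
      for (int pos = 0; pos < n; ++pos) {
        double alpha = alpha0 * (1.0 - processed / (grand_total + 1.0));
        if (alpha < alpha_min) alpha = alpha_min;
        processed += 1;
        const int w = sen[pos];
        const int b = (int)(next_rand(rng) % (uint64_t)window);
        for (int a = b; a < window * 2 + 1 - b; ++a) {
          if (a == window) continue;
          const int cpos = pos - window + a;
          if (cpos < 0 || cpos >= n) continue;
          const int last = sen[cpos];
          double *l1 = &syn0[(size_t)last * dim];
          std::fill(neu1e.begin(), neu1e.end(), 0.0);
          for (int d = 0; d <= negative; ++d) {
            int target, label;
            if (d == 0) {
              target = w;
              label = 1;
            } else {
              target = sample_negative(cum, rng);
              if (target == w) continue;
              label = 0;
            }
            double *l2 = &syn1[(size_t)target * dim];
            double f = 0;
            for (int k = 0; k < dim; ++k) f += l1[k] * l2[k];
            double g;
            if (f > 6.0) g = (label - 1) * alpha;
            else if (f < -6.0) g = label * alpha;
            else g = (label - 1.0 / (1.0 + std::exp(-f))) * alpha;
            for (int k = 0; k < dim; ++k) neu1e[k] += g * l2[k];
            for (int k = 0; k < dim; ++k) l2[k] += g * l1[k];
          }
          for (int k = 0; k < dim; ++k) l1[k] += neu1e[k];
        }
      }
    }
  }

  NumericMatrix out(vocab_size, dim);
  for (int i = 0; i < vocab_size; ++i)
    for (int k = 0; k < dim; ++k)
      out(i, k) = syn0[(size_t)i * dim + k];
  return out;
}
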