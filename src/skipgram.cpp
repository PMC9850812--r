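// Skip-gram with negative sampling over token sequences (graph walks or
// verbalized axioms). Single-threaded, seeded xorshift RNG: training is
// bit-reproducible for a fixed (corpus, hyperparameters, seed).

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

namespace {

struct XorShift {
  uint64_t s;
  explicit XorShift(uint64_t seed) : s(seed ? seed : 88172645463325252ULL) {}
  uint64_t next() {
    s ^= s >> 12;
    s ^= s << 25;
    s ^= s >> 27;
    return s * 2685821657736338717ULL;
  }
  // uniform in [0, n)
  uint64_t next_below(uint64_t n) { return next() % n; }
  double next_unit() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
};

inline double sigmoid(double x) {
  if (x > 8.0) return 1.0;
  if (x < -8.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

}  // namespace

// [[Rcpp::export(name = ".sgns_train")]]
NumericMatrix sgns_train(List sentences, int vocab_size, IntegerVector counts,
                         int dim, int window, int epochs, int negative,
                         double alpha, double seed) {
  XorShift rng(static_cast<uint64_t>(seed));

  // negative-sampling table, unigram^0.75
  const int table_size = 1 << 20;
  std::vector<int> table(table_size);
  double z = 0.0;
  for (int v = 0; v < vocab_size; ++v) z += std::pow((double)counts[v], 0.75);
  {
    int v = 0;
    double cum = std::pow((double)counts[0], 0.75) / z;
    for (int i = 0; i < table_size; ++i) {
      table[i] = v;
      if ((double)(i + 1) / table_size > cum && v < vocab_size - 1) {
        ++v;
        cum += std::pow((double)counts[v], 0.75) / z;
      }
    }
  }

  std::vector<double> syn0((size_t)vocab_size * dim);
  std::vector<double> syn1((size_t)vocab_size * dim, 0.0);
  for (size_t i = 0; i < syn0.size(); ++i) {
    syn0[i] = (rng.next_unit() - 0.5) / dim;
  }

  // pre-decode sentences once
  std::vector<std::vector<int>> sents;
  sents.reserve(sentences.size());
  long long total_tokens = 0;
  for (int i = 0; i < sentences.size(); ++i) {
    IntegerVector s = sentences[i];
    sents.emplace_back(s.begin(), s.end());
    total_tokens += s.size();
  }
  const double total_work = (double)total_tokens * epochs;
  long long processed = 0;
  std::vector<double> grad(dim);

  for (int ep = 0; ep < epochs; ++ep) {
    for (const auto& sen : sents) {
      const int slen = (int)sen.size();
      for (int pos = 0; pos < slen; ++pos) {
        ++processed;
        double lr = alpha * std::max(1.0 - processed / (total_work + 1.0),
                                     1e-4);
        const int center = sen[pos];
        const int b = (int)rng.next_below((uint64_t)window);
        for (int off = b - window; off <= window - b; ++off) {
          if (off == 0) continue;
          const int cpos = pos + off;
          if (cpos < 0 || cpos >= slen) continue;
          const int context = sen[cpos];
          double* v0 = &syn0[(size_t)center * dim];
          std::fill(grad.begin(), grad.end(), 0.0);
          for (int k = 0; k <= negative; ++k) {
            int target;
            double label;
            if (k == 0) {
              target = context;
              label = 1.0;
            } else {
              target = table[rng.next_below(table_size)];
              if (target == context) continue;
              label = 0.0;
            }
            double* v1 = &syn1[(size_t)target * dim];
            double dot = 0.0;
            for (int d = 0; d < dim; ++d) dot += v0[d] * v1[d];
            const double g = (label - sigmoid(dot)) * lr;
            for (int d = 0; d < dim; ++d) {
              grad[d] += g * v1[d];
              v1[d] += g * v0[d];
            }
          }
          for (int d = 0; d < dim; ++d) v0[d] += grad[d];
        }
      }
    }
  }

  NumericMatrix out(vocab_size, dim);
  for (int v = 0; v < vocab_size; ++v) {
    for (int d = 0; d < dim; ++d) out(v, d) = syn0[(size_t)v * dim + d];
  }
  return out;
}
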