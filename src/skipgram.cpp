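#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// Deterministic xorshift64* generator so that training is reproducible
// independently of R's RNG state.
struct XRng {
  uint64_t s;
  explicit XRng(uint64_t seed) : s(seed ? seed : 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {
    s ^= s >> 12; s ^= s << 25; s ^= s >> 27;
    return s * 0x2545F4914F6CDD1DULL;
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  int below(int n) { return (int)(next() % (uint64_t)n); }
};

static inline double sigmoid(double x) {
  if (x > 8.0) return 1.0;
  if (x < -8.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

// Skip-gram with negative sampling where the input representation of a
// word is the mean of its atomic word vector and its character-bigram
// subword vectors (fastText-style). Single-threaded, deterministic.
//
// corpus: list of integer vectors, 1-based word ids (0 = dropped token)
// subwords: list (per word) of 1-based subword ids
// counts: word frequencies (for the unigram^0.75 negative table)
// [[Rcpp::export(name = ".sg_train")]]
List sg_train(List corpus, List subwords, NumericVector counts,
              int n_words, int n_subwords, int dim,
              int window, int epochs, int negative,
              double lr0, int seed) {
  std::vector<double> in_word((size_t)n_words * dim);
  std::vector<double> in_sub((size_t)n_subwords * dim);
  std::vector<double> out((size_t)n_words * dim, 0.0);

  XRng rng((uint64_t)seed * 2654435761ULL + 1ULL);
  for (size_t i = 0; i < in_word.size(); ++i)
    in_word[i] = (rng.unif() - 0.5) / dim;
  for (size_t i = 0; i < in_sub.size(); ++i)
    in_sub[i] = (rng.unif() - 0.5) / dim;

  // unigram^0.75 negative-sampling table
  const int table_size = 100000;
  std::vector<int> neg_table(table_size);
  {
    double z = 0.0;
    for (int w = 0; w < n_words; ++w) z += std::pow(counts[w], 0.75);
    double cum = 0.0; int w = 0;
    cum = std::pow(counts[0], 0.75) / z;
    for (int i = 0; i < table_size; ++i) {
      neg_table[i] = w;
      if ((double)(i + 1) / table_size > cum && w < n_words - 1) {
        ++w;
        cum += std::pow(counts[w], 0.75) / z;
      }
    }
  }

  // cache subword id vectors
  std::vector<std::vector<int>> sub_of(n_words);
  for (int w = 0; w < n_words; ++w) {
    IntegerVector s = subwords[w];
    sub_of[w].assign(s.begin(), s.end());
  }

  long long total_tokens = 0;
  int n_sent = corpus.size();
  for (int s = 0; s < n_sent; ++s)
    total_tokens += (long long)(Rf_length(corpus[s]));
  total_tokens *= epochs;
  if (total_tokens < 1) total_tokens = 1;

  std::vector<double> hidden(dim), grad(dim);
  long long processed = 0;

  for (int ep = 0; ep < epochs; ++ep) {
    for (int s = 0; s < n_sent; ++s) {
      IntegerVector sent = corpus[s];
      int len = sent.size();
      for (int pos = 0; pos < len; ++pos) {
        ++processed;
        int w = sent[pos];
        if (w <= 0) continue;
        --w; // to 0-based
        double lr = lr0 * (1.0 - (double)processed / (total_tokens + 1));
        if (lr < lr0 * 1e-4) lr = lr0 * 1e-4;

        // composed input vector: mean of word vector and subword vectors
        const std::vector<int>& subs = sub_of[w];
        int n_parts = 1 + (int)subs.size();
        double inv = 1.0 / n_parts;
        for (int d = 0; d < dim; ++d) hidden[d] = in_word[(size_t)w * dim + d];
        for (int g : subs) {
          const double* sv = &in_sub[(size_t)(g - 1) * dim];
          for (int d = 0; d < dim; ++d) hidden[d] += sv[d];
        }
        for (int d = 0; d < dim; ++d) hidden[d] *= inv;

        int b = rng.below(window) + 1;
        for (int off = -b; off <= b; ++off) {
          if (off == 0) continue;
          int cpos = pos + off;
          if (cpos < 0 || cpos >= len) continue;
          int c = sent[cpos];
          if (c <= 0) continue;
          --c;

          std::fill(grad.begin(), grad.end(), 0.0);
          for (int neg = 0; neg <= negative; ++neg) {
            int target; double label;
            if (neg == 0) { target = c; label = 1.0; }
            else {
              target = neg_table[rng.below(table_size)];
              if (target == c) continue;
              label = 0.0;
            }
            double* ov = &out[(size_t)target * dim];
            double dot = 0.0;
            for (int d = 0; d < dim; ++d) dot += hidden[d] * ov[d];
            double g2 = (label - sigmoid(dot)) * lr;
            for (int d = 0; d < dim; ++d) {
              grad[d] += g2 * ov[d];
              ov[d] += g2 * hidden[d];
            }
          }
          // distribute gradient over the word and its subwords
          double* wv = &in_word[(size_t)w * dim];
          for (int d = 0; d < dim; ++d) wv[d] += grad[d] * inv;
          for (int g : subs) {
            double* sv = &in_sub[(size_t)(g - 1) * dim];
            for (int d = 0; d < dim; ++d) sv[d] += grad[d] * inv;
          }
        }
      }
    }
  }

  // final word vectors: composed (mean of atomic + subwords), as used at
  // query time for in-vocabulary tokens
  NumericMatrix W(n_words, dim), S(n_subwords, dim);
  for (int w = 0; w < n_words; ++w) {
    const std::vector<int>& subs = sub_of[w];
    double inv = 1.0 / (1 + (int)subs.size());
    for (int d = 0; d < dim; ++d) {
      double v = in_word[(size_t)w * dim + d];
      for (int g : subs) v += in_sub[(size_t)(g - 1) * dim + d];
      W(w, d) = v * inv;
    }
  }
  for (int g = 0; g < n_subwords; ++g)
    for (int d = 0; d < dim; ++d)
      S(g, d) = in_sub[(size_t)g * dim + d];

  return List::create(_["words"] = W, _["subwords"] = S);
}
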