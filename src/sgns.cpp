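#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Fast internal PRNG (splitmix64), seeded once from R's RNG stream so that
// results remain reproducible under set.seed() while avoiding per-draw
// overhead in the inner training loop.
static uint64_t rng_state;
static inline uint64_t next_u64() {
  uint64_t z = (rng_state += 0x9e3779b97f4a7c15ULL);
  z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
  z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
  return z ^ (z >> 31);
}
static inline int rand_int(int n) {
  return (int)(next_u64() % (uint64_t)n);
}

// precomputed sigmoid table over [-MAX_EXP, MAX_EXP], as in word2vec
#define EXP_TABLE_SIZE 1000
#define MAX_EXP 6.0
static double exp_table[EXP_TABLE_SIZE];
static void init_exp_table() {
  for (int i = 0; i < EXP_TABLE_SIZE; ++i) {
    double x = (i / (double)EXP_TABLE_SIZE * 2 - 1) * MAX_EXP;
    double e = std::exp(x);
    exp_table[i] = e / (e + 1.0);
  }
}
static inline double fast_sigmoid(double f) {
  if (f > MAX_EXP) return 1.0;
  if (f < -MAX_EXP) return 0.0;
  return exp_table[(int)((f + MAX_EXP) * (EXP_TABLE_SIZE / MAX_EXP / 2))];
}

// Skip-gram with negative sampling over walk sequences (word2vec objective).
// Single-threaded; all randomness (window shrinkage, negative draws) comes from
// R's RNG stream, so results are reproducible under set.seed().
//
// sequences: list of 1-based integer token vectors over a vocabulary of size
// `vocab`.  Returns the vocab x dim input-vector matrix; tokens that never take
// part in a (center, context) update keep an all-zero row.
//
// [[Rcpp::export]]
NumericMatrix sgns_train_cpp(List sequences, int vocab, int dim, int window,
                             int epochs, int negative, double alpha) {
  const int nseq = sequences.size();
  const double MIN_ALPHA_FRAC = 1e-4;
  const int TABLE_SIZE = 1 << 17;

  // token frequencies for the unigram^0.75 negative-sampling table
  std::vector<double> cnt(vocab, 0.0);
  long long total_tokens = 0;
  for (int s = 0; s < nseq; ++s) {
    IntegerVector seq = sequences[s];
    total_tokens += seq.size();
    for (int i = 0; i < seq.size(); ++i) cnt[seq[i] - 1] += 1.0;
  }
  if (total_tokens == 0) return NumericMatrix(vocab, dim);

  std::vector<int> table(TABLE_SIZE);
  double norm = 0.0;
  for (int w = 0; w < vocab; ++w) norm += std::pow(cnt[w], 0.75);
  {
    int w = 0;
    double cum = std::pow(cnt[0], 0.75) / norm;
    for (int t = 0; t < TABLE_SIZE; ++t) {
      table[t] = w;
      if ((t + 1) / (double)TABLE_SIZE > cum && w < vocab - 1) {
        ++w;
        cum += std::pow(cnt[w], 0.75) / norm;
      }
    }
  }

  init_exp_table();
  rng_state = (uint64_t)(unif_rand() * 4294967295.0) << 32 |
              (uint64_t)(unif_rand() * 4294967295.0);
  std::vector<double> syn0((size_t)vocab * dim);
  std::vector<double> syn1((size_t)vocab * dim, 0.0);
  for (size_t i = 0; i < syn0.size(); ++i)
    syn0[i] = ((next_u64() >> 11) * (1.0 / 9007199254740992.0) - 0.5) / dim;
  std::vector<bool> touched(vocab, false);

  const double total_steps = (double)total_tokens * epochs;
  double processed = 0.0;
  std::vector<double> grad(dim);

  for (int ep = 0; ep < epochs; ++ep) {
    for (int s = 0; s < nseq; ++s) {
      IntegerVector seq = sequences[s];
      const int len = seq.size();
      for (int pos = 0; pos < len; ++pos, processed += 1.0) {
        double lr = alpha * (1.0 - processed / (total_steps + 1.0));
        if (lr < alpha * MIN_ALPHA_FRAC) lr = alpha * MIN_ALPHA_FRAC;
        int center = seq[pos] - 1;
        int b = rand_int(window); // shrunk window, as in word2vec
        for (int j = pos - window + b; j <= pos + window - b; ++j) {
          if (j == pos || j < 0 || j >= len) continue;
          int ctx = seq[j] - 1;
          double *v_in = &syn0[(size_t)ctx * dim];
          for (int d = 0; d < dim; ++d) grad[d] = 0.0;
          for (int neg = 0; neg <= negative; ++neg) {
            int tgt; double label;
            if (neg == 0) { tgt = center; label = 1.0; }
            else {
              tgt = table[rand_int(TABLE_SIZE)];
              if (tgt == center) continue;
              label = 0.0;
            }
            double *v_out = &syn1[(size_t)tgt * dim];
            double f = 0.0;
            for (int d = 0; d < dim; ++d) f += v_in[d] * v_out[d];
            double sig = fast_sigmoid(f);
            double g = (label - sig) * lr;
            for (int d = 0; d < dim; ++d) {
              grad[d] += g * v_out[d];
              v_out[d] += g * v_in[d];
            }
          }
          for (int d = 0; d < dim; ++d) v_in[d] += grad[d];
          touched[ctx] = true;
          touched[center] = true;
        }
      }
    }
  }

  NumericMatrix out(vocab, dim);
  for (int w = 0; w < vocab; ++w) {
    if (!touched[w]) continue; // no context pairs -> zero vector
    for (int d = 0; d < dim; ++d) out(w, d) = syn0[(size_t)w * dim + d];
  }
  return out;
}
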