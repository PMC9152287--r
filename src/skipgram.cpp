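#include <Rcpp.h>
#include <vector>
#include <cmath>
#include "rng.h"
using namespace Rcpp;

// Skip-gram with negative sampling over a walk corpus (word2vec SGNS).
// Input vectors syn0 are the published embedding; context vectors syn1 are
// the output side. Learning rate decays linearly over the planned number of
// tokens; negatives are drawn from the unigram^(3/4) table. Single-threaded
// and fully determined by `seed`.

static const int SIG_TABLE = 4096;
static const double SIG_MAX = 8.0;

// [[Rcpp::export]]
List cpp_train_skipgram(IntegerMatrix walks, int vocab, int dim, int window,
                        int negatives, int epochs, double lr0, int seed,
                        bool snapshots) {
  const int nw = walks.nrow(), wl = walks.ncol();
  std::vector<double> sig(SIG_TABLE);
  for (int i = 0; i < SIG_TABLE; ++i) {
    double x = ((double)i / SIG_TABLE * 2.0 - 1.0) * SIG_MAX;
    sig[i] = 1.0 / (1.0 + std::exp(-x));
  }
  auto sigmoid = [&](float f) -> double {
    if (f >= SIG_MAX) return 1.0;
    if (f <= -SIG_MAX) return 0.0;
    int idx = (int)((f + SIG_MAX) / (2.0 * SIG_MAX) * SIG_TABLE);
    if (idx >= SIG_TABLE) idx = SIG_TABLE - 1;
    return sig[idx];
  };

  // unigram^0.75 negative-sampling table
  std::vector<double> cnt(vocab, 0.0);
  for (int i = 0; i < nw; ++i)
    for (int j = 0; j < wl; ++j) cnt[walks(i, j) - 1] += 1.0;
  const int TBL = 1000000;
  std::vector<int> table(TBL);
  {
    double z = 0.0;
    for (int v = 0; v < vocab; ++v) z += std::pow(cnt[v], 0.75);
    if (z <= 0) stop("empty walk corpus");
    int v = 0;
    double acc = std::pow(cnt[v], 0.75) / z;
    for (int i = 0; i < TBL; ++i) {
      table[i] = v;
      if ((double)(i + 1) / TBL > acc && v < vocab - 1) {
        ++v;
        acc += std::pow(cnt[v], 0.75) / z;
      }
    }
  }

  Splitmix rng((uint64_t)seed * 0x9E3779B9ULL + 7ULL);
  std::vector<float> syn0((size_t)vocab * dim), syn1((size_t)vocab * dim, 0.0f);
  for (size_t i = 0; i < syn0.size(); ++i)
    syn0[i] = (float)((rng.unif() - 0.5) / dim);

  const double total = (double)epochs * nw * wl;
  double processed = 0.0;
  std::vector<float> neu1e(dim);
  List snaps;

  for (int ep = 0; ep < epochs; ++ep) {
    for (int w = 0; w < nw; ++w) {
      for (int i = 0; i < wl; ++i) {
        double lr = lr0 * (1.0 - processed / (total + 1.0));
        if (lr < lr0 * 1e-4) lr = lr0 * 1e-4;
        processed += 1.0;
        int center = walks(w, i) - 1;
        int b = 1 + rng.randint(window);  // dynamic window as in word2vec
        for (int j = i - b; j <= i + b; ++j) {
          if (j < 0 || j >= wl || j == i) continue;
          int ctx = walks(w, j) - 1;
          float* __restrict__ l1 = &syn0[(size_t)ctx * dim];
          float* __restrict__ ne = neu1e.data();
          std::fill(neu1e.begin(), neu1e.end(), 0.0f);
          for (int d = 0; d <= negatives; ++d) {
            int target;
            double label;
            if (d == 0) {
              target = center;
              label = 1.0;
            } else {
              target = table[rng.randint(TBL)];
              if (target == center) continue;
              label = 0.0;
            }
            float* __restrict__ l2 = &syn1[(size_t)target * dim];
            float f0 = 0.0f, f1 = 0.0f, f2 = 0.0f, f3 = 0.0f;
            int c = 0;
            for (; c + 3 < dim; c += 4) {
              f0 += l1[c] * l2[c];
              f1 += l1[c + 1] * l2[c + 1];
              f2 += l1[c + 2] * l2[c + 2];
              f3 += l1[c + 3] * l2[c + 3];
            }
            float f = (f0 + f1) + (f2 + f3);
            for (; c < dim; ++c) f += l1[c] * l2[c];
            float g = (float)((label - sigmoid(f)) * lr);
            for (int c2 = 0; c2 < dim; ++c2) {
              float t = l2[c2];
              ne[c2] += g * t;
              l2[c2] = t + g * l1[c2];
            }
          }
          for (int c2 = 0; c2 < dim; ++c2) l1[c2] += ne[c2];
        }
      }
    }
    if (snapshots) {
      NumericMatrix m(vocab, dim);
      for (int v = 0; v < vocab; ++v)
        for (int c = 0; c < dim; ++c) m(v, c) = syn0[(size_t)v * dim + c];
      snaps.push_back(m);
    }
  }

  NumericMatrix emb(vocab, dim);
  for (int v = 0; v < vocab; ++v)
    for (int c = 0; c < dim; ++c) emb(v, c) = syn0[(size_t)v * dim + c];
  return List::create(_["embedding"] = emb, _["snapshots"] = snaps);
}
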