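#include <Rcpp.h>
#include <vector>
#include "rng.h"
using namespace Rcpp;

// Graphs arrive as CSR: offsets (length n+1, 0-based), nbr (0-based neighbor
// ids), wts (edge weights). Undirected graphs list both directions.

static int pick_weighted(const std::vector<double>& sc, double tot, Splitmix& rng) {
  double r = rng.unif() * tot, acc = 0.0;
  for (size_t i = 0; i < sc.size(); ++i) {
    acc += sc[i];
    if (r <= acc) return (int)i;
  }
  return (int)sc.size() - 1;
}

// Second-order transition scores over the neighbors of `curr` given the
// previously visited node `prev` (-1 for the first step): score(x) =
// w(curr,x) * alpha with alpha = 1/p if x == prev, 1 if x adjacent to prev,
// 1/q otherwise. Returned normalized to sum 1.
// [[Rcpp::export]]
NumericVector cpp_transition_probs(IntegerVector offsets, IntegerVector nbr,
                                   NumericVector wts, int prev, int curr,
                                   double p, double q) {
  int lo = offsets[curr], hi = offsets[curr + 1];
  int deg = hi - lo;
  NumericVector out(deg);
  if (deg == 0) return out;
  std::vector<char> mark;
  if (prev >= 0) {
    int n = offsets.size() - 1;
    mark.assign(n, 0);
    for (int e = offsets[prev]; e < offsets[prev + 1]; ++e) mark[nbr[e]] = 1;
  }
  double tot = 0.0;
  for (int e = lo; e < hi; ++e) {
    int x = nbr[e];
    double alpha = 1.0;
    if (prev >= 0) {
      if (x == prev) alpha = 1.0 / p;
      else if (mark[x]) alpha = 1.0;
      else alpha = 1.0 / q;
    }
    out[e - lo] = wts[e] * alpha;
    tot += out[e - lo];
  }
  for (int i = 0; i < deg; ++i) out[i] /= tot;
  return out;
}

// Generate num_walks biased walks of fixed length from every non-isolated
// node. Node visit order is reshuffled each pass. Returns 1-based node ids,
// one walk per row.
// [[Rcpp::export]]
IntegerMatrix cpp_generate_walks(IntegerVector offsets, IntegerVector nbr,
                                 NumericVector wts, int num_walks,
                                 int walk_length, double p, double q,
                                 int seed) {
  int n = offsets.size() - 1;
  std::vector<int> active;
  for (int v = 0; v < n; ++v)
    if (offsets[v + 1] > offsets[v]) active.push_back(v);
  int na = (int)active.size();
  IntegerMatrix walks(num_walks * na, walk_length);
  if (na == 0) return walks;

  Splitmix rng((uint64_t)seed * 2654435761ULL + 1ULL);
  std::vector<int> order(active);
  std::vector<char> mark(n, 0);
  std::vector<double> sc;
  int row = 0;

  for (int r = 0; r < num_walks; ++r) {
    // Fisher-Yates reshuffle per pass
    for (int i = na - 1; i > 0; --i) {
      int j = rng.randint(i + 1);
      std::swap(order[i], order[j]);
    }
    for (int s = 0; s < na; ++s) {
      int start = order[s];
      walks(row, 0) = start + 1;
      int prev = -1, curr = start;
      for (int t = 1; t < walk_length; ++t) {
        int lo = offsets[curr], hi = offsets[curr + 1];
        int deg = hi - lo;
        sc.assign(deg, 0.0);
        double tot = 0.0;
        if (prev >= 0)
          for (int e = offsets[prev]; e < offsets[prev + 1]; ++e) mark[nbr[e]] = 1;
        for (int e = lo; e < hi; ++e) {
          int x = nbr[e];
          double alpha = 1.0;
          if (prev >= 0) {
            if (x == prev) alpha = 1.0 / p;
            else if (mark[x]) alpha = 1.0;
            else alpha = 1.0 / q;
          }
          sc[e - lo] = wts[e] * alpha;
          tot += sc[e - lo];
        }
        if (prev >= 0)
          for (int e = offsets[prev]; e < offsets[prev + 1]; ++e) mark[nbr[e]] = 0;
        int k = pick_weighted(sc, tot, rng);
        prev = curr;
        curr = nbr[lo + k];
        walks(row, t) = curr + 1;
      }
      ++row;
    }
  }
  return walks;
}
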