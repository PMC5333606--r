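#include <Rcpp.h>
#include <vector>
#include <cstdint>
#include <cmath>
using namespace Rcpp;

#if defined(__GNUC__) || defined(__clang__)
static inline int popcount64(uint64_t x) { return __builtin_popcountll(x); }
#else
static inline int popcount64(uint64_t x) {
  int c = 0;
  while (x) { x &= x - 1; ++c; }
  return c;
}
#endif

// Core of the greedy pair-merge information loss; see ic_merge_loss() below
// for the definition. Connection patterns are bitsets of WF 64-bit words
// (WF = 0 selects the runtime word count W, letting the compiler fully
// unroll the common small cases).
template <int WF>
static double ic_merge_impl(std::vector<uint64_t>& P,
                            std::vector<uint64_t>& mask,
                            const int n, const int W) {
  const int WW = WF > 0 ? WF : W;
  std::vector<int> alive(n);
  for (int i = 0; i < n; ++i) alive[i] = i;
  int r = n;
  double total = 0.0;
  const double log2inv = 1.0 / std::log(2.0);

  while (r > 1) {
    const int m = r - 2;
    int bi = 0, bj = 1, bestkey = (m > 0) ? m + 1 : 0, bestd = 0;
    if (m > 0) {
      for (int ia = 0; ia < r - 1 && bestkey > 0; ++ia) {
        const int u = alive[ia];
        const uint64_t* Pu = &P[static_cast<size_t>(u) * WW];
        for (int ja = ia + 1; ja < r; ++ja) {
          const int v = alive[ja];
          const uint64_t* Pv = &P[static_cast<size_t>(v) * WW];
          int d = 0;
          for (int w = 0; w < WW; ++w)
            d += popcount64((Pu[w] ^ Pv[w]) & mask[w]);
          // the only disagreements at positions u and v are the u-v link
          // itself, seen once from each side
          if (Pu[v >> 6] & (1ULL << (v & 63))) d -= 2;
          const int key = d < m - d ? d : m - d;
          if (key < bestkey) {
            bestkey = key; bestd = d; bi = ia; bj = ja;
            if (key == 0) break;  // lexicographically first zero-cost pair
          }
        }
      }
    }

    if (m > 0 && bestd > 0 && bestd < m) {
      const double p = static_cast<double>(bestd) / m;
      total += m * (-(p * std::log(p) + (1.0 - p) * std::log(1.0 - p)) * log2inv);
    }
    if (r == 2) break;

    const int bu = alive[bi], bv = alive[bj];
    uint64_t* Pbu = &P[static_cast<size_t>(bu) * WW];
    const uint64_t* Pbv = &P[static_cast<size_t>(bv) * WW];
    // union of link sets; the merged pair's own link is consumed
    for (int w = 0; w < WW; ++w) Pbu[w] |= Pbv[w];
    Pbu[bu >> 6] &= ~(1ULL << (bu & 63));
    Pbu[bv >> 6] &= ~(1ULL << (bv & 63));
    // neighbours of bv gain a link to the merged node bu
    for (int ia = 0; ia < r; ++ia) {
      const int w2 = alive[ia];
      if (w2 == bu || w2 == bv) continue;
      uint64_t* Pw = &P[static_cast<size_t>(w2) * WW];
      if (Pw[bv >> 6] & (1ULL << (bv & 63)))
        Pw[bu >> 6] |= 1ULL << (bu & 63);
    }
    // retire bv (its pattern position is masked out everywhere)
    mask[bv >> 6] &= ~(1ULL << (bv & 63));
    alive.erase(alive.begin() + bj);
    --r;
  }
  return total;
}

// Cumulative information loss of the greedy pair-merge reduction of a binary
// network given as an upper-triangular edge list (1-based node indices)
// over n nodes. At each step, for every pair (u, v) of remaining nodes, p is
// the fraction of the other remaining nodes whose connection to u and to v
// disagrees, and the merge cost is m * H2(p) bits with m = remaining - 2.
// The minimum-cost pair is merged (ties: lexicographically first in node
// order), the merged node inheriting the union of the two link sets; the
// link between the merged pair itself is consumed by the merge. The total
// accumulated cost is returned.
//
// Node order is significant for tie-breaking: callers wanting a
// label-invariant value must supply canonically ordered node indices (see
// information_content() on the R side). m * H2(d/m) is strictly increasing
// in min(d, m - d), so pairs compare on that integer key and the entropy is
// evaluated once per merge.
// [[Rcpp::export(rng = false)]]
double ic_merge_loss(const IntegerVector& ki, const IntegerVector& li,
                     const int n) {
  if (n <= 0) stop("empty node set");
  if (ki.size() != li.size()) stop("edge index vectors differ in length");
  if (n == 1) return 0.0;

  const int W = (n + 63) / 64;
  std::vector<uint64_t> P(static_cast<size_t>(n) * W, 0ULL), mask(W, 0ULL);
  for (int i = 0; i < n; ++i) mask[i >> 6] |= 1ULL << (i & 63);
  for (int e = 0; e < ki.size(); ++e) {
    const int a = ki[e] - 1, b = li[e] - 1;
    if (a < 0 || b < 0 || a >= n || b >= n || a == b)
      stop("invalid edge index");
    P[static_cast<size_t>(a) * W + (b >> 6)] |= 1ULL << (b & 63);
    P[static_cast<size_t>(b) * W + (a >> 6)] |= 1ULL << (a & 63);
  }

  switch (W) {
    case 1: return ic_merge_impl<1>(P, mask, n, W);
    case 2: return ic_merge_impl<2>(P, mask, n, W);
    default: return ic_merge_impl<0>(P, mask, n, W);
  }
}
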