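#ifndef TRELLISDNA_CORE_H
#define TRELLISDNA_CORE_H

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <limits>
#include <vector>

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// ---- integer hash ---------------------------------------------------------
// murmur3-style 32-bit avalanche finalizer; chained over the digest fields
// (salt, history, base index, bit guess).  Pinned: changing this changes the
// codebook, so the golden-value test in the suite must never be "updated".
static inline uint32_t fmix32(uint32_t h) {
  h ^= h >> 16; h *= 0x85ebca6bu;
  h ^= h >> 13; h *= 0xc2b2ae35u;
  h ^= h >> 16;
  return h;
}

static inline uint32_t hedges_hash(uint32_t salt, uint32_t history,
                                   uint32_t idx, uint32_t bit) {
  uint32_t h = fmix32(salt ^ 0x9e3779b9u);
  h = fmix32(h ^ history);
  h = fmix32(h ^ (idx * 0x85ebca6bu));
  h = fmix32(h ^ (bit + 0x165667b1u));
  return h;
}

// the 24 permutations of {0,1,2,3} in lexicographic order
static const uint8_t PERM24[24][4] = {
  {0,1,2,3},{0,1,3,2},{0,2,1,3},{0,2,3,1},{0,3,1,2},{0,3,2,1},
  {1,0,2,3},{1,0,3,2},{1,2,0,3},{1,2,3,0},{1,3,0,2},{1,3,2,0},
  {2,0,1,3},{2,0,3,1},{2,1,0,3},{2,1,3,0},{2,3,0,1},{2,3,1,0},
  {3,0,1,2},{3,0,2,1},{3,1,0,2},{3,1,2,0},{3,2,0,1},{3,2,1,0}
};

// ---- code parameters ------------------------------------------------------
// bases are coded 0=A, 1=C, 2=G, 3=T (alphabetical); CTC column b+1,
// column 0 is blank.  G/C are codes 1 and 2.
struct CodePars {
  int k;              // one payload bit consumed every k-th base step
  int H;              // history bits
  uint32_t mask;      // 2^H - 1
  uint32_t salt;
  int max_h;          // max homopolymer run
  int gc_window;      // GC constraint window (bases)
  double gc_target;   // target GC fraction
  double gc_tol;      // allowed deviation of window GC fraction
};

static inline CodePars codepars_from_list(Rcpp::List p) {
  CodePars P;
  P.k = Rcpp::as<int>(p["k"]);
  P.H = Rcpp::as<int>(p["history_bits"]);
  P.mask = (P.H >= 32) ? 0xFFFFFFFFu : ((1u << P.H) - 1u);
  P.salt = (uint32_t)Rcpp::as<double>(p["salt"]);
  P.max_h = Rcpp::as<int>(p["max_homopolymer"]);
  P.gc_window = Rcpp::as<int>(p["gc_window"]);
  P.gc_target = Rcpp::as<double>(p["gc_target"]);
  P.gc_tol = Rcpp::as<double>(p["gc_tolerance"]);
  return P;
}

// recent emitted bases packed 2 bits each, newest in the low bits;
// capacity 15 bases, enough for gc_window-1 = 11 and max_h = 3.
static inline uint32_t push_recent(uint32_t recent, int b) {
  return ((recent << 2) | (uint32_t)b) & 0x3FFFFFFFu;
}

// Constrained candidate selection: hard homopolymer mask, then restrict to
// candidates keeping the trailing gc_window-base window inside the GC band
// when any such candidate survives, then take the hash-top-ranked survivor.
static inline int next_base_core(uint32_t history, int idx, int bit,
                                 uint32_t recent, int nrecent,
                                 const CodePars& P) {
  uint32_t h = hedges_hash(P.salt, history & P.mask, (uint32_t)idx,
                           (uint32_t)bit);
  const uint8_t* perm = PERM24[h % 24u];
  bool ok[4] = {true, true, true, true};
  if (nrecent >= P.max_h && P.max_h >= 1) {
    int b0 = (int)(recent & 3u);
    bool same = true;
    for (int j = 1; j < P.max_h; j++)
      if ((int)((recent >> (2 * j)) & 3u) != b0) { same = false; break; }
    if (same) ok[b0] = false;   // only the current run's base can deadlock
  }
  int w = P.gc_window - 1;
  if (nrecent >= w) {
    int g = 0;
    for (int j = 0; j < w; j++) {
      int b = (int)((recent >> (2 * j)) & 3u);
      if (b == 1 || b == 2) g++;
    }
    bool band[4];
    bool any = false;
    for (int b = 0; b < 4; b++) {
      if (!ok[b]) { band[b] = false; continue; }
      double frac = (g + ((b == 1 || b == 2) ? 1 : 0)) / (double)P.gc_window;
      band[b] = std::fabs(frac - P.gc_target) <= P.gc_tol + 1e-12;
      if (band[b]) any = true;
    }
    if (any) for (int b = 0; b < 4; b++) ok[b] = ok[b] && band[b];
  }
  for (int r = 0; r < 4; r++) {
    int b = perm[r];
    if (ok[b]) return b;
  }
  return perm[0];  // unreachable for max_h >= 1 with a 4-letter alphabet
}

// ---- -Inf-safe log-sum-exp ------------------------------------------------
static inline double lse2(double a, double b) {
  if (a == NEG_INF) return b;
  if (b == NEG_INF) return a;
  double m = (a > b) ? a : b;
  return m + std::log(std::exp(a - m) + std::exp(b - m));
}

static inline double lse3(double a, double b, double c) {
  return lse2(lse2(a, b), c);
}

#endif
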