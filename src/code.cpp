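#include "trellis_core.h"
using namespace Rcpp;

// [[Rcpp::export]]
IntegerVector hash_rank_cpp(double salt, double history, double base_index,
                            int bit_guess) {
  uint32_t h = hedges_hash((uint32_t)salt, (uint32_t)history,
                           (uint32_t)base_index, (uint32_t)bit_guess);
  const uint8_t* perm = PERM24[h % 24u];
  IntegerVector out(4);
  for (int i = 0; i < 4; i++) out[i] = perm[i];
  return out;
}

// [[Rcpp::export]]
int next_base_cpp(double history, int base_index, int bit,
                  IntegerVector recent_bases, List params) {
  CodePars P = codepars_from_list(params);
  uint32_t recent = 0;
  int n = recent_bases.size();
  for (int i = 0; i < n; i++) recent = push_recent(recent, recent_bases[i]);
  return next_base_core((uint32_t)history, base_index, bit, recent, n, P);
}

// Encode a bit vector into the payload base sequence.  One base step per
// trellis step; bits are consumed on steps s with s %% k == 0, history is
// (history << 1 | bit) & mask on consuming steps and untouched otherwise.
// [[Rcpp::export]]
IntegerVector encode_cpp(IntegerVector bits, List params) {
  CodePars P = codepars_from_list(params);
  int B = bits.size();
  int L = B * P.k;
  IntegerVector out(L);
  uint32_t history = 0, recent = 0;
  int bitpos = 0;
  for (int s = 0; s < L; s++) {
    bool consume = (s % P.k) == 0;
    int bit = consume ? bits[bitpos] : 0;
    int b = next_base_core(history, s, bit, recent, s, P);
    out[s] = b;
    recent = push_recent(recent, b);
    if (consume) {
      history = ((history << 1) | (uint32_t)bit) & P.mask;
      bitpos++;
    }
  }
  return out;
}
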