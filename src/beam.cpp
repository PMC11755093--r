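#include "trellis_core.h"
using namespace Rcpp;

// Beam Trellis decoding (Chandak-style): 2^H * (L+1) states, one per
// (history, message index) slot, updated once per CTC time step.  Every
// state carries a blank and a non-blank score half.  Per time step a state
// yields a stay candidate (S_W: blank extension / repeat of its last base)
// and advance candidates (S_X, S_Y: one per bit guess, emitting the base
// chosen by the code hash).  Candidates landing on one slot are merged:
// identical messages have their score halves log-sum-exp combined, distinct
// messages keep the higher-total-score survivor.
//
// Messages are held in a shared parent-pointer arena (O(1) append) and
// compared by 64-bit rolling hash with an exact suffix walk on hash match;
// the arena is mark-swept periodically so memory tracks live survivors.
// Slots with msg_index > t + 1 or < L - (T - t) are unreachable or can no
// longer complete and are skipped (a feasibility bound, not a beam cut).

namespace {

struct BSt {
  double sb, snb, tot;  // blank / non-blank halves and cached total
  int msg;              // arena node of last base (-1 = empty message)
  uint64_t mh;          // rolling hash of the base string
  uint32_t recent;
  int8_t last;          // last emitted base (-1 none)
  bool alive;
};

const uint64_t FNV0 = 1469598103934665603ULL;
const uint64_t HMUL = 1099511628211ULL;

struct Arena {
  std::vector<int> parent;
  std::vector<int8_t> sym;  // base | (bit << 2)
  int add(int par, int base, int bit) {
    parent.push_back(par);
    sym.push_back((int8_t)(base | (bit << 2)));
    return (int)parent.size() - 1;
  }
  // exact content comparison of two equal-length messages: walk suffixes
  // until the shared prefix node is reached
  bool equal(int a, int b) const {
    while (a != b) {
      if (a < 0 || b < 0) return false;
      if ((sym[a] & 3) != (sym[b] & 3)) return false;
      a = parent[a];
      b = parent[b];
    }
    return true;
  }
  // array-style comparison: touch every position with no early exit, the
  // O(L) cost model of beam implementations that store explicit message
  // arrays per state; semantics identical to equal()
  bool equal_exact(int a, int b) const {
    bool eq = true;
    while (a >= 0 || b >= 0) {
      if (a < 0 || b < 0) return false;
      eq = eq && ((sym[a] & 3) == (sym[b] & 3));
      a = parent[a];
      b = parent[b];
    }
    return eq;
  }
};

}  // namespace

// [[Rcpp::export]]
List decode_beam_cpp(NumericMatrix logp, int nbits, List params,
                     bool exact_compare = false) {
  CodePars P = codepars_from_list(params);
  const int T = logp.nrow();
  const int L = nbits * P.k;
  const int S = 1 << P.H;
  const int W = L + 1;
  const size_t NS = (size_t)S * W;

  // column-major pointers into the matrix
  std::vector<double> lp((size_t)T * logp.ncol());
  for (int j = 0; j < logp.ncol(); j++)
    for (int t = 0; t < T; t++) lp[(size_t)j * T + t] = logp(t, j);

  std::vector<BSt> cur(NS), nxt(NS);
  for (size_t i = 0; i < NS; i++) cur[i].alive = nxt[i].alive = false;
  cur[0] = BSt{0.0, NEG_INF, 0.0, -1, FNV0, 0u, -1, true};

  Arena ar;
  ar.parent.reserve(1 << 16);
  ar.sym.reserve(1 << 16);

  int gc_countdown = 64;
  std::vector<int> remap;

  for (int t = 0; t < T; t++) {
    if (--gc_countdown == 0) {  // mark-sweep the message arena
      gc_countdown = 64;
      std::vector<char> mark(ar.parent.size(), 0);
      for (size_t i = 0; i < NS; i++) {
        if (!cur[i].alive) continue;
        for (int n = cur[i].msg; n >= 0 && !mark[n]; n = ar.parent[n])
          mark[n] = 1;
      }
      remap.assign(ar.parent.size(), -1);
      Arena ar2;
      ar2.parent.reserve(ar.parent.size() / 2 + 64);
      ar2.sym.reserve(ar.parent.size() / 2 + 64);
      for (size_t n = 0; n < ar.parent.size(); n++) {
        if (!mark[n]) continue;
        int par = ar.parent[n];
        remap[n] = ar2.add(par < 0 ? -1 : remap[par], ar.sym[n] & 3,
                           (ar.sym[n] >> 2) & 1);
      }
      for (size_t i = 0; i < NS; i++)
        if (cur[i].alive && cur[i].msg >= 0) cur[i].msg = remap[cur[i].msg];
      ar = ar2;
    }

    const double p_blank = lp[t];
    const double* pb = &lp[(size_t)T + t];  // base b at pb[(size_t)b * T]

    const int i_lo = (L - (T - t)) > 0 ? (L - (T - t)) : 0;
    const int i_hi = (t < L) ? t : L;
    for (size_t i = 0; i < NS; i++) nxt[i].alive = false;

    for (int h = 0; h < S; h++) {
      const size_t row = (size_t)h * W;
      for (int i = i_lo; i <= i_hi; i++) {
        const BSt& st = cur[row + i];
        if (!st.alive || st.tot == NEG_INF) continue;

        // stay candidate S_W
        {
          double sb2 = p_blank + st.tot;
          double snb2 = (st.last >= 0) ? pb[(size_t)st.last * T] + st.snb
                                       : NEG_INF;
          BSt& slot = nxt[row + i];
          if (!slot.alive) {
            slot = BSt{sb2, snb2, lse2(sb2, snb2), st.msg, st.mh, st.recent,
                       st.last, true};
          } else if (exact_compare
                         ? ar.equal_exact(slot.msg, st.msg)
                         : (slot.mh == st.mh && ar.equal(slot.msg, st.msg))) {
            slot.sb = lse2(slot.sb, sb2);
            slot.snb = lse2(slot.snb, snb2);
            slot.tot = lse2(slot.sb, slot.snb);
          } else {
            double tot2 = lse2(sb2, snb2);
            if (tot2 > slot.tot)
              slot = BSt{sb2, snb2, tot2, st.msg, st.mh, st.recent, st.last,
                         true};
          }
        }

        // advance candidates S_X / S_Y
        if (i < L) {
          bool consume = (i % P.k) == 0;
          int nb = consume ? 2 : 1;
          for (int bit = 0; bit < nb; bit++) {
            int c = next_base_core((uint32_t)h, i, bit, st.recent, i, P);
            int h2 = consume ? (int)(((uint32_t)(h << 1) | (uint32_t)bit) &
                                     P.mask)
                             : h;
            double v = (st.last >= 0 && c == st.last)
                           ? pb[(size_t)c * T] + st.sb
                           : pb[(size_t)c * T] + st.tot;
            if (v == NEG_INF) continue;
            uint64_t mh2 = st.mh * HMUL + (uint64_t)(c + 1);
            BSt& slot = nxt[(size_t)h2 * W + i + 1];
            if (!slot.alive) {
              slot = BSt{NEG_INF, v, v,
                         ar.add(st.msg, c, bit), mh2,
                         push_recent(st.recent, c), (int8_t)c, true};
            } else {
              bool same = false;
              if (exact_compare) {
                same = slot.msg >= 0 && (ar.sym[slot.msg] & 3) == c &&
                       ar.equal_exact(ar.parent[slot.msg], st.msg);
              } else if (slot.mh == mh2 && slot.msg >= 0 &&
                         (ar.sym[slot.msg] & 3) == c &&
                         ar.equal(ar.parent[slot.msg], st.msg)) {
                same = true;
              }
              if (same) {
                slot.snb = lse2(slot.snb, v);
                slot.tot = lse2(slot.sb, slot.snb);
              } else if (v > slot.tot) {
                slot = BSt{NEG_INF, v, v, ar.add(st.msg, c, bit), mh2,
                           push_recent(st.recent, c), (int8_t)c, true};
              }
            }
          }
        }
      }
    }
    std::swap(cur, nxt);
  }

  int best_h = -1;
  double best_tot = NEG_INF;
  for (int h = 0; h < S; h++) {
    const BSt& st = cur[(size_t)h * W + L];
    if (st.alive && st.tot > best_tot) { best_tot = st.tot; best_h = h; }
  }
  if (best_h < 0)
    return List::create(_["success"] = false, _["states"] = (double)NS);

  const BSt& win = cur[(size_t)best_h * W + L];
  IntegerVector bases(L), bits(nbits);
  int n = win.msg;
  int bi = nbits;
  for (int i = L - 1; i >= 0; i--) {
    bases[i] = ar.sym[n] & 3;
    if (i % P.k == 0) bits[--bi] = (ar.sym[n] >> 2) & 1;
    n = ar.parent[n];
  }
  return List::create(_["success"] = true, _["bits"] = bits,
                      _["bases"] = bases, _["score"] = best_tot,
                      _["score_blank"] = win.sb, _["score_nonblank"] = win.snb,
                      _["states"] = (double)NS);
}
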