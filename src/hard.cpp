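#include "trellis_core.h"
#include <queue>
using namespace Rcpp;

// Best-first search over the guess tree of the constrained convolutional
// code.  Each node hypothesizes the bit consumed at a code step together
// with an edit event against the observed basecalls: match/substitution
// (both positions advance), deletion (code advances, observation does not)
// or insertion (observation advances only; generated once per node since it
// is independent of the bit guess).  With non-negative per-edit penalties
// the first full-length hypothesis popped has minimal total penalty.

namespace {

struct HNode {
  int parent;
  int s;          // code step reached (bases emitted so far)
  int seq;        // observed positions consumed
  uint32_t hist;
  uint32_t recent;
  double score;
  int8_t bit;     // -1 none (insertion / root)
  int8_t base;    // emitted base, -1 if none
};

struct QEnt {
  double score;
  int s;
  int8_t bit;
  int id;
};

struct QCmp {
  // priority queue is a max-heap; return true when a is WORSE than b.
  bool operator()(const QEnt& a, const QEnt& b) const {
    if (a.score != b.score) return a.score > b.score;
    if (a.s != b.s) return a.s > b.s;          // lower msg_pos first
    if (a.bit != b.bit) return a.bit > b.bit;  // bit 0 first
    return a.id > b.id;                        // FIFO determinism
  }
};

}  // namespace

// [[Rcpp::export]]
List decode_hard_cpp(IntegerVector obs, int nbits, List params,
                     double guess_limit, NumericVector penalties,
                     bool consume_all) {
  CodePars P = codepars_from_list(params);
  const double pen_sub = penalties[0], pen_ins = penalties[1],
               pen_del = penalties[2];
  const int Lsteps = nbits * P.k;
  const int olen = obs.size();

  std::vector<HNode> arena;
  arena.reserve(4096);
  std::priority_queue<QEnt, std::vector<QEnt>, QCmp> pq;

  arena.push_back(HNode{-1, 0, 0, 0u, 0u, 0.0, -1, -1});
  pq.push(QEnt{0.0, 0, -1, 0});

  long guesses = 0;
  int found = -1;
  double final_score = NA_REAL;

  while (!pq.empty()) {
    QEnt top = pq.top();
    pq.pop();
    HNode nd = arena[top.id];
    guesses++;
    if (guesses > (long)guess_limit) { guesses--; break; }

    if (nd.s == Lsteps) {
      if (!consume_all || nd.seq == olen) {
        found = top.id;
        final_score = nd.score;
        break;
      }
      // only trailing insertions remain
      int id = (int)arena.size();
      arena.push_back(HNode{top.id, nd.s, nd.seq + 1, nd.hist, nd.recent,
                            nd.score + pen_ins, -1, -1});
      pq.push(QEnt{nd.score + pen_ins, nd.s, -1, id});
      continue;
    }

    // insertion hypothesis (bit-independent)
    if (nd.seq < olen) {
      int id = (int)arena.size();
      arena.push_back(HNode{top.id, nd.s, nd.seq + 1, nd.hist, nd.recent,
                            nd.score + pen_ins, -1, -1});
      pq.push(QEnt{nd.score + pen_ins, nd.s, -1, id});
    }

    bool consume = (nd.s % P.k) == 0;
    int nb = consume ? 2 : 1;
    for (int bit = 0; bit < nb; bit++) {
      int b = next_base_core(nd.hist, nd.s, bit, nd.recent, nd.s, P);
      uint32_t h2 = consume ? (((nd.hist << 1) | (uint32_t)bit) & P.mask)
                            : nd.hist;
      uint32_t r2 = push_recent(nd.recent, b);
      if (nd.seq < olen) {  // match / substitution
        double c = (obs[nd.seq] == b) ? 0.0 : pen_sub;
        int id = (int)arena.size();
        arena.push_back(HNode{top.id, nd.s + 1, nd.seq + 1, h2, r2,
                              nd.score + c, (int8_t)bit, (int8_t)b});
        pq.push(QEnt{nd.score + c, nd.s + 1, (int8_t)bit, id});
      }
      {  // deletion (base emitted, never observed)
        int id = (int)arena.size();
        arena.push_back(HNode{top.id, nd.s + 1, nd.seq, h2, r2,
                              nd.score + pen_del, (int8_t)bit, (int8_t)b});
        pq.push(QEnt{nd.score + pen_del, nd.s + 1, (int8_t)bit, id});
      }
    }
  }

  IntegerVector bits(nbits), bases(Lsteps);
  bool success = (found >= 0);
  if (success) {
    std::vector<int> path;
    for (int id = found; id >= 0; id = arena[id].parent) path.push_back(id);
    int bi = 0, si = 0;
    for (int i = (int)path.size() - 1; i >= 0; i--) {
      const HNode& nd = arena[path[i]];
      if (nd.base >= 0) {
        bases[si++] = nd.base;
        if ((si - 1) % P.k == 0) bits[bi++] = nd.bit;
      }
    }
  } else {
    std::fill(bits.begin(), bits.end(), NA_INTEGER);
    std::fill(bases.begin(), bases.end(), NA_INTEGER);
  }

  return List::create(_["success"] = success, _["bits"] = bits,
                      _["bases"] = bases, _["guesses_used"] = (double)guesses,
                      _["score"] = final_score);
}
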