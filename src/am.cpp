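#include "trellis_core.h"
using namespace Rcpp;

// Alignment-matrix trellis decoding.  Each of the 2^H trellis states stores
// one row of CTC forward variables M(i, t) for the prefix emitted along its
// survivor path; extending the prefix by one base derives the interleaved
// blank row and the new base row from the stored row alone:
//
//   B(t)  = ctc[t, blank] + lse(B(t-1),  M_i(t-1))
//   M'(t) = ctc[t, base]  + lse(M'(t-1), B(t-1), M_i(t-1))
//
// where the direct M_i(t-1) term is dropped when the new base repeats the
// previous one (a blank must intervene between CTC repeats).  Rows carry a
// conceptual t = 0 entry: 0 for the empty prefix, -Inf otherwise.

namespace {

// pool of (T+1)-length rows with live/peak accounting (the memory contract:
// no full L x T matrix is ever materialized per state)
struct RowPool {
  std::vector<std::vector<double> > bufs;
  std::vector<int> freelist;
  int Tp1;
  long live, peak;
  explicit RowPool(int Tp1_) : Tp1(Tp1_), live(0), peak(0) {}
  int acquire() {
    int id;
    if (!freelist.empty()) { id = freelist.back(); freelist.pop_back(); }
    else { id = (int)bufs.size(); bufs.push_back(std::vector<double>(Tp1)); }
    live++;
    if (live > peak) peak = live;
    return id;
  }
  void release(int id) { freelist.push_back(id); live--; }
  double* get(int id) { return bufs[id].data(); }
};

inline void fill_blank_row(const double* logp, int T, int ncol,
                           const double* prev, double* bk) {
  bk[0] = NEG_INF;
  for (int t = 1; t <= T; t++) {
    double a = bk[t - 1], b = prev[t - 1];
    if (a == NEG_INF && b == NEG_INF) { bk[t] = NEG_INF; continue; }
    bk[t] = logp[(t - 1)] /* column 0 */ + lse2(a, b);
  }
  (void)ncol;
}

// prev row has prefix_len `plen`; bk is its blank row (ignored when plen==0,
// where prev itself is the leading-blank/empty-prefix row)
inline double fill_base_row(const double* logp, int T, int ncol, int base,
                            const double* prev, const double* bk, int plen,
                            bool repeat, double* nb) {
  nb[0] = NEG_INF;
  const double* pb = logp + (size_t)T * (base + 1);
  double score = NEG_INF, smax = NEG_INF, ssum = 0.0;
  if (plen == 0) {
    for (int t = 1; t <= T; t++) {
      double a = nb[t - 1], b = prev[t - 1];
      if (a == NEG_INF && b == NEG_INF) { nb[t] = NEG_INF; continue; }
      double v = pb[t - 1] + lse2(a, b);
      nb[t] = v;
      if (v > smax) { ssum = ssum * std::exp(smax - v) + 1.0; smax = v; }
      else ssum += std::exp(v - smax);
    }
  } else {
    for (int t = 1; t <= T; t++) {
      double a = nb[t - 1], b = bk[t - 1];
      double c = repeat ? NEG_INF : prev[t - 1];
      if (a == NEG_INF && b == NEG_INF && c == NEG_INF) {
        nb[t] = NEG_INF;
        continue;
      }
      double m = a > b ? a : b;
      if (c > m) m = c;
      double s = 0.0;
      if (a != NEG_INF) s += std::exp(a - m);
      if (b != NEG_INF) s += std::exp(b - m);
      if (c != NEG_INF) s += std::exp(c - m);
      double v = pb[t - 1] + m + std::log(s);
      nb[t] = v;
      if (v > smax) { ssum = ssum * std::exp(smax - v) + 1.0; smax = v; }
      else ssum += std::exp(v - smax);
    }
  }
  if (smax != NEG_INF) score = smax + std::log(ssum);
  (void)ncol;
  return score;
}

}  // namespace

// [[Rcpp::export]]
NumericVector init_row_cpp(NumericMatrix logp) {
  int T = logp.nrow();
  NumericVector out(T);
  double acc = 0.0;
  for (int t = 0; t < T; t++) { acc += logp(t, 0); out[t] = acc; }
  return out;
}

// [[Rcpp::export]]
List extend_row_cpp(NumericVector prev, int prefix_len, int last_base,
                    int new_base, NumericMatrix logp) {
  int T = logp.nrow();
  if (prev.size() != T) stop("prev row length must equal T");
  std::vector<double> pv(T + 1), bk(T + 1), nb(T + 1);
  pv[0] = (prefix_len == 0) ? 0.0 : NEG_INF;
  for (int t = 1; t <= T; t++) pv[t] = prev[t - 1];

  // column-major copy of logp for fill_base_row's column pointers
  std::vector<double> lp((size_t)T * logp.ncol());
  for (int j = 0; j < logp.ncol(); j++)
    for (int t = 0; t < T; t++) lp[(size_t)j * T + t] = logp(t, j);

  bool repeat = (prefix_len > 0 && last_base == new_base);
  if (prefix_len == 0) {
    // the leading blank row IS the empty-prefix row
    for (int t = 0; t <= T; t++) bk[t] = pv[t];
  } else {
    fill_blank_row(lp.data(), T, logp.ncol(), pv.data(), bk.data());
  }
  double score = fill_base_row(lp.data(), T, logp.ncol(), new_base, pv.data(),
                               bk.data(), prefix_len, repeat, nb.data());

  NumericVector blank_row(T), base_row(T);
  for (int t = 1; t <= T; t++) {
    blank_row[t - 1] = bk[t];
    base_row[t - 1] = nb[t];
  }
  return List::create(_["blank_row"] = blank_row, _["base_row"] = base_row,
                      _["score"] = score);
}

// [[Rcpp::export]]
List decode_am_cpp(NumericMatrix logp, int nbits, List params) {
  CodePars P = codepars_from_list(params);
  const int T = logp.nrow();
  const int L = nbits * P.k;
  const int S = 1 << P.H;
  if (T < 1 || L < 1)
    return List::create(_["success"] = false);

  // column-major copy of the matrix
  std::vector<double> lp((size_t)T * logp.ncol());
  for (int j = 0; j < logp.ncol(); j++)
    for (int t = 0; t < T; t++) lp[(size_t)j * T + t] = logp(t, j);

  RowPool pool(T + 1);

  struct St {
    int row;
    double score;
    uint32_t recent;
    int8_t last;
    bool alive;
  };
  std::vector<St> cur(S), nxt(S);
  for (int s = 0; s < S; s++) cur[s].alive = nxt[s].alive = false;

  {  // initial state: history 0, empty prefix (leading blank row)
    int r0 = pool.acquire();
    double* pv = pool.get(r0);
    pv[0] = 0.0;
    double acc = 0.0;
    for (int t = 1; t <= T; t++) { acc += lp[t - 1]; pv[t] = acc; }
    cur[0] = St{r0, 0.0, 0u, -1, true};
  }

  std::vector<int> tb_pred((size_t)L * S, -1);
  std::vector<int8_t> tb_bit((size_t)L * S, -1), tb_base((size_t)L * S, -1);

  int bk_id = pool.acquire();   // shared blank-row scratch
  int tmp_id = pool.acquire();  // challenger base-row scratch

  for (int step = 0; step < L; step++) {
    bool consume = (step % P.k) == 0;
    for (int s = 0; s < S; s++) nxt[s].alive = false;

    if (consume) {
      // butterfly: sources {s0, s0 + S/2} feed targets {2 s0, 2 s0 + 1}
      int half = S / 2;
      if (S == 1) half = 1;  // degenerate H = 0
      for (int s0 = 0; s0 < half; s0++) {
        int srcs[2] = {s0, (S == 1) ? -1 : s0 + half};
        int t0 = (S == 1) ? 0 : ((s0 << 1) & (int)P.mask);
        for (int ti = 0; ti < ((S == 1) ? 2 : 2); ti++) {
          int tgt = (S == 1) ? 0 : (t0 | ti);
          int bit = (S == 1) ? ti : (tgt & 1);
          for (int si = 0; si < 2; si++) {
            int src = srcs[si];
            if (src < 0 || !cur[src].alive || cur[src].score == NEG_INF)
              continue;
            int b = next_base_core((uint32_t)src, step, bit,
                                   cur[src].recent, step, P);
            bool rep = (cur[src].last >= 0 && cur[src].last == b);
            double* pv = pool.get(cur[src].row);
            double* bk = pool.get(bk_id);
            if (step == 0) {
              for (int t = 0; t <= T; t++) bk[t] = pv[t];
            } else {
              fill_blank_row(lp.data(), T, logp.ncol(), pv, bk);
            }
            int cand = nxt[tgt].alive ? tmp_id : pool.acquire();
            double sc = fill_base_row(lp.data(), T, logp.ncol(), b, pv, bk,
                                      step, rep, pool.get(cand));
            bool take;
            if (!nxt[tgt].alive) take = true;
            else if (sc > nxt[tgt].score) take = true;
            else if (sc == nxt[tgt].score && sc != NEG_INF &&
                     bit == tb_bit[(size_t)step * S + tgt] &&
                     b < nxt[tgt].last) take = true;  // same bit: smaller base
            else take = false;
            if (take) {
              if (nxt[tgt].alive) {  // swap challenger into place
                int old = nxt[tgt].row;
                nxt[tgt].row = cand;
                tmp_id = old;
              } else {
                nxt[tgt].row = cand;
              }
              nxt[tgt].score = sc;
              nxt[tgt].recent = push_recent(cur[src].recent, b);
              nxt[tgt].last = (int8_t)b;
              nxt[tgt].alive = (sc != NEG_INF);
              if (!nxt[tgt].alive) {  // dead candidate: recycle its row
                pool.release(nxt[tgt].row);
                nxt[tgt].row = -1;
              } else {
                tb_pred[(size_t)step * S + tgt] = src;
                tb_bit[(size_t)step * S + tgt] = (int8_t)bit;
                tb_base[(size_t)step * S + tgt] = (int8_t)b;
              }
            }
          }
          // re-mark as alive-with-row only when a row is held
          if (nxt[tgt].alive && nxt[tgt].row < 0) nxt[tgt].alive = false;
        }
        for (int si = 0; si < 2; si++)
          if (srcs[si] >= 0 && cur[srcs[si]].alive)
            pool.release(cur[srcs[si]].row);
      }
    } else {
      // non-consuming step: identity edge, bit-less digest (bit field 0)
      for (int src = 0; src < S; src++) {
        if (!cur[src].alive || cur[src].score == NEG_INF) continue;
        int b = next_base_core((uint32_t)src, step, 0, cur[src].recent,
                               step, P);
        bool rep = (cur[src].last >= 0 && cur[src].last == b);
        double* pv = pool.get(cur[src].row);
        double* bk = pool.get(bk_id);
        if (step == 0) {
          for (int t = 0; t <= T; t++) bk[t] = pv[t];
        } else {
          fill_blank_row(lp.data(), T, logp.ncol(), pv, bk);
        }
        int cand = pool.acquire();
        double sc = fill_base_row(lp.data(), T, logp.ncol(), b, pv, bk, step,
                                  rep, pool.get(cand));
        pool.release(cur[src].row);
        if (sc == NEG_INF) {
          pool.release(cand);
          continue;
        }
        nxt[src] = St{cand, sc, push_recent(cur[src].recent, b), (int8_t)b,
                      true};
        tb_pred[(size_t)step * S + src] = src;
        tb_bit[(size_t)step * S + src] = 0;
        tb_base[(size_t)step * S + src] = (int8_t)b;
      }
    }
    std::swap(cur, nxt);
    bool any = false;
    for (int s = 0; s < S; s++) any = any || cur[s].alive;
    if (!any) {
      return List::create(_["success"] = false,
                          _["rows_peak"] = (double)pool.peak,
                          _["T"] = T);
    }
  }

  // Final selection: edge survival used the prefix row score (log-sum-exp
  // over all end times), but the winning full-length message must account
  // for the entire read, so states are compared by their full-matrix
  // forward probability lse(M(L, T), B(L+1, T)).
  int best = -1;
  double best_final = NEG_INF;
  for (int s = 0; s < S; s++) {
    if (!cur[s].alive) continue;
    double* pv = pool.get(cur[s].row);
    double* bk = pool.get(bk_id);
    fill_blank_row(lp.data(), T, logp.ncol(), pv, bk);
    double fin = lse2(pv[T], bk[T]);
    if (best < 0 || fin > best_final) { best = s; best_final = fin; }
  }
  if (best >= 0) cur[best].score = best_final;

  IntegerVector bits(nbits), bases(L), states(L);
  int st = best;
  int bi = nbits;
  for (int step = L - 1; step >= 0; step--) {
    states[step] = st;
    bases[step] = tb_base[(size_t)step * S + st];
    if (step % P.k == 0) bits[--bi] = tb_bit[(size_t)step * S + st];
    st = tb_pred[(size_t)step * S + st];
  }

  return List::create(_["success"] = true, _["bits"] = bits,
                      _["bases"] = bases, _["score"] = cur[best].score,
                      _["states"] = states,
                      _["rows_peak"] = (double)pool.peak, _["T"] = T);
}
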