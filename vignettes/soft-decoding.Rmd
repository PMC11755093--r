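---
title: "Soft trellis decoding of nanopore CTC output for DNA data storage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Soft trellis decoding of nanopore CTC output for DNA data storage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trellisdna)
```

## The problem

DNA data storage writes bytes into synthesized molecules and reads them back
by sequencing. With nanopore readout, the basecaller's machine-learning model
emits, for every time step of the ionic-current signal, a distribution over
the four bases plus a *blank* symbol — a CTC (connectionist temporal
classification) matrix. Decoding a stored message from discrete basecalls
("hard" decoding) throws this probability information away, and at
nanopore-level error rates (5–10 % per base) a guess-tree hard decoder burns
enormous compute for byte error rates that are still too high for an outer
code to absorb. `trellisdna` implements the full stack needed to study this
trade-off at desk scale:

* a hash-based constrained convolutional encoder (HEDGES-style) with
  homopolymer and GC-window constraints;
* a best-first **hard decoder** over basecalls;
* a **Beam Trellis soft decoder** (the accuracy baseline) and an
  **Alignment Matrix trellis soft decoder** (the fast algorithm of interest),
  both consuming CTC matrices directly;
* a synthetic CTC simulator, buffer trimming/orientation, CRC
  demultiplexing, and a Reed–Solomon outer-code model that converts byte
  error rates into storage density in bits per base.

## The code

The encoder consumes one payload bit every $k$-th base step (rate
$1/k \in \{1/8, 1/6, 1/3, 1/2\}$ bits per base). Each emitted base is the
top-ranked survivor of a salted integer hash of `(history, base index, bit)`,
where the history is the last $H$ consumed bits; the trellis therefore has
$2^H$ states with two outgoing edges on bit-consuming steps. Constraints are
enforced at emission: a hard mask forbids homopolymer runs beyond
`max_homopolymer` (default 3), and among surviving candidates those keeping
every 12-base window within GC $0.5 \pm 1/6$ (4–8 G/C per window) are
preferred. The homopolymer mask removes at most one base and the GC band is
always reachable because both a G/C and an A/T candidate survive the mask, so
emission can never deadlock and the band is maintained deterministically.

Strands carry a fixed layout: a 19 bp T7 promoter (the same molecules can be
transcribed and decoded as RNA), an 8 bp synthesis buffer, 50 bp signal
buffers on both sides of the payload, and a 10 base poly-A tail. The payload
region starts with a 2-byte strand index and a CRC-8 (polynomial `0x97`) of
the index, which is what demultiplexing validates.

### Design choices left open by the problem

* **Hash**: chained 32-bit murmur-style avalanche mix, reduced mod 24 to an
  alphabet permutation. Any avalanche hash preserves the code's distance
  properties; this one is pinned by a golden-value test plus an independent
  plain-R reimplementation, because changing it silently changes every
  codebook.
* **History update**: history shifts only on bit-consuming steps;
  non-consuming steps hash with a zero bit field and contribute one trellis
  edge. This keeps the state count at exactly $2^H$.
* **Context length**: a flipped message bit scrambles the emitted bases for
  the $(H+1)k$ bases it spends inside the shift register and the encoders
  then reconverge exactly. Tests assert both halves of this statement; a
  claim of whole-suffix divergence would be structurally false for any
  finite-history convolutional code.

## CTC scoring

A message's probability under a CTC matrix is the sum over all
*CTC-encodings*: length-$T$ paths over `{blank, A, C, G, T}` that collapse to
it (merge adjacent repeats, then drop blanks). Repeated message bases require
an intervening blank — `AA` is only reachable through paths like `A-A`.
`forward_probability()` computes this with the standard forward recursion
and is the package's shared oracle: the unit and acceptance suites verify it
against exhaustive path enumeration (all $(|\Sigma|+1)^T$ paths for small
$T$), and both soft decoders are checked for consistency with it.

### Alignment Matrix decoder

Each trellis state stores one row of forward variables $M(i, t)$ — the
probability of all encodings of its prefix within $t$ steps, ending in the
prefix's last base. Extending a prefix by one base derives an interleaved
blank row and the new base row from the stored row alone:

$$B(t) = \mathrm{ctc}_{t,-} + \mathrm{lse}(B(t-1), M_i(t-1)), \qquad
  M'(t) = \mathrm{ctc}_{t,b} + \mathrm{lse}(M'(t-1), B(t-1), M_i(t-1)),$$

with the direct $M_i(t-1)$ term dropped when the base repeats the previous
one. Edges are scored by the log-sum-exp of the fresh row over all $t$, and
per state the best incoming edge survives (Viterbi over prefix scores, ties
toward bit 0 then the lexicographically smaller base). Prefix scores reward
alignments that end early — a full-length impostor leaving trailing signal
unexplained pays no penalty — so while edge survival uses the row score, the
*final* winner among the $2^H$ states at step $L$ is chosen by full-matrix
forward probability, $\mathrm{lse}(M(L,T), B(L{+}1,T))$, which is also the
`score` reported (directly comparable to the beam decoder's total and to
`forward_probability()`). Without that final rule, zero-noise decodes can
return a message that genuinely out-scores the truth under prefix scoring.
Runtime is
$O(2^H L T)$ and live row storage $O(2^H T)$ — the decoder returns its peak
live row count so the memory contract is testable, and the trellis is
processed in source-pair "butterflies" so at most $2^H + 4$ rows are ever
live. Because a state's score aggregates its prefix across *all* times, a
locally attractive wrong base can poison every later row — the error-cascade
profile (late byte positions failing more often) that the positional
acceptance criterion reproduces.

### Beam Trellis decoder

The baseline expands the state space to $2^H (L+1)$ states — one per
(history, message index) — updated once per CTC time step, each carrying
blank/non-blank score halves. A state emits a stay candidate (blank
extension, or a repeat of its last base drawn from the non-blank half only)
and advance candidates per bit guess; candidates landing on one slot are
merged: identical messages sum their halves, distinct messages keep the
higher total. The winning state's total equals `forward_probability()` of
its message — asserted to 1e-6 at zero noise, where every encoding of the
winner provably survives merging. Messages live in a shared parent-pointer
arena compared by rolling hash with an exact suffix walk on collision
(mark-swept periodically). That merge is amortized $O(1)$, which — a fact
worth stating plainly — removes the extra factor of $L$ from the published
complexity $O(L^2 T 2^H)$: with hashed merging the beam costs the same order
as the alignment-matrix decoder and their runtime ratio is flat.
`decode_soft_beam(compare = "exact")` restores the positionwise
array-comparison cost model of the published algorithm (identical outputs,
asserted by tests); the complexity contract measures that mode and observes
the beam/AM ratio growing roughly linearly in $L$. Slots that can no longer
reach full length ($i < L - (T - t)$) are skipped — an exact feasibility
bound, not a beam cut.

### Hard decoder

Best-first search over a tree of (bit guess × edit hypothesis) nodes with
unit penalties for substitution/insertion/deletion, priority
(penalty, lower message position, bit 0, FIFO), and a guess budget. With
non-negative penalties the first completed hypothesis is penalty-minimal,
verified against an exhaustive codebook × Levenshtein oracle. Demultiplexing
hard-decodes only the index+CRC header (retrying the reverse complement) and
attributes a read iff the CRC validates, giving a ~1/256 false-accept rate
on random sequence.

## The synthetic CTC simulator

The generator emulates basecaller output, not raw current. Per true base it
draws a dwell of $1 + \mathrm{Geom}(1/\texttt{dwell\_mean})$ time steps
(default mean 2, typical of the strided output of CTC basecallers); each
dwell row routes `blank_weight` (0.35) to blank, a `miscall_rate` soft spread
to wrong bases, and the rest to the dominant base. Error modes: with
probability `miscall_rate` the dominant symbol of a base is swapped
(substitution-like), with `skip_rate` the base emits no steps
(deletion-like), with `stutter_rate` an extra step dominated by a random base
is inserted (insertion-like). Consecutive equal bases are always separated by
a blank-dominated row, probabilities are floored at $e^{-30}$ and rows
renormalized.

Two presets define the stated experimental world: `noiseless` (all error
rates zero; greedy argmax collapse provably returns the input) and
`basecaller` (miscall 0.05, skip 0.01, stutter 0.015), chosen to land in the
error regime of CTC basecalls on nanopore reads — measured greedy-basecall
identity loss ≈ 7 %. A subtlety worth recording: a simulator that only
*spreads* miscall mass over wrong bases can never flip a row's argmax, and
blank stutter vanishes under collapse, so such a model produces no
substitution or insertion errors in basecalls at all; the dominant-symbol
swap is what makes the hard-decoder comparison meaningful.

What a green test does **not** establish: the simulator has no burst errors,
no sequence-context-dependent error rates, no chimeric or truncated reads,
and no quality-score structure — all present in real nanopore data. Results
transfer qualitatively (ordering of decoders, cascade shapes, density
trends), not quantitatively.

## Outer code and density

Residual byte errors after inner decoding are absorbed by Reed–Solomon
codewords striped diagonally across strands, so symbol errors look i.i.d. at
rate $\bar P_B$ (the unweighted mean of positional byte error rates over
positions, then strands). A codeword $(n, k)$ fails with the binomial tail
$P[X > \lfloor (n-k)/2 \rfloor]$, and the design rule picks the largest $k$
keeping the expected failures below one over `capacity/k` codewords ×
`mttf` accesses (defaults 1 TB and $10^6$). Density is
$\varphi = (k/n) \cdot \text{rate} \cdot \text{info bases}/\text{total
bases}$; sweeping strand length against a truncated positional error profile
reproduces the characteristic interior maximum — short strands waste
overhead, long strands accumulate cascade errors that collapse $k$.

## Numerical choices

* All probability arithmetic is in log space with max-shifted, `-Inf`-safe
  log-sum-exp; structurally impossible prefixes stay exactly `-Inf`.
* Row conventions carry a conceptual $t = 0$ entry (0 for the empty prefix,
  `-Inf` otherwise) so the recursions need no special-casing at $t = 1$.
* Ties: AM survivor — bit 0, then smaller base; beam slot conflicts — first
  candidate in deterministic iteration order wins exact ties; hard decoder —
  see priority above. All decoders are bit-for-bit reproducible.
* Degenerate inputs: empty/blank-only matrices decode to a failure flag;
  an all-blank matrix triggers an `orientation-ambiguous` warning in
  `trim_and_orient()`.

## Limitations

Single-threaded reference implementations (the measured complexity contracts,
not wall-clock throughput, are the portable claims); no GPU kernels, no
FAST5/POD5 ingestion or basecaller execution; RNA support is an alphabet
relabeling (the physics of RNA pores is not modeled); the RS model omits
erasures by default and uses the documented binomial construction rather
than any supplementary-material variant.
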