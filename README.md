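# trellisdna

Trellis soft decoders for nanopore DNA data storage.

## What this is for

DNA data storage encodes bytes into synthesized molecules; nanopore
sequencing reads them back. The basecaller's neural network emits a **CTC
matrix** — per time step, log probabilities over `{blank, A, C, G, T}` —
and most pipelines immediately collapse it to discrete basecalls, discarding
the probability information. At nanopore error rates (5–10 % per base) a
hard decoder working from basecalls needs millions of guesses per read and
still leaves byte error rates that no practical outer code can absorb.
`trellisdna` is for studying the alternative: decoding the constrained
convolutional code **directly from the CTC matrix**.

The package implements, end to end:

* **`hedges_code`-style encoder** — rate 1/k ∈ {1/8, 1/6, 1/3, 1/2} bits per
  base; each base is the top hash-ranked candidate of
  `(salt, H-bit history, base index, bit)` surviving a homopolymer-≤3 mask
  and a GC 0.50 ± 1/6 preference over 12 bp windows; strands carry a T7
  promoter, synthesis buffer, 50 bp signal buffers, index + CRC-8 header and
  a poly-A tail.
* **Hard decoder** — best-first search over bit-guess × edit-hypothesis
  trees with a guess budget (`decode_hard()`, `demultiplex()`).
* **Beam Trellis soft decoder** — 2^H·(L+1) states with blank/non-blank
  score halves and duplicate-message merging (`decode_soft_beam()`);
  time O(L²T·2^H).
* **Alignment Matrix soft decoder** — 2^H states each holding one row of
  CTC forward variables M(i, t), extended per emitted base by a dynamic
  programming recurrence and scored by log-sum-exp (`decode_soft_am()`);
  time O(2^H·L·T), memory O(2^H·T).
* **Synthetic CTC simulator** (`simulate_ctc()`), buffer
  trimming/orientation (`trim_and_orient()`), and a Reed–Solomon
  outer-code density model (`rs_failure_prob()`, `choose_design()`,
  `density_phi()`, `density_sweep()`): byte error rate P̄B → largest RS
  dimension k meeting a capacity/MTTF constraint → density
  φ = (k/n)·rate·(info bases / total bases).

A message's CTC probability is the sum over all label paths that collapse to
it (merge repeats, drop blanks; repeated bases need an intervening blank —
`AA` is only reachable via `A-A`). `forward_probability()` computes this sum
and serves as the shared correctness oracle for both soft decoders.

## Worked example

```r
library(trellisdna)

p   <- code_params("1/6", history_bits = 4)      # 1/6 bit per base, 16 states
rec <- message_record(3, as.raw(1:8), p)          # index 3 + CRC + 8 bytes
st  <- encode_strand(rec, p)                      # full molecule
st
#> <encoded_strand> index 3 | 665 bases | payload span [ 77 , 605 ) | rate 1/6

ctc <- simulate_ctc(st$sequence, sim_config(profile = "basecaller"), seed = 7)
tr  <- trim_and_orient(ctc, strand_layout(), p)   # locate payload, orient
tr$orientation
#> [1] "forward"

decode_soft_am(tr$ctc, p, n_payload_bytes = 8)
#> <decode_result> am | index 3 | crc ok | 8 payload bytes | score -400.356

decode_hard(greedy_basecall(tr$ctc), p, 8, guess_limit = 1e5)
#> <decode_result> hard FAILED
```

The same read that the hard decoder cannot crack within 100 000 guesses (the
`basecaller` preset injects ≈7 % base-level error into greedy basecalls) is
decoded exactly by the Alignment Matrix decoder from the matrix it was
basecalled from; `score` is the log-sum-exp of the winning prefix row. From
many such decodes, `per_byte_error_profile()` gives P̄B and the positional
error profile, and `density_sweep()` turns that profile into a φ(L) curve
whose interior maximum reflects the overhead-vs-cascade trade-off.

## Command line

```sh
Rscript inst/cli/trellisdna.R encode --rate 1/6 --payload data.bin --salt 0 --out strands.fasta
Rscript inst/cli/trellisdna.R simulate --strands strands.fasta --out ctc/
Rscript inst/cli/trellisdna.R decode-soft --algo am --ctc ctc/ --rate 1/6 --payload-bytes 8 --out results.tsv
Rscript inst/cli/trellisdna.R decode-hard --reads reads.fastq --format fastq --rate 1/6 --payload-bytes 8 --guess-limit 1000000 --out results.tsv
Rscript inst/cli/trellisdna.R density --profile profile.tsv --rate 1/6 --out density.tsv
```

See `vignettes/soft-decoding.Rmd` for the model, the simulator's stated
world and its limits, and the numerical design choices.
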