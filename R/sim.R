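#' Simulator configuration for synthetic CTC matrices
#'
#' Generative stand-in for a nanopore basecaller's CTC output.  Per true
#' base the model draws a dwell of `1 + Geometric(1/dwell_mean)` time steps;
#' each dwell row routes `blank_weight` mass to blank, a `miscall_rate` soft
#' spread to the wrong bases, and the rest to the step's dominant base.
#' With probability `miscall_rate` a base's dominant symbol is swapped for a
#' random wrong base (substitution-like), with `skip_rate` the base emits no
#' steps at all (deletion-like), and with `stutter_rate` one extra step
#' dominated by a random base is inserted after the dwell (insertion-like).
#' Consecutive equal bases are always separated by a blank-dominated row.
#' `temperature` rescales rows as `p^(1/temperature)` (values > 1 flatten).
#'
#' @param dwell_mean expected CTC steps per base (>= 1, default 2: typical
#'   of the strided output of CTC basecallers)
#' @param blank_weight fraction of dwell-row mass routed to blank
#' @param miscall_rate substitution-like noise level in `[0, 1)`
#' @param skip_rate deletion-like noise level in `[0, 1)`
#' @param stutter_rate insertion-like noise level in `[0, 1)`
#' @param temperature flatness of the rows (> 0, default 1)
#' @param seed optional RNG seed applied by [simulate_ctc()]
#' @param profile shortcut presets: `"noiseless"` zeroes all error rates;
#'   `"basecaller"` emulates the error regime of nanopore CTC basecalls
#'   (roughly 7% base-level identity loss: miscall 0.05, skip 0.01,
#'   stutter 0.015)
#' @return an object of class `sim_config`
#' @export
sim_config <- function(dwell_mean = 2, blank_weight = 0.35,
                       miscall_rate = 0.03, skip_rate = 0.005,
                       stutter_rate = 0.01, temperature = 1, seed = NULL,
                       profile = NULL) {
  if (!is.null(profile)) {
    preset <- switch(profile,
      noiseless = list(miscall_rate = 0, skip_rate = 0, stutter_rate = 0),
      basecaller = list(miscall_rate = 0.05, skip_rate = 0.01,
                        stutter_rate = 0.015),
      stop("unknown profile: ", profile))
    miscall_rate <- preset$miscall_rate
    skip_rate <- preset$skip_rate
    stutter_rate <- preset$stutter_rate
  }
  stopifnot(dwell_mean >= 1, temperature > 0,
            blank_weight >= 0, blank_weight < 1,
            miscall_rate >= 0, miscall_rate < 1,
            skip_rate >= 0, skip_rate < 1,
            stutter_rate >= 0, stutter_rate < 1,
            blank_weight + miscall_rate < 1)
  structure(list(dwell_mean = dwell_mean, blank_weight = blank_weight,
                 miscall_rate = miscall_rate, skip_rate = skip_rate,
                 stutter_rate = stutter_rate, temperature = temperature,
                 seed = seed),
            class = "sim_config")
}

## probability floor: avoids -Inf arithmetic in the decoders while keeping
## rows normalized
.ctc_floor <- exp(-30)

.finish_row <- function(p, temperature) {
  if (temperature != 1) p <- p^(1 / temperature)
  p <- pmax(p / sum(p), .ctc_floor)
  p / sum(p)
}

.row_for <- function(dom, config) {
  ## dom: 0-based base code, or -1 for a blank-dominated row
  p <- numeric(5)
  if (dom < 0) {
    p[1] <- 1 - config$miscall_rate
    p[2:5] <- config$miscall_rate / 4
  } else {
    p[1] <- config$blank_weight
    p[2:5] <- (1 - config$blank_weight) * config$miscall_rate / 3
    p[dom + 2L] <- (1 - config$blank_weight) * (1 - config$miscall_rate)
  }
  .finish_row(p, config$temperature)
}

#' Simulate a CTC matrix for a sequence
#'
#' See [sim_config()] for the generative model.  Deterministic under a
#' fixed seed.
#'
#' @param sequence character scalar over the alphabet
#' @param config [sim_config()]
#' @param seed optional seed (overrides `config$seed`)
#' @param alphabet `"DNA"` or `"RNA"` (default inferred from the sequence)
#' @return a [ctc_matrix()]
#' @export
simulate_ctc <- function(sequence, config = sim_config(), seed = NULL,
                         alphabet = NULL) {
  if (is.null(seed)) seed <- config$seed
  if (!is.null(seed)) set.seed(seed)
  if (is.null(alphabet))
    alphabet <- if (grepl("U", sequence, fixed = TRUE)) "RNA" else "DNA"
  ab <- alphabet_chars(alphabet)
  x <- seq_to_int(sequence, ab)
  n <- length(x)
  stopifnot(n >= 1)

  rows <- vector("list", 2L * n + 8L)
  nr <- 0L
  add <- function(r) {
    nr <<- nr + 1L
    if (nr > length(rows)) length(rows) <<- 2L * nr
    rows[[nr]] <<- r
  }
  prev_emitted <- -1L
  base_start <- rep(NA_integer_, n)  # first time row of each input base
  for (i in seq_len(n)) {
    if (config$skip_rate > 0 && runif(1) < config$skip_rate) next
    dom <- x[i]
    if (config$miscall_rate > 0 && runif(1) < config$miscall_rate)
      dom <- sample(setdiff(0:3, x[i]), 1L)
    if (dom == prev_emitted) add(.row_for(-1L, config))  # forced separator
    base_start[i] <- nr + 1L
    d <- 1L + rgeom(1L, prob = 1 / config$dwell_mean)
    for (j in seq_len(d)) add(.row_for(dom, config))
    prev_emitted <- dom
    if (config$stutter_rate > 0 && runif(1) < config$stutter_rate) {
      ins <- sample(0:3, 1L)
      if (ins == prev_emitted) add(.row_for(-1L, config))
      add(.row_for(ins, config))
      prev_emitted <- ins
    }
  }
  if (nr == 0L) add(.row_for(-1L, config))  # fully skipped: degenerate blank
  m <- log(do.call(rbind, rows[seq_len(nr)]))
  out <- ctc_matrix(m, alphabet = ab, provenance = "simulated")
  attr(out, "base_start") <- base_start
  out
}

#' Greedy basecall of a CTC matrix
#'
#' Per-row argmax path collapsed under CTC rules; the hard decoder's input
#' when only the matrix is available.
#'
#' @param ctc a [ctc_matrix()]
#' @return character scalar message
#' @export
greedy_basecall <- function(ctc) {
  ab <- ctc_alphabet(ctc)
  idx <- max.col(unclass(ctc), ties.method = "first")
  path <- paste(c("-", ab)[idx], collapse = "")
  collapse_path(path)
}
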