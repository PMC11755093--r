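## Reference (pure-R) beam-state semantics: states are lists with fields
## history, msg_index, message, score_blank, score_nonblank.  These
## functions define the update and merge rules at desk scale; the
## production path decode_soft_beam() runs the same algorithm in C++ and is
## tested for agreement against this reference on small instances.

beam_state <- function(history = 0L, msg_index = 0L, message = "",
                       score_blank = 0, score_nonblank = -Inf) {
  list(history = as.integer(history), msg_index = as.integer(msg_index),
       message = message, score_blank = score_blank,
       score_nonblank = score_nonblank)
}

beam_total <- function(s) logsumexp(c(s$score_blank, s$score_nonblank))

#' One Beam Trellis time step
#'
#' Advances a set of beam states across one CTC column.  Every state emits
#' a stay candidate `S_W` (blank extension of either half; repeat of the
#' last base from the non-blank half only) and, below full message length,
#' advance candidates `S_X`/`S_Y` -- one per bit guess on bit-consuming
#' steps -- emitting the hash-determined base; a repeated base draws only
#' from the predecessor's blank half.  Candidates are then merged with
#' [merge_duplicates()].
#'
#' @param states list of beam states (see Details)
#' @param ctc_column named or positional numeric vector of log
#'   probabilities for one time step: blank first, then the alphabet
#' @param params [code_params()]
#' @param L full message length in bases (advances stop at `msg_index = L`)
#' @return merged list of beam states at the next time step
#' @export
beam_step <- function(states, ctc_column, params = code_params(), L) {
  ab <- params$alphabet
  cands <- list()
  for (s in states) {
    tot <- beam_total(s)
    if (tot == -Inf) next
    last <- if (nchar(s$message) > 0)
      substr(s$message, nchar(s$message), nchar(s$message)) else NA
    ## stay
    sw <- s
    sw$score_blank <- ctc_column[1] + tot
    sw$score_nonblank <- if (!is.na(last))
      ctc_column[match(last, ab) + 1L] + s$score_nonblank else -Inf
    cands[[length(cands) + 1L]] <- sw
    ## advance
    if (s$msg_index < L) {
      consume <- (s$msg_index %% params$k) == 0L
      for (bit in if (consume) 0:1 else 0L) {
        b <- next_base(s$history, s$msg_index, bit,
                       substr(s$message,
                              max(1L, nchar(s$message) - 14L),
                              nchar(s$message)),
                       params)
        h2 <- if (consume) {
          bitwAnd(bitwShiftL(s$history, 1L) + bit,
                  bitwShiftL(1L, params$history_bits) - 1L)
        } else s$history
        v <- if (!is.na(last) && b == last) {
          ctc_column[match(b, ab) + 1L] + s$score_blank
        } else {
          ctc_column[match(b, ab) + 1L] + tot
        }
        if (v == -Inf) next
        cands[[length(cands) + 1L]] <- beam_state(
          h2, s$msg_index + 1L, paste0(s$message, b), -Inf, v)
      }
    }
  }
  merge_duplicates(cands)
}

#' Merge duplicate beam states
#'
#' Within each `(history, msg_index)` slot, states carrying the identical
#' message have their blank and non-blank score halves log-sum-exp
#' combined (they are CTC-encodings of the same message); distinct
#' messages are resolved by keeping the higher-total-score survivor.
#' Idempotent.
#'
#' @param states list of beam states
#' @return list with one state per occupied `(history, msg_index)` slot
#' @export
merge_duplicates <- function(states) {
  if (length(states) == 0L) return(states)
  keys <- vapply(states, function(s) paste(s$history, s$msg_index), "")
  out <- list()
  for (key in unique(keys)) {
    grp <- states[keys == key]
    by_msg <- split(grp, vapply(grp, `[[`, "", "message"))
    merged <- lapply(by_msg, function(g) {
      s <- g[[1]]
      s$score_blank <- logsumexp(vapply(g, `[[`, 0, "score_blank"))
      s$score_nonblank <- logsumexp(vapply(g, `[[`, 0, "score_nonblank"))
      s
    })
    tots <- vapply(merged, beam_total, 0)
    out[[length(out) + 1L]] <- merged[[which.max(tots)]]
  }
  out
}

#' Beam Trellis soft decoding
#'
#' The baseline soft decoder: `2^H * (L + 1)` trellis states, one per
#' (history, message index), updated across all `T` CTC time steps with
#' blank/non-blank score halves and duplicate-message merging.  Time
#' complexity grows as `O(L^2 T 2^H)` in the worst case (an extra factor L
#' over the alignment-matrix decoder from message comparisons, mitigated
#' here with rolling hashes).
#'
#' @param ctc payload-region [ctc_matrix()]
#' @param params [code_params()]
#' @param n_payload_bytes payload bytes expected per strand
#' @param engine `"cpp"` (default) or `"r"` (reference implementation,
#'   tiny instances only)
#' @param compare duplicate-message comparison strategy: `"hash"` (rolling
#'   hash with an exact walk on collision; amortized O(1)) or `"exact"`
#'   (positionwise array comparison, the O(L) cost model of the published
#'   algorithm; identical results, used for complexity measurements)
#' @return a `decode_result` whose `score` is the winning message's total
#'   (blank + non-blank) log probability
#' @export
decode_soft_beam <- function(ctc, params = code_params(), n_payload_bytes,
                             engine = c("cpp", "r"),
                             compare = c("hash", "exact")) {
  engine <- match.arg(engine)
  compare <- match.arg(compare)
  nbits <- 8L * (params$n_index_bytes + 1L + n_payload_bytes)
  if (engine == "cpp") {
    out <- decode_beam_cpp(unclass(ctc), nbits, params,
                           compare == "exact")
    return(.decode_result(out, params, n_payload_bytes, "beam"))
  }
  L <- nbits * params$k
  states <- list(beam_state())
  for (t in seq_len(nrow(ctc))) {
    states <- beam_step(states, unclass(ctc)[t, ], params, L)
  }
  full <- Filter(function(s) s$msg_index == L, states)
  if (length(full) == 0L)
    return(.decode_result(list(success = FALSE), params, n_payload_bytes,
                          "beam"))
  best <- full[[which.max(vapply(full, beam_total, 0))]]
  bases <- seq_to_int(best$message, params$alphabet)
  ## bits recovered by replaying the encoder along the winning base path
  bits <- .bits_from_bases(bases, params, nbits)
  .decode_result(list(success = !is.null(bits), bits = bits, bases = bases,
                      score = beam_total(best)),
                 params, n_payload_bytes, "beam")
}

## invert a base path to its bit sequence by replaying the encoder edges;
## both bit guesses can emit the same base (hash collision), so this is a
## depth-first search with backtracking, bit 0 preferred
.bits_from_bases <- function(bases, params, nbits) {
  L <- nbits * params$k
  if (length(bases) != L) return(NULL)
  mask <- bitwShiftL(1L, params$history_bits) - 1L
  recur <- function(s, history, bits) {
    if (s == L) return(bits)
    consume <- (s %% params$k) == 0L
    recent <- if (s > 0) bases[max(1L, s - 14L):s] else integer(0)
    for (bit in if (consume) 0:1 else 0L) {
      b <- next_base_cpp(history, s, bit, recent, params)
      if (b != bases[s + 1L]) next
      h2 <- if (consume) bitwAnd(bitwShiftL(history, 1L) + bit, mask)
            else history
      res <- recur(s + 1L, h2, if (consume) c(bits, bit) else bits)
      if (!is.null(res)) return(res)
    }
    NULL
  }
  recur(0L, 0L, integer(0))
}
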