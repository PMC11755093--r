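## Buffer localization by free-start Viterbi alignment of a short anchor
## sequence against the matrix: the best-scoring path of the anchor ending
## at each time step, with re-entry allowed at any time (accumulated score
## restarts at 0).  All log probabilities are <= 0, so the maximum is taken
## by tight windows where the anchor aligns well.
viterbi_locate <- function(anchor_ints, logp) {
  Tn <- nrow(logp)
  n <- length(anchor_ints)
  ns <- 2L * n + 1L
  colmap <- integer(ns)
  colmap[seq(1, ns, by = 2)] <- 1L
  colmap[seq(2, ns - 1, by = 2)] <- anchor_ints + 2L
  skip_ok <- rep(FALSE, ns)
  if (n >= 2) {
    ev <- seq(4, ns - 1, by = 2)
    skip_ok[ev] <- anchor_ints[ev / 2] != anchor_ints[ev / 2 - 1L]
  }
  v <- rep(-Inf, ns)
  endscore <- numeric(Tn)
  for (t in seq_len(Tn)) {
    stay <- v
    diag1 <- c(-Inf, v[-ns])
    diag2 <- c(-Inf, -Inf, v[seq_len(ns - 2L)])
    diag2[!skip_ok] <- -Inf
    best <- pmax(stay, diag1, diag2)
    best[1] <- max(best[1], 0)  # free start into the leading blank
    best[2] <- max(best[2], 0)  # or directly into the first anchor base
    v <- logp[t, colmap] + best
    endscore[t] <- max(v[ns - 1L], v[ns])
  }
  endscore
}

.rc_matrix <- function(ctc) {
  ## reverse time, complement base columns (blank, A, C, G, T|U) ->
  ## (blank, T|U, G, C, A)
  m <- unclass(ctc)[rev(seq_len(nrow(ctc))), c(1L, 5L, 4L, 3L, 2L),
                    drop = FALSE]
  ctc_matrix(m, alphabet = ctc_alphabet(ctc),
             provenance = attr(ctc, "provenance"))
}

#' Trim buffer regions from basecalled reads
#'
#' Base-space counterpart of [trim_and_orient()]: slides the left and right
#' signal buffers over the read (and its reverse complement), picks the
#' orientation with the better left-buffer match, and returns the sequence
#' between the buffers.
#'
#' @param read character scalar basecalled sequence
#' @param layout [strand_layout()]
#' @param alphabet `"DNA"` or `"RNA"`
#' @return list with `payload` (trimmed sequence) and `orientation`
#' @export
trim_basecalls <- function(read, layout = strand_layout(),
                           alphabet = "DNA") {
  ab <- alphabet_chars(alphabet)
  slide <- function(x, pat) {
    n <- length(x)
    m <- length(pat)
    if (n < m) return(list(pos = NA_integer_, mm = Inf))
    mm <- vapply(seq_len(n - m + 1L), function(i) {
      sum(x[i:(i + m - 1L)] != pat)
    }, 0)
    list(pos = which.min(mm), mm = min(mm))
  }
  lb <- seq_to_int(layout$left_buffer, DNA_ALPHABET)
  rb <- seq_to_int(layout$right_buffer, DNA_ALPHABET)
  fw <- seq_to_int(read, ab)
  rc <- rev(3L - fw)
  hit_fw <- slide(fw, lb)
  hit_rc <- slide(rc, lb)
  orientation <- if (hit_fw$mm <= hit_rc$mm) "forward" else
    "reverse_complement"
  x <- if (orientation == "forward") fw else rc
  left <- slide(x, lb)
  right <- slide(x, rb)
  start <- left$pos + length(lb)
  stop_ <- if (!is.na(right$pos) && right$pos > start) right$pos - 1L
           else length(x)
  list(payload = int_to_seq(x[start:stop_], ab), orientation = orientation)
}

#' Trim buffer regions from a full-strand CTC matrix and detect orientation
#'
#' Molecules are read either forward or as their reverse complement.  Both
#' orientations are scored by aligning the tail of the left signal buffer
#' against the matrix; the winner is trimmed to the time span between the
#' located end of the left buffer and start of the right buffer, leaving
#' the payload-region time steps.
#'
#' @param ctc full-strand [ctc_matrix()]
#' @param layout [strand_layout()]
#' @param params [code_params()] (for the alphabet)
#' @param anchor_len anchor length in bases taken from each buffer
#' @param margin_threshold orientation score margin (log units) below which
#'   an `orientation-ambiguous` warning is raised
#' @return list with `ctc` (trimmed, oriented), `orientation` (`"forward"`
#'   or `"reverse_complement"`), `t_start`, `t_end` (1-based inclusive time
#'   span retained) and `margin`
#' @export
trim_and_orient <- function(ctc, layout = strand_layout(),
                            params = code_params(), anchor_len = 30,
                            margin_threshold = 5) {
  ab <- ctc_alphabet(ctc)
  dna_ab <- DNA_ALPHABET  # layout sequences are written as DNA
  left_anchor <- substr(layout$left_buffer,
                        nchar(layout$left_buffer) - anchor_len + 1L,
                        nchar(layout$left_buffer))
  right_anchor <- substr(layout$right_buffer, 1L, anchor_len)
  la <- seq_to_int(left_anchor, dna_ab)
  ra <- seq_to_int(right_anchor, dna_ab)

  fw <- unclass(ctc)
  rc <- unclass(.rc_matrix(ctc))
  score_fw <- viterbi_locate(la, fw)
  score_rc <- viterbi_locate(la, rc)
  margin <- abs(max(score_fw) - max(score_rc))
  if (margin < margin_threshold)
    warning("orientation-ambiguous: score margin ", format(margin),
            " below threshold ", margin_threshold)
  orientation <- if (max(score_fw) >= max(score_rc)) "forward" else
    "reverse_complement"
  m <- if (orientation == "forward") fw else rc

  Tn <- nrow(m)
  sl <- viterbi_locate(la, m)
  t_start <- which.max(sl) + 1L
  ## right buffer located on the time-reversed matrix (same strand, so
  ## reverse the anchor, not its complement)
  mrev <- m[rev(seq_len(Tn)), , drop = FALSE]
  sr <- viterbi_locate(rev(ra), mrev)
  t_end <- Tn - which.max(sr)
  if (t_start > t_end) {  # degenerate localization; keep everything
    t_start <- 1L
    t_end <- Tn
  }
  trimmed <- ctc_matrix(m[t_start:t_end, , drop = FALSE], alphabet = ab,
                        provenance = attr(ctc, "provenance"))
  list(ctc = trimmed, orientation = orientation, t_start = t_start,
       t_end = t_end, margin = margin)
}
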