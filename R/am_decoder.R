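#' Initial forward-variable row (empty prefix)
#'
#' `M(0, t)` is the probability that the first `t` time steps are all
#' blanks: the cumulative sum of blank log probabilities.
#'
#' @param ctc a [ctc_matrix()]
#' @return a `prefix_row` for the empty prefix
#' @export
init_row <- function(ctc) {
  structure(list(values = as.numeric(init_row_cpp(unclass(ctc))),
                 prefix_len = 0L, last_base = NA_character_),
            class = "prefix_row")
}

#' Extend a forward-variable row by one base
#'
#' Derives the interleaved blank row and the new base row from the stored
#' row alone, left to right over time:
#' `blank[t] = ctc[t, blank] + lse(blank[t-1], prev[t-1])` and
#' `base[t] = ctc[t, base] + lse(base[t-1], blank[t-1], prev[t-1])`, with
#' the direct `prev[t-1]` term dropped when `new_base` repeats the previous
#' base (at least one blank must separate CTC repeats).
#'
#' @param prev a `prefix_row` (from [init_row()] or a previous extension)
#' @param new_base single character in the matrix alphabet
#' @param ctc a [ctc_matrix()]
#' @return list with `blank_row` and `base_row` (`prefix_row` objects) and
#'   the scalar `score` (log-sum-exp of the base row over all times)
#' @export
extend_row <- function(prev, new_base, ctc) {
  ab <- ctc_alphabet(ctc)
  b <- match(new_base, ab) - 1L
  if (is.na(b)) stop("new_base not in alphabet")
  last <- if (is.na(prev$last_base)) -1L else match(prev$last_base, ab) - 1L
  out <- extend_row_cpp(prev$values, prev$prefix_len, last, b, unclass(ctc))
  blank_row <- structure(list(values = out$blank_row,
                              prefix_len = prev$prefix_len,
                              last_base = prev$last_base),
                         class = "prefix_row")
  base_row <- structure(list(values = out$base_row,
                             prefix_len = prev$prefix_len + 1L,
                             last_base = new_base),
                        class = "prefix_row")
  list(blank_row = blank_row, base_row = base_row, score = out$score)
}

.decode_result <- function(raw_out, params, n_payload_bytes, algo) {
  nb <- params$n_index_bytes
  if (!isTRUE(raw_out$success)) {
    return(structure(list(success = FALSE, algo = algo, bytes = NULL,
                          payload = NULL, index = NA_integer_,
                          crc_ok = FALSE, message = NA_character_,
                          score = NA_real_,
                          guesses_used = raw_out$guesses_used %||% NA_real_,
                          rows_peak = raw_out$rows_peak %||% NA_real_),
                     class = "decode_result"))
  }
  bytes <- bits_to_bytes(raw_out$bits)
  rec <- parse_record_bytes(bytes, params)
  structure(list(success = TRUE, algo = algo, bytes = bytes,
                 payload = rec$payload, index = rec$index,
                 crc_ok = rec$crc_ok,
                 message = int_to_seq(raw_out$bases, params$alphabet),
                 score = raw_out$score %||% NA_real_,
                 guesses_used = raw_out$guesses_used %||% NA_real_,
                 rows_peak = raw_out$rows_peak %||% NA_real_),
            class = "decode_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.decode_result <- function(x, ...) {
  if (!x$success) {
    cat("<decode_result>", x$algo, "FAILED\n")
  } else {
    cat("<decode_result>", x$algo, "| index", x$index,
        "| crc", if (x$crc_ok) "ok" else "BAD",
        "|", length(x$payload), "payload bytes | score",
        format(x$score, digits = 6), "\n")
  }
  invisible(x)
}

#' Alignment Matrix trellis soft decoding
#'
#' Runs `L` trellis steps over `2^H` states.  Each state stores one row of
#' CTC forward variables for the prefix along its survivor path; incoming
#' edges (two bit guesses on bit-consuming steps, one edge otherwise) emit
#' the hash-determined base, the row is extended by [extend_row()] and
#' scored by log-sum-exp, and the best-scoring incoming edge survives per
#' state.  Time scales as `O(2^H L T)` and live forward-variable memory as
#' `O(2^H T)`.
#'
#' @param ctc payload-region [ctc_matrix()] (see [trim_and_orient()])
#' @param params [code_params()]
#' @param n_payload_bytes payload bytes expected per strand
#' @return a `decode_result`; `rows_peak` records the peak number of live
#'   forward-variable rows for the memory-contract check
#' @export
decode_soft_am <- function(ctc, params = code_params(), n_payload_bytes) {
  nbits <- 8L * (params$n_index_bytes + 1L + n_payload_bytes)
  out <- decode_am_cpp(unclass(ctc), nbits, params)
  .decode_result(out, params, n_payload_bytes, "am")
}

#' Positional byte error profile
#'
#' Per-byte-position failure frequencies across decoded reads with known
#' truth, with Wilson 95% confidence intervals and the grand mean byte
#' error rate `p_bar` attached as an attribute.
#'
#' @param results list of `decode_result` objects (or raw byte vectors)
#' @param truth raw vector of true record bytes, or a list of such vectors
#'   parallel to `results`
#' @return data.frame (`position`, `errors`, `n`, `rate`, `lo`, `hi`) of
#'   class `byte_error_profile`; attribute `p_bar` holds the mean rate
#' @export
per_byte_error_profile <- function(results, truth) {
  get_bytes <- function(r) if (inherits(r, "decode_result")) r$bytes else r
  if (!is.list(truth)) truth <- rep(list(truth), length(results))
  stopifnot(length(results) >= 1, length(truth) == length(results))
  npos <- length(truth[[1]])
  err <- matrix(NA, nrow = length(results), ncol = npos)
  for (i in seq_along(results)) {
    b <- get_bytes(results[[i]])
    err[i, ] <- if (is.null(b) || length(b) != npos) TRUE else b != truth[[i]]
  }
  errors <- colSums(err)
  n <- nrow(err)
  rate <- errors / n
  z <- qnorm(0.975)
  den <- 1 + z^2 / n
  ctr <- (rate + z^2 / (2 * n)) / den
  hw <- z * sqrt(rate * (1 - rate) / n + z^2 / (4 * n^2)) / den
  out <- data.frame(position = seq_len(npos) - 1L, errors = errors, n = n,
                    rate = rate, lo = pmax(0, ctr - hw),
                    hi = pmin(1, ctr + hw))
  structure(out, class = c("byte_error_profile", "data.frame"),
            p_bar = mean(rate))
}
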