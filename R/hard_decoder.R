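#' Best-first hard decoding of basecalled reads
#'
#' Searches the tree of bit guesses combined with error hypotheses
#' (match, substitution, insertion, deletion) against the observed
#' basecalls, expanding nodes in best-first (lowest accumulated penalty)
#' order under a guess budget.  With non-negative penalties the first
#' completed full-length hypothesis has minimal total penalty.
#'
#' @param basecalls character scalar: basecalled payload-region sequence
#'   (buffers trimmed by the caller)
#' @param params [code_params()]
#' @param n_payload_bytes payload bytes expected per strand
#' @param guess_limit maximum nodes expanded before giving up
#' @param penalties named numeric vector `c(sub=, ins=, del=)`
#' @param consume_all require the hypothesis to explain the whole read
#'   (default); `FALSE` permits partial decodes such as header-only
#'   demultiplexing
#' @return a `decode_result` with `guesses_used` and the final penalty in
#'   `score`
#' @export
decode_hard <- function(basecalls, params = code_params(), n_payload_bytes,
                        guess_limit = 1e6,
                        penalties = c(sub = 1, ins = 1, del = 1),
                        consume_all = TRUE) {
  nbits <- 8L * (params$n_index_bytes + 1L + n_payload_bytes)
  obs <- seq_to_int(basecalls, params$alphabet)
  out <- decode_hard_cpp(obs, nbits, params, guess_limit,
                         as.numeric(penalties[c("sub", "ins", "del")]),
                         consume_all)
  .decode_result(out, params, n_payload_bytes, "hard")
}

#' Demultiplex a read by decoding its index and CRC header
#'
#' Hard-decodes only the header (index bytes plus CRC-8) and attributes the
#' read to a strand iff the CRC validates; the reverse complement is tried
#' when the forward orientation fails.  Reads whose header decodes to an
#' inconsistent CRC are returned as unattributed (`NA`), which accepts
#' random sequences at a rate of about 1/256.
#'
#' @param basecalls character scalar: payload-region basecalls
#' @param params [code_params()]
#' @param guess_limit search budget per orientation
#' @param try_rc also try the reverse complement (default `TRUE`)
#' @return the decoded strand index, or `NA` if unattributed; attribute
#'   `orientation` records which orientation validated
#' @export
demultiplex <- function(basecalls, params = code_params(),
                        guess_limit = 20000, try_rc = TRUE) {
  header_bytes <- params$n_index_bytes + 1L
  nbits <- 8L * header_bytes
  try_one <- function(s) {
    obs <- seq_to_int(s, params$alphabet)
    out <- decode_hard_cpp(obs, nbits, params, guess_limit, c(1, 1, 1),
                           FALSE)
    if (!isTRUE(out$success)) return(NULL)
    parse_record_bytes(c(bits_to_bytes(out$bits), as.raw(0)), params)
  }
  r <- try_one(basecalls)
  if (!is.null(r) && r$crc_ok)
    return(structure(r$index, orientation = "forward"))
  if (try_rc) {
    r <- try_one(reverse_complement(basecalls, params$alphabet))
    if (!is.null(r) && r$crc_ok)
      return(structure(r$index, orientation = "reverse_complement"))
  }
  structure(NA_integer_, orientation = NA_character_)
}
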