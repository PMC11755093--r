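#' Hash-based alphabet ranking
#'
#' Digests `(salt, history, base_index, bit_guess)` through a chained
#' 32-bit avalanche hash and returns the resulting deterministic ordering of
#' the alphabet.  The top-ranked surviving candidate after constraint
#' masking becomes the emitted base.
#'
#' @param history H-bit integer history
#' @param base_index 0-based base step index
#' @param bit_guess 0 or 1 (0 on non-bit-consuming steps)
#' @param salt integer hash seed
#' @param params [code_params()] supplying the alphabet labels
#' @return character vector: the alphabet in hash-rank order
#' @export
hash_rank <- function(history, base_index, bit_guess, salt = 0,
                      params = code_params(salt = salt)) {
  perm <- hash_rank_cpp(salt, history, base_index, as.integer(bit_guess))
  params$alphabet[perm + 1L]
}

#' Constrained next-base selection
#'
#' Returns the highest hash-ranked base that does not extend a homopolymer
#' run beyond `max_homopolymer`; among the survivors, candidates keeping the
#' trailing GC window inside `gc_target +/- gc_tolerance` are preferred when
#' any exists.  A pure function of its inputs.
#'
#' @param history H-bit integer history
#' @param base_index 0-based base step index
#' @param bit 0 or 1
#' @param recent_bases string (or character vector) of most recently emitted
#'   bases, newest last; must cover the homopolymer and GC windows when full
#' @param params [code_params()]
#' @return single character, the emitted base
#' @export
next_base <- function(history, base_index, bit, recent_bases,
                      params = code_params()) {
  rec <- if (length(recent_bases) == 1L && nchar(recent_bases[1]) != 1L) {
    seq_to_int(recent_bases, params$alphabet)
  } else if (length(recent_bases) == 0L || identical(recent_bases, "")) {
    integer(0)
  } else {
    match(recent_bases, params$alphabet) - 1L
  }
  b <- next_base_cpp(history, as.integer(base_index), as.integer(bit),
                     as.integer(rec), params)
  params$alphabet[b + 1L]
}

#' Encode a message record into the payload base sequence
#'
#' Serializes the record (index, CRC, payload; MSB first), then walks the
#' convolutional encoder: one base per step, one bit consumed every `k`-th
#' step, history updated as `(history << 1 | bit) & (2^H - 1)` on consuming
#' steps.  Payload region length is exactly `total_bits * k` bases.
#'
#' @param record [message_record()]
#' @param params [code_params()]
#' @return character scalar, the payload-region sequence
#' @export
encode_payload <- function(record, params = code_params()) {
  bits <- record_bits(record)
  bases <- encode_cpp(as.integer(bits), params)
  int_to_seq(bases, params$alphabet)
}

#' Encode a full strand with layout regions
#'
#' @param record [message_record()]
#' @param params [code_params()]
#' @param layout [strand_layout()]
#' @return list with `sequence`, 0-based half-open `payload_span`, and the
#'   inputs; class `encoded_strand`
#' @export
encode_strand <- function(record, params = code_params(),
                          layout = strand_layout()) {
  payload <- encode_payload(record, params)
  seqn <- paste0(layout$t7_promoter, layout$synthesis_buffer,
                 layout$left_buffer, payload, layout$right_buffer,
                 layout$poly_a)
  span <- c(layout$prefix_length, layout$prefix_length + nchar(payload))
  structure(list(sequence = seqn, payload = payload, payload_span = span,
                 record = record, params = params, layout = layout),
            class = "encoded_strand")
}

#' @export
print.encoded_strand <- function(x, ...) {
  cat("<encoded_strand> index", x$record$index, "|", nchar(x$sequence),
      "bases | payload span [", x$payload_span[1], ",", x$payload_span[2],
      ") | rate", x$params$rate_id, "\n")
  invisible(x)
}

#' Write encoded strands to FASTA
#'
#' One record per strand; IDs are the strand indices.
#'
#' @param strands list of `encoded_strand` objects
#' @param path output FASTA path
#' @export
write_strands_fasta <- function(strands, path) {
  ids <- vapply(strands, function(s) as.character(s$record$index), "")
  seqs <- vapply(strands, function(s) s$sequence, "")
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    x <- Biostrings::DNAStringSet(setNames(seqs, ids))
    Biostrings::writeXStringSet(x, path)
  } else {
    writeLines(as.vector(rbind(paste0(">", ids), seqs)), path)
  }
  invisible(path)
}

#' Read sequences from FASTA/FASTQ
#'
#' Thin wrapper around Biostrings; returns a named character vector.
#'
#' @param path input path
#' @param format `"fasta"` or `"fastq"`
#' @export
read_reads <- function(path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    x <- Biostrings::readDNAStringSet(path, format = format)
    setNames(as.character(x), names(x))
  } else {
    stopifnot(format == "fasta")
    ln <- readLines(path)
    hd <- grepl("^>", ln)
    setNames(tapply(ln[!hd], cumsum(hd)[!hd], paste, collapse = ""),
             sub("^>", "", ln[hd]))
  }
}
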