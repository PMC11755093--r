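#' Code parameters for the constrained convolutional encoder
#'
#' The encoder consumes one payload bit every `k`-th base step, where the
#' code rate is `1/k` bits per base; supported rates are 1/8, 1/6, 1/3 and
#' 1/2.  Each emitted base is chosen by a salted integer hash of the
#' H-bit history, the base index and the bit guess, masked by a hard
#' homopolymer limit and a GC-content band over a sliding window.
#'
#' @param rate code rate as a string (`"1/6"`) or numeric (`1/6`)
#' @param history_bits trellis history width H (2^H decoder states)
#' @param salt integer seed mixed into the hash
#' @param max_homopolymer maximum run of identical bases (default 3)
#' @param gc_window GC constraint window in bases (default 12)
#' @param gc_target target GC fraction over the window (default 0.5)
#' @param gc_tolerance allowed deviation of the window GC fraction; the
#'   default 1/6 keeps 4-8 G/C bases in every 12-base window
#' @param alphabet `"DNA"` or `"RNA"`
#' @param n_index_bytes width of the strand index field (default 2)
#' @param crc_poly CRC-8 generator polynomial (default `0x97`)
#' @return an object of class `code_params`
#' @examples
#' p <- code_params("1/2", history_bits = 4)
#' p$bit_pattern   # one bit consumed every 2nd base step
#' @export
code_params <- function(rate = "1/6", history_bits = 8, salt = 0,
                        max_homopolymer = 3, gc_window = 12, gc_target = 0.5,
                        gc_tolerance = 1 / 6, alphabet = "DNA",
                        n_index_bytes = 2, crc_poly = 0x97) {
  rates <- c("1/8" = 8L, "1/6" = 6L, "1/3" = 3L, "1/2" = 2L)
  if (is.numeric(rate)) {
    k <- rates[which(abs(1 / rates - rate) < 1e-9)]
    if (length(k) != 1L) stop("rate must be one of 1/8, 1/6, 1/3, 1/2")
    rate <- names(k)
  } else {
    if (!rate %in% names(rates)) stop("rate must be one of ",
                                      paste(names(rates), collapse = ", "))
    k <- rates[[rate]]
  }
  k <- as.integer(k)
  stopifnot(history_bits >= 1, max_homopolymer >= 1, gc_window >= 2,
            gc_target > 0, gc_target < 1, n_index_bytes >= 1)
  structure(list(
    rate_id = rate, rate = 1 / k, k = k,
    bit_pattern = as.integer(seq_len(k) == 1L),
    history_bits = as.integer(history_bits),
    salt = as.numeric(salt),
    max_homopolymer = as.integer(max_homopolymer),
    gc_window = as.integer(gc_window),
    gc_target = gc_target, gc_tolerance = gc_tolerance,
    alphabet = alphabet_chars(alphabet),
    n_index_bytes = as.integer(n_index_bytes),
    crc_poly = as.integer(crc_poly)
  ), class = "code_params")
}

#' @export
print.code_params <- function(x, ...) {
  cat("<code_params> rate", x$rate_id, "| H =", x$history_bits,
      "| salt =", x$salt, "| homopolymer <=", x$max_homopolymer,
      "| GC", x$gc_target, "+/-", round(x$gc_tolerance, 3),
      "over", x$gc_window, "bp |",
      paste(x$alphabet, collapse = ""), "\n")
  invisible(x)
}

## fixed functional sequences of the default strand design; the buffers were
## drawn once from a seeded generator under the homopolymer constraint and
## are shipped as constants so every install encodes identically
T7_PROMOTER  <- "TAATACGACTCACTATAGG"
SYNTH_BUFFER <- "CCAAGTCT"
LEFT_BUFFER  <- "CGCTAATTTAATTAGGTGTTTGCCGAAGCGTGCCACCGTCTTTGATCACC"
RIGHT_BUFFER <- "CTGTCAACTCCGTAGGTTTGATATCGCTTGTATCAATTTATTAAGCTTAG"
POLY_A       <- "AAAAAAAAAA"

#' Strand layout: fixed regions around the information-carrying payload
#'
#' The default design is, 5' to 3': a 19 bp T7 promoter (enables RNA
#' transcription of the same molecules), an 8 bp synthesis buffer, a 50 bp
#' signal buffer, the payload, a second 50 bp signal buffer and a 10 base
#' poly-A tail, for `19 + 8 + 50 + payload + 50 + 10` bases in total.
#'
#' @param t7_promoter,synthesis_buffer,left_buffer,right_buffer,poly_a
#'   fixed region sequences (defaults are package constants)
#' @return an object of class `strand_layout`
#' @export
strand_layout <- function(t7_promoter = T7_PROMOTER,
                          synthesis_buffer = SYNTH_BUFFER,
                          left_buffer = LEFT_BUFFER,
                          right_buffer = RIGHT_BUFFER,
                          poly_a = POLY_A) {
  x <- list(t7_promoter = t7_promoter, synthesis_buffer = synthesis_buffer,
            left_buffer = left_buffer, right_buffer = right_buffer,
            poly_a = poly_a)
  x$prefix_length <- nchar(t7_promoter) + nchar(synthesis_buffer) +
    nchar(left_buffer)
  x$suffix_length <- nchar(right_buffer) + nchar(poly_a)
  x$overhead <- x$prefix_length + x$suffix_length
  structure(x, class = "strand_layout")
}

#' @export
print.strand_layout <- function(x, ...) {
  cat("<strand_layout> T7(", nchar(x$t7_promoter), ") + synth(",
      nchar(x$synthesis_buffer), ") + buffer(", nchar(x$left_buffer),
      ") + payload + buffer(", nchar(x$right_buffer), ") + polyA(",
      nchar(x$poly_a), "); overhead ", x$overhead, " bases\n", sep = "")
  invisible(x)
}

#' CRC-8 checksum
#'
#' Bitwise CRC-8 (MSB first, zero initial value) under the configured
#' generator polynomial; used to validate decoded strand indices during
#' demultiplexing.
#'
#' @param bytes raw vector or integer vector of byte values
#' @param poly generator polynomial (default `0x97`)
#' @return a single byte as `raw`
#' @export
crc8 <- function(bytes, poly = 0x97) {
  poly <- as.integer(poly)
  crc <- 0L
  for (b in as.integer(bytes)) {
    crc <- bitwXor(crc, b)
    for (i in 1:8) {
      crc <- if (bitwAnd(crc, 0x80L) != 0L) {
        bitwAnd(bitwXor(bitwShiftL(crc, 1L), poly), 0xFFL)
      } else {
        bitwAnd(bitwShiftL(crc, 1L), 0xFFL)
      }
    }
  }
  as.raw(crc)
}

#' Message record: index, CRC and payload bytes
#'
#' Serialized bit order is fixed: index bytes (big-endian), then the CRC-8
#' of the index bytes, then the payload bytes; bits are MSB first.
#'
#' @param index non-negative strand index
#' @param payload raw vector of payload bytes
#' @param params [code_params()] (supplies index width and CRC polynomial)
#' @return an object of class `message_record`
#' @export
message_record <- function(index, payload, params = code_params()) {
  stopifnot(is.raw(payload), index >= 0, index < 256^params$n_index_bytes)
  nb <- params$n_index_bytes
  idx_bytes <- as.raw(sapply(seq_len(nb), function(i) {
    bitwAnd(bitwShiftR(as.integer(index), 8L * (nb - i)), 0xFFL)
  }))
  structure(list(index = as.integer(index), index_bytes = idx_bytes,
                 crc_byte = crc8(idx_bytes, params$crc_poly),
                 payload_bytes = payload),
            class = "message_record")
}

record_bytes <- function(record) {
  c(record$index_bytes, record$crc_byte, record$payload_bytes)
}

record_bits <- function(record) {
  bytes_to_bits(record_bytes(record))
}

## inverse of record serialization; returns NULL fields on CRC mismatch
parse_record_bytes <- function(bytes, params) {
  nb <- params$n_index_bytes
  idx_bytes <- bytes[seq_len(nb)]
  crc <- bytes[nb + 1L]
  payload <- bytes[-seq_len(nb + 1L)]
  index <- sum(as.integer(idx_bytes) * 256^((nb - 1):0))
  list(index = as.integer(index), payload = payload,
       crc_ok = identical(crc8(idx_bytes, params$crc_poly), crc))
}
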