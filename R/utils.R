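#' Numerically stable log-sum-exp
#'
#' Max-shifted, `-Inf`-safe reduction used throughout the CTC machinery.
#'
#' @param x numeric vector of log values (may contain `-Inf`)
#' @return `log(sum(exp(x)))` as a scalar
#' @export
logsumexp <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (m == -Inf) return(-Inf)
  m + log(sum(exp(x - m)))
}

DNA_ALPHABET <- c("A", "C", "G", "T")
RNA_ALPHABET <- c("A", "C", "G", "U")

alphabet_chars <- function(alphabet) {
  if (length(alphabet) == 1L) {
    switch(toupper(alphabet), DNA = DNA_ALPHABET, RNA = RNA_ALPHABET,
           stop("unknown alphabet: ", alphabet))
  } else {
    alphabet
  }
}

## sequences travel as character strings at the API surface and as
## 0-based integer codes (A=0, C=1, G=2, T/U=3) internally
seq_to_int <- function(s, alphabet = DNA_ALPHABET) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  idx <- match(ch, alphabet) - 1L
  if (anyNA(idx)) stop("invalid symbol in sequence: ",
                       paste(unique(ch[is.na(idx)]), collapse = ", "))
  idx
}

int_to_seq <- function(x, alphabet = DNA_ALPHABET) {
  paste(alphabet[x + 1L], collapse = "")
}

## bits are integer 0/1 vectors, MSB first within each byte
bytes_to_bits <- function(bytes) {
  bytes <- as.integer(bytes)
  as.integer(vapply(bytes, function(b) {
    as.integer(bitwAnd(bitwShiftR(b, 7:0), 1L))
  }, integer(8)))
}

bits_to_bytes <- function(bits) {
  stopifnot(length(bits) %% 8L == 0L)
  m <- matrix(as.integer(bits), nrow = 8L)
  as.raw(colSums(m * 2L^(7:0)))
}

#' Reverse complement of a DNA or RNA sequence
#'
#' An involution over the configured alphabet: A pairs T (or U for RNA) and
#' C pairs G.
#'
#' @param sequence character scalar over the alphabet
#' @param alphabet `"DNA"` (default) or `"RNA"`, or a 4-character vector
#' @return the reverse-complemented sequence
#' @examples
#' reverse_complement("AAAC")   # "GTTT"
#' reverse_complement("ACGU", alphabet = "RNA")
#' @export
reverse_complement <- function(sequence, alphabet = "DNA") {
  ab <- alphabet_chars(alphabet)
  x <- seq_to_int(sequence, ab)
  int_to_seq(rev(3L - x), ab)
}
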