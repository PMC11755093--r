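#' CTC log-probability matrix
#'
#' Container for a basecaller-style CTC output: a `T x (|alphabet| + 1)`
#' matrix of log probabilities with column 1 the blank symbol and columns
#' 2.. the alphabet in order.  Every row is a normalized distribution.
#'
#' @param logp numeric matrix of log probabilities
#' @param alphabet symbol labels for the non-blank columns
#' @param provenance `"simulated"` or `"loaded"`
#' @param tol row-normalization tolerance
#' @return a `ctc_matrix` (a matrix with attributes)
#' @export
ctc_matrix <- function(logp, alphabet = DNA_ALPHABET,
                       provenance = "simulated", tol = 1e-9) {
  logp <- as.matrix(logp)
  alphabet <- alphabet_chars(alphabet)
  stopifnot(nrow(logp) >= 1, ncol(logp) == length(alphabet) + 1L)
  rows <- apply(logp, 1, logsumexp)
  if (any(abs(rows) > tol))
    stop("CTC rows must be normalized distributions (max |logsumexp| = ",
         format(max(abs(rows))), ")")
  if (any(logp > tol)) stop("CTC entries must be log probabilities (<= 0)")
  structure(logp, class = c("ctc_matrix", "matrix"),
            alphabet = alphabet, provenance = provenance)
}

#' @export
print.ctc_matrix <- function(x, ...) {
  cat("<ctc_matrix>", nrow(x), "time steps x ( blank +",
      paste(attr(x, "alphabet"), collapse = ""), ") |",
      attr(x, "provenance"), "\n")
  invisible(x)
}

ctc_alphabet <- function(ctc) {
  ab <- attr(ctc, "alphabet")
  if (is.null(ab)) DNA_ALPHABET else ab
}

#' Write / read a CTC matrix as TSV plus a JSON sidecar
#'
#' The payload is a plain TSV of log probabilities (columns `blank`,
#' alphabet symbols); `<path>.json` records alphabet and provenance.
#'
#' @param ctc a [ctc_matrix()]
#' @param path TSV path; the sidecar is written at `paste0(path, ".json")`
#' @return `path`, invisibly (`write_ctc`) or the matrix (`read_ctc`)
#' @export
write_ctc <- function(ctc, path) {
  ab <- ctc_alphabet(ctc)
  m <- unclass(ctc)
  colnames(m) <- c("blank", ab)
  write.table(format(m, digits = 17), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(list(alphabet = ab,
                            provenance = attr(ctc, "provenance"),
                            T = nrow(ctc)),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_ctc
#' @export
read_ctc <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  m <- as.matrix(read.table(path, header = TRUE, sep = "\t"))
  ctc_matrix(m, alphabet = meta$alphabet, provenance = "loaded")
}

#' Collapse a CTC path to its message
#'
#' Standard CTC collapse: merge adjacent repeats, then drop blanks (`"-"`).
#'
#' @param path character scalar over alphabet symbols and `"-"`
#' @return the collapsed message
#' @examples
#' collapse_path("AAA")  # "A"
#' collapse_path("A-A")  # "AA"
#' @export
collapse_path <- function(path) {
  ch <- strsplit(path, "", fixed = TRUE)[[1]]
  if (length(ch) == 0L) return("")
  r <- rle(ch)$values
  paste(r[r != "-"], collapse = "")
}

#' Total CTC probability of a message
#'
#' Log of the summed probability over all CTC-encodings of `message` (paths
#' that collapse to it) under the matrix, via the standard forward recursion
#' over the blank-interleaved expanded sequence.  Returns `-Inf` for
#' messages with no valid encoding (e.g. longer than `T`).
#'
#' @param message character scalar over the matrix alphabet
#' @param ctc a [ctc_matrix()]
#' @return log probability scalar
#' @export
forward_probability <- function(message, ctc) {
  ab <- ctc_alphabet(ctc)
  Tn <- nrow(ctc)
  if (nchar(message) == 0L) return(sum(ctc[, 1]))
  m <- seq_to_int(message, ab)
  n <- length(m)
  if (n > Tn) return(-Inf)
  ns <- 2L * n + 1L
  ## expanded states: odd = blank, even s = base m[s/2]; columns in ctc
  colmap <- integer(ns)
  colmap[seq(1, ns, by = 2)] <- 1L
  colmap[seq(2, ns - 1, by = 2)] <- m + 2L
  ## skip transition s-2 -> s allowed only into a base state differing from
  ## the previous base state
  skip_ok <- rep(FALSE, ns)
  if (n >= 2) {
    ev <- seq(4, ns - 1, by = 2)
    skip_ok[ev] <- m[ev / 2] != m[ev / 2 - 1L]
  }
  alpha <- rep(-Inf, ns)
  alpha[1] <- ctc[1, 1]
  alpha[2] <- ctc[1, m[1] + 2L]
  if (Tn >= 2) {
    for (t in 2:Tn) {
      prev <- alpha
      stay <- prev
      diag1 <- c(-Inf, prev[-ns])
      diag2 <- c(-Inf, -Inf, prev[seq_len(ns - 2L)])
      diag2[!skip_ok] <- -Inf
      mx <- pmax(stay, diag1, diag2)
      acc <- ifelse(mx == -Inf, -Inf,
                    mx + log(exp(stay - mx) + exp(diag1 - mx) +
                             exp(diag2 - mx)))
      alpha <- ctc[t, colmap] + acc
    }
  }
  logsumexp(alpha[c(ns - 1L, ns)])
}
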