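## Independent oracles used across the suite.  These deliberately avoid the
## package's own code paths: the CTC oracle enumerates label paths, the
## hash oracle re-implements the integer mix in plain R arithmetic, and the
## edit-distance oracle uses base R's adist().

## ---- exhaustive CTC path enumeration --------------------------------------
## For a T x (n+1) matrix, enumerate all (n+1)^T label paths, collapse each
## (merge repeats, drop blanks) and group-sum path probabilities by message.
## Paths and collapse classes depend only on (T, alphabet), so they are
## cached and reused across matrices.
.path_cache <- new.env(parent = emptyenv())

enumerate_paths <- function(Tn, alphabet) {
  key <- paste(Tn, paste(alphabet, collapse = ""))
  if (!is.null(.path_cache[[key]])) return(.path_cache[[key]])
  ns <- length(alphabet) + 1L
  paths <- as.matrix(expand.grid(rep(list(seq_len(ns)), Tn)))
  syms <- c("-", alphabet)
  coll <- vapply(seq_len(nrow(paths)), function(i) {
    r <- rle(syms[paths[i, ]])$values
    paste(r[r != "-"], collapse = "")
  }, "")
  out <- list(paths = paths, collapsed = factor(coll))
  .path_cache[[key]] <- out
  out
}

## log probability of every collapsed message under the matrix; named vector
brute_message_probs <- function(logp, alphabet) {
  Tn <- nrow(logp)
  pc <- enumerate_paths(Tn, alphabet)
  lp <- numeric(nrow(pc$paths))
  for (t in seq_len(Tn)) lp <- lp + logp[t, pc$paths[, t]]
  grp <- tapply(lp, pc$collapsed, logsumexp)
  setNames(as.numeric(grp), names(grp))
}

brute_forward <- function(message, logp, alphabet) {
  probs <- brute_message_probs(logp, alphabet)
  hit <- which(names(probs) == message)  # robust for message == ""
  if (length(hit) == 0L) -Inf else probs[[hit]]
}

## random normalized CTC log-matrix
random_ctc <- function(Tn, alphabet = c("A", "C"), concentrate = FALSE) {
  ns <- length(alphabet) + 1L
  p <- matrix(runif(Tn * ns)^(if (concentrate) 4 else 1), nrow = Tn) + 1e-4
  ctc_matrix(log(p / rowSums(p)), alphabet = alphabet, tol = 1e-6)
}

## ---- independent reimplementation of the codebook hash --------------------
## 32-bit arithmetic on doubles: exact because all intermediates < 2^53.
u32 <- function(x) x %% 2^32
xor32 <- function(a, b) {
  lo <- bitwXor(as.integer(a %% 65536), as.integer(b %% 65536))
  hi <- bitwXor(as.integer(a %/% 65536), as.integer(b %/% 65536))
  hi * 65536 + lo
}
mul32 <- function(a, b) {
  alo <- a %% 65536; ahi <- a %/% 65536
  blo <- b %% 65536; bhi <- b %/% 65536
  u32(alo * blo + u32((alo * bhi + ahi * blo) %% 65536 * 65536))
}
shr32 <- function(a, k) a %/% 2^k

fmix32_r <- function(h) {
  h <- xor32(h, shr32(h, 16)); h <- mul32(h, 0x85ebca6b)
  h <- xor32(h, shr32(h, 13)); h <- mul32(h, 0xc2b2ae35)
  xor32(h, shr32(h, 16))
}

hedges_hash_r <- function(salt, history, idx, bit) {
  h <- fmix32_r(xor32(u32(salt), 0x9e3779b9))
  h <- fmix32_r(xor32(h, u32(history)))
  h <- fmix32_r(xor32(h, mul32(u32(idx), 0x85ebca6b)))
  fmix32_r(xor32(h, u32(bit + 0x165667b1)))
}

perms4 <- function() {
  out <- list()
  for (a in 0:3) for (b in 0:3) for (c in 0:3) for (d in 0:3)
    if (length(unique(c(a, b, c, d))) == 4L)
      out[[length(out) + 1L]] <- c(a, b, c, d)
  out  # lexicographic by construction
}

hash_rank_r <- function(salt, history, idx, bit) {
  perms4()[[hedges_hash_r(salt, history, idx, bit) %% 24 + 1]]
}

## ---- misc helpers ---------------------------------------------------------
tiny_params <- function(rate = "1/2", H = 2, ...) {
  code_params(rate, history_bits = H, n_index_bytes = 1, ...)
}

random_record <- function(params, n_payload = 2L) {
  message_record(sample(0:(256^params$n_index_bytes - 1), 1),
                 as.raw(sample(0:255, n_payload, replace = TRUE)), params)
}

## count max homopolymer run and worst GC-window deviation of a sequence
max_run <- function(s) max(rle(strsplit(s, "")[[1]])$lengths)
gc_windows <- function(s, w = 12) {
  x <- strsplit(s, "")[[1]] %in% c("G", "C")
  if (length(x) < w) return(numeric(0))
  cs <- cumsum(c(0, x))
  (cs[(w + 1):length(cs)] - cs[1:(length(cs) - w)]) / w
}
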