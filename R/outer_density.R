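#' Mean byte error rate across strands
#'
#' Unweighted mean over byte positions within each strand, then over
#' strands.
#'
#' @param profiles a single [per_byte_error_profile()] result, a numeric
#'   vector of positional rates, or a list of either
#' @return scalar mean byte error rate
#' @export
mean_byte_error <- function(profiles) {
  as_rates <- function(p) {
    if (inherits(p, "byte_error_profile")) p$rate else as.numeric(p)
  }
  if (inherits(profiles, "byte_error_profile") || is.numeric(profiles))
    profiles <- list(profiles)
  stopifnot(length(profiles) >= 1)
  mean(vapply(profiles, function(p) mean(as_rates(p)), 0))
}

#' Reed-Solomon codeword failure probability
#'
#' Probability that a codeword with `n` symbols and `k` data symbols fails
#' to decode when symbol errors are i.i.d. with rate `p_byte` (bytes of one
#' codeword are striped diagonally across strands, so per-strand failures
#' look independent to the outer code): the binomial tail
#' `P[X > floor((n - k) / 2)]`, summed in log space.
#'
#' @param n codeword length (<= 255 for RS over GF(256))
#' @param k data symbols (0 < k < n)
#' @param p_byte symbol error rate in `[0, 1]`
#' @return failure probability
#' @export
rs_failure_prob <- function(n, k, p_byte) {
  stopifnot(n >= 1, k >= 1, k < n, p_byte >= 0, p_byte <= 1)
  t <- floor((n - k) / 2)
  if (p_byte == 0) return(0)
  if (p_byte == 1) return(if (t < n) 1 else 0)
  i <- (t + 1):n
  exp(logsumexp(dbinom(i, n, p_byte, log = TRUE)))
}

#' Choose the outer-code dimension under capacity/MTTF constraints
#'
#' Picks the largest `k` such that the expected number of codeword
#' failures over `mttf_accesses` full reads of `capacity_bytes` stays
#' below one, i.e. per-codeword failure probability at most
#' `k / (capacity_bytes * mttf_accesses)` (there are `capacity_bytes / k`
#' codewords per full capacity).
#'
#' @param p_byte mean byte error rate after inner decoding
#' @param capacity_bytes target system capacity (default 1e12, 1 TB)
#' @param mttf_accesses target mean accesses to failure (default 1e6)
#' @param n codeword length (default 255)
#' @return the chosen `k`, or `NA_integer_` when even `k = 1` cannot meet
#'   the constraint (infeasible design)
#' @export
choose_design <- function(p_byte, capacity_bytes = 1e12,
                          mttf_accesses = 1e6, n = 255) {
  stopifnot(p_byte >= 0, p_byte <= 1)
  if (p_byte == 0) return(as.integer(n - 1))
  for (k in (n - 1):1) {
    budget <- k / (capacity_bytes * mttf_accesses)
    if (rs_failure_prob(n, k, p_byte) <= budget) return(as.integer(k))
  }
  NA_integer_
}

#' Overall storage density in bits per base
#'
#' `phi = (rs_k / rs_n) * rate * information_bases / total_bases`, where
#' information bases exclude the index/CRC header and the fixed layout
#' overhead only enters the denominator.
#'
#' @param params [code_params()]
#' @param layout [strand_layout()] (`NULL` for zero overhead)
#' @param n_payload_bytes payload bytes per strand
#' @param rs_k,rs_n outer-code dimensions
#' @return density in bits per base (`NA` when `rs_k` is `NA`)
#' @export
density_phi <- function(params, layout = strand_layout(), n_payload_bytes,
                        rs_k, rs_n = 255) {
  if (is.na(rs_k)) return(NA_real_)
  k <- params$k
  header_bases <- 8L * (params$n_index_bytes + 1L) * k
  info_bases <- 8L * n_payload_bytes * k
  overhead <- if (is.null(layout)) 0L else layout$overhead
  total <- overhead + header_bases + info_bases
  (rs_k / rs_n) * params$rate * info_bases / total
}

#' Density projection over strand length
#'
#' Truncates a positional byte error profile at each candidate payload
#' size to emulate shorter strands, recomputes the mean byte error rate,
#' re-chooses the outer-code dimension and reports the resulting density.
#'
#' @param profile numeric vector of per-byte-position error rates (or a
#'   [per_byte_error_profile()])
#' @param params [code_params()]
#' @param layout [strand_layout()]
#' @param payload_bytes integer vector of candidate payload sizes (default:
#'   every size up to the profile length)
#' @param capacity_bytes,mttf_accesses,rs_n passed to [choose_design()]
#' @return data.frame with `payload_bytes`, `strand_length`, `p_bar`,
#'   `rs_k` and `phi`
#' @export
density_sweep <- function(profile, params = code_params(),
                          layout = strand_layout(), payload_bytes = NULL,
                          capacity_bytes = 1e12, mttf_accesses = 1e6,
                          rs_n = 255) {
  if (inherits(profile, "byte_error_profile")) profile <- profile$rate
  npos <- length(profile)
  header <- params$n_index_bytes + 1L
  if (is.null(payload_bytes))
    payload_bytes <- seq_len(npos - header)
  out <- lapply(payload_bytes, function(nb) {
    rates <- profile[seq_len(header + nb)]
    p_bar <- mean(rates)
    rs_k <- choose_design(p_bar, capacity_bytes, mttf_accesses, rs_n)
    strand_length <- layout$overhead + 8L * (header + nb) * params$k
    data.frame(payload_bytes = nb, strand_length = strand_length,
               p_bar = p_bar, rs_k = rs_k,
               phi = density_phi(params, layout, nb, rs_k, rs_n))
  })
  do.call(rbind, out)
}
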