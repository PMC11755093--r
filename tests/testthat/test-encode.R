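test_that("code_params validates rates and derives the bit pattern", {
  for (r in c("1/8", "1/6", "1/3", "1/2")) {
    p <- code_params(r)
    expect_equal(mean(p$bit_pattern), p$rate)
    expect_equal(p$rate_id, r)
  }
  expect_equal(code_params(1 / 6)$k, 6L)
  expect_error(code_params("1/5"))
})

test_that("rate arithmetic fixes the payload region length", {
  ## one byte of payload, zero-width header would need 8 bits; with the
  ## 1-index-byte header: (1 + 1 + 1) * 8 bits * k bases/bit
  p <- tiny_params("1/2")
  rec <- message_record(0, as.raw(7), p)
  expect_equal(nchar(encode_payload(rec, p)), 3 * 8 * 2)
  expect_equal(nchar(encode_payload(rec, tiny_params("1/8"))), 3 * 8 * 8)
})

test_that("encoding is deterministic and salt-dependent", {
  p <- code_params("1/6", history_bits = 6, salt = 4)
  rec <- message_record(1, as.raw(1:5), p)
  expect_identical(encode_payload(rec, p), encode_payload(rec, p))
  p2 <- code_params("1/6", history_bits = 6, salt = 5)
  expect_false(encode_payload(rec, p) == encode_payload(rec, p2))
})

test_that("strand layout assembles and measures correctly", {
  lay <- strand_layout()
  p <- code_params("1/2", history_bits = 4)
  rec <- message_record(2, as.raw(1:4), p)
  st <- encode_strand(rec, p, lay)
  payload_len <- nchar(st$payload)
  expect_equal(nchar(st$sequence), 19 + 8 + 50 + payload_len + 50 + 10)
  expect_equal(st$payload_span, c(77, 77 + payload_len))
  expect_identical(substr(st$sequence, st$payload_span[1] + 1,
                          st$payload_span[2]), st$payload)
})

test_that("homopolymer constraint holds on random strands", {
  set.seed(101)
  p <- code_params("1/6", history_bits = 6)
  for (i in 1:1000) {
    rec <- random_record(p, n_payload = 3L)
    s <- encode_payload(rec, p)
    expect_lte(max_run(s), p$max_homopolymer)
  }
})

test_that("max_homopolymer = 1 forbids adjacent repeats", {
  p <- code_params("1/6", history_bits = 4, max_homopolymer = 1)
  s <- encode_payload(message_record(9, as.raw(1:6), p), p)
  expect_equal(max_run(s), 1)
})

test_that("GC windows stay inside the configured band", {
  set.seed(202)
  p <- code_params("1/6", history_bits = 6)
  for (i in 1:50) {
    s <- encode_payload(random_record(p, n_payload = 8L), p)
    gw <- gc_windows(s, p$gc_window)
    expect_true(all(abs(gw - p$gc_target) <= p$gc_tolerance + 1e-9))
  }
})

test_that("next_base refuses to extend a maximal homopolymer", {
  p <- code_params()
  for (h in 0:7) {
    for (idx in c(3, 15, 40)) {
      expect_false(next_base(h, idx, 0, "AAA", p) == "A")
      expect_false(next_base(h, idx, 1, "TTT", p) == "T")
    }
  }
})

test_that("early bit flips decorrelate the constraint-length window", {
  ## convolutional embedded-context property: a flipped bit scrambles the
  ## emitted bases while it sits in the H-bit history (the constraint
  ## length (H + 1) * k bases); beyond it the shift registers reconverge,
  ## so full-suffix divergence is structurally impossible for a
  ## finite-history code.  Monte-Carlo over 100 pairs.
  set.seed(303)
  p <- code_params("1/2", history_bits = 8)
  out <- replicate(100, {
    payload <- as.raw(sample(0:255, 6, replace = TRUE))
    rec1 <- message_record(0, payload, p)
    bits1 <- trellisdna:::record_bits(rec1)
    flip_at <- sample(5:12, 1)
    bits2 <- bits1
    bits2[flip_at] <- 1L - bits2[flip_at]
    s1 <- trellisdna:::encode_cpp(bits1, p)
    s2 <- trellisdna:::encode_cpp(bits2, p)
    win <- ((flip_at - 1) * p$k + 1):((flip_at + p$history_bits) * p$k)
    tail_idx <- (max(win) + 1):length(s1)
    c(window = mean(s1[win] != s2[win]),
      after = mean(s1[tail_idx] != s2[tail_idx]))
  })
  expect_gt(mean(out["window", ]), 0.40)   # decorrelated inside the window
  expect_lt(mean(out["after", ]), 0.05)    # reconverged beyond it
})

test_that("reverse_complement is an involution with the expected pairs", {
  expect_identical(reverse_complement("ACGT"), "ACGT")
  expect_identical(reverse_complement("AAAC"), "GTTT")
  expect_identical(reverse_complement("ACGU", alphabet = "RNA"), "ACGU")
  set.seed(7)
  for (i in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE),
               collapse = "")
    expect_identical(reverse_complement(reverse_complement(s)), s)
  }
  expect_error(reverse_complement("ACGX"))
})

test_that("message records serialize index, CRC, payload in order", {
  p <- code_params()
  rec <- message_record(0x0102, as.raw(c(0xAA, 0xBB)), p)
  bytes <- trellisdna:::record_bytes(rec)
  expect_identical(bytes[1:2], as.raw(c(1, 2)))
  expect_identical(bytes[3], crc8(as.raw(c(1, 2)), p$crc_poly))
  expect_identical(bytes[4:5], as.raw(c(0xAA, 0xBB)))
  parsed <- trellisdna:::parse_record_bytes(bytes, p)
  expect_equal(parsed$index, 0x0102)
  expect_true(parsed$crc_ok)
  ## bit serialization round trip
  bits <- trellisdna:::bytes_to_bits(bytes)
  expect_identical(trellisdna:::bits_to_bytes(bits), bytes)
  expect_identical(bits[1:8], c(0L, 0L, 0L, 0L, 0L, 0L, 0L, 1L))
})

test_that("FASTA output round-trips strand sequences", {
  p <- code_params("1/2", history_bits = 4)
  strands <- lapply(0:2, function(i) {
    encode_strand(message_record(i, as.raw(i + 1), p), p)
  })
  path <- tempfile(fileext = ".fasta")
  write_strands_fasta(strands, path)
  back <- read_reads(path)
  expect_equal(unname(back),
               vapply(strands, function(s) s$sequence, ""))
  expect_equal(names(back), c("0", "1", "2"))
})
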