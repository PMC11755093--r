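test_that("error-free basecalls decode exactly with zero penalty", {
  set.seed(1)
  for (rate in c("1/8", "1/2")) {
    p <- code_params(rate, history_bits = 4)
    rec <- random_record(p, 4L)
    s <- encode_payload(rec, p)
    r <- decode_hard(s, p, 4, guess_limit = 1e5)
    expect_true(r$success)
    expect_identical(r$bytes, trellisdna:::record_bytes(rec))
    expect_equal(r$score, 0)
    expect_lte(r$guesses_used, 2 * nchar(s))  # < 2 L guesses on clean input
  }
})

test_that("a single substitution is recovered in >= 99/100 trials", {
  set.seed(42)
  p <- code_params("1/2", history_bits = 8)
  rec <- message_record(3, as.raw(1:6), p)
  s <- encode_payload(rec, p)
  truth <- trellisdna:::record_bytes(rec)
  hits <- replicate(100, {
    pos <- sample(nchar(s), 1)
    orig <- substr(s, pos, pos)
    sub <- sample(setdiff(c("A", "C", "G", "T"), orig), 1)
    noisy <- paste0(substr(s, 1, pos - 1), sub,
                    substr(s, pos + 1, nchar(s)))
    r <- decode_hard(noisy, p, 6, guess_limit = 1e4)
    isTRUE(r$success) && identical(r$bytes, truth)
  })
  expect_gte(sum(hits), 99)
})

test_that("byte error rate rises with the base error rate", {
  set.seed(7)
  p <- code_params("1/2", history_bits = 6)
  rec <- message_record(1, as.raw(1:3), p)
  s <- encode_payload(rec, p)
  truth <- trellisdna:::record_bytes(rec)
  corrupt <- function(s, rate) {
    ch <- strsplit(s, "")[[1]]
    hit <- runif(length(ch)) < rate
    ch[hit] <- vapply(ch[hit], function(x) {
      sample(setdiff(c("A", "C", "G", "T"), x), 1)
    }, "")
    paste(ch, collapse = "")
  }
  ber <- vapply(c(0.01, 0.05, 0.10), function(rate) {
    mean(replicate(40, {
      r <- decode_hard(corrupt(s, rate), p, 3, guess_limit = 1e5)
      if (!r$success) 1 else mean(r$bytes != truth)
    }))
  }, 0)
  expect_true(all(diff(ber) > 0))
})

test_that("best-first search is optimal against exhaustive enumeration", {
  ## tiny instances: compare the returned penalty with the minimum edit
  ## distance between the observation and any codeword (adist oracle)
  set.seed(9)
  p <- tiny_params("1/2", H = 2)
  nbits <- 8L  # 1 index byte + 1 crc + 0 payload would be 16; use raw bits
  all_codewords <- vapply(0:255, function(v) {
    bits <- as.integer(intToBits(v))[8:1]
    trellisdna:::int_to_seq(trellisdna:::encode_cpp(bits, p), p$alphabet)
  }, "")
  for (trial in 1:10) {
    base <- sample(all_codewords, 1)
    ## inject up to 3 random edits
    obs <- base
    for (e in seq_len(sample(0:3, 1))) {
      pos <- sample(nchar(obs), 1)
      op <- sample(c("sub", "del", "ins"), 1)
      obs <- switch(op,
        sub = paste0(substr(obs, 1, pos - 1),
                     sample(c("A", "C", "G", "T"), 1),
                     substr(obs, pos + 1, nchar(obs))),
        del = paste0(substr(obs, 1, pos - 1),
                     substr(obs, pos + 1, nchar(obs))),
        ins = paste0(substr(obs, 1, pos),
                     sample(c("A", "C", "G", "T"), 1),
                     substr(obs, pos + 1, nchar(obs))))
    }
    oracle <- min(adist(obs, all_codewords))
    out <- trellisdna:::decode_hard_cpp(
      trellisdna:::seq_to_int(obs, p$alphabet), nbits, p, 1e7,
      c(1, 1, 1), TRUE)
    expect_true(out$success)
    expect_equal(out$score, oracle)
  }
})

test_that("success rate is non-decreasing in the guess budget", {
  set.seed(77)
  p <- code_params("1/2", history_bits = 6)
  rec <- message_record(2, as.raw(1:4), p)
  s <- encode_payload(rec, p)
  ch <- strsplit(s, "")[[1]]
  reads <- replicate(20, {
    hit <- runif(length(ch)) < 0.04
    ch2 <- ch
    ch2[hit] <- vapply(ch2[hit], function(x)
      sample(setdiff(c("A", "C", "G", "T"), x), 1), "")
    paste(ch2, collapse = "")
  })
  succ <- vapply(c(100, 2000, 50000), function(lim) {
    mean(vapply(reads, function(rd) {
      r <- decode_hard(rd, p, 4, guess_limit = lim)
      isTRUE(r$success) &&
        identical(r$bytes, trellisdna:::record_bytes(rec))
    }, TRUE))
  }, 0)
  expect_true(all(diff(succ) >= 0))
  ## guess accounting never exceeds the budget
  r <- decode_hard(reads[[1]], p, 4, guess_limit = 500)
  expect_lte(r$guesses_used, 500)
})

test_that("demultiplexing attributes clean and RC reads, rejects noise", {
  set.seed(5)
  p <- code_params("1/6", history_bits = 6)
  s3 <- encode_payload(message_record(3, as.raw(1:4), p), p)
  expect_equal(as.integer(demultiplex(s3, p)), 3L)
  rc <- demultiplex(reverse_complement(s3), p)
  expect_equal(as.integer(rc), 3L)
  expect_equal(attr(rc, "orientation"), "reverse_complement")
  rejections <- replicate(200, {
    soup <- paste(sample(c("A", "C", "G", "T"), nchar(s3), replace = TRUE),
                  collapse = "")
    is.na(demultiplex(soup, p, guess_limit = 3000, try_rc = FALSE))
  })
  expect_gte(mean(rejections), 0.97)
})
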