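test_that("collapse merges repeats then drops blanks", {
  expect_identical(collapse_path("AAA"), "A")
  expect_identical(collapse_path("A-A"), "AA")
  expect_identical(collapse_path("---"), "")
  expect_identical(collapse_path("-AA-GG-G"), "AGG")
})

test_that("simulated matrices are normalized and seeded-deterministic", {
  cfg <- sim_config()
  m1 <- simulate_ctc("ACGTAC", cfg, seed = 3)
  m2 <- simulate_ctc("ACGTAC", cfg, seed = 3)
  expect_identical(unclass(m1), unclass(m2))
  rows <- apply(unclass(m1), 1, function(r) sum(exp(r)))
  expect_true(all(abs(rows - 1) < 1e-9))
  expect_true(all(unclass(m1) <= 0))
})

test_that("noiseless simulation collapses back to the input", {
  cfg <- sim_config(profile = "noiseless")
  set.seed(10)
  for (i in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T"), 40, replace = TRUE),
               collapse = "")
    ctc <- simulate_ctc(s, cfg, seed = i)
    expect_identical(greedy_basecall(ctc), s)
  }
  ## repeats are separated by a blank-dominated row
  ctc <- simulate_ctc("AA", cfg, seed = 4)
  path <- c("-", "A", "C", "G", "T")[max.col(unclass(ctc))]
  runs <- rle(path)$values
  expect_identical(runs, c("A", "-", "A"))
})

test_that("dwell controls the expected number of time steps", {
  set.seed(11)
  s <- paste(rep(c("A", "C", "G", "T"), 50), collapse = "")
  for (dm in c(1.5, 3)) {
    Tn <- mean(replicate(20, nrow(simulate_ctc(s, sim_config(
      dwell_mean = dm, profile = "noiseless")))))
    expect_lt(abs(Tn / nchar(s) - dm), 0.5)
  }
})

test_that("forward probability matches exhaustive path enumeration", {
  set.seed(21)
  ab <- c("A", "C")
  for (trial in 1:20) {
    Tn <- sample(3:5, 1)
    ctc <- random_ctc(Tn, ab)
    probs <- brute_message_probs(unclass(ctc), ab)
    msgs <- c("A", "C", "AA", "AC", "CA", "CC", "AAA", "ACA", "CCA")
    for (msg in msgs) {
      oracle <- brute_forward(msg, unclass(ctc), ab)
      got <- forward_probability(msg, ctc)
      if (oracle == -Inf) expect_equal(got, -Inf)
      else expect_lt(abs(got - oracle), 1e-9)
    }
    ## empty message: all-blank paths
    expect_lt(abs(forward_probability("", ctc) -
                    sum(unclass(ctc)[, 1])), 1e-9)
    ## partition of path space: sum over all collapsed messages = 1
    expect_lt(abs(sum(exp(probs)) - 1), 1e-9)
  }
})

test_that("impossible messages have probability zero", {
  ctc <- random_ctc(3, c("A", "C"))
  expect_identical(forward_probability("ACAC", ctc), -Inf)  # longer than T
  expect_identical(forward_probability("AAA", ctc), -Inf)   # needs blanks
})

test_that("forward probability of the truth degrades with miscall noise", {
  s <- paste(sample(c("A", "C", "G", "T"), 15, replace = TRUE),
             collapse = "")
  mean_fwd <- vapply(c(0, 0.1, 0.25), function(mc) {
    mean(vapply(1:50, function(i) {
      ctc <- simulate_ctc(s, sim_config(miscall_rate = mc, skip_rate = 0,
                                        stutter_rate = 0), seed = i)
      forward_probability(s, ctc)
    }, 0))
  }, 0)
  expect_true(all(diff(mean_fwd) < 0))
})

test_that("CTC matrices survive a TSV round trip", {
  ctc <- simulate_ctc("ACGGT", sim_config(), seed = 2)
  path <- tempfile(fileext = ".tsv")
  write_ctc(ctc, path)
  back <- read_ctc(path)
  expect_equal(unclass(back), unclass(ctc), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_identical(attr(back, "provenance"), "loaded")
  expect_identical(ctc_alphabet(back), ctc_alphabet(ctc))
})

test_that("trim_and_orient recovers orientation and the payload span", {
  p <- code_params("1/2", history_bits = 4)
  lay <- strand_layout()
  rec <- message_record(5, as.raw(1:8), p)
  st <- encode_strand(rec, p, lay)
  ctc <- simulate_ctc(st$sequence, sim_config(profile = "noiseless"),
                      seed = 9)
  tr <- trim_and_orient(ctc, lay, p)
  expect_identical(tr$orientation, "forward")
  r <- decode_soft_am(tr$ctc, p, 8)
  expect_identical(r$bytes, trellisdna:::record_bytes(rec))
  ## the reverse-complement counterpart flips orientation, same payload
  tr2 <- trim_and_orient(trellisdna:::.rc_matrix(ctc), lay, p)
  expect_identical(tr2$orientation, "reverse_complement")
  r2 <- decode_soft_am(tr2$ctc, p, 8)
  expect_identical(r2$bytes, trellisdna:::record_bytes(rec))
  ## trimmed span stays within 2% of the true payload time span, read off
  ## the simulator's per-base time offsets
  bs <- attr(ctc, "base_start")
  payload_t <- c(bs[st$payload_span[1] + 1L], bs[st$payload_span[2] + 1L])
  slack <- 0.02 * nrow(ctc)
  expect_lt(abs(tr$t_start - payload_t[1]), slack)
  expect_lt(abs(tr$t_end - payload_t[2]), slack)
})

test_that("an all-blank matrix is orientation-ambiguous", {
  m <- matrix(rep(log(c(1 - 4e-4, 1e-4, 1e-4, 1e-4, 1e-4)), each = 60),
              nrow = 60)
  ctc <- ctc_matrix(m - log(sum(exp(m[1, ]))), tol = 1e-6)
  expect_warning(trim_and_orient(ctc), "orientation-ambiguous")
})
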