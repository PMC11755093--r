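#' Read length filter
#'
#' Keeps reads whose length lies within a band around the expected full
#' strand length, eliminating short fragments and exceedingly long
#' chimeric reads; a per-read predicate, so the kept set is independent of
#' input order.
#'
#' @param reads character vector of read sequences
#' @param full_length expected full-strand length in bases
#' @param band relative `c(lower, upper)` multipliers (default 0.5-1.5)
#' @return list with `kept` (subset of `reads`) and `log` (data.frame of
#'   per-read dispositions)
#' @export
filter_reads <- function(reads, full_length, band = c(0.5, 1.5)) {
  len <- nchar(reads)
  keep <- len >= band[1] * full_length & len <= band[2] * full_length
  log <- data.frame(read = seq_along(reads), length = len, kept = keep)
  list(kept = reads[keep], log = log)
}

#' Experiment configuration for the end-to-end runner
#'
#' @param designs list of `list(rate=, payload_bytes=)` strand designs
#' @param noise named list of [sim_config()] noise levels
#' @param n_strands encoded strands per design
#' @param reads_per_strand simulated reads per strand
#' @param decoders subset of `c("am", "beam", "hard")`
#' @param guess_limit hard-decoder budget
#' @param history_bits,salt code parameters shared by all designs
#' @param seed master RNG seed (all randomness derives from it)
#' @return an `experiment_config`
#' @export
experiment_config <- function(designs = list(list(rate = "1/6",
                                                  payload_bytes = 16)),
                              noise = list(noiseless =
                                             sim_config(profile = "noiseless")),
                              n_strands = 2, reads_per_strand = 10,
                              decoders = c("am", "beam", "hard"),
                              guess_limit = 1e5, history_bits = 4, salt = 0,
                              seed = 1) {
  structure(list(designs = designs, noise = noise, n_strands = n_strands,
                 reads_per_strand = reads_per_strand, decoders = decoders,
                 guess_limit = guess_limit, history_bits = history_bits,
                 salt = salt, seed = seed),
            class = "experiment_config")
}

#' Run an encode / simulate / decode / evaluate experiment
#'
#' For every design and noise level: encodes random payloads, simulates
#' payload-region CTC matrices, decodes each read with the selected
#' decoders (the hard decoder consumes the greedy basecall of the same
#' matrix), and reports byte error rates, positional profiles, error-free
#' read fractions, decoder agreement and the projected outer-code density.
#' Deterministic given the seed; a failing design is isolated and reported
#' with an `error` field rather than aborting the bundle.
#'
#' @param config an [experiment_config()]
#' @return list of class `experiment_report`: `summary` data.frame,
#'   per-design `profiles`, `agreement` and the `config`
#' @export
run_experiment <- function(config = experiment_config()) {
  set.seed(config$seed)
  summaries <- list()
  profiles <- list()
  agreement <- list()
  for (d in seq_along(config$designs)) {
    des <- config$designs[[d]]
    res <- tryCatch(
      .run_design(des, config),
      error = function(e) list(error = conditionMessage(e)))
    label <- paste0(des$rate, "x", des$payload_bytes, "B")
    if (!is.null(res$error)) {
      summaries[[label]] <- data.frame(
        design = label, noise = NA_character_, decoder = NA_character_,
        n_reads = NA_integer_, p_bar = NA_real_, error_free_frac = NA_real_,
        rs_k = NA_integer_, phi = NA_real_, error = res$error)
      next
    }
    summaries[[label]] <- res$summary
    profiles[[label]] <- res$profiles
    agreement[[label]] <- res$agreement
  }
  structure(list(summary = do.call(rbind, c(summaries,
                                            make.row.names = FALSE)),
                 profiles = profiles, agreement = agreement,
                 config = config),
            class = "experiment_report")
}

.run_design <- function(des, config) {
  params <- code_params(des$rate, history_bits = config$history_bits,
                        salt = config$salt)
  strands <- lapply(seq_len(config$n_strands) - 1L, function(i) {
    payload <- as.raw(sample(0:255, des$payload_bytes, replace = TRUE))
    rec <- message_record(i, payload, params)
    list(record = rec, truth = record_bytes(rec),
         payload_seq = encode_payload(rec, params))
  })
  summary_rows <- list()
  profs <- list()
  agree <- list()
  for (nz in names(config$noise)) {
    cfg <- config$noise[[nz]]
    reads <- list()
    for (r in seq_len(config$n_strands * config$reads_per_strand)) {
      s <- strands[[(r - 1L) %% config$n_strands + 1L]]
      ctc <- simulate_ctc(s$payload_seq, cfg, seed = NULL)
      reads[[r]] <- list(ctc = ctc, truth = s$truth)
    }
    decoded <- list()
    for (dec in config$decoders) {
      decoded[[dec]] <- lapply(reads, function(rd) {
        switch(dec,
          am = decode_soft_am(rd$ctc, params, des$payload_bytes),
          beam = decode_soft_beam(rd$ctc, params, des$payload_bytes),
          hard = decode_hard(greedy_basecall(rd$ctc), params,
                             des$payload_bytes,
                             guess_limit = config$guess_limit))
      })
      prof <- per_byte_error_profile(decoded[[dec]],
                                     lapply(reads, `[[`, "truth"))
      p_bar <- attr(prof, "p_bar")
      ef <- mean(vapply(seq_along(reads), function(i) {
        isTRUE(decoded[[dec]][[i]]$success) &&
          identical(decoded[[dec]][[i]]$bytes, reads[[i]]$truth)
      }, TRUE))
      rs_k <- choose_design(p_bar)
      summary_rows[[paste(nz, dec)]] <- data.frame(
        design = paste0(des$rate, "x", des$payload_bytes, "B"),
        noise = nz, decoder = dec, n_reads = length(reads), p_bar = p_bar,
        error_free_frac = ef, rs_k = rs_k,
        phi = density_phi(params, strand_layout(), des$payload_bytes, rs_k),
        error = NA_character_)
      profs[[paste(nz, dec)]] <- prof
    }
    if (all(c("am", "beam") %in% names(decoded))) {
      agree[[nz]] <- mean(vapply(seq_along(reads), function(i) {
        identical(decoded$am[[i]]$bytes, decoded$beam[[i]]$bytes)
      }, TRUE))
    }
  }
  list(summary = do.call(rbind, c(summary_rows, make.row.names = FALSE)),
       profiles = profs, agreement = agree)
}

#' Write an experiment report to TSV + JSON
#'
#' Byte-identical across runs with the same config (full reproducibility).
#'
#' @param report an `experiment_report`
#' @param dir output directory (created if missing)
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(report$summary, file.path(dir, "summary.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  for (label in names(report$profiles)) {
    for (key in names(report$profiles[[label]])) {
      fn <- file.path(dir, paste0("profile_", gsub("[^A-Za-z0-9]", "_",
                                                   paste(label, key)),
                                  ".tsv"))
      write.table(report$profiles[[label]][[key]], fn, sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
  }
  jsonlite::write_json(list(seed = report$config$seed,
                            agreement = report$agreement),
                       file.path(dir, "summary.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
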