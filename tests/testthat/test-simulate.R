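tpl_g <- default_template("G")

test_that("degenerate mixtures produce exactly the expected transcripts", {
  cfg <- generator_config()  # all mass on +1 start, no extra G, run-off
  sim <- simulate_transcripts(tpl_g, cfg, depth = 50, seed = 1)
  expect_true(all(sim$transcript == tpl_g$transcript))
  expect_true(all(sim$end_mode == "runoff"))
  expect_true(all(sim$end_offset == 0L))

  cfg_c <- generator_config(end_modes = list(
    end_nta(1, tail_len_probs = c(`1` = 1), base_probs = c(C = 1))
  ))
  sim_c <- simulate_transcripts(tpl_g, cfg_c, depth = 50, seed = 1)
  expect_true(all(sim_c$transcript == paste0(tpl_g$transcript, "C")))
  expect_true(all(sim_c$extension == "C"))

  cfg_p <- generator_config(end_modes = list(
    end_premature(1, stop_probs = c(`-10` = 1))
  ))
  sim_p <- simulate_transcripts(tpl_g, cfg_p, depth = 50, seed = 1)
  segs <- extract_three_prime(simulate_reads(tpl_g, cfg_p, depth = 50, seed = 1))
  expect_true(all(segs$size == 40L))
})

test_that("self-templated reads append the fold-back extension after the stop", {
  cfg <- generator_config(end_modes = list(
    end_self_templated(1, stop_offset = -10L, cap_probs = c(`12` = 1))
  ))
  sim <- simulate_transcripts(tpl_g, cfg, depth = 20, seed = 2)
  tr240 <- substr(tpl_g$transcript, 1, 240)
  ext12 <- substr(oracle_foldback(tr240)$extension, 1, 12)
  expect_true(all(sim$transcript == paste0(tr240, ext12)))
  expect_true(all(sim$end_mode == "self_templated"))
  expect_true(all(sim$end_offset == 2L))   # -10 stop + 12-nt extension
})

test_that("same seed gives byte-identical FASTQ output", {
  cfg <- preset("T7")
  f1 <- withr::local_tempfile(fileext = ".fastq")
  f2 <- withr::local_tempfile(fileext = ".fastq")
  t1 <- withr::local_tempfile(fileext = ".tsv")
  ligate_and_emit(simulate_transcripts(tpl_g, cfg, depth = 500, seed = 99),
                  f1, t1)
  ligate_and_emit(simulate_transcripts(tpl_g, cfg, depth = 500, seed = 99), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  truth <- readr::read_tsv(t1, show_col_types = FALSE)
  expect_equal(nrow(truth), 500L)
  expect_true(all(c("read_id", "start_offset", "n_extra_5g", "end_mode",
                    "end_offset", "extension") %in% names(truth)))
})

test_that("emitted reads are adaptor-flanked transcripts", {
  cfg <- generator_config()
  reads <- simulate_reads(tpl_g, cfg, depth = 3, seed = 5)
  expect_true(all(reads$seq ==
    paste0("CCAGGCTTATGGCAGTCACA", tpl_g$transcript, "CACGAGCGTTTTCCCACCTA")))
  empty <- simulate_transcripts(tpl_g, cfg, depth = 1, seed = 1)[0, ]
  fq <- withr::local_tempfile(fileext = ".fastq")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  ligate_and_emit(empty, fq, tsv)
  expect_equal(nrow(read_fastq(fq)), 0L)
  expect_equal(nrow(readr::read_tsv(tsv, show_col_types = FALSE)), 0L)
})

test_that("empirical mixture frequencies converge to the configured probabilities", {
  cfg <- preset("CD23823")
  tpl_a <- default_template(cfg$plus_one)
  sim <- simulate_transcripts(tpl_a, cfg, depth = 2e4, seed = 7)
  ok <- !is.na(sim$start_offset)
  # start offsets (conditioned on non-degraded reads)
  for (o in names(cfg$start_offset_probs)) {
    p <- cfg$start_offset_probs[[o]]
    emp <- mean(sim$start_offset[ok] == as.integer(o))
    expect_lt(abs(emp - p), binom_band(p, sum(ok), 4))
  }
  # end modes (self_templated + premature share the truncation machinery)
  p_run <- cfg$end_modes[[1]]$prob
  emp_run <- mean(sim$end_mode[ok] == "runoff")
  expect_lt(abs(emp_run - p_run), binom_band(p_run, sum(ok), 4))
  # degradation
  expect_lt(abs(mean(!ok) - cfg$degradation_prob),
            binom_band(cfg$degradation_prob, nrow(sim), 4))
})

test_that("degraded reads are strictly internal fragments of at least 20 nt", {
  cfg <- generator_config(degradation_prob = 1)
  sim <- simulate_transcripts(tpl_g, cfg, depth = 300, seed = 8)
  expect_true(all(sim$end_mode == "degraded"))
  expect_true(all(nchar(sim$transcript) >= 20L))
  expect_true(all(nchar(sim$transcript) < nchar(tpl_g$transcript)))
  # never the intact 5' or 3' terminus
  expect_false(any(startsWith(tpl_g$transcript, sim$transcript)))
  pos <- vapply(sim$transcript, function(s) find_first(tpl_g$transcript, s),
                integer(1))
  expect_true(all(pos >= 1L))
  expect_true(all(pos + nchar(sim$transcript) <= nchar(tpl_g$transcript) - 1L))
  expect_true(all(sim$end_offset <= -1L))
})

test_that("substitution errors are applied at the configured rate", {
  cfg <- generator_config(seq_error_rate = 0.01)
  sim <- simulate_transcripts(tpl_g, cfg, depth = 400, seed = 9)
  nm <- vapply(sim$transcript, function(s) {
    sum(strsplit(s, "")[[1]] != strsplit(tpl_g$transcript, "")[[1]])
  }, numeric(1))
  emp <- sum(nm) / (400 * nchar(tpl_g$transcript))
  expect_lt(abs(emp - 0.01), binom_band(0.01, 400 * 250, 4))
})

test_that("generator configs validate their probability maps", {
  expect_error(generator_config(start_offset_probs = c(`0` = 0.5)), "sum to 1")
  expect_error(generator_config(end_modes = list(end_runoff(0.5))), "sum to 1")
  expect_error(
    generator_config(end_modes = list(
      end_runoff(0.5),
      end_nta(0.5, tail_len_probs = c(`1` = 0.7))
    )),
    "sum to 1"
  )
  expect_error(preset("SP6"))
})
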