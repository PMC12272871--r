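tpl <- default_template("G")
tsuf <- template_suffix(tpl)

test_that("extract_three_prime returns the bases between tag and adaptor", {
  mk <- function(mid) paste0("AAAA", tpl$tag, mid, "CACGAGCGTTTT", "GGGG")
  out <- extract_three_prime(mk(tsuf))
  expect_equal(out$segment, tsuf)
  expect_equal(out$size, 50L)
  out0 <- extract_three_prime(mk(""))
  expect_equal(out0$segment, "")
  expect_equal(out0$size, 0L)
  # tag but no adaptor: skipped
  noad <- paste0("AAAA", tpl$tag, "CCCCC")
  expect_equal(nrow(extract_three_prime(noad)), 0L)
  # multiple tag occurrences: first used, flagged
  multi <- paste0(tpl$tag, "AA", tpl$tag, "CC", "CACGAGCGTTTT")
  outm <- extract_three_prime(multi)
  expect_true(outm$multi_tag)
  expect_equal(outm$segment, paste0("AA", tpl$tag, "CC"))
})

test_that("size_distribution normalizes exactly and exposes the mode", {
  d <- size_distribution(c(50L, 50L, 50L, 40L))
  expect_equal(d$frequency[d$size == 50], 0.75)
  expect_equal(sum(d$frequency), 1, tolerance = 1e-12)
  expect_equal(modal_size(d), 50L)
  expect_equal(size_frequency(d, 41L), 0)
  expect_error(size_distribution(integer()), "no 3'")
})

test_that("top_sequences_at_size is restricted and renormalized per size", {
  rec <- tibble::tibble(
    read_id = sprintf("r%d", 1:5),
    segment = c(rep("AAA", 3), "CCC", "GGGG"),
    size = c(3L, 3L, 3L, 3L, 4L)
  )
  top <- top_sequences_at_size(rec, 3L)
  expect_equal(top$frequency, c(0.75, 0.25))
  expect_equal(nrow(top_sequences_at_size(rec, 10L)), 0L)
})

test_that("classify_three_prime distinguishes the five terminus categories", {
  expect_equal(classify_three_prime(tsuf, tpl)$category, "correct_runoff")
  tr <- classify_three_prime(substr(tsuf, 1, 40), tpl)
  expect_equal(tr$category, "templated_truncation")
  expect_equal(tr$trunc_offset, -10L)
  nta <- classify_three_prime(paste0(tsuf, "A"), tpl)
  expect_equal(nta$category, "nontemplated_addition")
  expect_equal(nta$ext, "A")
  ext12 <- substr(oracle_foldback(substr(tpl$transcript, 1, 240))$extension, 1, 12)
  st <- classify_three_prime(paste0(substr(tsuf, 1, 40), ext12), tpl)
  expect_equal(st$category, "self_templated")
  expect_equal(st$ext, ext12)
  expect_equal(classify_three_prime(strrep("T", 50), tpl)$category, "unrelated")
  # internal mismatch with a non-foldback continuation stays unrelated
  bad <- paste0(substr(tsuf, 1, 30), "TTTTTTTT")
  expect_equal(classify_three_prime(bad, tpl)$category, "unrelated")
})

test_that("classification recovers generator end modes on error-free reads", {
  cfg <- preset("Ro45Iw")
  cfg$degradation_prob <- 0
  reads <- simulate_reads(tpl, cfg, depth = 4000, seed = 27)
  rec <- extract_three_prime(reads)
  truth <- reads[match(rec$read_id, reads$read_id), ]
  cls <- classify_three_prime(rec, tpl)
  map <- c(runoff = "correct_runoff", premature_stop = "templated_truncation",
           nta = "nontemplated_addition", self_templated = "self_templated")
  expect_equal(mean(cls$category == map[truth$end_mode]), 1)
  st <- cls$category == "self_templated"
  expect_equal(cls$ext[st], truth$extension[st])
})

test_that("the fidelity product equals the direct joint fraction on any record set", {
  mk_records <- function(n, seed) {
    cfg <- preset(sample(c("T7", "KpnP", "Ro45Iw", "CD23823"), 1))
    extract_three_prime(simulate_reads(tpl, cfg, depth = n, seed = seed))
  }
  withr::with_seed(41, {
    for (i in 1:5) {
      rec <- mk_records(2000, seed = i)
      dist <- size_distribution(rec)
      at <- rec$segment[rec$size == 50L]
      ratio <- if (length(at) == 0) 0 else mean(at == tsuf)
      expect_equal(runoff_fidelity(dist, ratio, 50L),
                   direct_runoff_fraction(rec, tpl),
                   tolerance = 1e-14)
    }
  })
  # hand-built boundary cases
  rec1 <- tibble::tibble(read_id = "a", segment = tsuf, size = 50L)
  expect_equal(direct_runoff_fraction(rec1, tpl), 1)
  rec0 <- tibble::tibble(read_id = "a", segment = substr(tsuf, 1, 10), size = 10L)
  expect_equal(direct_runoff_fraction(rec0, tpl), 0)
})

test_that("adding a correct run-off read never decreases the fidelity", {
  cfg <- preset("KpnP")
  rec <- extract_three_prime(simulate_reads(tpl, cfg, depth = 500, seed = 5))
  fid0 <- direct_runoff_fraction(rec, tpl)
  rec2 <- dplyr::bind_rows(rec, tibble::tibble(read_id = "extra",
                                               segment = tsuf, size = 50L,
                                               multi_tag = FALSE))
  expect_gte(direct_runoff_fraction(rec2, tpl), fid0)
})

test_that("fidelity_report bundles the statistics coherently", {
  cfg <- preset("CD23823")
  tpl_a <- default_template("A")
  rec <- extract_three_prime(simulate_reads(tpl_a, cfg, depth = 3000, seed = 6))
  rep <- fidelity_report(rec, tpl_a, enzyme = "CD23823")
  expect_s3_class(rep, "fidelity_report")
  expect_equal(rep$runoff_fidelity,
               rep$freq_at_expected_size * rep$correct_ratio_at_expected_size)
  g <- glance(rep)
  expect_equal(g$enzyme, "CD23823")
  expect_true(all(c("modal_size", "runoff_fidelity") %in% names(g)))
  td <- tidy(rep)
  expect_equal(sum(td$frequency), 1, tolerance = 1e-12)
})
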