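test_that("scan_genome counts overlapping occurrences on both strands", {
  motif <- "AAAATTTT"
  genome <- paste0("CC", motif, "GG", motif, "CC")
  hits <- scan_genome(motif, genome)
  # the motif is its own reverse complement: each site hits on both strands
  expect_equal(sum(hits$strand == "+"), 2L)
  expect_equal(sum(hits$strand == "-"), 2L)
  expect_equal(sort(unique(hits$position)), c(2L, 12L))
  expect_equal(nrow(scan_genome("GGGGGGGG", genome)), 0L)
  # overlapping self-similar motif
  ov <- scan_genome("AAAAAAAA", strrep("A", 10), both_strands = FALSE)
  expect_equal(ov$position, 0:2)
  expect_error(scan_genome("AAAA", genome), "at least 8")
})

test_that("select_candidates applies the multi-hit upstream-of-ORF rule", {
  # background over {A,C} and motifs over {A,C,G} whose reverse complements
  # all contain T: planted occurrences are the only ones possible
  withr::with_seed(51, {
    bg <- paste(sample(c("A", "C"), 400, replace = TRUE), collapse = "")
  })
  m1 <- "GAGAGAGAGG"   # 3 hits, 2 upstream of ORFs
  m2 <- "GGAACCGGAA"   # 3 hits, 1 upstream
  m3 <- "GGCCAAGGCC"   # 1 hit only
  genome <- paste0(
    substr(bg, 1, 50), m1,            # hit at 50, ORF at 70
    substr(bg, 61, 150), m1,          # hit at 150, ORF at 180
    substr(bg, 161, 250), m1,         # hit at 250, no ORF nearby
    substr(bg, 261, 300), m2,         # hits at 300, 310, 320; ORF at 350 is
    m2, m2,                           # within 25 nt of the last hit only
    substr(bg, 331, 360), m3          # single hit at 360
  )
  orfs <- tibble::tibble(pos = c(70L, 180L, 350L), strand = "+")
  sel <- select_candidates(c(m3, m2, m1), genome, orfs,
                           min_hits = 2L, upstream_window = 25L)
  expect_equal(sel$seq, c(m1, m2))
  expect_equal(sel$n_hits, c(3L, 3L))
  expect_equal(sel$n_upstream, c(2L, 1L))
  # thresholds: every kept candidate satisfies both predicates
  expect_true(all(sel$n_hits >= 2L & sel$n_upstream >= 1L))
  # order invariance
  sel2 <- select_candidates(c(m1, m3, m2), genome, orfs,
                            min_hits = 2L, upstream_window = 25L)
  expect_equal(sel, sel2)
  expect_equal(nrow(select_candidates(character(), genome, orfs)), 0L)
})

test_that("select_candidates matches brute-force evaluation on a planted toy genome", {
  brute <- function(cands, genome, orfs, min_hits, win) {
    res <- list()
    for (cand in sort(unique(cands))) {
      hits <- data.frame(position = integer(), strand = character())
      for (str in c("+", "-")) {
        pat <- if (str == "+") cand else {
          paste(rev(chartr("ACGT", "TGCA", strsplit(cand, "")[[1]])), collapse = "")
        }
        for (i in seq_len(nchar(genome) - nchar(pat) + 1L)) {
          if (substr(genome, i, i + nchar(pat) - 1L) == pat) {
            hits <- rbind(hits, data.frame(position = i - 1L, strand = str))
          }
        }
      }
      nup <- 0L
      for (r in seq_len(nrow(hits))) {
        h <- hits[r, ]
        up <- FALSE
        for (o in seq_len(nrow(orfs))) {
          if (orfs$strand[o] != h$strand) next
          gap <- if (h$strand == "+") orfs$pos[o] - (h$position + nchar(cand))
                 else h$position - orfs$pos[o] - 1L
          if (gap >= 0L && gap <= win) up <- TRUE
        }
        nup <- nup + up
      }
      if (nrow(hits) >= min_hits && nup >= 1L) {
        res[[length(res) + 1L]] <- data.frame(seq = cand, n_hits = nrow(hits),
                                              n_upstream = nup)
      }
    }
    if (length(res) == 0L) return(NULL)
    out <- do.call(rbind, res)
    out[order(-out$n_upstream, -out$n_hits, out$seq), , drop = FALSE]
  }
  withr::with_seed(52, {
    for (rep in 1:5) {
      genome <- random_dna(300)
      cands <- vapply(1:6, function(i) {
        # half planted from the genome, half random
        if (i %% 2 == 0) substr(genome, 10 * i, 10 * i + 8) else random_dna(9)
      }, "")
      orfs <- tibble::tibble(
        pos = sort(sample(0:299, 4)),
        strand = sample(c("+", "-"), 4, replace = TRUE)
      )
      got <- select_candidates(cands, genome, orfs, min_hits = 1L,
                               upstream_window = 60L)
      want <- brute(cands, genome, orfs, 1L, 60L)
      if (is.null(want)) {
        expect_equal(nrow(got), 0L)
      } else {
        expect_equal(got$seq, want$seq)
        expect_equal(got$n_hits, want$n_hits)
        expect_equal(got$n_upstream, want$n_upstream)
      }
    }
  })
})
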