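# Independent brute-force oracles used to cross-check the implementation.
# These deliberately share no code with the package: plain loops and base R.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

oracle_revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

oracle_find_first <- function(hay, ndl) {
  nh <- nchar(hay)
  nn <- nchar(ndl)
  if (nn > nh) return(NA_integer_)
  for (i in seq_len(nh - nn + 1L)) {
    if (substr(hay, i, i + nn - 1L) == ndl) return(i - 1L)
  }
  NA_integer_
}

# Enumerate every (suffix length, window position) duplex and apply the
# stated selection rule: longest suffix wins, ties broken to the 3'-most
# window. Returns NULL or list(duplex_len, anneal_start0, extension).
oracle_foldback <- function(t, min_duplex = 3L) {
  rc <- function(x) paste(rev(chartr("ACGT", "TGCA", strsplit(x, "")[[1]])),
                          collapse = "")
  n <- nchar(t)
  best <- NULL
  if (n < 2L * min_duplex) return(NULL)
  for (l in min_duplex:floor(n / 2)) {
    target <- rc(substr(t, n - l + 1L, n))
    for (a in seq_len(n - 2L * l + 1L)) {  # window [a, a+l-1] ends <= n - l
      if (substr(t, a, a + l - 1L) == target) {
        if (is.null(best) || l > best$duplex_len ||
            (l == best$duplex_len && a > best$anneal_start0 + 1L)) {
          best <- list(duplex_len = l, anneal_start0 = a - 1L,
                       extension = rc(substr(t, 1L, a - 1L)))
        }
      }
    }
  }
  best
}

# Enumerate all stem placements (arm1 start i, stem s, loop l) with exact
# reverse-complement arms and loop in bounds, then keep the maximal ones:
# extending outward (i-1, s+1, l) or inward (i, s+1, l-2) must be impossible
# (out of bounds, loop too small, or arms no longer reverse complements).
oracle_hairpins <- function(seq, min_stem = 4L, loop_min = 3L, loop_max = 8L) {
  rc <- function(x) paste(rev(chartr("ACGT", "TGCA", strsplit(x, "")[[1]])),
                          collapse = "")
  n <- nchar(seq)
  is_stem <- function(i, s, l) {
    j <- i + s + l
    if (i < 1L || s < 1L || j + s - 1L > n) return(FALSE)
    substr(seq, j, j + s - 1L) == rc(substr(seq, i, i + s - 1L))
  }
  out <- list()
  for (i in seq_len(n)) {
    for (s in seq_len(floor((n - i + 1L) / 2L))) {
      for (l in loop_min:loop_max) {
        if (!is_stem(i, s, l)) next
        if (s < min_stem) next
        if (is_stem(i - 1L, s + 1L, l)) next              # outward extension
        if (l - 2L >= loop_min && is_stem(i, s + 1L, l - 2L)) next  # inward
        out[[length(out) + 1L]] <- data.frame(
          stem5_start = i - 1L, stem_len = s, loop_len = l,
          terminus_offset = (i + s + l + s - 1L) - n
        )
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(stem5_start = integer(), stem_len = integer(),
                      loop_len = integer(), terminus_offset = integer()))
  }
  res <- do.call(rbind, out)
  res[order(-res$stem_len, res$stem5_start), , drop = FALSE]
}

binom_band <- function(p, n, k = 3) k * sqrt(p * (1 - p) / n)
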