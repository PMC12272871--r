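#' Find hairpins by exact reverse-complement stem search
#'
#' Enumerates all maximal stem-loop placements in which the two stem arms are
#' exact Watson-Crick reverse complements (no G-T wobble) separated by a loop
#' of bounded length. A stem is maximal when it can be extended neither
#' outward (flanking bases do not pair or the sequence ends) nor inward
#' (pairing the innermost flanking bases would shrink the loop below
#' `loop_min`, or they do not pair). This exact-stem detector deliberately
#' replaces free-energy folding: the mechanism modeled here only needs the
#' existence and register of a duplex, not its energy.
#'
#' @param seq DNA string.
#' @param min_stem Minimum stem length (bp). Default 4.
#' @param loop_min,loop_max Loop length bounds (nt). Defaults 3 and 8.
#' @return Tibble with columns `stem5_start` (0-based start of the 5' arm),
#'   `stem_len`, `loop_len`, `terminus_offset` (signed offset of the stem's
#'   3'-most base relative to the sequence 3' terminus, e.g. -10 means the
#'   stem ends 10 nt before the terminus), sorted by `stem_len` descending
#'   then position. Zero rows when no hairpin exists.
#' @examples
#' find_hairpins("GGGGAAATCCCC")
#' @export
find_hairpins <- function(seq, min_stem = 4L, loop_min = 3L, loop_max = 8L) {
  check_dna(seq)
  n <- nchar(seq)
  empty <- tibble(stem5_start = integer(), stem_len = integer(),
                  loop_len = integer(), terminus_offset = integer())
  if (n < 2L * min_stem + loop_min) return(empty)
  s <- strsplit(seq, "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  pairs_ok <- function(i, j) i >= 1L && j <= n && comp[[s[i]]] == s[j]
  out <- list()
  # Innermost closing pair (a, b): extend outward maximally, then test
  # stem length and inward maximality.
  for (a in seq_len(n - 1L)) {
    for (l in loop_min:loop_max) {
      b <- a + l + 1L
      if (b > n) break
      if (!pairs_ok(a, b)) next
      # inward maximality: a longer stem with loop l - 2 would absorb this one
      if (l - 2L >= loop_min && pairs_ok(a + 1L, b - 1L)) next
      st <- 1L
      while (pairs_ok(a - st, b + st)) st <- st + 1L
      if (st < min_stem) next
      out[[length(out) + 1L]] <- c(
        stem5_start = (a - st + 1L) - 1L,  # 0-based
        stem_len = st,
        loop_len = l,
        terminus_offset = (b + st - 1L) - n
      )
    }
  }
  if (length(out) == 0L) return(empty)
  res <- as_tibble(as.data.frame(do.call(rbind, out)))
  arrange(res, desc(.data$stem_len), .data$stem5_start)
}

#' Predict fold-back self-templated extension
#'
#' Models self-templating polymerization: the transcript's 3' end anneals
#' intramolecularly to an upstream window and the polymerase restarts,
#' copying the transcript itself. The predicted extension is the reverse
#' complement of the bases 5' of the annealing window, appended in synthesis
#' order (template-proximal bases first) and optionally capped.
#'
#' The annealing site is the longest 3' suffix (>= `min_duplex` nt) that is
#' the exact reverse complement of an internal window ending strictly before
#' the suffix; ties between windows are broken toward the 3'-most window
#' (physical proximity of the fold-back loop).
#'
#' @param transcript DNA string (the possibly truncated transcript).
#' @param min_duplex Minimum suffix/window duplex length. Default 3.
#' @param max_extension Cap on extension length (`NULL` = extend to the 5'
#'   end of the template region); the cap keeps the synthesis-proximal part.
#' @return One-row tibble with `anneal_start` (0-based window start),
#'   `duplex_len`, `extension`, `capped`; or `NULL` when no duplex of at
#'   least `min_duplex` exists.
#' @examples
#' fold_back_extend("AAAACCCGGG")  # extension "TTTT"
#' @export
fold_back_extend <- function(transcript, min_duplex = 3L, max_extension = NULL) {
  check_dna(transcript)
  n <- nchar(transcript)
  if (n < 2L * min_duplex) return(NULL)
  best_len <- NA_integer_
  best_pos <- NA_integer_
  l <- min_duplex
  # If no internal window matches the length-l suffix, no longer suffix can
  # match either (its reverse complement contains the shorter one's as a
  # prefix, in a smaller search space), so scan upward and stop at failure.
  while (l <= n - l) {
    suffix <- substr(transcript, n - l + 1L, n)
    space <- substr(transcript, 1L, n - l)
    hit <- stringi::stri_locate_last_fixed(space, revcomp(suffix))[, 1L]
    if (is.na(hit)) break
    best_len <- l
    best_pos <- as.integer(hit)  # 1-based, last (3'-most) occurrence
    l <- l + 1L
  }
  if (is.na(best_len)) return(NULL)
  ext <- revcomp(substr(transcript, 1L, best_pos - 1L))
  capped <- FALSE
  if (!is.null(max_extension) && nchar(ext) > max_extension) {
    ext <- substr(ext, 1L, max_extension)
    capped <- TRUE
  }
  tibble(
    anneal_start = best_pos - 1L,
    duplex_len = best_len,
    extension = ext,
    capped = capped
  )
}

#' Test whether an observed 3' extension is explained by fold-back
#'
#' Inverse of [fold_back_extend()]: `TRUE` when the observed non-templated
#' extension is a prefix of the extension predicted from the truncated
#' transcript, with a configurable minimum matched length that guards
#' against chance matches of very short tails.
#'
#' @param observed_ext Non-empty observed extension.
#' @param truncated_transcript Transcript up to the point where templated
#'   synthesis stopped.
#' @param min_duplex Passed to [fold_back_extend()].
#' @param min_match Minimum extension length for a call. Default 3.
#' @return Logical scalar.
#' @export
match_self_templated <- function(observed_ext, truncated_transcript,
                                 min_duplex = 3L, min_match = 3L) {
  stopifnot(nchar(observed_ext) > 0L)
  if (nchar(observed_ext) < min_match) return(FALSE)
  fb <- fold_back_extend(truncated_transcript, min_duplex = min_duplex)
  if (is.null(fb)) return(FALSE)
  startsWith(fb$extension, observed_ext)
}
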