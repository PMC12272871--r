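# 5'-terminal analysis: anchored extraction of the 20-nt window after the
# 5' adaptor, frequency tabulation, +1-site estimation and classification.

as_reads_tbl <- function(reads) {
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    reads <- read_fastq(reads)
  }
  if (is.character(reads)) {
    reads <- tibble(read_id = sprintf("read_%07d", seq_along(reads)), seq = reads)
  }
  stopifnot(is.data.frame(reads), all(c("read_id", "seq") %in% names(reads)))
  reads
}

#' Extract 5'-terminal windows
#'
#' Collects reads containing the 5' adaptor anchor (leftmost exact
#' occurrence) followed by at least `window` bases, and returns those
#' `window` bases: the 5'-terminal region of the transcript. Reads lacking
#' the anchor, or with fewer than `window` bases after it, are skipped and
#' counted.
#'
#' @param reads Tibble with `read_id` and `seq`, a character vector of read
#'   sequences, or a FASTQ path.
#' @param anchor Anchor subsequence of the 5' adaptor. Default
#'   `"ATGGCAGTCACA"`.
#' @param window Window length (nt). Default 20.
#' @return Tibble with `read_id`, `window`; attributes `n_in`,
#'   `n_extracted`, `n_skipped`.
#' @export
extract_five_prime <- function(reads, anchor = ANCHOR_5P, window = 20L) {
  stopifnot(nchar(anchor) > 0L)
  reads <- as_reads_tbl(reads)
  pos_end <- stringi::stri_locate_first_fixed(reads$seq, anchor)[, 2L]
  win <- stringr::str_sub(reads$seq, pos_end + 1L, pos_end + window)
  keep <- !is.na(pos_end) & nchar(win) == window
  out <- tibble(read_id = reads$read_id[keep], window = win[keep])
  attr(out, "n_in") <- nrow(reads)
  attr(out, "n_extracted") <- nrow(out)
  attr(out, "n_skipped") <- nrow(reads) - nrow(out)
  out
}

new_freq_table <- function(seqs, n_analyzed) {
  tab <- tibble(sequence = seqs) |>
    count(.data$sequence, name = "count") |>
    arrange(desc(.data$count), .data$sequence) |>
    mutate(frequency = .data$count / n_analyzed)
  attr(tab, "n_analyzed") <- n_analyzed
  class(tab) <- c("freq_table", class(tab))
  tab
}

#' Frequency table of 5'-terminal windows
#'
#' Exact-sequence counts of the extracted windows, normalized to the total
#' number of analyzed reads. Rows are sorted by count descending, ties
#' broken lexicographically, so top-N views are deterministic.
#'
#' @param records Output of [extract_five_prime()] (or a character vector of
#'   windows).
#' @return A `freq_table` tibble with `sequence`, `count`, `frequency` and
#'   attribute `n_analyzed`.
#' @export
five_prime_table <- function(records) {
  seqs <- if (is.data.frame(records)) records$window else records
  if (length(seqs) == 0L) abort("no 5' records to tabulate")
  new_freq_table(seqs, length(seqs))
}

#' Classify 5'-terminal windows against the template
#'
#' Assigns each window exactly one category, in precedence order:
#' 1. `starts_at_plus1`: the window equals the transcript's first bases.
#' 2. `shifted_start`: the window matches the template sense strand at a
#'    start offset `o` with `0 < |o| <= search_span`.
#' 3. `nontemplated_5prime`: stripping 1..`search_span` identical leading
#'    bases (a homopolymer run, e.g. extra Gs) leaves a match at +1.
#' 4. `unrelated`: anything else (degradation products, nonstandard starts).
#'
#' @param windows Character vector of windows (all the same length) or the
#'   output of [extract_five_prime()].
#' @param template A `template_spec`.
#' @param search_span Bound on start offsets and stripped leading bases.
#'   Default 10.
#' @return Tibble with `window`, `category`, `offset` (shifted starts),
#'   `n_extra` and `base` (non-templated leading bases), one row per input
#'   window.
#' @export
classify_five_prime <- function(windows, template, search_span = 10L) {
  if (is.data.frame(windows)) windows <- windows$window
  wlen <- unique(nchar(windows))
  if (length(wlen) != 1L) abort("all windows must have the same length")
  sense <- template$sense
  p1 <- template$plus_one_index
  tx <- template$transcript

  u <- unique(windows)
  cat_u <- rep("unrelated", length(u))
  off_u <- rep(NA_integer_, length(u))
  nex_u <- rep(NA_integer_, length(u))
  base_u <- rep(NA_character_, length(u))

  # 1) +1 start
  plus1 <- substr(tx, 1L, wlen)
  hit <- u == plus1
  cat_u[hit] <- "starts_at_plus1"
  off_u[hit] <- 0L

  # 2) shifted starts
  for (o in setdiff(seq(-search_span, search_span), 0L)) {
    if (p1 + o < 0L) next
    target <- substr(sense, p1 + 1L + o, p1 + wlen + o)
    if (nchar(target) != wlen) next
    hit <- cat_u == "unrelated" & u == target
    cat_u[hit] <- "shifted_start"
    off_u[hit] <- o
  }

  # 3) non-templated identical leading bases before a +1 start
  todo <- cat_u == "unrelated"
  if (any(todo)) {
    lead <- stringi::stri_extract_first_regex(u, "^(.)\\1*")
    runlen <- nchar(lead)
    for (k in seq_len(search_span)) {
      cand <- todo & runlen >= k &
        stringr::str_sub(u, k + 1L) == substr(tx, 1L, wlen - k)
      cand[is.na(cand)] <- FALSE
      newhit <- cand & cat_u == "unrelated"
      cat_u[newhit] <- "nontemplated_5prime"
      nex_u[newhit] <- k
      base_u[newhit] <- substr(u[newhit], 1L, 1L)
    }
  }

  idx <- match(windows, u)
  tibble(
    window = windows,
    category = cat_u[idx],
    offset = off_u[idx],
    n_extra = nex_u[idx],
    base = base_u[idx]
  )
}

#' Estimate the +1 initiation site from a frequency table
#'
#' Takes the most frequent window (ties already resolved by the table's
#' deterministic ordering) and reports the 0-based sense-strand position it
#' implies together with its frequency. A top window that cannot be placed
#' near the template (an unrelated sequence, e.g. a degradation product) is
#' flagged and gets an `NA` position.
#'
#' @param table A `freq_table` from [five_prime_table()].
#' @param template A `template_spec`.
#' @param search_span Passed to [classify_five_prime()].
#' @return One-row tibble: `position` (0-based on the sense strand),
#'   `frequency`, `window`, `flagged`.
#' @export
plus_one_estimate <- function(table, template, search_span = 10L) {
  if (nrow(table) == 0L) abort("empty frequency table")
  top <- table$sequence[1L]
  cls <- classify_five_prime(top, template, search_span)
  pos <- switch(cls$category,
    starts_at_plus1 = template$plus_one_index,
    shifted_start = template$plus_one_index + cls$offset,
    nontemplated_5prime = template$plus_one_index,  # initiated at +1
    NA_integer_
  )
  tibble(
    position = as.integer(pos),
    frequency = table$frequency[1L],
    window = top,
    flagged = is.na(pos)
  )
}

#' Summarize the 5'-end analysis
#'
#' @param records Output of [extract_five_prime()].
#' @param template A `template_spec`.
#' @param search_span Passed to [classify_five_prime()].
#' @return One-row tibble: `n_analyzed`, `plus_one_position`,
#'   `plus_one_frequency`, `extra_g_fraction` (windows with non-templated
#'   leading Gs), `shifted_fraction`, `unrelated_fraction`.
#' @export
five_prime_summary <- function(records, template, search_span = 10L) {
  tab <- five_prime_table(records)
  est <- plus_one_estimate(tab, template, search_span)
  cls <- classify_five_prime(records, template, search_span)
  n <- nrow(cls)
  tibble(
    n_analyzed = n,
    plus_one_position = est$position,
    plus_one_frequency = est$frequency,
    extra_g_fraction = sum(cls$category == "nontemplated_5prime" &
                             cls$base == "G", na.rm = TRUE) / n,
    shifted_fraction = sum(cls$category == "shifted_start") / n,
    unrelated_fraction = sum(cls$category == "unrelated") / n
  )
}
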