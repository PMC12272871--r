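# 3'-terminal analysis: tag-anchored segment extraction, size distribution,
# per-size top sequences, terminus classification and run-off fidelity.

#' Extract 3'-terminal segments
#'
#' Collects reads containing the internal tag (leftmost exact occurrence)
#' followed, anywhere downstream, by the 3' adaptor anchor, and returns the
#' bases strictly between the tag end and the adaptor start: the 3'-terminal
#' region of the transcript. The adaptor search starts at the tag end so
#' that adaptor-like sequence upstream of the tag cannot match. Reads with
#' more than one tag occurrence are kept (first occurrence used) but
#' flagged.
#'
#' @param reads Tibble with `read_id`, `seq`, a character vector, or a FASTQ
#'   path.
#' @param tag Internal tag. Default `"ACTATTGCTTTCACG"`.
#' @param adaptor 3' adaptor anchor. Default `"CACGAGCGTTTT"`.
#' @return Tibble with `read_id`, `segment` (may be empty), `size`,
#'   `multi_tag`; attributes `n_in`, `n_extracted`, `n_skipped`.
#' @export
extract_three_prime <- function(reads, tag = TAG_SEQ, adaptor = ANCHOR_3P) {
  stopifnot(nchar(tag) > 0L, nchar(adaptor) > 0L)
  reads <- as_reads_tbl(reads)
  tag_end <- stringi::stri_locate_first_fixed(reads$seq, tag)[, 2L]
  downstream <- stringr::str_sub(reads$seq, tag_end + 1L)
  ad_start <- stringi::stri_locate_first_fixed(downstream, adaptor)[, 1L]
  keep <- !is.na(tag_end) & !is.na(ad_start)
  segment <- stringr::str_sub(downstream[keep], 1L, ad_start[keep] - 1L)
  out <- tibble(
    read_id = reads$read_id[keep],
    segment = segment,
    size = nchar(segment),
    multi_tag = stringi::stri_count_fixed(reads$seq[keep], tag) > 1L
  )
  attr(out, "n_in") <- nrow(reads)
  attr(out, "n_extracted") <- nrow(out)
  attr(out, "n_skipped") <- nrow(reads) - nrow(out)
  out
}

#' Size distribution of 3'-terminal segments
#'
#' @param records Output of [extract_three_prime()] (or an integer vector of
#'   sizes).
#' @return A `size_dist` tibble with `size`, `count`, `frequency`
#'   (normalized to the number of analyzed records), sorted by size;
#'   attribute `n_analyzed`.
#' @export
size_distribution <- function(records) {
  sizes <- if (is.data.frame(records)) records$size else records
  if (length(sizes) == 0L) abort("no 3' records to tabulate")
  out <- tibble(size = as.integer(sizes)) |>
    count(.data$size, name = "count") |>
    arrange(.data$size) |>
    mutate(frequency = .data$count / length(sizes))
  attr(out, "n_analyzed") <- length(sizes)
  class(out) <- c("size_dist", class(out))
  out
}

#' Modal segment size
#'
#' @param dist A `size_dist`.
#' @return The size with the highest count (smallest size on ties).
#' @export
modal_size <- function(dist) {
  dist$size[which.max(dist$count)]
}

#' Frequency of a given size in a size distribution
#'
#' @param dist A `size_dist`.
#' @param size Segment size (nt).
#' @return Frequency (0 when the size is absent).
#' @export
size_frequency <- function(dist, size) {
  i <- match(size, dist$size)
  if (is.na(i)) 0 else dist$frequency[i]
}

#' Top sequences among segments of one size
#'
#' Frequency table of the segments with exactly the given size, normalized
#' to the number of records at that size (the published per-size top-5
#' tables use this normalization).
#'
#' @param records Output of [extract_three_prime()].
#' @param size Segment size (nt).
#' @param n Number of rows to return. Default 5.
#' @return A `freq_table` tibble (possibly with zero rows).
#' @export
top_sequences_at_size <- function(records, size, n = 5L) {
  stopifnot(size >= 0L)
  at <- records$segment[records$size == size]
  if (length(at) == 0L) {
    out <- tibble(sequence = character(), count = integer(),
                  frequency = double())
    attr(out, "n_analyzed") <- 0L
    class(out) <- c("freq_table", class(out))
    return(out)
  }
  tab <- new_freq_table(at, length(at))
  utils::head(tab, n)
}

#' Classify 3'-terminal segments against the template
#'
#' Let `T` be the expected template suffix downstream of the tag
#' ([template_suffix()]). Each segment gets exactly one category:
#' 1. `correct_runoff`: segment equals `T`.
#' 2. `templated_truncation`: segment is a proper prefix of `T`
#'    (`trunc_offset` = segment length minus `length(T)`).
#' 3. `self_templated`: segment is `T[0:k]` plus a non-empty extension that
#'    is a prefix of the fold-back prediction from the correspondingly
#'    truncated transcript ([match_self_templated()]).
#' 4. `nontemplated_addition`: extension after the complete suffix (`k =
#'    length(T)`) not explained by fold-back.
#' 5. `unrelated`: internal mismatches not explained by any of the above.
#'
#' @param segments Character vector of segments or the output of
#'   [extract_three_prime()].
#' @param template A `template_spec`.
#' @param min_match Minimum extension length for a self-templated call.
#'   Default 3.
#' @param min_duplex Minimum fold-back duplex length. Default 3.
#' @return Tibble with `segment`, `category`, `trunc_offset`, `ext`, one row
#'   per input segment.
#' @export
classify_three_prime <- function(segments, template, min_match = 3L,
                                 min_duplex = 3L) {
  if (is.data.frame(segments)) segments <- segments$segment
  tsuf <- template_suffix(template)
  S <- nchar(tsuf)
  tx <- template$transcript
  Lt <- nchar(tx)

  u <- unique(segments)
  cat_u <- character(length(u))
  off_u <- rep(NA_integer_, length(u))
  ext_u <- rep("", length(u))

  fb_cache <- new.env(parent = emptyenv())
  fb_ext_at <- function(k) {
    key <- as.character(k)
    if (is.null(fb_cache[[key]])) {
      fb <- fold_back_extend(substr(tx, 1L, Lt - S + k), min_duplex = min_duplex)
      fb_cache[[key]] <- if (is.null(fb)) NA_character_ else fb$extension
    }
    fb_cache[[key]]
  }

  lcp_with <- function(s, t) {
    nmax <- min(nchar(s), nchar(t))
    if (nmax == 0L) return(0L)
    a <- utils::head(strsplit(s, "")[[1]], nmax)
    b <- utils::head(strsplit(t, "")[[1]], nmax)
    neq <- which(a != b)
    if (length(neq) == 0L) nmax else neq[1L] - 1L
  }

  for (i in seq_along(u)) {
    seg <- u[i]
    if (seg == tsuf) {
      cat_u[i] <- "correct_runoff"
      off_u[i] <- 0L
      next
    }
    if (nchar(seg) < S && startsWith(tsuf, seg)) {
      cat_u[i] <- "templated_truncation"
      off_u[i] <- nchar(seg) - S
      next
    }
    k <- lcp_with(seg, tsuf)
    ext <- stringr::str_sub(seg, k + 1L)
    pred <- fb_ext_at(k)
    if (!is.na(pred) && nchar(ext) >= min_match && startsWith(pred, ext)) {
      cat_u[i] <- "self_templated"
      off_u[i] <- k - S
      ext_u[i] <- ext
    } else if (k == S) {
      cat_u[i] <- "nontemplated_addition"
      off_u[i] <- 0L
      ext_u[i] <- ext
    } else {
      cat_u[i] <- "unrelated"
    }
  }

  idx <- match(segments, u)
  tibble(
    segment = segments,
    category = cat_u[idx],
    trunc_offset = off_u[idx],
    ext = ext_u[idx]
  )
}

#' Run-off fidelity statistic
#'
#' The frequency of the expected segment size multiplied by the ratio of
#' correct sequences at that size: the fraction of transcripts whose 3' end
#' has both the expected size and the exact template sequence. This product
#' is an exact factorization of the joint frequency computed directly by
#' [direct_runoff_fraction()].
#'
#' @param dist A `size_dist`.
#' @param correct_ratio Fraction of segments at the expected size that match
#'   the template suffix exactly, in `[0, 1]`.
#' @param expected_size Expected run-off segment size (nt).
#' @return Fraction in `[0, 1]`.
#' @export
runoff_fidelity <- function(dist, correct_ratio, expected_size) {
  stopifnot(correct_ratio >= 0, correct_ratio <= 1)
  size_frequency(dist, expected_size) * correct_ratio
}

#' Direct correct-run-off fraction
#'
#' Fraction of records whose segment has the expected size and exactly
#' matches the template suffix; the direct (unfactorized) form of
#' [runoff_fidelity()].
#'
#' @param records Output of [extract_three_prime()].
#' @param template A `template_spec`.
#' @return Fraction in `[0, 1]`.
#' @export
direct_runoff_fraction <- function(records, template) {
  if (nrow(records) == 0L) abort("no 3' records")
  tsuf <- template_suffix(template)
  mean(records$size == nchar(tsuf) & records$segment == tsuf)
}

#' Per-enzyme 3'-end fidelity report
#'
#' Bundles the size distribution, the modal size, the frequency at the
#' expected size, the correct-sequence ratio at that size and the run-off
#' fidelity statistic.
#'
#' @param records Output of [extract_three_prime()].
#' @param template A `template_spec`.
#' @param enzyme Label for the report.
#' @param expected_size Expected run-off segment size; defaults to the
#'   template's `tag_end_offset`.
#' @param n_reads_in Optional number of raw reads before extraction.
#' @return An object of class `fidelity_report`.
#' @export
fidelity_report <- function(records, template, enzyme = "sample",
                            expected_size = template$tag_end_offset,
                            n_reads_in = attr(records, "n_in") %||% NA_integer_) {
  if (nrow(records) == 0L) abort("no 3' records")
  dist <- size_distribution(records)
  tsuf <- template_suffix(template)
  at <- records$segment[records$size == expected_size]
  ratio <- if (length(at) == 0L) 0 else mean(at == tsuf)
  structure(
    list(
      enzyme = enzyme,
      n_reads_in = n_reads_in,
      n_extracted = nrow(records),
      expected_size = as.integer(expected_size),
      modal_size = modal_size(dist),
      freq_at_expected_size = size_frequency(dist, expected_size),
      correct_ratio_at_expected_size = ratio,
      runoff_fidelity = runoff_fidelity(dist, ratio, expected_size),
      size_distribution = dist,
      top_at_expected = top_sequences_at_size(records, expected_size)
    ),
    class = "fidelity_report"
  )
}

#' @export
print.fidelity_report <- function(x, ...) {
  cat("<fidelity_report> ", x$enzyme, "\n", sep = "")
  cat(sprintf("  reads in / extracted: %s / %d\n",
              ifelse(is.na(x$n_reads_in), "?", format(x$n_reads_in)),
              x$n_extracted))
  cat(sprintf("  modal size: %d nt (expected %d nt)\n",
              x$modal_size, x$expected_size))
  cat(sprintf("  freq at expected size:   %.4f\n", x$freq_at_expected_size))
  cat(sprintf("  correct ratio at size:   %.4f\n", x$correct_ratio_at_expected_size))
  cat(sprintf("  run-off fidelity:        %.4f\n", x$runoff_fidelity))
  invisible(x)
}

#' Tidy and glance methods for fidelity reports
#'
#' `glance()` returns the scalar summary as one row; `tidy()` returns the
#' per-size distribution.
#'
#' @param x A `fidelity_report`.
#' @param ... Unused.
#' @return A tibble.
#' @method glance fidelity_report
#' @export
glance.fidelity_report <- function(x, ...) {
  tibble(
    enzyme = x$enzyme,
    n_reads_in = x$n_reads_in,
    n_extracted = x$n_extracted,
    expected_size = x$expected_size,
    modal_size = x$modal_size,
    freq_at_expected_size = x$freq_at_expected_size,
    correct_ratio_at_expected_size = x$correct_ratio_at_expected_size,
    runoff_fidelity = x$runoff_fidelity
  )
}

#' @rdname glance.fidelity_report
#' @method tidy fidelity_report
#' @export
tidy.fidelity_report <- function(x, ...) {
  as_tibble(x$size_distribution)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
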