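# Promoter-candidate filtering downstream of any motif predictor: keep
# candidate motifs that occur multiple times in the genome and lie upstream
# of annotated ORF starts, and rank them.

#' Scan a genome for exact occurrences of a candidate motif
#'
#' Overlapping occurrences are counted. Minus-strand hits are occurrences of
#' the reverse complement, reported at their plus-strand start coordinate.
#'
#' @param candidate Motif (>= 8 nt).
#' @param genome Genome sequence (character scalar or a tibble from
#'   [read_fasta()]; multiple records are scanned independently and
#'   positions reported per record).
#' @param both_strands Scan the minus strand too. Default `TRUE`.
#' @return Tibble with `position` (0-based plus-strand start), `strand`.
#' @export
scan_genome <- function(candidate, genome, both_strands = TRUE) {
  if (is.data.frame(genome)) genome <- genome$seq[[1]]
  candidate <- normalize_rna(candidate)
  if (nchar(candidate) < 8L) abort("candidate motifs must be at least 8 nt")
  find_all <- function(pat) {
    m <- gregexpr(sprintf("(?=%s)", pat), genome, perl = TRUE)[[1]]
    if (m[1] == -1L) integer() else as.integer(m) - 1L
  }
  plus <- find_all(candidate)
  out <- tibble(position = plus, strand = rep("+", length(plus)))
  if (both_strands) {
    minus <- find_all(revcomp(candidate))
    out <- dplyr::bind_rows(out, tibble(position = minus,
                                        strand = rep("-", length(minus))))
  }
  arrange(out, .data$position, .data$strand)
}

#' Filter and rank promoter candidates
#'
#' Implements the downstream selection heuristic applied to predicted
#' promoter motifs: keep candidates that occur at least `min_hits` times in
#' the genome and have at least one same-strand occurrence whose 3' end lies
#' within `upstream_window` nt upstream of an ORF start; rank by the number
#' of ORF-upstream occurrences, then total occurrences, then sequence.
#'
#' The gap between a motif and an ORF start is the number of bases strictly
#' between the motif's 3' end and the start coordinate (0 = adjacent); a
#' motif is "upstream" when `0 <= gap <= upstream_window` on the ORF's
#' strand.
#'
#' @param candidates Character vector of motifs (or tibble with a `seq`
#'   column, e.g. from [read_fasta()]).
#' @param genome Genome sequence.
#' @param orf_starts Tibble with `pos` (0-based start coordinate of the ORF
#'   on its strand) and `strand` (`"+"`/`"-"`).
#' @param min_hits Minimum genome occurrences. Default 2.
#' @param upstream_window Maximum gap to an ORF start (nt). Default 100.
#' @return Tibble with `seq`, `n_hits`, `n_upstream` and a `hits` list
#'   column, ranked; zero rows if nothing passes.
#' @export
select_candidates <- function(candidates, genome, orf_starts,
                              min_hits = 2L, upstream_window = 100L) {
  if (is.data.frame(candidates)) candidates <- candidates$seq
  candidates <- unique(normalize_rna(candidates))
  if (length(candidates) == 0L) {
    return(tibble(seq = character(), n_hits = integer(),
                  n_upstream = integer(), hits = list()))
  }
  stopifnot(all(c("pos", "strand") %in% names(orf_starts)))
  rows <- purrr::map(candidates, function(cand) {
    hits <- scan_genome(cand, genome)
    len <- nchar(cand)
    upstream <- purrr::map_lgl(seq_len(nrow(hits)), function(i) {
      h <- hits[i, ]
      orfs <- orf_starts[orf_starts$strand == h$strand, ]
      if (nrow(orfs) == 0L) return(FALSE)
      gap <- if (h$strand == "+") {
        orfs$pos - (h$position + len)
      } else {
        h$position - orfs$pos - 1L
      }
      any(gap >= 0L & gap <= upstream_window)
    })
    tibble(seq = cand, n_hits = nrow(hits),
           n_upstream = sum(upstream), hits = list(hits))
  })
  out <- dplyr::bind_rows(rows)
  out <- out[out$n_hits >= min_hits & out$n_upstream >= 1L, ]
  arrange(out, desc(.data$n_upstream), desc(.data$n_hits), .data$seq)
}
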