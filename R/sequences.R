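#' @importFrom rlang %||% abort .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr arrange desc mutate filter count n left_join group_by summarise ungroup
NULL

DNA_BASES <- c("A", "C", "G", "T")

check_dna <- function(x, arg = "sequence") {
  bad <- stringr::str_detect(x, "[^ACGT]")
  if (any(bad, na.rm = TRUE)) {
    offender <- x[which(bad)[1]]
    abort(sprintf("%s contains non-ACGT characters: %s", arg, offender))
  }
  invisible(x)
}

#' Normalize an RNA or DNA string to the DNA alphabet
#'
#' Uppercases and converts U to T. All sequences in this package are held in
#' the DNA alphabet, in transcript sense; printed RNA oligo sequences
#' (adaptors) are normalized on ingest.
#'
#' @param x Character vector over `{A,C,G,T,U}`, any case.
#' @return Character vector over `{A,C,G,T}`, upper case.
#' @examples
#' normalize_rna("CCAGGCUUAUGGCAGUCACA")
#' @export
normalize_rna <- function(x) {
  x <- toupper(x)
  bad <- stringr::str_detect(x, "[^ACGUT]")
  if (any(bad, na.rm = TRUE)) {
    abort(sprintf("sequence contains characters outside {A,C,G,T,U}: %s",
                  x[which(bad)[1]]))
  }
  chartr("U", "T", x)
}

#' Reverse complement
#'
#' Watson-Crick reverse complement of DNA strings. Vectorized.
#'
#' @param x Character vector over `{A,C,G,T}`.
#' @return Character vector of reverse complements.
#' @examples
#' revcomp("ACGT")
#' @export
revcomp <- function(x) {
  check_dna(x)
  stringi::stri_reverse(chartr("ACGT", "TGCA", x))
}

#' Leftmost exact occurrence of a subsequence
#'
#' @param haystack Character vector to search in.
#' @param needle Single non-empty pattern.
#' @return Integer vector of 0-based positions of the leftmost occurrence,
#'   `NA` where absent. All coordinates in this package are 0-based.
#' @examples
#' find_first("AAATAGAAA", "TAG")
#' @export
find_first <- function(haystack, needle) {
  stopifnot(length(needle) == 1L, nchar(needle) > 0L)
  pos <- stringi::stri_locate_first_fixed(haystack, needle)[, 1L]
  as.integer(pos - 1L)
}

#' Percent identity of two aligned (gapped) sequences
#'
#' Computes 100 * matches / columns, where columns gapped in both sequences
#' are excluded from the denominator and a gap aligned to a base counts as a
#' mismatch. The gap character is `-`.
#'
#' @param aligned_a,aligned_b Equal-length aligned strings.
#' @return Percentage in `[0, 100]`.
#' @export
percent_identity <- function(aligned_a, aligned_b) {
  stopifnot(length(aligned_a) == 1L, length(aligned_b) == 1L)
  if (nchar(aligned_a) != nchar(aligned_b)) {
    abort("aligned sequences must have equal length (including gaps)")
  }
  a <- strsplit(aligned_a, "")[[1]]
  b <- strsplit(aligned_b, "")[[1]]
  keep <- !(a == "-" & b == "-")
  a <- a[keep]
  b <- b[keep]
  if (length(a) == 0L) return(NA_real_)
  100 * sum(a == b & a != "-") / length(a)
}

# ---- FASTA / FASTQ I/O (thin wrappers over Biostrings) ----------------------

#' Read a FASTA file into a tibble
#'
#' @param path FASTA file (optionally gzipped).
#' @return Tibble with columns `id`, `seq`.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  tibble(id = names(x), seq = as.character(x))
}

#' Write sequences to FASTA
#'
#' @param seqs Tibble with columns `id`, `seq`, or a named character vector.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  if (!is.data.frame(seqs)) seqs <- tibble(id = names(seqs), seq = unname(seqs))
  x <- Biostrings::DNAStringSet(seqs$seq)
  names(x) <- seqs$id
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a FASTQ file into a tibble
#'
#' @param path FASTQ file, optionally gzipped.
#' @return Tibble with columns `read_id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  empty <- tibble(read_id = character(), seq = character(), qual = character())
  if (length(readLines(path, n = 1L)) == 0L) return(empty)
  x <- withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path),
    # Biostrings warns about dropping its own internal metadata columns
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  tibble(
    read_id = names(x),
    seq = unname(as.character(x)),
    qual = unname(as.character(Biostrings::quality(x)))
  )
}

#' Write reads to FASTQ
#'
#' @param reads Tibble with columns `read_id`, `seq` and optionally `qual`
#'   (defaults to constant quality `I`).
#' @param path Output path; `.gz` suffix triggers gzip compression.
#' @export
write_fastq <- function(reads, path) {
  qual <- reads$qual %||% strrep("I", nchar(reads$seq))
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$read_id
  Biostrings::writeXStringSet(
    x, path, format = "fastq",
    qualities = Biostrings::BStringSet(qual),
    compress = grepl("\\.gz$", path)
  )
  invisible(path)
}
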