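# Adaptor / anchor constants. The 5' and 3' adaptors are the RNA oligos
# ligated to the transcript termini in the wet protocol (held here in DNA
# alphabet); the anchors are the subsequences used to locate them in reads.
ADAPTOR_5P <- "CCAGGCTTATGGCAGTCACA"
ADAPTOR_3P <- "CACGAGCGTTTTCCCACCTA"
ANCHOR_5P  <- "ATGGCAGTCACA"
ANCHOR_3P  <- "CACGAGCGTTTT"
TAG_SEQ    <- "ACTATTGCTTTCACG"

#' Build a template specification
#'
#' A `template_spec` describes the transcribed template: the sense strand
#' (upstream promoter context followed by the expected run-off transcript),
#' the 0-based position of the +1 base within the sense strand, and an
#' internal tag placed so that exactly `tag_end_offset` nt separate the end
#' of the tag from the transcript 3' terminus. The tag is spliced into the
#' body by replacement, so the transcript has the same length as `body`.
#'
#' @param body Transcript body (DNA, transcript sense); the tag replaces the
#'   body bases at its destination.
#' @param promoter Promoter sequence (annotation; also the default upstream
#'   context).
#' @param tag Internal tag; must not occur in `body` and must occur exactly
#'   once in the final transcript.
#' @param tag_end_offset Distance (nt) from the base after the tag's last
#'   base to the transcript 3' terminus, inclusive. Default 50.
#' @param upstream Sense-strand context 5' of the +1 base (defaults to
#'   `promoter`); needed to interpret transcription starts upstream of +1.
#' @param name Template name.
#' @return An object of class `template_spec`.
#' @examples
#' tpl <- default_template()
#' tpl
#' @export
build_template <- function(body, promoter, tag = TAG_SEQ, tag_end_offset = 50L,
                           upstream = promoter, name = "template") {
  body <- normalize_rna(body)
  promoter <- normalize_rna(promoter)
  tag <- normalize_rna(tag)
  upstream <- normalize_rna(upstream)
  lb <- nchar(body)
  lt <- nchar(tag)
  if (stringr::str_detect(body, stringr::fixed(tag))) {
    abort("tag already occurs in body; it must be unique in the transcript")
  }
  if (tag_end_offset < 0L || tag_end_offset + lt > lb) {
    abort("tag_end_offset overflows the body: need tag_end_offset + nchar(tag) <= nchar(body)")
  }
  tag_start <- lb - tag_end_offset - lt  # 0-based within transcript
  transcript <- paste0(
    substr(body, 1L, tag_start),
    tag,
    substr(body, tag_start + lt + 1L, lb)
  )
  spec <- structure(
    list(
      name = name,
      promoter = promoter,
      upstream = upstream,
      sense = paste0(upstream, transcript),
      transcript = transcript,
      tag = tag,
      tag_start = tag_start,
      tag_end_offset = as.integer(tag_end_offset),
      plus_one_index = nchar(upstream)
    ),
    class = "template_spec"
  )
  validate_template(spec)
  spec
}

#' @export
print.template_spec <- function(x, ...) {
  cat("<template_spec> ", x$name, "\n", sep = "")
  cat("  transcript: ", nchar(x$transcript), " nt, +1 base ",
      substr(x$transcript, 1, 1), "\n", sep = "")
  cat("  promoter:   ", x$promoter, "\n", sep = "")
  cat("  tag:        ", x$tag, " at ", x$tag_start, " (0-based), ",
      x$tag_end_offset, " nt to the 3' terminus\n", sep = "")
  invisible(x)
}

validate_template <- function(spec) {
  stopifnot(inherits(spec, "template_spec"))
  n_tag <- stringi::stri_count_fixed(spec$transcript, spec$tag)
  if (n_tag != 1L) abort(sprintf("tag must occur exactly once in transcript (found %d)", n_tag))
  tag_start <- find_first(spec$transcript, spec$tag)
  if (spec$tag_end_offset != nchar(spec$transcript) - (tag_start + nchar(spec$tag))) {
    abort("tag_end_offset inconsistent with tag position")
  }
  if (substr(spec$sense, spec$plus_one_index + 1L, spec$plus_one_index + 1L) !=
      substr(spec$transcript, 1L, 1L)) {
    abort("sense strand and transcript disagree at the +1 base")
  }
  invisible(spec)
}

#' Expected 3'-terminal segment of a template
#'
#' The `tag_end_offset`-nt transcript suffix downstream of the tag: the
#' segment a correct run-off transcript yields between tag and 3' adaptor.
#'
#' @param template A `template_spec`.
#' @return Character scalar.
#' @export
template_suffix <- function(template) {
  stringr::str_sub(template$transcript, -template$tag_end_offset)
}

# Frozen 250-nt synthetic transcript body used by `default_template()`.
# Engineered (and verified by tests) to contain:
#   * a unique site for the internal tag ending 50 nt before the 3' terminus,
#   * a hairpin whose stem 3' arm ends at terminus offset -10, so that a
#     transcript truncated there folds back on itself with a 6-bp duplex and
#     a predicted self-templated extension whose first 12 nt are unique,
#   * 5'-terminal windows that are distinct across all start offsets used by
#     the presets,
#   * no internal occurrence of the adaptor anchors or the tag.
IVT_BODY_250 <- paste0(
  "GCGACAGGCCGGAAACCCCGAGAAAACAACCCATGATGCCCCGTTTCTAGCATTAGTCCGGC",
  "CTTCCACCCCAGGTCGGTCTGGATATATAGCTGAATCATTTAAAGCAAGGGCCCTGTCCTGG",
  "TGACCAGGCGCATCTATGGTATCTAGCGGAACCCTTAAACAGCGGCGGTAATCTCACGGGGG",
  "TATGATGTCTATGATCACCCGACGGGGCGAGTTACTCTCGTAATAGGAATTACGTTGCATGTAC"
)

T7_PROMOTER <- "TAATACGACTCACTATA"

#' The packaged synthetic run-off template
#'
#' Returns the default 250-nt template used by the synthetic-data presets: a
#' fixed pseudo-random body carrying the internal tag at the -50 position and
#' a designed hairpin whose stem ends at terminus offset -10. Transcripts
#' truncated at that hairpin fold back with a 6-bp duplex and are extended by
#' a 12-nt self-templated extension, so a capped self-templated product is
#' 52 nt when measured from the tag (40 + 12). The template is synthetic: it
#' is not the luciferase-derived fragment used in the wet protocol, only a
#' sequence with the same designed features.
#'
#' @param plus_one `"G"` (T7, KpnP, Ro45Iw style) or `"A"` (CD23823 style);
#'   sets the +1 base of the transcript.
#' @param name Template name.
#' @return A `template_spec`.
#' @export
default_template <- function(plus_one = c("G", "A"), name = NULL) {
  plus_one <- match.arg(plus_one)
  body <- IVT_BODY_250
  substr(body, 1L, 1L) <- plus_one
  build_template(
    body, promoter = T7_PROMOTER, tag = TAG_SEQ, tag_end_offset = 50L,
    upstream = T7_PROMOTER,
    name = name %||% sprintf("synthetic-250nt-%s", plus_one)
  )
}

#' Write / read a template specification as YAML
#'
#' @param template A `template_spec`.
#' @param path YAML file path.
#' @export
write_template <- function(template, path) {
  yaml::write_yaml(unclass(template), path)
  invisible(path)
}

#' @rdname write_template
#' @export
read_template <- function(path) {
  x <- yaml::read_yaml(path)
  transcript <- normalize_rna(x$transcript)
  upstream <- normalize_rna(x$upstream)
  tag <- normalize_rna(x$tag)
  spec <- structure(
    list(
      name = x$name %||% "template",
      promoter = normalize_rna(x$promoter),
      upstream = upstream,
      sense = paste0(upstream, transcript),
      transcript = transcript,
      tag = tag,
      tag_start = find_first(transcript, tag),
      tag_end_offset = as.integer(x$tag_end_offset),
      plus_one_index = nchar(upstream)
    ),
    class = "template_spec"
  )
  validate_template(spec)
  spec
}
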