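# End-to-end per-enzyme report: extraction -> tables -> classification ->
# fidelity, with read counts logged at every filter so the behavior of each
# anchor/tag filter is auditable.

#' Run the full terminal-sequence pipeline
#'
#' Executes the 5' stage (anchored window extraction, frequency table,
#' classification, +1 estimate) and the 3' stage (tag-anchored segment
#' extraction, size distribution, per-size top sequences, classification,
#' run-off fidelity) on one read set, and optionally writes the report
#' tables (TSV) and summaries (JSON) to a directory. Read counts at every
#' filter (reads in, adaptor-matched, tag-matched) are part of the report.
#'
#' @param reads Tibble with `read_id`/`seq`, a character vector, or a FASTQ
#'   path (optionally gzipped).
#' @param template A `template_spec`.
#' @param enzyme Label used in the report.
#' @param expected_size Expected run-off segment size; defaults to the
#'   template's `tag_end_offset`.
#' @param top5,top10 Number of rows in the 3' per-size and 5' tables.
#' @param search_span Passed to [classify_five_prime()].
#' @param out_dir Optional output directory for TSV/JSON files.
#' @return An object of class `termini_report`: a list with elements
#'   `enzyme`, `counts` (per-stage read accounting), `five_prime` (table,
#'   classified windows, summary), `three_prime` (records, size
#'   distribution, top-at-size table, labels, `fidelity_report`).
#' @export
run_pipeline <- function(reads, template, enzyme = "sample",
                         expected_size = template$tag_end_offset,
                         top5 = 5L, top10 = 10L, search_span = 10L,
                         out_dir = NULL) {
  reads <- as_reads_tbl(reads)
  n_in <- nrow(reads)
  if (n_in == 0L) abort("extraction stage: no reads in input")

  fp <- extract_five_prime(reads)
  if (nrow(fp) == 0L) abort("five_prime extraction stage: no read contained the 5' adaptor anchor")
  fp_tab <- five_prime_table(fp)
  fp_cls <- classify_five_prime(fp, template, search_span)
  fp_sum <- five_prime_summary(fp, template, search_span)

  tp <- extract_three_prime(reads)
  if (nrow(tp) == 0L) abort("three_prime extraction stage: no read contained tag and adaptor")
  tp_dist <- size_distribution(tp)
  tp_top <- top_sequences_at_size(tp, expected_size, top5)
  tp_cls <- classify_three_prime(tp, template)
  fid <- fidelity_report(tp, template, enzyme, expected_size,
                         n_reads_in = n_in)

  counts <- tibble(
    stage = c("input", "five_prime_extracted", "five_prime_skipped",
              "three_prime_extracted", "three_prime_skipped"),
    n = c(n_in, attr(fp, "n_extracted"), attr(fp, "n_skipped"),
          attr(tp, "n_extracted"), attr(tp, "n_skipped"))
  )

  report <- structure(
    list(
      enzyme = enzyme,
      counts = counts,
      five_prime = list(
        records = fp,
        table = fp_tab,
        top = utils::head(fp_tab, top10),
        labels = fp_cls,
        summary = fp_sum
      ),
      three_prime = list(
        records = tp,
        size_distribution = tp_dist,
        top_at_expected = tp_top,
        labels = tp_cls,
        fidelity = fid
      )
    ),
    class = "termini_report"
  )
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.termini_report <- function(x, ...) {
  cat("<termini_report> ", x$enzyme, "\n", sep = "")
  n <- x$counts$n
  cat(sprintf("  reads: %d in; 5' extracted %d (skipped %d); 3' extracted %d (skipped %d)\n",
              n[1], n[2], n[3], n[4], n[5]))
  s <- x$five_prime$summary
  cat(sprintf("  +1 window frequency: %.4f (position %s)\n",
              s$plus_one_frequency,
              ifelse(is.na(s$plus_one_position), "unplaced", s$plus_one_position)))
  cat(sprintf("  extra-G fraction:    %.4f\n", s$extra_g_fraction))
  print(x$three_prime$fidelity)
  invisible(x)
}

#' Write a pipeline report to disk
#'
#' Writes `five_prime_table.tsv`, `five_prime_summary.json`,
#' `size_distribution.tsv`, `top_at_size_<k>.tsv`, `three_prime_labels.tsv`,
#' `fidelity_report.json` and `read_counts.tsv`. Every table carries its
#' normalization denominator (`n_analyzed`) as a column.
#'
#' @param report A `termini_report`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, `out_dir`.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(out_dir, ...)
  with_denominator <- function(tab) {
    tab$n_analyzed <- attr(tab, "n_analyzed") %||% NA_integer_
    tab
  }
  readr::write_tsv(report$counts, p("read_counts.tsv"))
  readr::write_tsv(
    with_denominator(
      left_join(report$five_prime$table, unique(report$five_prime$labels),
                by = c(sequence = "window"))
    ),
    p("five_prime_table.tsv")
  )
  jsonlite::write_json(as.list(report$five_prime$summary),
                       p("five_prime_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  readr::write_tsv(with_denominator(report$three_prime$size_distribution),
                   p("size_distribution.tsv"))
  fid <- report$three_prime$fidelity
  readr::write_tsv(with_denominator(report$three_prime$top_at_expected),
                   p(sprintf("top_at_size_%d.tsv", fid$expected_size)))
  readr::write_tsv(report$three_prime$labels, p("three_prime_labels.tsv"))
  jsonlite::write_json(as.list(glance(fid)), p("fidelity_report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
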