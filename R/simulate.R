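# Synthetic read generator: a mixture model over 5' start variants and 3'
# termination modes, with per-read ground truth. The generator emulates the
# adaptor-ligation protocol: transcripts are sampled from the mixture, then
# flanked by the 5' and 3' adaptor oligos.

#' End-mode descriptors for the generator mixture
#'
#' Each constructor returns one component of the 3'-termination mixture:
#' * `end_runoff()`: transcription to the template 3' terminus.
#' * `end_premature()`: termination at a sampled terminus offset (e.g. -10 =
#'   10 nt before the terminus), yielding a templated truncation.
#' * `end_nta()`: run-off followed by a non-templated 3' tail with sampled
#'   length and base composition.
#' * `end_self_templated()`: truncation at `stop_offset` followed by
#'   fold-back self-templated extension (see [fold_back_extend()]) capped at
#'   a sampled length. If the truncated transcript has no fold-back site the
#'   read falls back to a premature stop and is labeled accordingly.
#'
#' @param prob Mixture weight of the component.
#' @param stop_probs Named numeric: probabilities over negative terminus
#'   offsets for premature stops.
#' @param tail_len_probs Named numeric: probabilities over tail lengths.
#' @param base_probs Named numeric over `A`,`C`,`G`,`T`: tail base
#'   composition (default uniform).
#' @param stop_offset Single negative terminus offset at which the
#'   self-templated component truncates before fold-back.
#' @param cap_probs Named numeric: probabilities over extension caps (nt).
#' @return A list describing the component.
#' @name end_modes
NULL

#' @rdname end_modes
#' @export
end_runoff <- function(prob) {
  list(mode = "runoff", prob = prob)
}

#' @rdname end_modes
#' @export
end_premature <- function(prob, stop_probs) {
  stopifnot(all(as.integer(names(stop_probs)) < 0L))
  list(mode = "premature_stop", prob = prob, stop_probs = stop_probs)
}

#' @rdname end_modes
#' @export
end_nta <- function(prob, tail_len_probs = c(`1` = 1),
                    base_probs = c(A = .25, C = .25, G = .25, T = .25)) {
  stopifnot(all(as.integer(names(tail_len_probs)) >= 1L))
  list(mode = "nta", prob = prob, tail_len_probs = tail_len_probs,
       base_probs = base_probs)
}

#' @rdname end_modes
#' @export
end_self_templated <- function(prob, stop_offset, cap_probs) {
  stopifnot(length(stop_offset) == 1L, stop_offset < 0L,
            all(as.integer(names(cap_probs)) >= 1L))
  list(mode = "self_templated", prob = prob, stop_offset = as.integer(stop_offset),
       cap_probs = cap_probs)
}

check_probs <- function(p, what, tol = 1e-9) {
  if (length(p) == 0L || any(p < 0)) abort(sprintf("%s must be non-negative", what))
  if (abs(sum(p) - 1) > tol) {
    abort(sprintf("%s must sum to 1 (got %.12f)", what, sum(p)))
  }
  invisible(p)
}

#' Build a generator configuration
#'
#' Describes the mixture over terminal error modes from which synthetic
#' transcripts are drawn. Sampling order per read: start offset, then extra
#' 5' Gs (only for +1 starts: the classifier can only attribute leading
#' non-templated bases to a +1 initiation, so the generator conditions the
#' extra-G channel on a +1 start), then the end mode, then degradation, then
#' substitution errors.
#'
#' @param start_offset_probs Named numeric: probabilities over signed start
#'   offsets (0 = initiation at +1; negative = upstream of +1).
#' @param extra5g_probs Named numeric: probabilities over the number of
#'   non-templated leading Gs, conditional on a +1 start.
#' @param end_modes List of components built with the [end_modes]
#'   constructors; their `prob`s must sum to 1.
#' @param degradation_prob Probability that a read is a strictly internal
#'   random fragment (>= 20 nt, touching neither terminus) of the transcript.
#' @param seq_error_rate Per-base substitution probability applied last.
#' @param depth,seed Optional defaults for [simulate_transcripts()].
#' @param enzyme Optional label.
#' @param plus_one +1 base of the matching template (`"G"` or `"A"`).
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(start_offset_probs = c(`0` = 1),
                             extra5g_probs = c(`0` = 1),
                             end_modes = list(end_runoff(1)),
                             degradation_prob = 0,
                             seq_error_rate = 0,
                             depth = NULL, seed = NULL,
                             enzyme = NULL, plus_one = "G") {
  check_probs(start_offset_probs, "start_offset_probs")
  check_probs(extra5g_probs, "extra5g_probs")
  mode_probs <- purrr::map_dbl(end_modes, "prob")
  check_probs(mode_probs, "end mode probabilities")
  for (m in end_modes) {
    if (m$mode == "premature_stop") check_probs(m$stop_probs, "stop_probs")
    if (m$mode == "nta") {
      check_probs(m$tail_len_probs, "tail_len_probs")
      check_probs(m$base_probs, "base_probs")
    }
    if (m$mode == "self_templated") check_probs(m$cap_probs, "cap_probs")
  }
  stopifnot(degradation_prob >= 0, degradation_prob <= 1,
            seq_error_rate >= 0, seq_error_rate < 1)
  structure(
    list(
      start_offset_probs = start_offset_probs,
      extra5g_probs = extra5g_probs,
      end_modes = end_modes,
      degradation_prob = degradation_prob,
      seq_error_rate = seq_error_rate,
      depth = depth, seed = seed,
      enzyme = enzyme, plus_one = plus_one
    ),
    class = "generator_config"
  )
}

#' @export
print.generator_config <- function(x, ...) {
  cat("<generator_config>", x$enzyme %||% "", "\n")
  cat("  start offsets:", paste0(names(x$start_offset_probs), ":",
                                 signif(x$start_offset_probs, 3), collapse = " "), "\n")
  cat("  extra 5' Gs  :", paste0(names(x$extra5g_probs), ":",
                                 signif(x$extra5g_probs, 3), collapse = " "), "\n")
  for (m in x$end_modes) cat("  end mode     :", m$mode, signif(m$prob, 4), "\n")
  cat("  degradation  :", x$degradation_prob, " error rate:", x$seq_error_rate, "\n")
  invisible(x)
}

#' Per-enzyme generator presets
#'
#' Returns a `generator_config` whose true mixture parameters equal the
#' published per-enzyme measurements for the four polymerases: the +1-start
#' fraction (T7 28%, KpnP 22%, Ro45Iw 46%, CD23823 60%), the T7 extra-G
#' fraction (9%), the correct-run-off fraction (0.93%, 5.2%, 2.6%, 29%), the
#' correct-sequence ratio at the expected 50-nt size (22.5%, 88.2%, 83.3%,
#' 97.4%) and a dominant 3' mode placing the modal segment size at the
#' printed peak (T7 52 nt via fold-back self-templating capped at 12 nt
#' after a -10 stop; KpnP 51 nt via single-nucleotide non-templated
#' addition; Ro45Iw 40 nt via premature termination at the -10 hairpin;
#' CD23823 50 nt via correct run-off). Probability mass not pinned by a
#' printed value is spread over minor shifted starts and premature stops,
#' plus a nominal 0.2% degradation channel; those choices are documented in
#' the package vignette, not claimed from published data.
#'
#' @param enzyme One of `"T7"`, `"KpnP"`, `"Ro45Iw"`, `"CD23823"`.
#' @return A `generator_config`; pair it with
#'   `default_template(plus_one = config$plus_one)`.
#' @export
preset <- function(enzyme = c("T7", "KpnP", "Ro45Iw", "CD23823")) {
  enzyme <- match.arg(enzyme)
  deg <- 0.002
  # mass of incorrect-sequence segments at the expected size implied by a
  # printed (correct-run-off, correct-ratio-at-size) pair
  inc50 <- function(runoff, ratio) runoff / ratio - runoff
  spread <- function(sites, total) {
    p <- rep(total / length(sites), length(sites))
    names(p) <- sites
    p
  }
  cfg <- switch(enzyme,
    T7 = {
      runoff <- 0.0093
      st_total <- 0.55
      p50 <- inc50(runoff, 0.225) / st_total
      caps <- c(`12` = 0.50, `11` = 0.10, `10` = p50, `9` = 0.09,
                `8` = 0.08, `7` = 0.07, `6` = 0.06)
      caps <- c(caps, `5` = 1 - sum(caps))
      nta_p <- 0.04
      stop_total <- 1 - runoff - st_total - nta_p
      stops <- c(`-10` = 0.08, spread(setdiff(-1:-35, -10), stop_total - 0.08))
      generator_config(
        start_offset_probs = c(`-3` = .03, `-2` = .06, `-1` = .09, `0` = .37,
                               `1` = .13, `2` = .10, `3` = .08, `4` = .06,
                               `5` = .05, `6` = .03),
        extra5g_probs = c(`0` = 28 / 37, `1` = 6 / 37, `2` = 2 / 37, `3` = 1 / 37),
        end_modes = list(
          end_runoff(runoff),
          end_self_templated(st_total, stop_offset = -10L, cap_probs = caps),
          end_nta(nta_p),
          end_premature(stop_total, stop_probs = stops / stop_total)
        ),
        degradation_prob = deg, enzyme = "T7", plus_one = "G"
      )
    },
    KpnP = {
      runoff <- 0.052
      st_p <- inc50(runoff, 0.882)
      stop_total <- 1 - runoff - st_p - 0.45
      generator_config(
        start_offset_probs = c(`-3` = .05, `-2` = .08, `-1` = .11, `0` = .22,
                               `1` = .14, `2` = .12, `3` = .10, `4` = .08,
                               `5` = .06, `6` = .04),
        end_modes = list(
          end_runoff(runoff),
          end_self_templated(st_p, stop_offset = -10L, cap_probs = c(`10` = 1)),
          end_nta(0.45, tail_len_probs = c(`1` = 0.9, `2` = 0.1)),
          end_premature(stop_total, stop_probs = spread(-1:-35, 1))
        ),
        degradation_prob = deg, enzyme = "KpnP", plus_one = "G"
      )
    },
    Ro45Iw = {
      runoff <- 0.026
      st_p <- inc50(runoff, 0.833)
      stop_other <- 1 - runoff - st_p - 0.45 - 0.15
      stops <- c(`-10` = 0.45, spread(setdiff(-1:-35, -10), stop_other))
      generator_config(
        start_offset_probs = c(`-3` = .03, `-2` = .05, `-1` = .08, `0` = .46,
                               `1` = .12, `2` = .10, `3` = .07, `4` = .05,
                               `5` = .03, `6` = .01),
        end_modes = list(
          end_runoff(runoff),
          end_self_templated(st_p, stop_offset = -10L, cap_probs = c(`10` = 1)),
          end_nta(0.15),
          end_premature(sum(stops), stop_probs = stops / sum(stops))
        ),
        degradation_prob = deg, enzyme = "Ro45Iw", plus_one = "G"
      )
    },
    CD23823 = {
      runoff <- 0.29
      st_p <- inc50(runoff, 0.974)
      stop_total <- 1 - runoff - st_p - 0.10
      generator_config(
        start_offset_probs = c(`-2` = .04, `-1` = .07, `0` = .60, `1` = .10,
                               `2` = .08, `3` = .06, `4` = .03, `5` = .02),
        end_modes = list(
          end_runoff(runoff),
          end_self_templated(st_p, stop_offset = -10L, cap_probs = c(`10` = 1)),
          end_nta(0.10),
          end_premature(stop_total, stop_probs = spread(-1:-35, 1))
        ),
        degradation_prob = deg, enzyme = "CD23823", plus_one = "A"
      )
    }
  )
  cfg
}

sample_from <- function(values, n, probs) {
  values[sample.int(length(values), n, replace = TRUE, prob = probs)]
}

random_tails <- function(n, tail_len_probs, base_probs) {
  if (n == 0L) return(character())
  lens <- sample_from(as.integer(names(tail_len_probs)), n, tail_len_probs)
  mx <- max(lens)
  bp <- base_probs[DNA_BASES]
  bp[is.na(bp)] <- 0
  mat <- matrix(DNA_BASES[sample.int(4L, n * mx, replace = TRUE, prob = bp)], n, mx)
  stringr::str_sub(do.call(paste0, as.data.frame(mat, stringsAsFactors = FALSE)),
                   1L, lens)
}

apply_substitutions <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  n_err <- stats::rbinom(length(seqs), nchar(seqs), rate)
  for (i in which(n_err > 0L)) {
    ch <- strsplit(seqs[i], "")[[1]]
    for (p in sample.int(length(ch), n_err[i])) {
      ch[p] <- sample(setdiff(DNA_BASES, ch[p]), 1L)
    }
    seqs[i] <- paste(ch, collapse = "")
  }
  seqs
}

#' Simulate transcripts with per-read ground truth
#'
#' Draws `depth` transcripts from the mixture in `config` against `template`
#' and returns them with a truth label per read. With a non-`NULL` seed the
#' output is reproducible (bitwise within this implementation).
#'
#' @param template A `template_spec`.
#' @param config A `generator_config`.
#' @param depth Number of reads (default `config$depth`).
#' @param seed Integer seed (default `config$seed`).
#' @return Tibble with columns `read_id`, `transcript` (the synthesized RNA
#'   in DNA alphabet, before adaptor ligation), and the truth fields
#'   `start_offset`, `n_extra_5g`, `end_mode`, `end_offset`, `extension`.
#' @export
simulate_transcripts <- function(template, config, depth = config$depth,
                                 seed = config$seed) {
  stopifnot(inherits(template, "template_spec"),
            inherits(config, "generator_config"))
  if (is.null(depth) || depth <= 0) abort("depth must be a positive integer")
  run <- function() simulate_transcripts_impl(template, config, as.integer(depth))
  if (!is.null(seed)) withr::with_seed(as.integer(seed), run()) else run()
}

simulate_transcripts_impl <- function(template, config, depth) {
  sense <- template$sense
  p1 <- template$plus_one_index
  tx <- template$transcript
  Lt <- nchar(tx)

  # 1) start offsets
  off <- sample_from(as.integer(names(config$start_offset_probs)), depth,
                     config$start_offset_probs)
  if (any(p1 + off < 0L)) abort("start offset reaches beyond the upstream context")

  # 2) extra 5' Gs (only on +1 starts)
  gk <- integer(depth)
  at1 <- off == 0L
  gk[at1] <- sample_from(as.integer(names(config$extra5g_probs)), sum(at1),
                         config$extra5g_probs)

  # 3) end modes
  midx <- sample_from(seq_along(config$end_modes), depth,
                      purrr::map_dbl(config$end_modes, "prob"))

  product <- stringr::str_sub(sense, p1 + 1L + off, nchar(sense))
  end_mode <- character(depth)
  end_offset <- integer(depth)
  extension <- character(depth)
  extension[] <- ""

  for (j in seq_along(config$end_modes)) {
    m <- config$end_modes[[j]]
    sel <- which(midx == j)
    if (length(sel) == 0L) next
    if (m$mode == "runoff") {
      end_mode[sel] <- "runoff"
      end_offset[sel] <- 0L
    } else if (m$mode == "premature_stop") {
      k <- sample_from(as.integer(names(m$stop_probs)), length(sel), m$stop_probs)
      product[sel] <- stringr::str_sub(product[sel], 1L, nchar(product[sel]) + k)
      end_mode[sel] <- "premature_stop"
      end_offset[sel] <- k
    } else if (m$mode == "nta") {
      tails <- random_tails(length(sel), m$tail_len_probs, m$base_probs)
      product[sel] <- paste0(product[sel], tails)
      end_mode[sel] <- "nta"
      end_offset[sel] <- nchar(tails)
      extension[sel] <- tails
    } else if (m$mode == "self_templated") {
      k <- m$stop_offset
      fb <- fold_back_extend(substr(tx, 1L, Lt + k))
      if (is.null(fb)) {
        # no fold-back site on this template: fall back to a premature stop
        product[sel] <- stringr::str_sub(product[sel], 1L, nchar(product[sel]) + k)
        end_mode[sel] <- "premature_stop"
        end_offset[sel] <- k
      } else {
        caps <- sample_from(as.integer(names(m$cap_probs)), length(sel), m$cap_probs)
        ext <- stringr::str_sub(fb$extension, 1L, caps)
        product[sel] <- paste0(
          stringr::str_sub(product[sel], 1L, nchar(product[sel]) + k), ext
        )
        end_mode[sel] <- "self_templated"
        end_offset[sel] <- k + nchar(ext)
        extension[sel] <- ext
      }
    }
  }
  product <- paste0(strrep("G", gk), product)

  # 4) degradation: strictly internal fragments (>= 20 nt) of the transcript;
  # a fragment retaining a terminus would be indistinguishable from a
  # (truncated) standard product.
  start_offset <- off
  n_extra_5g <- gk
  if (config$degradation_prob > 0) {
    dsel <- which(stats::runif(depth) < config$degradation_prob)
    if (length(dsel) > 0L) {
      min_len <- 20L
      s1_vals <- 2:(Lt - min_len)                    # 1-based fragment starts
      w <- Lt - s1_vals - (min_len - 1L)             # choices of end per start
      s1 <- sample_from(s1_vals, length(dsel), w / sum(w))
      e1 <- s1 + (min_len - 1L) +
        floor(stats::runif(length(dsel)) * (Lt - s1 - (min_len - 1L)))
      product[dsel] <- stringr::str_sub(tx, s1, e1)
      end_mode[dsel] <- "degraded"
      end_offset[dsel] <- as.integer(e1 - Lt)
      extension[dsel] <- ""
      start_offset[dsel] <- NA_integer_
      n_extra_5g[dsel] <- NA_integer_
    }
  }

  # 5) substitution errors last
  product <- apply_substitutions(product, config$seq_error_rate)

  tibble(
    read_id = sprintf("read_%07d", seq_len(depth)),
    transcript = product,
    start_offset = start_offset,
    n_extra_5g = n_extra_5g,
    end_mode = end_mode,
    end_offset = end_offset,
    extension = extension
  )
}

#' Ligate adaptors and emit FASTQ plus truth table
#'
#' Flanks each simulated transcript with the 5' and 3' adaptor oligos,
#' writes a FASTQ file with constant qualities and, optionally, a truth TSV
#' with one row per read.
#'
#' @param sim Output of [simulate_transcripts()].
#' @param out_fastq FASTQ path (`.gz` for gzip).
#' @param out_truth Optional TSV path for the truth labels.
#' @param adaptor5,adaptor3 Adaptor sequences (defaults: the ligation oligos
#'   of the protocol, DNA alphabet).
#' @return Invisibly, the reads tibble (`read_id`, `seq`, `qual`).
#' @export
ligate_and_emit <- function(sim, out_fastq, out_truth = NULL,
                            adaptor5 = ADAPTOR_5P, adaptor3 = ADAPTOR_3P) {
  reads <- tibble(
    read_id = sim$read_id,
    seq = paste0(adaptor5, sim$transcript, adaptor3)
  )
  reads$qual <- strrep("I", nchar(reads$seq))
  write_fastq(reads, out_fastq)
  if (!is.null(out_truth)) {
    readr::write_tsv(sim[, c("read_id", "start_offset", "n_extra_5g",
                             "end_mode", "end_offset", "extension")],
                     out_truth)
  }
  invisible(reads)
}

#' Simulate adaptor-ligated reads in memory
#'
#' Convenience wrapper: [simulate_transcripts()] followed by in-silico
#' adaptor ligation, returning one tibble with reads and truth labels.
#'
#' @inheritParams simulate_transcripts
#' @inheritParams ligate_and_emit
#' @return Tibble with `read_id`, `seq` and the truth columns.
#' @export
simulate_reads <- function(template, config, depth = config$depth,
                           seed = config$seed,
                           adaptor5 = ADAPTOR_5P, adaptor3 = ADAPTOR_3P) {
  sim <- simulate_transcripts(template, config, depth = depth, seed = seed)
  sim$seq <- paste0(adaptor5, sim$transcript, adaptor3)
  sim[, c("read_id", "seq", "start_offset", "n_extra_5g", "end_mode",
          "end_offset", "extension")]
}
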