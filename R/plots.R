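#' Plot a 3'-segment size distribution
#'
#' Bar plot of segment-size frequencies, optionally marking the expected
#' run-off size.
#'
#' @param object A `size_dist`.
#' @param expected_size Optional expected size to mark with a dashed line.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot size_dist
#' @export
autoplot.size_dist <- function(object, expected_size = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$size, y = .data$frequency)) +
    ggplot2::geom_col(width = 0.8, fill = "grey30") +
    ggplot2::labs(x = "3' segment size (nt)", y = "frequency") +
    ggplot2::theme_minimal()
  if (!is.null(expected_size)) {
    p <- p + ggplot2::geom_vline(xintercept = expected_size,
                                 linetype = "dashed", colour = "red3")
  }
  p
}

#' Plot a terminal-sequence frequency table
#'
#' Horizontal bar plot of the top sequences of a frequency table.
#'
#' @param object A `freq_table`.
#' @param n Number of top sequences to show. Default 10.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot freq_table
#' @export
autoplot.freq_table <- function(object, n = 10L, ...) {
  top <- utils::head(object, n)
  top$sequence <- factor(top$sequence, levels = rev(top$sequence))
  ggplot2::ggplot(top, ggplot2::aes(x = .data$frequency, y = .data$sequence)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(x = "frequency", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the 3' stage of a pipeline report
#'
#' @param object A `termini_report`.
#' @param ... Passed to [autoplot.size_dist()].
#' @return A ggplot object.
#' @method autoplot termini_report
#' @export
autoplot.termini_report <- function(object, ...) {
  autoplot.size_dist(object$three_prime$size_distribution,
                     expected_size = object$three_prime$fidelity$expected_size,
                     ...)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
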