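#' Plot the tag length distribution of a library
#'
#' @param library A [tag_library].
#' @return A ggplot.
#' @export
plot_length_distribution <- function(library) {
  h <- length_histogram(library)
  ggplot2::ggplot(h, ggplot2::aes(x = length, y = count)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      x = "tag length (nt)", y = "reads",
      title = attr(library, "library_id")
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-position base composition
#'
#' Stacked per-position percentages of A/U/C/G, one bar per position.
#'
#' @param composition A [base_composition()] tibble.
#' @return A ggplot.
#' @export
plot_base_composition <- function(composition) {
  long <- tidyr::pivot_longer(composition, c("A", "U", "C", "G"),
                              names_to = "base", values_to = "percentage")
  long$base <- factor(long$base, levels = c("A", "U", "C", "G"))
  ggplot2::ggplot(long, ggplot2::aes(x = factor(position), y = percentage,
                                     fill = base)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(
      values = c(A = "#d62728", U = "#1f77b4", C = "#2ca02c", G = "#8c564b")
    ) +
    ggplot2::labs(x = "position on tag", y = "% of reads",
                  title = attr(composition, "group")) +
    ggplot2::theme_minimal()
}

#' Plot per-chromosome strand occupancy
#'
#' Sense-strand read counts above zero, antisense below, one panel of the
#' classic two-strand chromosome distribution plot.
#'
#' @param per_chromosome Tibble with `chrom`, `sense`, `antisense` (from
#'   a [mapping_summary()]).
#' @return A ggplot.
#' @export
plot_chromosome_distribution <- function(per_chromosome) {
  long <- tidyr::pivot_longer(per_chromosome, c("sense", "antisense"),
                              names_to = "strand", values_to = "reads")
  long$reads <- ifelse(long$strand == "antisense", -long$reads, long$reads)
  ggplot2::ggplot(long, ggplot2::aes(x = chrom, y = reads, fill = strand)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::scale_fill_manual(values = c(sense = "#1f77b4",
                                          antisense = "#d62728")) +
    ggplot2::labs(x = NULL, y = "reads (sense above, antisense below)") +
    ggplot2::theme_minimal()
}

#' Scatter plot of a differential expression result
#'
#' Normalized NC versus MN expression on log10 axes, colored by call
#' (up red, down green, unchanged blue).
#'
#' @param object A [diff_expression()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.de_result <- function(object, ...) {
  ggplot2::ggplot(
    tibble::as_tibble(object),
    ggplot2::aes(x = norm_nc, y = norm_mn, colour = call)
  ) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::scale_colour_manual(
      values = c(up = "#d62728", down = "#2ca02c", unchanged = "#1f77b4")
    ) +
    ggplot2::labs(x = "NC (reads per million)", y = "MN (reads per million)") +
    ggplot2::theme_minimal()
}

#' Heat map of a clustered pair matrix
#'
#' Fold-change cells on a red (up) / green (down) scale with missing
#' cells in gray, rows and columns in cluster order.
#'
#' @param object A [cluster_pairs()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pair_clustering <- function(object, ...) {
  long <- tidy(object)
  long$mirna <- factor(long$mirna, levels = object$row_order)
  long$pair <- factor(long$pair, levels = object$col_order)
  ggplot2::ggplot(long, ggplot2::aes(x = pair, y = mirna, fill = log2_fc)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2ca02c", mid = "black",
                                  high = "#d62728", na.value = "grey70") +
    ggplot2::labs(x = "sample pair", y = NULL, fill = "log2 FC") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_text(size = 6))
}
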