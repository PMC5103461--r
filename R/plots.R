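# ggplot2 figures for the two main result types.

#' Plot the smoothed divergence track
#'
#' One panel per reference scaffold, one colored line per query genome:
#' the flank-smoothed window divergence along the reference.
#'
#' @param smoothed Output of [smooth_windows()].
#' @return A ggplot object.
#' @export
plot_divergence_track <- function(smoothed) {
  ggplot2::ggplot(smoothed,
                  ggplot2::aes(x = .data$start / 1e3, y = .data$smoothed,
                               colour = .data$query)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::facet_wrap(~scaffold, ncol = 1, scales = "free_x") +
    ggplot2::labs(x = "reference position (kb)",
                  y = "nucleotide divergence (smoothed)",
                  colour = "query") +
    ggplot2::theme_minimal()
}

#' Plot a pairwise Kr distance matrix
#'
#' Tile heatmap of the symmetric Kr matrix; unreliable cells (above the
#' reliability cap) are marked.
#'
#' @param kr_tbl Output of [kr_matrix()].
#' @return A ggplot object.
#' @export
plot_kr_matrix <- function(kr_tbl) {
  both <- dplyr::bind_rows(
    kr_tbl,
    dplyr::rename(kr_tbl, a = "b", b = "a"))
  ggplot2::ggplot(both, ggplot2::aes(x = .data$a, y = .data$b,
                                     fill = .data$kr)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = ifelse(.data$reliable, sprintf("%.3g", .data$kr),
                     sprintf("%.3g*", .data$kr))), size = 3) +
    ggplot2::scale_fill_gradient(low = "#f7fbff", high = "#08306b") +
    ggplot2::labs(x = NULL, y = NULL, fill = "Kr",
                  caption = "* above the reliability cap") +
    ggplot2::theme_minimal()
}
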