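# ggplot2 views of the main result types.

#' Plot conserved intron-insertion events along the alignment
#'
#' One point per projected intron (alignment column x gene), shaped by
#' phase and coloured by event, mirroring the usual intron-map figure.
#'
#' @param object an [detect_events()] result.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.insertion_events <- function(object, ...) {
  introns <- attr(object, "introns")
  if (is.null(introns)) abort("events carry no intron attribute")
  introns$phase <- factor(introns$phase, levels = 0:2)
  ggplot2::ggplot(introns,
                  ggplot2::aes(x = .data$alignment_column, y = .data$gene_id,
                               colour = .data$event_id,
                               shape = .data$phase)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "alignment column", y = NULL, colour = "event",
                  shape = "phase") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_text(size = 5))
}

#' Expression heatmap (z-scored, cluster-ordered)
#'
#' @param m wide tibble or matrix (genes x samples).
#' @param metadata optional metadata for sample ordering (samples are kept
#'   in metadata order when given).
#' @return a ggplot tile map on the usual -2..2 scale.
#' @export
plot_expression_heatmap <- function(m, metadata = NULL) {
  z <- zscore_rows(m)
  ord <- cluster_rows(z)$order
  long <- tidyr::pivot_longer(z, -1, names_to = "sample_id",
                              values_to = "z")
  names(long)[1] <- "gene_id"
  long$gene_id <- factor(long$gene_id, levels = rev(ord))
  if (!is.null(metadata)) {
    long$sample_id <- factor(long$sample_id, levels = metadata$sample_id)
  }
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample_id, y = .data$gene_id,
                                     fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", limits = c(-2, 2),
                                  oob = scales_squish) +
    ggplot2::labs(x = NULL, y = NULL, fill = "z") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

# minimal squish (avoids a scales dependency for one oob rule)
scales_squish <- function(x, range = c(-2, 2)) {
  pmin(pmax(x, range[1]), range[2])
}

#' Plot transcript-metabolite correlations
#'
#' @param object a [correlate_profiles()] result.
#' @param q_max candidate threshold marked on the plot.
#' @param ... unused.
#' @return a ggplot tile map of r with significant positive pairs outlined.
#' @export
autoplot.correlation_results <- function(object, q_max = 0.05, ...) {
  df <- as_tibble(object)
  df$significant <- df$r > 0 & df$q <= q_max
  ggplot2::ggplot(df, ggplot2::aes(x = .data$compound_id, y = .data$gene_id,
                                   fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_point(data = df[df$significant, , drop = FALSE],
                        shape = 8, size = 1) +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_text(size = 6),
                   axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
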