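# Static renderings of the tables each stage emits. Every plot function
# returns a ggplot object; the pipeline runner saves them to file.

#' Bar chart of a signalment frequency table
#' @param ft A tibble from [frequency_table()].
#' @return A ggplot object.
#' @export
plot_frequency <- function(ft) {
  ft$level <- factor(ft$level, levels = rev(ft$level))
  ggplot2::ggplot(ft, ggplot2::aes(x = .data$level, y = .data$count)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = attr(ft, "variable") %||% "level", y = "records") +
    ggplot2::theme_minimal()
}

#' Proportion-by-frequency bar chart
#'
#' Bars are the levels of the frequency variable (heights = counts); fill
#' segments show the proportions of the proportion variable within each bar.
#'
#' @param ct A tibble from [cross_tab()].
#' @return A ggplot object.
#' @export
plot_cross_tab <- function(ct) {
  ggplot2::ggplot(ct, ggplot2::aes(x = .data$freq_level, y = .data$count,
                                   fill = .data$prop_level)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(x = attr(ct, "freq_variable") %||% "level", y = "records",
                  fill = attr(ct, "prop_variable") %||% "level") +
    ggplot2::theme_minimal()
}

#' Word-correlation network plot
#'
#' Force-directed layout (Fruchterman--Reingold, seeded so the image is
#' reproducible); edge darkness is mapped linearly from phi over
#' \[min_corr, 1\].
#'
#' @param edges Edge tibble from [word_correlations()].
#' @param min_corr The threshold used, for the darkness scale.
#' @param seed Layout seed.
#' @return A ggplot object.
#' @export
plot_correlation_network <- function(edges, min_corr = min(edges$phi), seed = 1) {
  if (nrow(edges) == 0L) stop("no edges to plot", call. = FALSE)
  g <- igraph::graph_from_data_frame(edges[, c("term_a", "term_b")], directed = FALSE)
  set.seed(seed)
  lay <- igraph::layout_with_fr(g)
  nodes <- tibble::tibble(term = igraph::V(g)$name, x = lay[, 1], y = lay[, 2])
  seg <- dplyr::left_join(edges, nodes, by = c(term_a = "term"))
  seg <- dplyr::left_join(seg, nodes, by = c(term_b = "term"),
                          suffix = c("", "_b"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$x_b, yend = .data$y_b,
                   alpha = .data$phi)) +
    ggplot2::scale_alpha_continuous(limits = c(min_corr, 1), range = c(0.25, 1)) +
    ggplot2::geom_text(data = nodes,
                       ggplot2::aes(x = .data$x, y = .data$y, label = .data$term),
                       size = 3) +
    ggplot2::labs(alpha = "phi") +
    ggplot2::theme_void()
}

#' Static word cloud of a topic model
#'
#' Words sized by topic-word probability and coloured by their assigned
#' (argmax) topic, laid out on a seeded jitter grid.
#'
#' @param cloud Tibble from [topic_word_cloud()].
#' @param seed Layout seed.
#' @return A ggplot object.
#' @export
plot_topic_cloud <- function(cloud, seed = 1) {
  set.seed(seed)
  cloud$x <- stats::runif(nrow(cloud))
  cloud$y <- stats::runif(nrow(cloud))
  ggplot2::ggplot(cloud, ggplot2::aes(x = .data$x, y = .data$y,
                                      label = .data$term,
                                      size = .data$weight,
                                      colour = factor(.data$assigned_topic))) +
    ggplot2::geom_text() +
    ggplot2::scale_size_continuous(range = c(2.5, 7), guide = "none") +
    ggplot2::labs(colour = "topic") +
    ggplot2::theme_void()
}

#' Histogram of positive-record counts per finding term
#' @param report A `findings_report` from [positive_records()].
#' @return A ggplot object.
#' @export
plot_findings <- function(report) {
  stopifnot(inherits(report, "findings_report"))
  ggplot2::ggplot(report$counts,
                  ggplot2::aes(x = .data$term, y = .data$n_positive)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "finding term", y = "positive records") +
    ggplot2::theme_minimal()
}
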