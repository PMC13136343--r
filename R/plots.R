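#' Plot a peri-event burst raster
#'
#' @param object A `burst_raster`.
#' @param ... Unused.
#' @return A ggplot object (channels x time, filled bins = bursts).
#' @export
autoplot.burst_raster <- function(object, ...) {
  d <- tidyr::expand_grid(channel = rownames(object) %||%
                            as.character(seq_len(nrow(object))),
                          bin = seq_len(ncol(object)))
  d <- arrange(d, .data$channel, .data$bin)
  d$value <- as.vector(t(object))
  d$time_s <- raster_bin_centers(object)[d$bin]
  ggplot2::ggplot(filter(d, .data$value > 0),
                  ggplot2::aes(x = .data$time_s, y = .data$channel)) +
    ggplot2::geom_tile(width = attr(object, "bin_width") %||% 0.01) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "time from event (s)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a channel clustering as an ordered distance heatmap
#'
#' Channels are ordered by the dendrogram leaf order, so co-bursting
#' modules appear as blocks along the diagonal.
#'
#' @param object A `cohfo_clust`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cohfo_clust <- function(object, ...) {
  ord <- object$leaf_order
  d <- as_tibble(as.table(object$dist[ord, ord]), .name_repair = "minimal")
  names(d) <- c("a", "b", "distance")
  d$a <- factor(d$a, levels = ord)
  d$b <- factor(d$b, levels = rev(ord))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$a, y = .data$b,
                                  fill = .data$distance)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(direction = -1) +
    ggplot2::labs(x = NULL, y = NULL, fill = "1 - r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90))
}
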