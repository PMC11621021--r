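# ggplot2 visualisations for the main result types.

#' @export
autoplot.cell_clusters <- function(object, colour = "cluster", ...) {
  d <- object$cells
  d$.lab <- factor(ifelse(d$cluster == -1L, NA, d$cluster))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$embed_1, y = .data$embed_2)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$.lab), size = 0.4,
                        na.rm = FALSE) +
    ggplot2::scale_colour_discrete(na.value = "black", name = "cluster") +
    ggplot2::labs(x = "UMAP 1", y = "UMAP 2",
                  caption = "black points are unclustered cells") +
    ggplot2::theme_minimal()
}

#' Sorted per-cluster silhouette plot
#'
#' @param clusters A `"cell_clusters"` object with silhouette scores.
#' @return A ggplot.
#' @export
plot_silhouette <- function(clusters) {
  d <- clusters$cells[clusters$cells$cluster != -1L, ]
  d <- d[order(d$cluster, -d$silhouette), ]
  d$rank <- seq_len(nrow(d))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$rank, y = .data$silhouette,
                                  fill = factor(.data$cluster))) +
    ggplot2::geom_col(width = 1) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = "cells (grouped by cluster)", y = "silhouette score",
                  fill = "cluster") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.cluster_profile <- function(object, what = c("normalized", "zscore",
                                                      "mean_intensity"),
                                     meta = NULL, ...) {
  what <- match.arg(what)
  m <- object[[what]]
  ord <- if (!is.null(meta)) as.character(attr(meta, "order")) else colnames(m)
  d <- tidy(object)
  d$cluster <- factor(d$cluster, levels = ord)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$cluster, y = .data$marker,
                                       fill = .data[[what]])) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = what) +
    ggplot2::labs(x = "cluster", y = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(meta)) {
    lab <- meta$meta_cluster[match(as.integer(ord), meta$cluster)]
    p <- p + ggplot2::scale_x_discrete(labels = paste0(ord, " (", lab, ")"))
  }
  p
}

#' Stacked QC category fractions
#'
#' Mirrors the stacked-bar summary of a QC run: the fraction of the raw
#' cell total redacted by each filter, per sample.
#'
#' @param table A gated spatial feature table.
#' @return A ggplot.
#' @export
plot_qc_partition <- function(table) {
  d <- dplyr::bind_rows(lapply(split(table, table$sample_id), function(t) {
    p <- qc_partition(t)
    p$sample_id <- t$sample_id[1]
    p
  }))
  d$status <- factor(d$status, levels = rev(qc_statuses()))
  ggplot2::ggplot(d[d$n > 0, ],
                  ggplot2::aes(x = .data$sample_id, y = .data$fraction,
                               fill = .data$status)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "fraction of cells") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Gate overlaid on a value histogram
#'
#' @param values Numeric vector the gate applies to (on the gate's scale).
#' @param gate A `"qc_gate"`.
#' @param bins Histogram bins.
#' @return A ggplot.
#' @export
plot_gate <- function(values, gate, bins = 100) {
  d <- tibble::tibble(v = values[is.finite(values)])
  ggplot2::ggplot(d, ggplot2::aes(x = .data$v)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey70") +
    ggplot2::geom_vline(xintercept = c(gate$lower, gate$upper),
                        colour = "red", linetype = 2) +
    ggplot2::labs(x = paste0("value (", gate$scale, " scale)"), y = "cells") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.thumbnail_gallery <- function(object, ncol = 10, ...) {
  w <- attr(object, "window")
  rows <- list()
  for (i in seq_len(nrow(object))) {
    p <- object$patch[[i]]
    rows[[i]] <- tibble::tibble(
      i = i, cluster = object$cluster[i],
      x = rep(seq_len(w), each = w), y = rep(rev(seq_len(w)), times = w),
      col = grDevices::rgb(as.numeric(t(p[, , 1])),
                           as.numeric(t(p[, , 2])),
                           as.numeric(t(p[, , 3]))))
  }
  d <- dplyr::bind_rows(rows)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y,
                                  fill = .data$col)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_identity() +
    ggplot2::facet_wrap(~ cluster + i, ncol = ncol) +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::theme(strip.text = ggplot2::element_blank())
}
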