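# Figures. The fingerprint heatmap uses a diverging scale centred on the
# neutral fitness 1: red for defects (dark red near 0), white at 1, blue
# for advantages.

#' Heatmap of a fitness matrix
#'
#' @param object A `tn_fitness` matrix.
#' @param cluster Optional `tn_clust` result; if given, rows follow the
#'   dendrogram leaf order.
#' @param limits Fitness range mapped onto the colour scale; values
#'   outside are squished to the ends.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot tn_fitness
#' @export
autoplot.tn_fitness <- function(object, cluster = NULL,
                                limits = c(0, 2), ...) {
  row_order <- if (!is.null(cluster)) cluster$leaf_order else
    attr(object, "gene_ids")
  df <- as_tibble(object)
  df$gene_id <- factor(df$gene_id, levels = rev(row_order))
  df$condition <- factor(df$condition, levels = attr(object, "conditions"))
  ggplot2::ggplot(df, ggplot2::aes(.data$condition, .data$gene_id,
                                   fill = .data$fitness)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(
      low = "#67000d", mid = "#ffffff", high = "#08306b",
      midpoint = 1, limits = limits, oob = scales_squish,
      na.value = "grey85", name = "fitness"
    ) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1))
}

# scales is a ggplot2 dependency; avoid importing it directly
scales_squish <- function(x, range = c(0, 1), only.finite = TRUE) {
  force <- if (only.finite) is.finite(x) else !is.na(x)
  x[force & x < range[1]] <- range[1]
  x[force & x > range[2]] <- range[2]
  x
}

#' @rdname autoplot.tn_fitness
#' @param fit A `tn_fitness` matrix.
#' @param path Optional file path; if given the plot is also saved there
#'   (format from the extension).
#' @param width,height Device size in inches when saving.
#' @export
plot_fitness_heatmap <- function(fit, cluster = NULL, path = NULL,
                                 limits = c(0, 2), width = 7, height = 7) {
  p <- autoplot(fit, cluster = cluster, limits = limits)
  if (!is.null(path))
    suppressMessages(ggplot2::ggsave(path, p, width = width, height = height))
  p
}

#' Dendrogram of a fingerprint clustering
#'
#' @param object A `tn_clust` result.
#' @param ... Ignored.
#' @return A ggplot object (leaves on the x axis, merge heights on y).
#' @method autoplot tn_clust
#' @export
autoplot.tn_clust <- function(object, ...) {
  if (is.null(object$hclust)) {
    return(
      ggplot2::ggplot(tibble(x = 1, y = 0, label = object$leaf_order)) +
        ggplot2::geom_text(ggplot2::aes(.data$x, .data$y,
                                        label = .data$label)) +
        ggplot2::theme_void()
    )
  }
  seg <- dendrogram_segments(object$hclust)
  labs <- tibble(x = seq_along(object$leaf_order),
                 label = object$leaf_order)
  ggplot2::ggplot(seg) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend)) +
    ggplot2::scale_x_continuous(breaks = labs$x, labels = labs$label) +
    ggplot2::labs(x = NULL, y = sprintf("%s distance (%s linkage)",
                                        object$metric, object$linkage)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1),
                   panel.grid.major.x = ggplot2::element_blank())
}

# x-position of each merge node = mean of its children; leaves sit at
# their dendrogram order index
dendrogram_segments <- function(hc) {
  n <- length(hc$order)
  leaf_x <- match(seq_len(n), hc$order)
  node_x <- numeric(nrow(hc$merge))
  node_y <- hc$height
  pos <- function(k) if (k < 0) leaf_x[-k] else node_x[k]
  hgt <- function(k) if (k < 0) 0 else node_y[k]
  segs <- vector("list", nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    a <- hc$merge[i, 1]; b <- hc$merge[i, 2]
    xa <- pos(a); xb <- pos(b)
    node_x[i] <- (xa + xb) / 2
    segs[[i]] <- tibble(
      x = c(xa, xb, xa), y = c(hgt(a), hgt(b), node_y[i]),
      xend = c(xa, xb, xb), yend = c(node_y[i], node_y[i], node_y[i])
    )
  }
  dplyr::bind_rows(segs)
}
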