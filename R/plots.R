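#' Plot a Mapper patient-patient network
#'
#' Draws the nerve graph with a deterministic Kamada-Kawai layout: nodes
#' sized by member count and coloured by a node-level statistic — the mean
#' lens value by default, or any per-subject variable averaged over each
#' node.
#'
#' @param object A `mapper_graph`.
#' @param colour Optional named per-subject vector to colour nodes by (via
#'   [map_attribute()]); default is the mean lens value. When the graph
#'   carries group labels, `colour = "group"` colours nodes by majority
#'   group.
#' @param ... Unused.
#'
#' @return A ggplot object.
#' @export
autoplot.mapper_graph <- function(object, colour = NULL, ...) {
  ig <- mapper_igraph(object)
  xy <- igraph::layout_with_kk(ig)
  nodes <- tidy(object)
  nodes$x <- xy[, 1]
  nodes$y <- xy[, 2]

  if (is.null(colour)) {
    nodes$colour <- nodes$mean_lens
    legend <- "mean lens"
  } else if (identical(colour, "group")) {
    if (is.null(object$groups)) abort("Graph carries no group labels.")
    nodes$colour <- nodes$majority_group
    legend <- "majority group"
  } else {
    nodes$colour <- unname(map_attribute(object, colour))
    legend <- "node mean"
  }

  seg <- dplyr::left_join(
    object$edges,
    dplyr::select(nodes, from = "node_id", x0 = "x", y0 = "y"),
    by = "from"
  )
  seg <- dplyr::left_join(
    seg,
    dplyr::select(nodes, to = "node_id", x1 = "x", y1 = "y"),
    by = "to"
  )

  p <- ggplot2::ggplot()
  if (nrow(seg) > 0) {
    p <- p + ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x1, yend = .data$y1),
      colour = "grey60"
    )
  }
  p +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, size = .data$size,
                   colour = .data$colour)
    ) +
    ggplot2::scale_size_area(max_size = 10) +
    ggplot2::labs(colour = legend, size = "subjects") +
    ggplot2::theme_void()
}

#' Bar chart of group-wise functional connectivity density
#'
#' Summarizes an [fcd_table()] by group: mean with SD error bars for each
#' intra-/inter-module measure.
#'
#' @param fcd_data Output of [fcd_table()] joined with a `group` column.
#' @param group Group column name.
#' @param measures Optional subset of FCD columns (default: all `intra_*`
#'   and `inter_*` columns).
#'
#' @return A ggplot object.
#' @export
plot_fcd <- function(fcd_data, group = "group", measures = NULL) {
  if (is.null(measures)) {
    measures <- grep("^(intra|inter)_", names(fcd_data), value = TRUE)
  }
  long <- tidyr::pivot_longer(
    fcd_data, dplyr::all_of(measures),
    names_to = "measure", values_to = "fcd"
  )
  summ <- dplyr::summarise(
    dplyr::group_by(long, .data$measure, .data[[group]]),
    mean = mean(.data$fcd, na.rm = TRUE),
    sd = sd(.data$fcd, na.rm = TRUE),
    .groups = "drop"
  )
  ggplot2::ggplot(
    summ,
    ggplot2::aes(x = .data$measure, y = .data$mean, fill = .data[[group]])
  ) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8), width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd),
      position = ggplot2::position_dodge(width = 0.8), width = 0.25
    ) +
    ggplot2::labs(x = NULL, y = "FCD (mean r)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Connectivity heatmap ordered by module
#'
#' @param R ROI x ROI correlation matrix.
#' @param assignment Optional module labels (vector or `module_partition`);
#'   when given, ROIs are ordered module-by-module.
#'
#' @return A ggplot object.
#' @export
plot_connectivity <- function(R, assignment = NULL) {
  if (inherits(assignment, "module_partition")) {
    assignment <- assignment$assignment
  }
  ord <- if (is.null(assignment)) seq_len(ncol(R)) else order(assignment)
  Ro <- R[ord, ord]
  df <- tidyr::expand_grid(
    i = factor(rownames(Ro), levels = rownames(Ro)),
    j = factor(colnames(Ro), levels = colnames(Ro))
  )
  df$r <- as.vector(t(Ro))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$j, y = .data$i, fill = .data$r)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}
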