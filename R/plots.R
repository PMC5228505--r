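#' Plot a usage-deviation signature
#'
#' Bar chart of the most deviant k-mers (largest |OUD|).
#'
#' @param object An `oud_signature`.
#' @param top Number of k-mers shown.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.oud_signature <- function(object, top = 30, ...) {
  df <- tidy.oud_signature(object)
  df <- df[order(-abs(df$oud)), ][seq_len(min(top, nrow(df))), ]
  df$kmer <- factor(df$kmer, levels = rev(df$kmer))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$oud, y = .data$kmer)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "usage deviation (OUD)", y = NULL,
                  title = sprintf("Top k-mer usage deviations (%s, k = %d)",
                                  attr(object, "strain"), attr(object, "k")))
}

#' Plot a signature distance matrix
#'
#' @param object An `oud_dist` matrix.
#' @param ... Unused.
#' @return A ggplot heat map.
#' @export
autoplot.oud_dist <- function(object, ...) {
  df <- as.data.frame(as.table(unclass(object)))
  names(df) <- c("strain_a", "strain_b", "distance")
  ggplot2::ggplot(df, ggplot2::aes(.data$strain_a, .data$strain_b,
                                   fill = .data$distance)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = NULL, y = NULL, fill = "distance") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot an ultrametric support tree
#'
#' Simple ggplot dendrogram of a rooted ultrametric tree with bootstrap
#' supports printed at internal nodes.
#'
#' @param object A `support_tree`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.support_tree <- function(object, ...) {
  n <- length(object$tip.label)
  heights <- tree_node_heights(object)
  # leaf y-positions in plotting (cladewise tip) order
  tr <- ape::reorder.phylo(object, "cladewise")
  tip_order <- tr$edge[tr$edge[, 2] <= n, 2]
  y <- numeric(n + object$Nnode)
  y[tip_order] <- seq_len(n)
  for (node in rev(unique(tr$edge[, 1]))) {
    kids <- tr$edge[tr$edge[, 1] == node, 2]
    y[node] <- mean(y[kids])
  }
  seg <- do.call(rbind, lapply(seq_len(nrow(tr$edge)), function(i) {
    p <- tr$edge[i, 1]; c_ <- tr$edge[i, 2]
    rbind(
      data.frame(x = heights[p], xend = heights[c_], y = y[c_], yend = y[c_]),
      data.frame(x = heights[p], xend = heights[p], y = y[p], yend = y[c_])
    )
  }))
  tips <- data.frame(x = heights[seq_len(n)], y = y[seq_len(n)],
                     label = object$tip.label)
  gg <- ggplot2::ggplot() +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$x, xend = .data$xend,
                                       y = .data$y, yend = .data$yend)) +
    ggplot2::geom_text(data = tips,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    label = .data$label),
                       hjust = 1.1, size = 3) +
    ggplot2::scale_x_reverse(expand = ggplot2::expansion(mult = c(0.05, 0.25))) +
    ggplot2::labs(x = "height (signature distance / 2)", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   panel.grid.major.y = ggplot2::element_blank())
  if (!is.null(object$node.label)) {
    nodes <- data.frame(x = heights[n + seq_len(object$Nnode)],
                        y = y[n + seq_len(object$Nnode)],
                        label = object$node.label)
    nodes <- nodes[!is.na(nodes$label) & nodes$label != "NA", ]
    if (nrow(nodes)) {
      gg <- gg + ggplot2::geom_text(
        data = nodes, ggplot2::aes(x = .data$x, y = .data$y,
                                   label = .data$label),
        vjust = -0.6, size = 2.8
      )
    }
  }
  gg
}

#' Plot a gene-content partition
#'
#' @param partition Output of [gene_content_partition()].
#' @return A ggplot bar chart of exclusive and core gene counts.
#' @export
plot_gene_content <- function(partition) {
  df <- partition[partition$category != "total", ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$category, y = .data$count)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "genes",
                  title = "Group-exclusive and core gene counts")
}

#' Plot pathway enrichment results
#'
#' @param enrichment Output of [hypergeom_pathway_enrichment()].
#' @return A ggplot of -log10 p per pathway.
#' @export
plot_enrichment <- function(enrichment) {
  df <- enrichment
  df$pathway_id <- factor(df$pathway_id,
                          levels = rev(df$pathway_id[order(df$p_value)]))
  ggplot2::ggplot(df, ggplot2::aes(x = -log10(.data$p_value),
                                   y = .data$pathway_id,
                                   size = .data$x)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = expression(-log[10](p)), y = NULL, size = "overlap")
}
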