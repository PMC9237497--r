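#' @export
autoplot.trait_correlations <- function(object, ...) {
  df <- tidy(object)
  ggplot(df, aes(x = .data$trait1, y = .data$trait2,
                 fill = .data$estimate)) +
    geom_tile() +
    geom_text(aes(label = paste0(sprintf("%.2f", .data$estimate),
                                 .data$stars)), size = 3) +
    scale_fill_gradient2(limits = c(-1, 1), low = "#b2182b",
                         mid = "white", high = "#2166ac",
                         name = paste0(object$method, "\nrho")) +
    labs(x = NULL, y = NULL,
         title = paste0("Trait correlations (", object$level,
                        " level, n = ", object$n, ")")) +
    theme_minimal()
}

#' @export
autoplot.population_pca <- function(object, components = c(1, 2), ...) {
  sc <- object$scores
  pcs <- paste0("PC", components)
  lab <- function(i) sprintf("%s (%.1f%%)", pcs[i],
                             object$pct_variance[components[i]])
  ggplot(sc, aes(x = .data[[pcs[1]]], y = .data[[pcs[2]]])) +
    geom_hline(yintercept = 0, linetype = 3, colour = "grey60") +
    geom_vline(xintercept = 0, linetype = 3, colour = "grey60") +
    geom_point() +
    geom_text(aes(label = .data$treatment), vjust = -0.6, size = 3) +
    labs(x = lab(1), y = lab(2), title = "Population PCA scores") +
    theme_minimal()
}

#' Bar chart of variable cos2 on the leading components
#'
#' @param pca A [pca_populations()] result.
#' @param n_components Components to display (default 2).
#' @return A ggplot object.
#' @export
plot_cos2 <- function(pca, n_components = 2) {
  stopifnot(inherits(pca, "population_pca"))
  df <- tidy(pca, "cos2") |>
    pivot_longer(-"trait", names_to = "component", values_to = "cos2") |>
    filter(.data$component %in% paste0("PC", seq_len(n_components)))
  ggplot(df, aes(x = stats::reorder(.data$trait, -.data$cos2),
                 y = .data$cos2, fill = .data$component)) +
    geom_col(position = "dodge") +
    labs(x = NULL, y = "cos2 (quality of representation)",
         title = "Trait representation on principal components") +
    theme_minimal()
}

#' @export
autoplot.gain_report <- function(object, control = "C", ...) {
  df <- filter(object, .data$treatment != control)
  ggplot(df, aes(x = stats::reorder(.data$treatment, -.data$gain_pct),
                 y = .data$gain_pct)) +
    geom_col(fill = "#4d9221") +
    geom_hline(yintercept = 0) +
    labs(x = "treatment", y = "genetic gain over control (%)",
         title = "Realized genetic gain") +
    theme_minimal()
}

#' @export
autoplot.dmrt <- function(object, ...) {
  df <- tidy(object)
  ggplot(df, aes(x = stats::reorder(.data$group, -.data$mean),
                 y = .data$mean)) +
    geom_col(fill = "grey70") +
    geom_text(aes(label = .data$letters), vjust = -0.5) +
    labs(x = "group", y = "mean",
         title = sprintf("Duncan grouping (alpha = %g)", object$alpha)) +
    theme_minimal()
}

# x positions and segment table of an hclust tree for ggplot rendering
dendrogram_segments <- function(h) {
  n <- length(h$order)
  leaf_x <- numeric(n)
  leaf_x[h$order] <- seq_len(n)
  pos <- function(i) {
    if (i < 0) c(leaf_x[-i], 0) else c(cluster_xy[i, 1], cluster_xy[i, 2])
  }
  cluster_xy <- matrix(0, nrow(h$merge), 2)
  segs <- vector("list", nrow(h$merge))
  for (i in seq_len(nrow(h$merge))) {
    a <- pos(h$merge[i, 1]); b <- pos(h$merge[i, 2])
    hgt <- h$height[i]
    cluster_xy[i, ] <- c((a[1] + b[1]) / 2, hgt)
    segs[[i]] <- tibble(
      x = c(a[1], b[1], a[1]), xend = c(a[1], b[1], b[1]),
      y = c(a[2], b[2], hgt), yend = c(hgt, hgt, hgt)
    )
  }
  list(segments = list_rbind(segs),
       leaves = tibble(x = seq_len(n), label = h$labels[h$order]))
}

#' Plot a UPGMA dendrogram
#'
#' @param dend An [stats::hclust] object (e.g. from [upgma()]).
#' @return A ggplot object.
#' @export
plot_dendrogram <- function(dend) {
  stopifnot(inherits(dend, "hclust"))
  dd <- dendrogram_segments(dend)
  ggplot() +
    geom_segment(data = dd$segments,
                 aes(x = .data$x, xend = .data$xend,
                     y = .data$y, yend = .data$yend)) +
    geom_text(data = dd$leaves,
              aes(x = .data$x, y = 0, label = .data$label),
              angle = 90, hjust = 1.1, size = 3) +
    scale_y_continuous(expand = ggplot2::expansion(mult = c(0.25, 0.05))) +
    labs(x = NULL, y = "merge height (Euclidean distance)",
         title = "UPGMA dendrogram") +
    theme_minimal() +
    theme(axis.text.x = element_blank(), panel.grid.major.x = element_blank())
}
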