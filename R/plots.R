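# ggplot2 displays for the result objects. These reproduce the standard
# zonation read-outs (mean +/- SD curves, PCA scatter, clustered heatmap,
# correlation matrix, overlap heatmap), not any particular figure styling.

#' @importFrom ggplot2 ggplot aes geom_line geom_point geom_ribbon geom_tile
#'   geom_text facet_wrap labs scale_fill_gradient2 scale_fill_viridis_c
#'   theme_minimal element_text theme
NULL

#' Plot a zonal profile as mean +/- SD curves per feature
#'
#' @param object A `zonal_profile`.
#' @param features Optional subset of features to show.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.zonal_profile <- function(object, features = NULL, ...) {
  df <- as_tibble(object)
  if (!is.null(features)) df <- df[df$feature %in% features, ]
  df$lo <- df$mean - df$sd
  df$hi <- df$mean + df$sd
  ggplot(df, aes(x = .data$bin, y = .data$mean)) +
    geom_ribbon(aes(ymin = .data$lo, ymax = .data$hi), alpha = 0.25,
                na.rm = TRUE) +
    geom_line(na.rm = TRUE) +
    geom_point(size = 0.8, na.rm = TRUE) +
    facet_wrap(~feature, scales = "free_y") +
    labs(x = "bin (R1 periportal → R12 pericentral)",
         y = "mean ± SD",
         title = attr(object, "condition")) +
    theme_minimal()
}

#' Plot PCA scores
#'
#' @param object A `lobule_pca`.
#' @param components Two components to display (default 1:2).
#' @param ... Unused.
#' @return A ggplot of the score scatter, labeled by row name.
#' @export
autoplot.lobule_pca <- function(object, components = c(1L, 2L), ...) {
  s <- object$scores
  df <- tibble(x = s[, components[1]], y = s[, components[2]],
               label = rownames(s) %||% as.character(seq_len(nrow(s))))
  ve <- object$var_explained
  ggplot(df, aes(.data$x, .data$y, label = .data$label)) +
    geom_point() +
    geom_text(vjust = -0.6, size = 3) +
    labs(x = sprintf("PC%d (%.1f%%)", components[1], 100 * ve[components[1]]),
         y = sprintf("PC%d (%.1f%%)", components[2], 100 * ve[components[2]])) +
    theme_minimal()
}

#' Plot a clustered heatmap (rows and columns in dendrogram order)
#'
#' @param object A `lobule_clustermap`.
#' @param ... Unused.
#' @return A ggplot tile heatmap of z-scores.
#' @export
autoplot.lobule_clustermap <- function(object, ...) {
  z <- object$z[object$row_order, object$col_order, drop = FALSE]
  df <- as_tibble(z, rownames = "row")
  df <- tidyr::pivot_longer(df, -"row", names_to = "feature",
                            values_to = "z")
  df$row <- factor(df$row, levels = rownames(z))
  df$feature <- factor(df$feature, levels = colnames(z))
  ggplot(df, aes(.data$feature, .data$row, fill = .data$z)) +
    geom_tile() +
    scale_fill_gradient2(low = "#2166AC", mid = "white", high = "#B2182B") +
    labs(x = NULL, y = NULL, fill = "z-score") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 45, hjust = 1))
}

#' Plot a cross-condition correlation matrix
#'
#' @param object A `condition_correlation`.
#' @param ... Unused.
#' @return A ggplot tile heatmap of Pearson r.
#' @export
autoplot.condition_correlation <- function(object, ...) {
  df <- tidy.condition_correlation(object)
  df$bin_a <- factor(df$bin_a, levels = rownames(object))
  df$bin_b <- factor(df$bin_b, levels = colnames(object))
  ggplot(df, aes(.data$bin_b, .data$bin_a, fill = .data$r)) +
    geom_tile() +
    scale_fill_gradient2(low = "#40004B", mid = "white", high = "#00441B",
                         limits = c(-1, 1)) +
    labs(x = attr(object, "condition_b") %||% "condition B",
         y = attr(object, "condition_a") %||% "condition A",
         fill = "Pearson r") +
    theme_minimal()
}

#' Plot the bin-by-condition overlap heatmap
#'
#' @param object An `overlap_heatmap`.
#' @param ... Unused.
#' @return A ggplot tile heatmap of mean overlapping pixels.
#' @export
autoplot.overlap_heatmap <- function(object, ...) {
  df <- tidyr::pivot_longer(as_tibble(object), -c("bin", "bin_label"),
                            names_to = "condition", values_to = "value")
  ggplot(df, aes(.data$condition, .data$bin_label, fill = .data$value)) +
    geom_tile() +
    scale_fill_viridis_c(na.value = "grey85") +
    labs(x = NULL, y = NULL, fill = attr(object, "feature")) +
    theme_minimal()
}
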