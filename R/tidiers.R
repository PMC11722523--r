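# broom-style tidiers for the fitted result objects

#' Tidy a PCA embedding
#'
#' @param x A `lobule_pca`.
#' @param matrix One of `"scores"`, `"loadings"`, `"eigenvalues"`.
#' @param ... Unused.
#' @return A tibble in long-friendly form: scores/loadings carry one row per
#'   row/feature with one column per component; eigenvalues carry one row per
#'   component with `std_dev` and `var_explained`.
#' @export
tidy.lobule_pca <- function(x, matrix = c("scores", "loadings", "eigenvalues"),
                            ...) {
  matrix <- match.arg(matrix)
  if (matrix == "eigenvalues") {
    return(tibble(component = seq_along(x$sdev), std_dev = x$sdev,
                  var_explained = x$var_explained))
  }
  m <- x[[matrix]]
  id_col <- if (matrix == "scores") "row" else "feature"
  out <- as_tibble(m, .name_repair = "minimal")
  names(out) <- colnames(m)
  out[[id_col]] <- rownames(m) %||% as.character(seq_len(nrow(m)))
  dplyr::relocate(out, dplyr::all_of(id_col))
}

#' @rdname tidy.lobule_pca
#' @export
glance.lobule_pca <- function(x, ...) {
  tibble(n_components = length(x$sdev),
         total_var_explained = sum(x$var_explained))
}

#' Tidy a hierarchical cluster map
#'
#' @param x A `lobule_clustermap`.
#' @param ... Unused.
#' @return Tibble with one row per clustered row: `row`, `order` (dendrogram
#'   position) and `cluster` (flat cluster id when the map was cut at `k`).
#' @export
tidy.lobule_clustermap <- function(x, ...) {
  rn <- rownames(x$z) %||% as.character(seq_len(nrow(x$z)))
  tibble(row = rn,
         order = match(seq_along(rn), x$row_order),
         cluster = if (is.null(x$clusters)) NA_integer_ else
           unname(x$clusters[rn]))
}

#' @rdname tidy.lobule_clustermap
#' @export
glance.lobule_clustermap <- function(x, ...) {
  tibble(n_rows = nrow(x$z), n_features = ncol(x$z),
         n_clusters = if (is.null(x$clusters)) NA_integer_ else
           length(unique(x$clusters)))
}

#' Tidy a cross-condition correlation matrix
#'
#' @param x A `condition_correlation`.
#' @param ... Unused.
#' @return Long tibble with `bin_a`, `bin_b`, `r`.
#' @export
tidy.condition_correlation <- function(x, ...) {
  m <- unclass(x)
  attr(m, "condition_a") <- NULL
  attr(m, "condition_b") <- NULL
  out <- as_tibble(m, rownames = "bin_a")
  tidyr::pivot_longer(out, -"bin_a", names_to = "bin_b", values_to = "r")
}

#' Tidy a zonal profile
#'
#' @param x A `zonal_profile`.
#' @param ... Unused.
#' @return The underlying tibble (`bin`, `bin_label`, `feature`, `mean`,
#'   `sd`, `n`) with a `condition` column.
#' @export
tidy.zonal_profile <- function(x, ...) {
  out <- as_tibble(x)
  out$condition <- attr(x, "condition")
  out
}

#' @rdname tidy.zonal_profile
#' @export
glance.zonal_profile <- function(x, ...) {
  tb <- as_tibble(x)
  tibble(condition = attr(x, "condition"),
         n_bins = attr(x, "n_bins"),
         n_features = length(unique(tb$feature)),
         n_cells = sum(tb$n[tb$feature == tb$feature[1]]),
         empty_bins = sum(tapply(tb$n, tb$bin, max) == 0))
}
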