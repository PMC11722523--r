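# Bin-level zonal statistics: per-bin mean/SD profiles, z-scoring, PCA,
# hierarchical cluster maps, cross-condition Pearson correlation and the
# overlap-pixel heatmap.

#' Aggregate per-cell features into a zonal profile
#'
#' Per-bin, per-feature mean, standard deviation (`n - 1` denominator) and
#' cell count. Bins without cells are retained with missing values so the
#' R1..Rn structure is always complete.
#'
#' @param cell_table Per-cell feature table with a `bin` column.
#' @param features Character vector of feature columns (default: all numeric
#'   feature columns except identifiers and spatial coordinates). Unknown
#'   names are an error.
#' @param n_bins Number of bins (default 12).
#' @param condition Optional condition label stored with the profile.
#' @return A `zonal_profile`: tibble with columns `bin`, `bin_label`,
#'   `feature`, `mean`, `sd`, `n`, plus attributes `condition` and `n_bins`.
#' @export
aggregate_by_bin <- function(cell_table, features = NULL, n_bins = 12L,
                             condition = NULL) {
  cell_table <- as_tibble(cell_table)
  if (!"bin" %in% names(cell_table)) data_error("`cell_table` needs a `bin` column")
  if (is.null(features)) {
    skip <- c("cell", "bin", "centroid_x", "centroid_y", "d_cv_um", "d_pv_um", "r")
    features <- setdiff(names(cell_table)[vapply(cell_table, is.numeric, logical(1))],
                        skip)
  }
  missing <- setdiff(features, names(cell_table))
  if (length(missing) > 0) {
    abort(paste0("unknown feature(s): ", paste(missing, collapse = ", ")),
          class = "lobulemap_key_error")
  }
  long <- tidyr::pivot_longer(cell_table[, c("bin", features)],
                              dplyr::all_of(features),
                              names_to = "feature", values_to = "value")
  agg <- long |>
    dplyr::filter(!is.na(.data$bin)) |>
    dplyr::group_by(.data$bin, .data$feature) |>
    dplyr::summarise(
      mean = if (any(!is.na(.data$value))) mean(.data$value, na.rm = TRUE) else NA_real_,
      sd = sd(.data$value, na.rm = TRUE),
      n = sum(!is.na(.data$value)),
      .groups = "drop"
    )
  full <- tidyr::expand_grid(bin = seq_len(n_bins), feature = features)
  out <- dplyr::left_join(full, agg, by = c("bin", "feature"))
  out$n[is.na(out$n)] <- 0L
  out$bin_label <- factor(paste0("R", out$bin), levels = bin_labels(n_bins))
  out <- dplyr::relocate(out, "bin", "bin_label", "feature")
  structure(out, class = c("zonal_profile", class(out)),
            condition = condition %||% NA_character_, n_bins = as.integer(n_bins))
}

#' Bins-by-features matrix of zonal means
#'
#' @param profile A `zonal_profile`.
#' @return Numeric matrix, rows `R1..Rn`, columns features.
#' @export
profile_matrix <- function(profile) {
  n_bins <- attr(profile, "n_bins")
  wide <- tidyr::pivot_wider(as_tibble(profile)[, c("bin", "feature", "mean")],
                             names_from = "feature", values_from = "mean")
  wide <- dplyr::arrange(wide, .data$bin)
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- paste0("R", wide$bin)
  m
}

#' Z-score a zonal profile across bins
#'
#' Centers and scales each feature to mean 0, SD 1 across bins. Features
#' with zero variance or without at least two observed bins are dropped with
#' a warning. The centering/scaling constants are kept so the transform
#' round-trips exactly via [unstandardize()].
#'
#' @param profile A `zonal_profile` or a bins-by-features numeric matrix.
#' @return A `zonal_zscore`: list with `z` (matrix), `center`, `scale`,
#'   `dropped` (character).
#' @export
standardize_profile <- function(profile) {
  m <- if (inherits(profile, "zonal_profile")) profile_matrix(profile) else
    as.matrix(profile)
  ok_n <- colSums(!is.na(m)) >= 2
  ctr <- colMeans(m, na.rm = TRUE)
  scl <- apply(m, 2, sd, na.rm = TRUE)
  keep <- ok_n & is.finite(scl) & scl > 0
  if (!any(keep)) data_error("no feature has >= 2 bins with non-zero variance")
  dropped <- colnames(m)[!keep]
  if (length(dropped) > 0) {
    warn(paste0("dropping constant or under-observed feature(s): ",
                paste(dropped, collapse = ", ")))
  }
  z <- sweep(sweep(m[, keep, drop = FALSE], 2, ctr[keep]), 2, scl[keep], "/")
  structure(list(z = z, center = ctr[keep], scale = scl[keep],
                 dropped = dropped),
            class = "zonal_zscore")
}

#' @rdname standardize_profile
#' @param zs A `zonal_zscore`.
#' @return `unstandardize()` returns the original bins-by-features matrix.
#' @export
unstandardize <- function(zs) {
  if (!inherits(zs, "zonal_zscore")) config_error("`zs` must be a zonal_zscore")
  sweep(sweep(zs$z, 2, zs$scale, "*"), 2, zs$center, "+")
}

as_stats_matrix <- function(x) {
  if (inherits(x, "zonal_zscore")) return(x$z)
  if (inherits(x, "zonal_profile")) return(profile_matrix(x))
  as.matrix(x)
}

#' Principal component embedding of bin profiles
#'
#' Projects the row-centered matrix onto its top right-singular directions.
#' The sign of each component is fixed deterministically: the loading entry
#' with the largest magnitude is made positive, so scores are reproducible
#' across runs and platforms. If the matrix rank is below `n_components`,
#' the available components are returned with a warning.
#'
#' @param x Bins-by-features (or cells-by-features) matrix, `zonal_profile`
#'   or `zonal_zscore`. Rows must be at least `n_components`.
#' @param n_components Number of components (2 or 3 typically).
#' @return A `lobule_pca`: list with `scores` (rows x components),
#'   `loadings` (features x components), `var_explained` (ratios,
#'   non-increasing, summing to <= 1), `sdev`, `center`.
#' @export
pca_embed <- function(x, n_components = 2L) {
  m <- as_stats_matrix(x)
  if (anyNA(m)) data_error("PCA input contains missing values")
  if (nrow(m) < n_components) {
    data_error("need at least `n_components` rows for the embedding")
  }
  pc <- prcomp(m, center = TRUE, scale. = FALSE)
  total_var <- sum(pc$sdev^2)
  rank <- sum(pc$sdev > max(pc$sdev) * 1e-10)
  k <- min(n_components, rank, ncol(pc$rotation))
  if (k < n_components) {
    warn(sprintf("matrix rank %d < %d requested components; returning %d",
                 rank, n_components, k))
  }
  k <- max(k, 1L)
  load <- pc$rotation[, seq_len(k), drop = FALSE]
  scores <- pc$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i_max <- which.max(abs(load[, j]))
    if (load[i_max, j] < 0) {
      load[, j] <- -load[, j]
      scores[, j] <- -scores[, j]
    }
  }
  structure(list(
    scores = scores, loadings = load,
    var_explained = if (total_var > 0) pc$sdev[seq_len(k)]^2 / total_var else
      rep(0, k),
    sdev = pc$sdev[seq_len(k)], center = pc$center
  ), class = "lobule_pca")
}

#' Hierarchical clustering of a z-scored bin-by-feature matrix
#'
#' Agglomerative clustering of rows (bins) and columns (features) for a
#' dendrogram-plus-heatmap display. Defaults: average linkage on Euclidean
#' distances of z-scores. `stats::hclust` merging is deterministic for a
#' fixed input ordering, so the returned orders are reproducible.
#'
#' @param z Z-scored matrix (or `zonal_zscore`), no missing values, >= 2 rows.
#' @param linkage Linkage method for [stats::hclust()].
#' @param metric Distance metric for [stats::dist()].
#' @param k Optional number of flat clusters to cut the row dendrogram at.
#' @return A `lobule_clustermap`: list with `row_hclust`, `col_hclust`,
#'   `row_order`, `col_order`, `clusters` (named integer vector or `NULL`),
#'   `z`.
#' @export
hierarchical_clustermap <- function(z, linkage = "average",
                                    metric = "euclidean", k = NULL) {
  m <- as_stats_matrix(z)
  if (anyNA(m)) data_error("clustering input contains missing values")
  if (nrow(m) < 2) data_error("need at least 2 rows to cluster")
  hr <- hclust(dist(m, method = metric), method = linkage)
  hc <- if (ncol(m) >= 2) hclust(dist(t(m), method = metric), method = linkage)
  clusters <- if (!is.null(k)) cutree(hr, k = k)
  structure(list(
    row_hclust = hr, col_hclust = hc,
    row_order = hr$order,
    col_order = if (is.null(hc)) seq_len(ncol(m)) else hc$order,
    clusters = clusters, z = m
  ), class = "lobule_clustermap")
}

#' Cross-condition Pearson correlation of bin profiles
#'
#' Entry `(i, j)` is the Pearson correlation between the bin-`i` feature
#' vector of profile A and the bin-`j` feature vector of profile B, computed
#' over the shared feature set after z-scoring each feature across the
#' pooled bins of both profiles (so both conditions share one scale).
#'
#' @param profile_a,profile_b `zonal_profile`s with complete bin vectors and
#'   at least 3 shared features.
#' @return A bins_A-by-bins_B correlation matrix of class
#'   `condition_correlation`, with the condition labels as attributes.
#' @export
condition_correlation <- function(profile_a, profile_b) {
  ma <- profile_matrix(profile_a)
  mb <- profile_matrix(profile_b)
  shared <- intersect(colnames(ma), colnames(mb))
  if (length(shared) < 3) {
    abort("need at least 3 shared features for bin correlations",
          class = "lobulemap_stats_error")
  }
  ma <- ma[, shared, drop = FALSE]
  mb <- mb[, shared, drop = FALSE]
  if (anyNA(ma) || anyNA(mb)) data_error("bin feature vectors must be complete")
  pooled <- rbind(ma, mb)
  ctr <- colMeans(pooled)
  scl <- apply(pooled, 2, sd)
  scl[scl == 0] <- 1
  za <- sweep(sweep(ma, 2, ctr), 2, scl, "/")
  zb <- sweep(sweep(mb, 2, ctr), 2, scl, "/")
  r <- cor(t(za), t(zb))
  structure(r, class = c("condition_correlation", class(r)),
            condition_a = attr(profile_a, "condition"),
            condition_b = attr(profile_b, "condition"))
}

#' Bin-by-condition matrix of mean overlapping pixels
#'
#' @param profiles Named list of `zonal_profile`s (names = condition labels;
#'   unnamed profiles fall back to their `condition` attribute).
#' @param feature Feature to extract (default `"overlap_px"`). Absent
#'   feature is an error.
#' @return An `overlap_heatmap`: tibble with `bin`, `bin_label` and one
#'   column per condition holding the per-bin mean; missing bins are `NA`.
#' @export
overlap_heatmap <- function(profiles, feature = "overlap_px") {
  if (inherits(profiles, "zonal_profile")) profiles <- list(profiles)
  nms <- names(profiles) %||% rep("", length(profiles))
  nms[nms == ""] <- vapply(profiles[nms == ""], function(p) {
    cond <- attr(p, "condition")
    if (is.null(cond) || is.na(cond)) "condition" else cond
  }, character(1))
  nms <- make.unique(nms)
  cols <- purrr::map2(profiles, nms, function(p, nm) {
    p <- as_tibble(p)
    if (!feature %in% p$feature) {
      abort(sprintf("feature '%s' absent from profile '%s'", feature, nm),
            class = "lobulemap_key_error")
    }
    sub <- p[p$feature == feature, c("bin", "mean")]
    names(sub)[2] <- nm
    sub
  })
  out <- purrr::reduce(cols, dplyr::left_join, by = "bin")
  out$bin_label <- factor(paste0("R", out$bin),
                          levels = paste0("R", sort(out$bin)))
  out <- dplyr::relocate(out, "bin", "bin_label")
  structure(out, class = c("overlap_heatmap", class(out)), feature = feature)
}
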