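# Per-cell feature extraction: organelle aggregates, mitochondria-LD contact
# metrics and the orchestration that produces one tidy row per hepatocyte.

#' Mitochondria-LD pixel overlap within a cell
#'
#' @param mito_mask,ld_mask Logical (or 0/1) matrices of identical shape,
#'   already restricted to one cell's organelles.
#' @return Tibble with `overlap_px` (`|M intersect L|`) and `overlap_pct`
#'   (`100 * |M intersect L| / |L|`; 0 when there are no LD pixels).
#' @export
mito_ld_overlap <- function(mito_mask, ld_mask) {
  check_same_shape(mito_mask, ld_mask, "mito and LD masks")
  m <- mito_mask > 0; l <- ld_mask > 0
  ov <- sum(m & l)
  nl <- sum(l)
  tibble(overlap_px = ov,
         overlap_pct = if (nl == 0L) 0 else 100 * ov / nl)
}

#' Shortest mitochondria-to-LD distance per droplet
#'
#' For each LD, the minimum Euclidean distance from any of its pixels to the
#' nearest mitochondrion pixel (0 when the masks overlap). The minimum over
#' all LD pixels equals the minimum over boundary pixels whenever the
#' mitochondrion lies outside the droplet, and is exactly 0 on overlap.
#' Distances are exact (Euclidean distance transform of the mitochondria
#' mask). An empty mitochondria mask yields missing distances.
#'
#' @param mito_mask Logical/0-1 matrix of mitochondria pixels.
#' @param ld_objects LD instance mask (integer matrix) or a list of linear
#'   pixel-index vectors per droplet.
#' @param pixel_size_um Pixel size in um/px.
#' @return Tibble with `ld_label` and `min_dist_um`; the per-cell mean is
#'   attached as attribute `mean_um` (NA when there are no droplets).
#' @export
mito_ld_min_distance <- function(mito_mask, ld_objects, pixel_size_um = 1) {
  if (is.matrix(ld_objects) && !is.list(ld_objects)) {
    check_same_shape(mito_mask, ld_objects, "mito and LD masks")
    ld_px <- label_pixels(ld_objects)
  } else {
    ld_px <- ld_objects
  }
  labs <- as.integer(names(ld_px) %||% seq_along(ld_px))
  if (length(ld_px) == 0L) {
    out <- tibble(ld_label = integer(), min_dist_um = numeric())
    attr(out, "mean_um") <- NA_real_
    return(out)
  }
  if (!any(mito_mask > 0)) {
    out <- tibble(ld_label = labs, min_dist_um = NA_real_)
    attr(out, "mean_um") <- NA_real_
    return(out)
  }
  dm <- EBImage::imageData(EBImage::distmap(EBImage::Image(!(mito_mask > 0))))
  d <- vapply(ld_px, function(idx) min(dm[idx]), numeric(1))
  out <- tibble(ld_label = labs, min_dist_um = unname(d) * pixel_size_um)
  attr(out, "mean_um") <- mean(out$min_dist_um)
  out
}

#' Per-cell aggregates over one organelle kind
#'
#' Computes count, total/mean area, density (organelle area fraction of the
#' cell), count density (objects per 100 um^2 of cell) and feature means for
#' the organelles assigned to one cell. With no organelles, counts and
#' densities are 0 while the means are missing (`NA`), never silently zero.
#'
#' @param cell_area_um2 The cell's area (> 0).
#' @param organelles Tibble of [organelle_table()] rows assigned to the cell
#'   (possibly empty).
#' @param prefix Column prefix (`"mito"` or `"ld"`).
#' @return One-row tibble of aggregates.
#' @export
per_cell_stats <- function(cell_area_um2, organelles, prefix = "org") {
  if (!is.numeric(cell_area_um2) || cell_area_um2 <= 0) {
    data_error("cell area must be > 0")
  }
  n <- nrow(organelles)
  total <- if (n > 0) sum(organelles$area_um2) else 0
  out <- tibble(
    count = n,
    total_area_um2 = total,
    mean_area_um2 = if (n > 0) total / n else NA_real_,
    density = total / cell_area_um2,
    count_density = n / cell_area_um2 * 100,
    mean_circularity = if (n > 0) mean(organelles$circularity) else NA_real_,
    mean_eccentricity = if (n > 0) mean(organelles$eccentricity) else NA_real_,
    mean_perimeter_um = if (n > 0) mean(organelles$perimeter_um) else NA_real_,
    mean_intensity = if (n > 0) mean(organelles$mean_intensity) else NA_real_
  )
  setNames(out, paste(prefix, names(out), sep = "_"))
}

#' Feature dictionary for the per-cell table
#'
#' @return Tibble with `column`, `unit`, `description` for every column of
#'   [build_feature_table()] output, in the stable export order.
#' @export
feature_dictionary <- function() {
  tibble::tribble(
    ~column, ~unit, ~description,
    "cell", "id", "cell instance label",
    "cell_area_um2", "um^2", "cell area",
    "centroid_x", "px", "cell centroid x (column)",
    "centroid_y", "px", "cell centroid y (row)",
    "d_cv_um", "um", "centroid distance to nearest central-vein pixel",
    "d_pv_um", "um", "centroid distance to nearest portal-vessel pixel",
    "r", "unitless", "normalized CV distance d_cv/(d_cv+d_pv), 0 = pericentral",
    "bin", "1..n_bins", "zonal bin, 1 periportal .. n_bins pericentral",
    "mito_count", "count", "mitochondria per cell",
    "mito_total_area_um2", "um^2", "total mitochondrial area",
    "mito_mean_area_um2", "um^2", "mean mitochondrion area",
    "mito_density", "fraction", "mitochondrial area fraction of the cell",
    "mito_count_density", "per 100 um^2", "mitochondria per 100 um^2 of cell",
    "mito_mean_circularity", "unitless", "mean 4*pi*A/P^2",
    "mito_mean_eccentricity", "unitless", "mean moment eccentricity",
    "mito_mean_perimeter_um", "um", "mean mitochondrion perimeter",
    "mito_mean_intensity", "a.u.", "mean mitochondrial fluorescence",
    "ld_count", "count", "lipid droplets per cell",
    "ld_total_area_um2", "um^2", "total LD area",
    "ld_mean_area_um2", "um^2", "mean LD area",
    "ld_density", "fraction", "LD area fraction of the cell",
    "ld_count_density", "per 100 um^2", "LDs per 100 um^2 of cell",
    "ld_mean_circularity", "unitless", "mean LD circularity",
    "ld_mean_eccentricity", "unitless", "mean LD eccentricity",
    "ld_mean_perimeter_um", "um", "mean LD perimeter",
    "ld_mean_intensity", "a.u.", "mean LD fluorescence",
    "overlap_px", "px", "mitochondria-LD overlapping pixels in the cell",
    "overlap_pct", "%", "100 * overlap / LD pixels in the cell",
    "min_dist_um", "um", "mean over LDs of shortest distance to a mitochondrion"
  )
}

empty_feature_table <- function() {
  cols <- feature_dictionary()$column
  out <- as_tibble(setNames(rep(list(numeric(0)), length(cols)), cols))
  out$cell <- integer(0)
  out$bin <- integer(0)
  out
}

#' Build the per-cell feature table
#'
#' Orchestrates the full single-cell profiling chain on aligned masks: per
#' organelle morphometry, organelle-to-cell assignment, per-cell aggregates,
#' mitochondria-LD contact metrics (computed on the binary union of each
#' cell's assigned organelles; cross-cell contacts are ignored) and the
#' spatial position (normalized CV distance and zonal bin). Deterministic
#' given its inputs; an empty image yields an empty table with the full
#' header.
#'
#' @param cell_mask,mito_mask,ld_mask Instance masks of identical shape.
#' @param channels A [channel_stack()] (for mean intensities), or `NULL`.
#' @param veins A [vein_annotation()], or `NULL` to skip spatial columns.
#' @param config List of options: `pixel_size_um` (default from `channels`,
#'   else 1), `n_bins` (12), `min_fraction` (0.5), `perimeter` ("crofton").
#' @return Tibble with one row per cell; columns documented in
#'   [feature_dictionary()].
#' @export
build_feature_table <- function(cell_mask, mito_mask, ld_mask,
                                channels = NULL, veins = NULL,
                                config = list()) {
  check_same_shape(cell_mask, mito_mask, "cell and mito masks")
  check_same_shape(cell_mask, ld_mask, "cell and LD masks")
  ps <- config$pixel_size_um %||%
    (if (!is.null(channels)) channels$pixel_size_um else 1)
  n_bins <- config$n_bins %||% 12L
  min_fraction <- config$min_fraction %||% 0.5
  perim <- config$perimeter %||% "crofton"

  cell_px <- label_pixels(cell_mask)
  if (length(cell_px) == 0L) return(empty_feature_table())
  h <- nrow(cell_mask)

  mito_tbl <- organelle_table(mito_mask, ps,
                              intensity = channels$channels$mito,
                              kind = "mito", perimeter = perim)
  ld_tbl <- organelle_table(ld_mask, ps,
                            intensity = channels$channels$ld,
                            kind = "ld", perimeter = perim)
  mito_assign <- assign_organelles_to_cells(mito_mask, cell_mask, min_fraction)
  ld_assign <- assign_organelles_to_cells(ld_mask, cell_mask, min_fraction)
  mito_px <- label_pixels(mito_mask)
  ld_px <- label_pixels(ld_mask)

  rows <- lapply(names(cell_px), function(lab) {
    cell_id <- as.integer(lab)
    idx <- cell_px[[lab]]
    coords <- cbind(((idx - 1L) %% h) + 1L, ((idx - 1L) %/% h) + 1L)
    area <- length(idx) * ps^2
    cx <- mean(coords[, 2]); cy <- mean(coords[, 1])

    my_mito <- mito_assign$map$organelle[mito_assign$map$cell == cell_id]
    my_ld <- ld_assign$map$organelle[ld_assign$map$cell == cell_id]
    mstats <- per_cell_stats(area, mito_tbl[mito_tbl$label %in% my_mito, ], "mito")
    lstats <- per_cell_stats(area, ld_tbl[ld_tbl$label %in% my_ld, ], "ld")

    # contact metrics on the cell's bounding box
    r0 <- min(coords[, 1]); r1 <- max(coords[, 1])
    c0 <- min(coords[, 2]); c1 <- max(coords[, 2])
    bh <- r1 - r0 + 1L; bw <- c1 - c0 + 1L
    to_local <- function(lin_idx) {
      rr <- ((lin_idx - 1L) %% h) + 1L - r0 + 1L
      cc <- ((lin_idx - 1L) %/% h) + 1L - c0 + 1L
      keep <- rr >= 1L & rr <= bh & cc >= 1L & cc <= bw
      (cc[keep] - 1L) * bh + rr[keep]
    }
    m_bin <- matrix(FALSE, bh, bw)
    for (o in my_mito) m_bin[to_local(mito_px[[as.character(o)]])] <- TRUE
    l_bin <- matrix(FALSE, bh, bw)
    ld_local <- list()
    for (o in my_ld) {
      li <- to_local(ld_px[[as.character(o)]])
      l_bin[li] <- TRUE
      ld_local[[as.character(o)]] <- li
    }
    ov <- mito_ld_overlap(m_bin, l_bin)
    md <- mito_ld_min_distance(m_bin, ld_local, ps)

    dplyr::bind_cols(
      tibble(cell = cell_id, cell_area_um2 = area,
             centroid_x = cx, centroid_y = cy),
      mstats, lstats,
      tibble(overlap_px = ov$overlap_px, overlap_pct = ov$overlap_pct,
             min_dist_um = attr(md, "mean_um"))
    )
  })
  out <- dplyr::bind_rows(rows)

  if (!is.null(veins)) {
    sp <- normalized_cv_distance(tibble(x = out$centroid_x, y = out$centroid_y),
                                 veins, ps)
    out$d_cv_um <- sp$d_cv_um
    out$d_pv_um <- sp$d_pv_um
    out$r <- sp$r
    out$bin <- assign_bin(sp$r, n_bins)
  } else {
    out$d_cv_um <- NA_real_
    out$d_pv_um <- NA_real_
    out$r <- NA_real_
    out$bin <- NA_integer_
  }
  out[, feature_dictionary()$column]
}
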