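# Lobule coordinates: Euclidean distances to the vein masks, the normalized
# central-vein distance r = d_cv / (d_cv + d_pv), and the periportal (R1) to
# pericentral (R12) bin assignment.

#' Vein annotation for one lobule axis
#'
#' @param cv_mask Logical/0-1 matrix marking central-vein pixels (non-empty).
#' @param pv_masks A single logical matrix or a list of matrices marking one
#'   or more portal vessels (each non-empty, same shape as `cv_mask`).
#' @param roi Optional rectangle `c(x0, y0, x1, y1)` (pixels) delimiting a
#'   manually cropped periportal-pericentral axis.
#' @return Object of class `vein_annotation`.
#' @export
vein_annotation <- function(cv_mask, pv_masks, roi = NULL) {
  cv_mask <- cv_mask > 0
  if (!is.list(pv_masks)) pv_masks <- list(pv_masks)
  pv_masks <- lapply(pv_masks, function(m) m > 0)
  if (!any(cv_mask)) data_error("central-vein mask is empty")
  if (length(pv_masks) == 0 || !all(vapply(pv_masks, any, logical(1)))) {
    data_error("need at least one non-empty portal-vessel mask")
  }
  for (m in pv_masks) check_same_shape(cv_mask, m, "vein masks")
  if (!is.null(roi) && (length(roi) != 4 || roi[1] >= roi[3] || roi[2] >= roi[4])) {
    config_error("`roi` must be c(x0, y0, x1, y1) with x0 < x1, y0 < y1")
  }
  structure(list(cv = cv_mask, pv = pv_masks, roi = roi),
            class = "vein_annotation")
}

#' Build a vein annotation from a label image
#'
#' Label 1 marks the central vein; labels 2 and above mark portal vessels.
#'
#' @param label_mask Integer matrix.
#' @param roi Optional `c(x0, y0, x1, y1)` rectangle in pixels.
#' @return A [vein_annotation()].
#' @export
veins_from_labels <- function(label_mask, roi = NULL) {
  labs <- sort(unique(label_mask[label_mask > 0]))
  if (!1 %in% labs) data_error("vein label image has no label 1 (central vein)")
  pv <- lapply(setdiff(labs, 1), function(l) label_mask == l)
  vein_annotation(label_mask == 1, pv, roi = roi)
}

#' Euclidean distance maps to the vein masks
#'
#' Exact Euclidean distance (in microns) from every pixel to the nearest
#' central-vein pixel and to the nearest portal-vessel pixel (union over all
#' portal vessels). Distances are zero on vein pixels.
#'
#' @param veins A [vein_annotation()].
#' @param pixel_size_um Pixel size in um/px.
#' @return List with matrices `cv` and `pv` (um).
#' @export
distance_maps <- function(veins, pixel_size_um = 1) {
  if (!inherits(veins, "vein_annotation")) data_error("`veins` must be a vein_annotation")
  stopifnot_scalar_number(pixel_size_um, "pixel_size_um", positive = TRUE)
  pv_union <- Reduce(`|`, veins$pv)
  dm <- function(m) {
    EBImage::imageData(EBImage::distmap(EBImage::Image(1 - m))) * pixel_size_um
  }
  list(cv = dm(veins$cv), pv = dm(pv_union))
}

# exact distance from fractional points (x, y in px) to the nearest TRUE pixel
min_dist_to_mask <- function(x, y, mask) {
  px <- which(mask, arr.ind = TRUE)
  vapply(seq_along(x), function(i) {
    sqrt(min((px[, 1] - y[i])^2 + (px[, 2] - x[i])^2))
  }, numeric(1))
}

#' Normalized central-vein distance of cell centroids
#'
#' For each centroid the distance `d_cv` to the nearest central-vein pixel and
#' `d_pv` to the nearest portal-vessel pixel are measured, and the normalized
#' central-vein distance is `r = d_cv / (d_cv + d_pv)`, clamped to `[0, 1]`.
#' The normalization distance `D = d_cv + d_pv` is per cell, which reduces to
#' the straight-axis CV-PV distance when the cell lies on that segment and is
#' robust to curved axes. `r = 0` is pericentral (on the CV), `r = 1`
#' periportal.
#'
#' @param centroids Data frame with columns `x`, `y` (pixel coordinates,
#'   pixel centers at integer positions) or a numeric length-2 vector.
#' @param veins A [vein_annotation()].
#' @param pixel_size_um Pixel size (um/px) used to report distances in um.
#' @param method `"centroid"` (default) measures from the centroid point;
#'   `"boundary"` measures the minimum over the cell's own pixels and requires
#'   `cell_pixels` (list of `cbind(row, col)` matrices per cell).
#' @param cell_pixels Optional list of pixel coordinate matrices, one per
#'   centroid row, for `method = "boundary"`.
#' @return Tibble with `d_cv_um`, `d_pv_um`, `r`.
#' @export
normalized_cv_distance <- function(centroids, veins, pixel_size_um = 1,
                                   method = c("centroid", "boundary"),
                                   cell_pixels = NULL) {
  method <- match.arg(method)
  if (is.numeric(centroids) && length(centroids) == 2) {
    centroids <- tibble(x = centroids[1], y = centroids[2])
  }
  centroids <- as_tibble(centroids)
  if (!all(c("x", "y") %in% names(centroids))) {
    config_error("`centroids` needs columns `x` and `y`")
  }
  h <- nrow(veins$cv); w <- ncol(veins$cv)
  if (any(centroids$x < 0.5 | centroids$x > w + 0.5 |
            centroids$y < 0.5 | centroids$y > h + 0.5)) {
    data_error("centroid outside the image")
  }
  pv_union <- Reduce(`|`, veins$pv)
  if (method == "centroid") {
    d_cv <- min_dist_to_mask(centroids$x, centroids$y, veins$cv)
    d_pv <- min_dist_to_mask(centroids$x, centroids$y, pv_union)
  } else {
    if (is.null(cell_pixels)) config_error("method 'boundary' needs `cell_pixels`")
    maps <- distance_maps(veins, 1)
    d_cv <- vapply(cell_pixels, function(rc) min(maps$cv[rc]), numeric(1))
    d_pv <- vapply(cell_pixels, function(rc) min(maps$pv[rc]), numeric(1))
  }
  D <- d_cv + d_pv
  if (any(D == 0)) {
    data_error("centroid lies on both vein masks; normalization undefined")
  }
  tibble(d_cv_um = d_cv * pixel_size_um,
         d_pv_um = d_pv * pixel_size_um,
         r = clamp(d_cv / D, 0, 1))
}

#' Assign periportal-to-pericentral bins from normalized CV distance
#'
#' `bin = clamp(n_bins - floor(n_bins * r), 1, n_bins)`: bin `n_bins` (R12 by
#' default) is closest to the central vein (`r = 0`), bin 1 (R1) closest to
#' the portal vessels (`r = 1`). The bin index is monotone non-increasing in
#' `r` with deterministic half-open boundaries.
#'
#' @param r Numeric vector in `[0, 1]`.
#' @param n_bins Number of bins (default 12).
#' @return Integer vector of bins in `1..n_bins`.
#' @examples
#' assign_bin(c(0, 0.49, 1), 12) # 12, 7, 1
#' @export
assign_bin <- function(r, n_bins = 12L) {
  if (!is.numeric(n_bins) || length(n_bins) != 1L || n_bins < 1) {
    config_error("`n_bins` must be a single integer >= 1")
  }
  if (any(!is.finite(r)) || any(r < 0 | r > 1)) {
    data_error("`r` must lie in [0, 1]")
  }
  n_bins <- as.integer(n_bins)
  as.integer(clamp(n_bins - floor(n_bins * r), 1L, n_bins))
}

#' Axis length and hepatocyte count for one PP-PC axis
#'
#' The axis length is the distance from the central-vein mask centroid to the
#' nearest portal-vessel mask centroid. Cells are counted inside the
#' annotation's `roi` rectangle when present, otherwise inside a band of
#' half-width `band_halfwidth_um` around the straight CV-PV centroid segment
#' (one hepatocyte radius by default, so a single row of cells is counted).
#'
#' @param cells Data frame of cell centroids with columns `x`, `y` (pixels).
#' @param veins A [vein_annotation()].
#' @param pixel_size_um Pixel size in um/px.
#' @param band_halfwidth_um Half-width of the default axis band (um).
#' @return Tibble with `axis_length_um` and `n_cells`.
#' @export
axis_summary <- function(cells, veins, pixel_size_um = 1,
                         band_halfwidth_um = 8) {
  cells <- as_tibble(cells)
  if (nrow(cells) == 0) data_error("need at least one cell")
  centroid_of <- function(m) {
    rc <- which(m, arr.ind = TRUE)
    c(x = mean(rc[, 2]), y = mean(rc[, 1]))
  }
  cv_c <- centroid_of(veins$cv)
  pv_cs <- lapply(veins$pv, centroid_of)
  d <- vapply(pv_cs, function(p) sqrt(sum((p - cv_c)^2)), numeric(1))
  pv_c <- pv_cs[[which.min(d)]]
  axis_len <- min(d) * pixel_size_um

  if (!is.null(veins$roi)) {
    roi <- veins$roi
    inside <- cells$x >= roi[1] & cells$x <= roi[3] &
      cells$y >= roi[2] & cells$y <= roi[4]
    if (!any(inside) && nrow(cells) > 0 && prod(roi[3:4] - roi[1:2]) <= 0) {
      data_error("empty ROI")
    }
  } else {
    # perpendicular distance to the CV-PV centroid segment
    v <- pv_c - cv_c
    len2 <- sum(v^2)
    t <- ((cells$x - cv_c[["x"]]) * v[["x"]] + (cells$y - cv_c[["y"]]) * v[["y"]]) / len2
    t <- clamp(t, 0, 1)
    px <- cv_c[["x"]] + t * v[["x"]]
    py <- cv_c[["y"]] + t * v[["y"]]
    perp <- sqrt((cells$x - px)^2 + (cells$y - py)^2) * pixel_size_um
    inside <- perp <= band_halfwidth_um
  }
  tibble(axis_length_um = axis_len, n_cells = sum(inside))
}
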