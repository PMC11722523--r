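# Per-object morphometry: pixel-count area, Crofton perimeter, circularity
# 4*pi*A/P^2, and moment eccentricity sqrt(1 - lambda_min/lambda_max).

# 8-direction Cauchy-Crofton perimeter estimate of a logical matrix.
# For each line family (direction v, line spacing 1/|v|) the number of
# foreground/background transitions along v counts boundary crossings; half
# the crossings times the spacing estimates the object's breadth
# perpendicular to v. Breadths are integrated over orientation with weights
# proportional to the angular gaps between the sampled directions
# (P = integral of breadth over [0, pi)). Eight directions (axes, diagonals
# and knight moves) keep the worst-case anisotropy bias below ~1.5%, against
# ~6% for the four-direction variant on an axis-aligned square.
crofton_perimeter <- function(m) {
  m <- m > 0
  h <- nrow(m); w <- ncol(m)
  pad <- matrix(FALSE, h + 8L, w + 8L)
  pad[5:(h + 4L), 5:(w + 4L)] <- m
  dirs <- rbind(c(0, 1), c(1, 0), c(1, 1), c(1, -1),
                c(1, 2), c(2, 1), c(1, -2), c(2, -1))
  crossings <- apply(dirs, 1, function(v) {
    H <- nrow(pad); W <- ncol(pad)
    r0 <- (1 + max(0, -v[1])):(H - max(0, v[1]))
    c0 <- (1 + max(0, -v[2])):(W - max(0, v[2]))
    sum(pad[r0, c0] != pad[r0 + v[1], c0 + v[2]])
  })
  spacing <- 1 / sqrt(rowSums(dirs^2))
  # the digital grid misses about (|dy| + |dx| - 1) boundary-grazing lines
  # per oblique family; credit half of them as an end correction
  end_corr <- (abs(dirs[, 1]) + abs(dirs[, 2]) - 1) / 2
  # breadth angle of each family = direction perpendicular to v, mod pi
  ang <- (atan2(dirs[, 1], dirs[, 2]) + pi / 2) %% pi
  ord <- order(ang)
  a <- ang[ord]
  gaps <- diff(c(a, a[1] + pi))
  wts <- (gaps + c(gaps[length(gaps)], gaps[-length(gaps)])) / 2
  breadth <- (crossings[ord] / 2 + end_corr[ord]) * spacing[ord]
  sum(wts * breadth)
}

# perimeter as weighted boundary-step count (chain-code style alternative)
boundary_step_perimeter <- function(m) {
  m <- m > 0
  h <- nrow(m); w <- ncol(m)
  pad <- matrix(FALSE, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- m
  n_ax <- sum(pad[-1, ] != pad[-nrow(pad), ]) + sum(pad[, -1] != pad[, -ncol(pad)])
  # calibrate the exposed-edge count toward Euclidean length
  n_ax * pi / 4
}

second_moment_eccentricity <- function(rows, cols) {
  n <- length(rows)
  if (n < 2L) return(0)
  dy <- rows - mean(rows); dx <- cols - mean(cols)
  mu20 <- sum(dx^2) / n; mu02 <- sum(dy^2) / n; mu11 <- sum(dx * dy) / n
  tr <- mu20 + mu02
  det <- mu20 * mu02 - mu11^2
  disc <- sqrt(max(0, (tr / 2)^2 - det))
  l_max <- tr / 2 + disc
  l_min <- max(0, tr / 2 - disc)
  if (l_max <= 0) return(0)
  sqrt(clamp(1 - l_min / l_max, 0, 1))
}

#' Geometric and intensity features of one labeled region
#'
#' Area is the pixel count times the squared pixel size; the perimeter is a
#' Crofton-style estimate over eight line directions (or a calibrated
#' boundary-step count with `perimeter = "boundary"`); circularity is
#' `4*pi*A/P^2`, clipped at 1.1 to absorb rasterization overshoot;
#' eccentricity comes from the eigenvalues of the second central moment
#' matrix, `sqrt(1 - lambda_min/lambda_max)`.
#'
#' @param pixels Integer matrix `cbind(row, col)` of the region's pixels, or
#'   a logical matrix.
#' @param pixel_size_um Pixel size in um/px.
#' @param intensity Optional intensity image (same frame as the pixel
#'   coordinates) for the mean intensity.
#' @param perimeter `"crofton"` (default) or `"boundary"`.
#' @return One-row tibble: `area_um2`, `perimeter_um`, `circularity`,
#'   `eccentricity`, `mean_intensity`, `centroid_x`, `centroid_y` (pixel
#'   coordinates, pixel centers at integer positions).
#' @examples
#' disk <- disk_mask(45, 45, 23, 23, 20)
#' object_geometry(disk, pixel_size_um = 1)$circularity
#' @export
object_geometry <- function(pixels, pixel_size_um = 1, intensity = NULL,
                            perimeter = c("crofton", "boundary")) {
  perimeter <- match.arg(perimeter)
  if (is.logical(pixels) || (is.matrix(pixels) && !is.null(dim(pixels)) &&
                               ncol(pixels) != 2L)) {
    coords <- which(pixels > 0, arr.ind = TRUE)
  } else {
    coords <- pixels
  }
  if (is.null(dim(coords)) || nrow(coords) == 0L) {
    data_error("empty region has no geometry")
  }
  v <- geometry_core(coords[, 1], coords[, 2], pixel_size_um, intensity,
                     perimeter)
  as_tibble(as.list(v))
}

# workhorse behind object_geometry()/organelle_table(): named numeric vector
geometry_core <- function(rows, cols, pixel_size_um, intensity, perimeter) {
  n <- length(rows)
  r0 <- min(rows); c0 <- min(cols)
  loc <- matrix(FALSE, max(rows) - r0 + 1L, max(cols) - c0 + 1L)
  loc[cbind(rows - r0 + 1L, cols - c0 + 1L)] <- TRUE
  P_px <- if (perimeter == "crofton") crofton_perimeter(loc) else
    boundary_step_perimeter(loc)
  area <- n * pixel_size_um^2
  P <- P_px * pixel_size_um
  circ <- if (P > 0) min(4 * pi * area / P^2, 1.1) else NA_real_
  mean_int <- if (is.null(intensity)) NA_real_ else
    mean(intensity[cbind(rows, cols)])
  c(area_um2 = area, perimeter_um = P, circularity = circ,
    eccentricity = second_moment_eccentricity(rows, cols),
    mean_intensity = mean_int,
    centroid_x = mean(cols), centroid_y = mean(rows))
}

#' Per-object morphometry for every label of an instance mask
#'
#' @param mask Instance mask (integer matrix, 0 = background).
#' @param pixel_size_um Pixel size in um/px.
#' @param intensity Optional intensity image for per-object mean intensity.
#' @param kind Optional organelle kind recorded in the output (`"mito"`,
#'   `"ld"`, ...).
#' @param perimeter Perimeter estimator, see [object_geometry()].
#' @return Tibble with one row per label: `label`, `kind`, plus the
#'   [object_geometry()] columns.
#' @export
organelle_table <- function(mask, pixel_size_um = 1, intensity = NULL,
                            kind = NA_character_,
                            perimeter = c("crofton", "boundary")) {
  perimeter <- match.arg(perimeter)
  px <- label_pixels(mask)
  if (length(px) == 0L) {
    return(tibble(label = integer(), kind = character(), area_um2 = numeric(),
                  perimeter_um = numeric(), circularity = numeric(),
                  eccentricity = numeric(), mean_intensity = numeric(),
                  centroid_x = numeric(), centroid_y = numeric()))
  }
  h <- nrow(mask)
  vals <- vapply(px, function(idx) {
    geometry_core(((idx - 1L) %% h) + 1L, ((idx - 1L) %/% h) + 1L,
                  pixel_size_um, intensity, perimeter)
  }, numeric(7))
  out <- as_tibble(as.data.frame(t(vals)))
  out$label <- as.integer(names(px))
  out$kind <- kind
  dplyr::relocate(out, "label", "kind")
}
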