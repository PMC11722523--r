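# Synthetic lobule generator: rasterized ground-truth masks plus rendered
# fluorescence channels. Cells are Voronoi-like convex regions seeded in rows
# along the CV-PV axis; organelles are rasterized disks (LDs) and ellipses
# (mitochondria). Mitochondria-LD contact is realized at placement time by
# centering a contacting LD close enough to a mitochondrion pixel that the two
# masks share at least one pixel.

#' Rasterize a disk mask
#'
#' @param h,w Image height and width in pixels.
#' @param cx,cy Disk center (pixel coordinates, x = column, y = row).
#' @param radius Radius in pixels.
#' @return Logical matrix.
#' @export
disk_mask <- function(h, w, cx, cy, radius) {
  outer((seq_len(h) - cy)^2, (seq_len(w) - cx)^2, "+") <= radius^2
}

# (dy, dx) integer offsets covering a rotated ellipse with semi-axes a >= b
ellipse_offsets <- function(a, b, theta = 0) {
  R <- max(1L, ceiling(a))
  g <- expand.grid(dy = -R:R, dx = -R:R)
  u <- g$dx * cos(theta) + g$dy * sin(theta)
  v <- -g$dx * sin(theta) + g$dy * cos(theta)
  keep <- (u / a)^2 + (v / b)^2 <= 1
  if (!any(keep)) keep[g$dy == 0 & g$dx == 0] <- TRUE
  cbind(dy = g$dy[keep], dx = g$dx[keep])
}

disk_offsets <- function(radius) ellipse_offsets(radius, radius, 0)

# linear indices of offsets placed at (row, col), restricted to the image
offset_indices <- function(row, col, offsets, h, w) {
  rr <- row + offsets[, 1L]
  cc <- col + offsets[, 2L]
  ok <- rr >= 1L & rr <= h & cc >= 1L & cc <= w
  (cc[ok] - 1L) * h + rr[ok]
}

# true normalized CV distance of a point, from the analytic vein geometry
true_r_of_point <- function(x, y, spec) {
  d_cv <- max(0, sqrt((x - spec$cv_center[["x"]])^2 +
                        (y - spec$cv_center[["y"]])^2) - spec$cv_radius)
  d_pv <- min(vapply(seq_along(spec$pv_centers), function(i) {
    max(0, sqrt((x - spec$pv_centers[[i]][["x"]])^2 +
                  (y - spec$pv_centers[[i]][["y"]])^2) - spec$pv_radii[i])
  }, numeric(1)))
  if (d_cv + d_pv <= 0) return(0)
  clamp(d_cv / (d_cv + d_pv), 0, 1)
}

place_cell_seeds <- function(spec) {
  h <- spec$image_shape[1]; w <- spec$image_shape[2]
  cr <- spec$cell_radius_px
  x_start <- spec$cv_center[["x"]] + spec$cv_radius
  x_end <- min(vapply(seq_along(spec$pv_centers),
                      function(i) spec$pv_centers[[i]][["x"]] - spec$pv_radii[i],
                      numeric(1)))
  gap <- x_end - x_start
  n <- spec$n_cells_per_axis
  slot <- gap / n
  if (2 * cr > slot * 1.05) {
    abort(sprintf(paste0(
      "cells cannot be packed without overlap: %d cells of radius %.1f px ",
      "need %.1f px along an axis gap of %.1f px"),
      n, cr, 2 * cr * n, gap), class = "lobulemap_placement_error")
  }
  rows <- spec$n_cell_rows
  pitch <- 2 * cr
  grid <- expand.grid(i = seq_len(n), row = seq_len(rows))
  x <- x_start + (grid$i - 0.5) * slot +
    runif(nrow(grid), -0.08, 0.08) * slot
  y <- spec$cv_center[["y"]] + (grid$row - (rows + 1) / 2) * pitch +
    runif(nrow(grid), -0.1, 0.1) * cr
  tibble(cell = seq_len(nrow(grid)), x = x, y = y,
         row = grid$row, axis_index = grid$i)
}

# Voronoi assignment of pixels to seeds, capped at a maximum radius and
# excluding vein pixels
voronoi_cells <- function(seeds, spec, exclude) {
  h <- spec$image_shape[1]; w <- spec$image_shape[2]
  cap2 <- (1.3 * spec$cell_radius_px)^2
  best_d2 <- matrix(Inf, h, w)
  best_id <- matrix(0L, h, w)
  rows2 <- seq_len(h)
  cols2 <- seq_len(w)
  for (k in seq_len(nrow(seeds))) {
    d2 <- outer((rows2 - seeds$y[k])^2, (cols2 - seeds$x[k])^2, "+")
    upd <- d2 < best_d2
    best_d2[upd] <- d2[upd]
    best_id[upd] <- k
  }
  best_id[best_d2 > cap2] <- 0L
  best_id[exclude] <- 0L
  best_id
}

#' Simulate a synthetic lobule
#'
#' Renders a three-channel (mitochondria, lipid droplets, actin) image of a
#' synthetic liver lobule together with full ground truth: instance masks for
#' cells, mitochondria and LDs, the vein annotation, each cell's true
#' normalized CV distance and bin, and per-organelle contact flags. Identical
#' `(spec, seed)` pairs give bit-identical output.
#'
#' Per-cell organelle counts are Poisson draws from the spec's gradients
#' evaluated at the cell's true `r`; mitochondria sizes follow the
#' `mito_area_fraction` gradient given the drawn count and elongation. A
#' "contacting" LD is placed so that it shares at least one pixel with a
#' mitochondrion of the same cell; contact flags in the returned ground truth
#' are re-derived from the final masks, so they are consistent with pixel
#' overlap by construction.
#'
#' Channel values lie on the 16-bit grid (multiples of 1/65535) so TIFF round
#' trips are bit-identical. With `noise$sigma = 0` an organelle channel is
#' exactly `background` off-organelle and exactly the organelle intensity on
#' ground-truth pixels.
#'
#' @param spec A [lobule_spec()].
#' @param seed Integer seed; defaults to `spec$seed`.
#' @return A list with elements `channels` (a `channel_stack`) and `truth`
#'   (class `lobule_truth`: `cell_mask`, `mito_mask`, `ld_mask`, `veins`,
#'   `cells`, `organelles`, `spec`, `seed`).
#' @examples
#' sim <- simulate_lobule(lobule_spec(list(n_cells_per_axis = 6,
#'                                         n_cell_rows = 2,
#'                                         axis_length_um = 100)), seed = 1)
#' nrow(sim$truth$cells)
#' @export
simulate_lobule <- function(spec, seed = spec$seed) {
  if (!inherits(spec, "lobule_spec")) config_error("`spec` must be a lobule_spec")
  set.seed(as.integer(seed))
  h <- spec$image_shape[1]; w <- spec$image_shape[2]

  cv_mask <- disk_mask(h, w, spec$cv_center[["x"]], spec$cv_center[["y"]],
                       spec$cv_radius)
  pv_masks <- lapply(seq_along(spec$pv_centers), function(i) {
    disk_mask(h, w, spec$pv_centers[[i]][["x"]], spec$pv_centers[[i]][["y"]],
              spec$pv_radii[i])
  })
  vein_any <- Reduce(`|`, pv_masks, cv_mask)

  seeds <- place_cell_seeds(spec)
  cell_mask <- voronoi_cells(seeds, spec, exclude = vein_any)

  cells <- seeds
  cells$r_true <- vapply(seq_len(nrow(cells)),
                         function(k) true_r_of_point(cells$x[k], cells$y[k], spec),
                         numeric(1))
  cells$bin <- assign_bin(cells$r_true, 12L)

  cell_px <- label_pixels(cell_mask)
  mito_mask <- matrix(0L, h, w)
  ld_mask <- matrix(0L, h, w)
  # per-organelle records accumulated as parallel chunks (one per cell)
  rec <- list(label = list(), kind = list(), cell = list(),
              contact = list(), area = list())
  push_rec <- function(label, kind, cell, contact, area) {
    i <- length(rec$label) + 1L
    rec$label[[i]] <<- label; rec$kind[[i]] <<- kind
    rec$cell[[i]] <<- cell; rec$contact[[i]] <<- contact
    rec$area[[i]] <<- area
  }
  mito_lab <- 0L
  ld_lab <- 0L

  for (k in seq_len(nrow(cells))) {
    px <- cell_px[[as.character(k)]]
    if (is.null(px) || length(px) < 50L) next
    r <- cells$r_true[k]
    area_px <- length(px)
    # pixel -> (row, col)
    prow <- ((px - 1L) %% h) + 1L
    pcol <- ((px - 1L) %/% h) + 1L

    n_mito <- rpois(1L, eval_gradient(spec$gradients$mito_count, r, "mito_count"))
    elong <- max(1, eval_gradient(spec$gradients$mito_elongation, r, "mito_elongation"))
    maf <- eval_gradient(spec$gradients$mito_area_fraction, r, "mito_area_fraction")
    cell_mito <- integer(0)
    cell_mito_px <- list()
    if (n_mito > 0L && maf > 0) {
      target_area <- maf * area_px / n_mito
      for (m in seq_len(n_mito)) {
        a_px <- max(2, target_area * rlnorm(1L, 0, 0.2))
        b_ax <- max(0.9, sqrt(a_px / (pi * elong)))
        a_ax <- b_ax * elong
        theta <- runif(1L, 0, pi)
        off <- ellipse_offsets(a_ax, b_ax, theta)
        placed <- FALSE
        for (try in seq_len(20L)) {
          j <- sample.int(area_px, 1L)
          idx <- offset_indices(prow[j], pcol[j], off, h, w)
          idx <- idx[cell_mask[idx] == k]
          if (length(idx) < 0.7 * nrow(off)) next
          if (any(mito_mask[idx] > 0L)) next
          mito_lab <- mito_lab + 1L
          mito_mask[idx] <- mito_lab
          cell_mito <- c(cell_mito, mito_lab)
          cell_mito_px[[as.character(mito_lab)]] <- idx
          push_rec(mito_lab, "mito", k, NA, length(idx))
          placed <- TRUE
          break
        }
      }
    }

    n_ld <- rpois(1L, eval_gradient(spec$gradients$ld_count, r, "ld_count"))
    cf <- eval_gradient(spec$gradients$contact_fraction, r, "contact_fraction")
    if (n_ld > 0L) {
      radii <- pmax(1.2, eval_gradient(spec$gradients$ld_radius_um, r, "ld_radius_um") /
                      spec$pixel_size_um * rlnorm(n_ld, 0, 0.15))
      contact <- rbinom(n_ld, 1L, cf) == 1L & length(cell_mito) > 0L
      for (m in seq_len(n_ld)) {
        off <- disk_offsets(radii[m])
        placed_idx <- NULL
        if (contact[m]) {
          anchor <- cell_mito_px[[as.character(sample(cell_mito, 1L))]]
          for (try in seq_len(20L)) {
            p <- anchor[sample.int(length(anchor), 1L)]
            phi <- runif(1L, 0, 2 * pi)
            shift <- max(0, radii[m] - spec$contact_overlap_px)
            row0 <- ((p - 1L) %% h) + 1L + round(shift * sin(phi))
            col0 <- ((p - 1L) %/% h) + 1L + round(shift * cos(phi))
            idx <- offset_indices(row0, col0, off, h, w)
            idx <- idx[cell_mask[idx] == k]
            if (length(idx) < 0.6 * nrow(off)) next
            if (any(ld_mask[idx] > 0L)) next
            if (!any(mito_mask[idx] > 0L)) next
            placed_idx <- idx
            break
          }
          if (is.null(placed_idx)) {
            # fallback: center on mitochondrion pixels until the clipped
            # droplet still shares at least one pixel with a mitochondrion;
            # droplets that cannot realize contact are skipped, never placed
            # contact-free
            for (p in anchor[sample.int(length(anchor))]) {
              idx <- offset_indices(((p - 1L) %% h) + 1L, ((p - 1L) %/% h) + 1L,
                                    off, h, w)
              idx <- idx[cell_mask[idx] == k & ld_mask[idx] == 0L]
              if (length(idx) > 0L && any(mito_mask[idx] > 0L)) {
                placed_idx <- idx
                break
              }
            }
          }
        } else {
          for (try in seq_len(20L)) {
            j <- sample.int(area_px, 1L)
            idx <- offset_indices(prow[j], pcol[j], off, h, w)
            idx <- idx[cell_mask[idx] == k]
            if (length(idx) < 0.6 * nrow(off)) next
            if (any(ld_mask[idx] > 0L)) next
            if (try <= 14L && any(mito_mask[idx] > 0L)) next
            placed_idx <- idx
            break
          }
        }
        if (is.null(placed_idx)) next
        ld_lab <- ld_lab + 1L
        ld_mask[placed_idx] <- ld_lab
        push_rec(ld_lab, "ld", k, contact[m], length(placed_idx))
      }
    }
  }

  organelles <- tibble(
    label = as.integer(unlist(rec$label)),
    kind = as.character(unlist(rec$kind)),
    cell = as.integer(unlist(rec$cell)),
    contact_intended = as.logical(unlist(rec$contact)),
    area_px = as.integer(unlist(rec$area))
  )
  # realized contact from the final masks
  ld_px <- label_pixels(ld_mask)
  organelles$contact_realized <- NA
  is_ld <- organelles$kind == "ld"
  organelles$contact_realized[is_ld] <- vapply(
    organelles$label[is_ld],
    function(l) any(mito_mask[ld_px[[as.character(l)]]] > 0L),
    logical(1)
  )

  channels <- render_channels(spec, cell_mask, mito_mask, ld_mask)
  veins <- vein_annotation(cv_mask, pv_masks)

  truth <- structure(list(
    cell_mask = cell_mask, mito_mask = mito_mask, ld_mask = ld_mask,
    veins = veins, cells = cells, organelles = organelles,
    spec = spec, seed = as.integer(seed)
  ), class = "lobule_truth")
  list(channels = channels, truth = truth)
}

render_channels <- function(spec, cell_mask, mito_mask, ld_mask) {
  h <- spec$image_shape[1]; w <- spec$image_shape[2]
  bg <- spec$noise$background
  it <- spec$intensities

  mito_ch <- matrix(bg, h, w); mito_ch[mito_mask > 0L] <- it$mito
  ld_ch <- matrix(bg, h, w); ld_ch[ld_mask > 0L] <- it$ld
  actin_ch <- matrix(bg, h, w)
  actin_ch[cell_mask > 0L] <- it$actin_interior
  actin_ch[label_boundaries(cell_mask)] <- it$actin_ridge

  add_noise <- function(x) {
    if (isTRUE(spec$noise$poisson)) {
      x <- rpois(length(x), x * 200) / 200
      dim(x) <- c(h, w)
    }
    if (spec$noise$sigma > 0) x <- x + rnorm(length(x), 0, spec$noise$sigma)
    round(clamp(x, 0, 1) * 65535) / 65535
  }
  channel_stack(mito = add_noise(mito_ch), ld = add_noise(ld_ch),
                actin = add_noise(actin_ch), pixel_size_um = spec$pixel_size_um)
}

# pixels whose 4-neighborhood crosses an instance-label boundary
label_boundaries <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  b <- matrix(FALSE, h, w)
  fg <- mask > 0L
  d <- mask[-1, ] != mask[-h, ]
  b[-1, ][d] <- TRUE; b[-h, ][d] <- TRUE
  d <- mask[, -1] != mask[, -w]
  b[, -1][d] <- TRUE; b[, -w][d] <- TRUE
  b & fg
}
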