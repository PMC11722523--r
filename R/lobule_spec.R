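#' Build a synthetic lobule specification
#'
#' A `lobule_spec` describes the geometry, zonal gradients and noise model of a
#' synthetic liver lobule: one central vein (CV) and one portal vessel (PV)
#' whose centers sit `axis_length_um` apart, with hepatocytes packed in rows
#' along the periportal-to-pericentral axis. Zonal gradients are expressed as
#' functions of the normalized central-vein distance `r` (0 = pericentral at
#' the CV, 1 = periportal at the PV).
#'
#' Gradients may be given either as a length-2 numeric `c(pc = , pp = )`
#' (linear interpolation from the value at `r = 0` to the value at `r = 1`)
#' or as a function of `r`. Evaluated gradients are clamped to be
#' non-negative; `contact_fraction` is additionally clamped to `[0, 1]`.
#'
#' Default geometry: a 250 um CV-PV center distance with 14 hepatocytes per
#' axis (the mid-point of the 12-16 cells typically spanning an axis) at a
#' pixel size of 0.2 um/px. The pixel size is a configurable stand-in, since
#' acquisition settings vary between microscopes.
#'
#' @param overrides Named list of fields to override. Unknown field names are
#'   an error. Pixel-unit geometry (`image_shape`, `cv_center`, `cv_radius`,
#'   `pv_centers`, `pv_radii`, `cell_radius_px`) is derived from the
#'   micron-unit fields unless overridden explicitly.
#'
#' @return A validated object of class `lobule_spec`.
#'
#' @examples
#' spec <- lobule_spec()
#' spec$axis_length_um
#' spec2 <- lobule_spec(list(pixel_size_um = 0.5, cell_radius_um = 10))
#' spec2$cell_radius_px # 20
#' @export
lobule_spec <- function(overrides = list()) {
  defaults <- list(
    pixel_size_um      = 0.2,
    axis_length_um     = 250,
    cv_radius_um       = 15,
    pv_radius_um       = 10,
    margin_um          = 8,
    n_cells_per_axis   = 14,
    n_cell_rows        = 5,
    cell_radius_um     = 7.5,
    image_shape        = NULL,   # c(H, W) px; derived when NULL
    cv_center          = NULL,   # c(x, y) px
    cv_radius          = NULL,   # px
    pv_centers         = NULL,   # list of c(x, y) px
    pv_radii           = NULL,   # px
    cell_radius_px     = NULL,
    gradients = list(
      ld_count           = c(pc = 10,   pp = 1),
      ld_radius_um       = c(pc = 0.8,  pp = 0.5),
      mito_count         = c(pc = 30,   pp = 18),
      mito_elongation    = c(pc = 2.4,  pp = 1.2),
      mito_area_fraction = c(pc = 0.15, pp = 0.08),
      contact_fraction   = c(pc = 0.35, pp = 0)
    ),
    noise = list(sigma = 0.02, background = 0.03, poisson = FALSE),
    intensities = list(mito = 0.85, ld = 0.9,
                       actin_interior = 0.15, actin_ridge = 0.95),
    contact_overlap_px = 1.5,
    seed = 1L
  )

  if (!is.list(overrides)) config_error("`overrides` must be a named list")
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown) > 0) {
    config_error(paste0("unknown lobule_spec field(s): ",
                        paste(unknown, collapse = ", ")))
  }
  spec <- modifyList(defaults, overrides)
  if (!is.null(overrides$gradients)) {
    # replace, not merge element-wise beyond named entries
    spec$gradients <- modifyList(defaults$gradients, overrides$gradients)
  }

  stopifnot_scalar_number(spec$pixel_size_um, "pixel_size_um", positive = TRUE)
  stopifnot_scalar_number(spec$axis_length_um, "axis_length_um", positive = TRUE)
  stopifnot_scalar_number(spec$cell_radius_um, "cell_radius_um", positive = TRUE)
  if (!is.numeric(spec$n_cells_per_axis) || spec$n_cells_per_axis < 1) {
    config_error("`n_cells_per_axis` must be >= 1")
  }
  spec$n_cells_per_axis <- as.integer(spec$n_cells_per_axis)
  if (!is.numeric(spec$n_cell_rows) || spec$n_cell_rows < 1) {
    config_error("`n_cell_rows` must be >= 1")
  }

  ps <- spec$pixel_size_um
  um2px <- function(x) x / ps
  if (is.null(spec$cell_radius_px)) spec$cell_radius_px <- um2px(spec$cell_radius_um)
  if (is.null(spec$cv_radius)) spec$cv_radius <- um2px(spec$cv_radius_um)
  if (is.null(spec$pv_radii)) spec$pv_radii <- um2px(spec$pv_radius_um)
  margin_px <- um2px(spec$margin_um)
  axis_px <- um2px(spec$axis_length_um)

  if (is.null(spec$cv_center)) {
    band_h <- 2 * spec$cell_radius_px * spec$n_cell_rows
    h <- ceiling(max(band_h, 2 * spec$cv_radius) + 2 * margin_px)
    spec$cv_center <- c(x = margin_px + spec$cv_radius, y = h / 2)
  }
  if (is.null(spec$pv_centers)) {
    spec$pv_centers <- list(c(x = spec$cv_center[["x"]] + axis_px,
                              y = spec$cv_center[["y"]]))
  }
  if (!is.list(spec$pv_centers)) spec$pv_centers <- list(spec$pv_centers)
  if (length(spec$pv_radii) == 1L) {
    spec$pv_radii <- rep(spec$pv_radii, length(spec$pv_centers))
  }
  if (is.null(spec$image_shape)) {
    max_x <- max(vapply(seq_along(spec$pv_centers),
                        function(i) spec$pv_centers[[i]][["x"]] + spec$pv_radii[i],
                        numeric(1)))
    band_h <- 2 * spec$cell_radius_px * spec$n_cell_rows
    h <- ceiling(max(band_h, 2 * spec$cv_radius) + 2 * margin_px)
    spec$image_shape <- c(H = as.integer(h), W = as.integer(ceiling(max_x + margin_px)))
  }

  validate_lobule_spec(structure(spec, class = "lobule_spec"))
}

validate_lobule_spec <- function(spec) {
  if (any(spec$image_shape <= 0)) config_error("`image_shape` must be positive")
  if (spec$cv_radius <= 0 || any(spec$pv_radii <= 0)) {
    config_error("vein radii must be positive")
  }
  if (spec$cell_radius_px <= 0) config_error("cell radius must be positive")
  # CV and PV disks must be disjoint
  for (i in seq_along(spec$pv_centers)) {
    d <- sqrt(sum((spec$pv_centers[[i]] - spec$cv_center)^2))
    if (d <= spec$cv_radius + spec$pv_radii[i]) {
      config_error("central vein and portal vessel masks must be disjoint")
    }
  }
  need <- c("ld_count", "ld_radius_um", "mito_count", "mito_elongation",
            "mito_area_fraction", "contact_fraction")
  missing <- setdiff(need, names(spec$gradients))
  if (length(missing) > 0) {
    config_error(paste0("missing gradient(s): ", paste(missing, collapse = ", ")))
  }
  rr <- seq(0, 1, by = 0.01)
  for (nm in need) {
    g <- spec$gradients[[nm]]
    # function gradients are validated on their raw values; the linear
    # c(pc, pp) form is clamped by eval_gradient() as documented
    v <- if (is.function(g)) g(rr) else eval_gradient(g, rr, nm)
    if (any(!is.finite(v)) || (is.function(g) && any(v < 0))) {
      config_error(sprintf("gradient `%s` must be finite and non-negative on [0, 1]", nm))
    }
    if (nm == "contact_fraction" && any(v > 1)) {
      config_error("`contact_fraction` gradient must stay within [0, 1]")
    }
  }
  if (spec$noise$sigma < 0 || spec$noise$background < 0) {
    config_error("noise sigma and background must be non-negative")
  }
  spec
}

#' Evaluate a zonal gradient at normalized CV distance r
#'
#' @param g Either a length-2 numeric `c(pc, pp)` (linear from `r = 0` to
#'   `r = 1`) or a function of `r`.
#' @param r Numeric vector in `[0, 1]`.
#' @param name Gradient name (controls clamping: `contact_fraction` is clamped
#'   to `[0, 1]`, everything else to `>= 0`).
#' @return Numeric vector of evaluated, clamped gradient values.
#' @export
eval_gradient <- function(g, r, name = "") {
  v <- if (is.function(g)) {
    g(r)
  } else if (is.numeric(g) && length(g) == 2L) {
    g[[1]] + (g[[2]] - g[[1]]) * r
  } else {
    config_error(sprintf("gradient `%s` must be a function or length-2 numeric", name))
  }
  v <- pmax(v, 0)
  if (identical(name, "contact_fraction")) v <- pmin(v, 1)
  v
}

#' Lobule specifications for the dietary condition presets
#'
#' Returns a `lobule_spec` whose zonal gradients emulate the qualitative
#' phenotype of each nutritional state:
#' \describe{
#'   \item{control}{Lipid droplets concentrated pericentrally (LD count
#'     decreasing with `r`), mitochondria rounder and sparser periportally,
#'     mitochondria-LD contacts essentially absent outside the pericentral
#'     zone (`contact_fraction` reaches 0 for `r > 1/3`).}
#'   \item{fasted}{Elevated LD counts across the whole lobule and a high
#'     contact fraction everywhere except the most pericentral bins;
#'     mitochondria elongated throughout.}
#'   \item{western_diet}{Large periportal LDs, uniformly low contact
#'     fraction, rounder mitochondria.}
#' }
#'
#' @param name One of `"control"`, `"fasted"`, `"western_diet"`.
#' @param overrides Extra spec overrides applied on top of the preset.
#' @return A `lobule_spec` with a `condition` attribute.
#' @export
condition_preset <- function(name, overrides = list()) {
  presets <- list(
    control = list(
      ld_count           = c(pc = 10,   pp = 1),
      ld_radius_um       = c(pc = 0.8,  pp = 0.5),
      mito_count         = c(pc = 30,   pp = 18),
      mito_elongation    = c(pc = 2.4,  pp = 1.2),
      mito_area_fraction = c(pc = 0.15, pp = 0.08),
      contact_fraction   = function(r) pmax(0, 0.35 - 1.05 * r)
    ),
    fasted = list(
      ld_count           = c(pc = 14,   pp = 9),
      ld_radius_um       = c(pc = 0.7,  pp = 0.7),
      mito_count         = c(pc = 30,   pp = 24),
      mito_elongation    = c(pc = 2.6,  pp = 2.2),
      mito_area_fraction = c(pc = 0.16, pp = 0.13),
      contact_fraction   = function(r) ifelse(r < 1 / 6, 0.3, 0.85)
    ),
    western_diet = list(
      ld_count           = c(pc = 6,    pp = 6),
      ld_radius_um       = c(pc = 0.6,  pp = 1.6),
      mito_count         = c(pc = 26,   pp = 20),
      mito_elongation    = c(pc = 1.3,  pp = 1.15),
      mito_area_fraction = c(pc = 0.12, pp = 0.10),
      contact_fraction   = c(pc = 0.05, pp = 0.05)
    )
  )
  if (!is.character(name) || length(name) != 1L || !name %in% names(presets)) {
    config_error(paste0("unknown condition preset; expected one of: ",
                        paste(names(presets), collapse = ", ")))
  }
  ov <- modifyList(list(gradients = presets[[name]]), overrides)
  spec <- lobule_spec(ov)
  attr(spec, "condition") <- name
  spec
}

#' @export
print.lobule_spec <- function(x, ...) {
  cat("<lobule_spec>\n")
  cat(sprintf("  image: %d x %d px @ %.3g um/px\n",
              x$image_shape[1], x$image_shape[2], x$pixel_size_um))
  cat(sprintf("  CV-PV axis: %.0f um, %d cells/axis x %d rows (cell radius %.3g um)\n",
              x$axis_length_um, x$n_cells_per_axis, x$n_cell_rows, x$cell_radius_um))
  cond <- attr(x, "condition")
  if (!is.null(cond)) cat("  condition preset:", cond, "\n")
  invisible(x)
}
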