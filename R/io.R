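# TIFF and CSV input/output. Channel stacks are written as multi-page TIFF
# (one page per channel) with a JSON sidecar recording channel order and
# pixel size; instance masks as 16-bit label TIFF. Channel intensities live
# on the 16-bit grid, so write-then-read round trips are bit-identical.

#' Registered multi-channel image stack
#'
#' @param mito,ld,actin Numeric matrices in `[0, 1]`, identical dimensions.
#' @param pixel_size_um Pixel size in um/px.
#' @param extra Optional named list of further channels.
#' @return Object of class `channel_stack`: `$channels` (named list of
#'   matrices, order mito, ld, actin) and `$pixel_size_um`.
#' @export
channel_stack <- function(mito, ld, actin, pixel_size_um, extra = list()) {
  check_same_shape(mito, ld); check_same_shape(mito, actin)
  stopifnot_scalar_number(pixel_size_um, "pixel_size_um", positive = TRUE)
  structure(list(channels = c(list(mito = mito, ld = ld, actin = actin), extra),
                 pixel_size_um = pixel_size_um),
            class = "channel_stack")
}

#' @export
print.channel_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<channel_stack> %d x %d px, %.3g um/px, channels: %s\n",
              d[1], d[2], x$pixel_size_um,
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

sidecar_path <- function(path) paste0(path, ".json")

#' Write a channel stack as multi-page TIFF
#'
#' One 16-bit page per channel; channel order and pixel size go to a JSON
#' sidecar (`<path>.json`).
#'
#' @param stack A [channel_stack()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_channel_stack <- function(stack, path) {
  tiff::writeTIFF(unname(stack$channels), path, bits.per.sample = 16L)
  jsonlite::write_json(list(channel_order = names(stack$channels),
                            pixel_size_um = stack$pixel_size_um),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a multi-page TIFF into a channel stack
#'
#' Pages are mapped to channels by `channel_order`. The pixel size comes from
#' the JSON sidecar when present; an explicit `pixel_size_um` argument wins
#' over the sidecar.
#'
#' @param path TIFF path.
#' @param channel_order Character vector naming the pages in order.
#' @param pixel_size_um Optional pixel size override (um/px).
#' @return A [channel_stack()].
#' @export
read_image_stack <- function(path, channel_order = c("mito", "ld", "actin"),
                             pixel_size_um = NULL) {
  if (!file.exists(path)) data_error(paste0("no such file: ", path))
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]   # collapse any extra samples
    p
  })
  if (length(pages) < length(channel_order)) {
    data_error(sprintf("TIFF has %d page(s) but %d channel name(s) given (page %d missing)",
                       length(pages), length(channel_order), length(pages) + 1L))
  }
  meta <- list()
  if (file.exists(sidecar_path(path))) {
    meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  }
  ps <- pixel_size_um %||% meta$pixel_size_um %||% 1
  chans <- setNames(pages[seq_along(channel_order)], channel_order)
  need <- c("mito", "ld", "actin")
  if (!all(need %in% channel_order)) {
    data_error("`channel_order` must include mito, ld and actin")
  }
  channel_stack(chans$mito, chans$ld, chans$actin, ps,
                extra = chans[setdiff(channel_order, need)])
}

#' Write / read a 16-bit instance label TIFF
#'
#' @param mask Integer matrix with labels in `0..65535`.
#' @param path TIFF path.
#' @return `path` (write) or an integer matrix (read).
#' @export
write_label_mask <- function(mask, path) {
  if (max(mask) > 65535L) data_error("labels exceed the 16-bit range")
  tiff::writeTIFF(mask / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_label_mask
#' @export
read_label_mask <- function(path) {
  if (!file.exists(path)) data_error(paste0("no such file: ", path))
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  out <- round(m * 65535)
  storage.mode(out) <- "integer"
  out
}

#' Write / read the per-cell feature table
#'
#' UTF-8 CSV with a header row, missing values as empty fields, and the
#' stable column order of [feature_dictionary()] (unknown columns keep their
#' incoming order at the end).
#'
#' @param table Data frame of [build_feature_table()] output.
#' @param path CSV path.
#' @return `path` (write) or a tibble (read).
#' @export
write_feature_table <- function(table, path) {
  dict_order <- feature_dictionary()$column
  ord <- c(intersect(dict_order, names(table)),
           setdiff(names(table), dict_order))
  ok <- tryCatch({
    write.csv(table[, ord, drop = FALSE], path, row.names = FALSE, na = "",
              fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) data_error(paste0("cannot write feature table: ",
                                     conditionMessage(ok)))
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) data_error(paste0("no such file: ", path))
  as_tibble(read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8"))
}

#' Write the ground truth of a simulated lobule to disk
#'
#' Writes the channel TIFF, the three instance-mask TIFFs, the vein label
#' TIFF (1 = CV, 2.. = PV), the per-cell and per-organelle ground-truth CSVs
#' and a JSON sidecar with the spec's scalar fields.
#'
#' @param sim Result of [simulate_lobule()].
#' @param dir Output directory (created if missing).
#' @return Named character vector of written paths, invisibly.
#' @export
write_lobule_truth <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_channel_stack(sim$channels, p("channels.tif"))
  write_label_mask(sim$truth$cell_mask, p("cells_truth.tif"))
  write_label_mask(sim$truth$mito_mask, p("mito_truth.tif"))
  write_label_mask(sim$truth$ld_mask, p("ld_truth.tif"))
  veins <- sim$truth$veins
  vm <- matrix(0L, nrow(veins$cv), ncol(veins$cv))
  vm[veins$cv] <- 1L
  for (i in seq_along(veins$pv)) vm[veins$pv[[i]]] <- 1L + i
  write_label_mask(vm, p("veins.tif"))
  write.csv(sim$truth$cells, p("cells_truth.csv"), row.names = FALSE, na = "")
  write.csv(sim$truth$organelles, p("organelles_truth.csv"),
            row.names = FALSE, na = "")
  spec <- sim$truth$spec
  scalars <- spec[vapply(spec, function(x) is.numeric(x) && length(x) <= 2,
                         logical(1))]
  jsonlite::write_json(c(scalars, list(seed = sim$truth$seed)),
                       p("truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(c(channels = p("channels.tif"), cells = p("cells_truth.tif"),
              mito = p("mito_truth.tif"), ld = p("ld_truth.tif"),
              veins = p("veins.tif")))
}
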