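# End-to-end pipeline: simulate -> segment -> profile -> zonate, with a
# config object, plain TIFF/CSV intermediates so every stage can be audited
# or resumed, and a JSON run manifest written on success and failure alike.

#' Pipeline configuration
#'
#' Precedence is caller arguments > config file > defaults (the CLI applies
#' its flag overrides on top of the file).
#'
#' @param out_dir Output directory (required).
#' @param conditions Character vector of [condition_preset()] names to
#'   simulate and analyze.
#' @param seed Top-level seed; all randomness derives from it (condition `i`
#'   simulates with `seed + i - 1`).
#' @param n_bins Number of zonal bins.
#' @param pixel_size_um Pixel size override for image inputs (um/px).
#' @param spec_overrides Overrides passed to [condition_preset()].
#' @param use_truth_masks Profile stage uses the generator's ground-truth
#'   masks instead of the segmented ones (validation mode).
#' @param cell_input Image fed to hepatocyte segmentation: `"actin"`
#'   (classical membrane baseline) or `"combination"`.
#' @param combination_sigma_px Blur sigma for [make_combination_channel()].
#' @param cell_min_area_px,mito_min_area_px,ld_min_area_px Minimum object
#'   areas (speckle suppression at the default pixel size).
#' @param ld_threshold LD intensity filter threshold (`"otsu"` or numeric).
#' @param min_fraction Organelle-to-cell assignment plurality fraction.
#' @param perimeter Perimeter estimator (`"crofton"` or `"boundary"`).
#' @param features Feature subset for zonation (default: all).
#' @param n_components PCA components.
#' @param k Optional flat-cluster count for the cluster map.
#' @param resume Reuse on-disk intermediates when input checksums match the
#'   previous manifest.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir,
                            conditions = "control",
                            seed = 1L,
                            n_bins = 12L,
                            pixel_size_um = NULL,
                            spec_overrides = list(),
                            use_truth_masks = FALSE,
                            cell_input = c("actin", "combination"),
                            combination_sigma_px = 2,
                            cell_min_area_px = 500L,
                            mito_min_area_px = 5L,
                            ld_min_area_px = 5L,
                            ld_threshold = "otsu",
                            min_fraction = 0.5,
                            perimeter = "crofton",
                            features = NULL,
                            n_components = 2L,
                            k = NULL,
                            resume = FALSE) {
  if (missing(out_dir) || !is.character(out_dir) || length(out_dir) != 1) {
    config_error("`out_dir` is required")
  }
  cell_input <- match.arg(cell_input)
  if (n_bins < 1) config_error("`n_bins` must be >= 1")
  if (!is.null(pixel_size_um)) {
    stopifnot_scalar_number(pixel_size_um, "pixel_size_um", positive = TRUE)
  }
  structure(list(
    out_dir = out_dir, conditions = conditions, seed = as.integer(seed),
    n_bins = as.integer(n_bins), pixel_size_um = pixel_size_um,
    spec_overrides = spec_overrides, use_truth_masks = use_truth_masks,
    cell_input = cell_input, combination_sigma_px = combination_sigma_px,
    cell_min_area_px = cell_min_area_px, mito_min_area_px = mito_min_area_px,
    ld_min_area_px = ld_min_area_px, ld_threshold = ld_threshold,
    min_fraction = min_fraction, perimeter = perimeter, features = features,
    n_components = as.integer(n_components), k = k, resume = resume
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML or JSON file
#'
#' @param path Config file path.
#' @param overrides Named list applied on top of the file's values.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, overrides = list()) {
  if (!file.exists(path)) config_error(paste0("no such config file: ", path))
  vals <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  vals <- modifyList(as.list(vals), overrides)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    config_error(paste0("unknown config field(s): ", paste(unknown, collapse = ", ")))
  }
  do.call(pipeline_config, vals)
}

md5_of <- function(paths) {
  paths <- paths[file.exists(paths)]
  if (length(paths) == 0) return(character(0))
  setNames(as.character(tools::md5sum(paths)), basename(paths))
}

#' Run the analysis pipeline
#'
#' Stages: `simulate` (synthetic lobules per condition preset), `segment`
#' (cells, mitochondria, LDs from the channel TIFFs), `profile` (per-cell
#' feature tables with spatial bins), `zonate` (zonal profiles, PCA,
#' clustered heatmap orders, cross-condition correlations, overlap heatmap),
#' or `all`. Each stage reads its inputs from `out_dir`, so stages are
#' resumable from on-disk intermediates; identical config and seed give
#' byte-identical CSV outputs. A JSON manifest (config snapshot, package
#' version, input checksums, per-stage timings, warnings and status) is
#' written on every run, success or failure.
#'
#' @param config A [pipeline_config()] or path to a config file.
#' @param stage One of `"all"`, `"simulate"`, `"segment"`, `"profile"`,
#'   `"zonate"`.
#' @return The manifest list, invisibly.
#' @export
run_pipeline <- function(config, stage = c("all", "simulate", "segment",
                                           "profile", "zonate")) {
  stage <- match.arg(stage)
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!inherits(config, "pipeline_config")) {
    config_error("`config` must be a pipeline_config or a config file path")
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    package = "lobulemap",
    version = as.character(packageVersion("lobulemap")),
    config = config[!vapply(config, is.function, logical(1))],
    stages = list(), warnings = character(0), status = "running"
  )
  manifest_path <- file.path(config$out_dir, "manifest.json")
  flush_manifest <- function() {
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         digits = NA, null = "null", force = TRUE)
  }
  on.exit(flush_manifest(), add = TRUE)

  stages <- if (stage == "all") c("simulate", "segment", "profile", "zonate")
    else stage
  prev_manifest <- if (config$resume && file.exists(manifest_path)) {
    tryCatch(jsonlite::read_json(manifest_path, simplifyVector = TRUE),
             error = function(e) NULL)
  }

  for (st in stages) {
    t0 <- Sys.time()
    res <- tryCatch({
      withCallingHandlers(
        run_stage(st, config, prev_manifest),
        warning = function(w) {
          manifest$warnings <<- c(manifest$warnings, conditionMessage(w))
          invokeRestart("muffleWarning")
        }
      )
    }, error = function(e) {
      manifest$stages[[st]] <<- list(status = "failed",
                                     error = conditionMessage(e))
      manifest$status <<- "failed"
      flush_manifest()
      abort(sprintf("stage '%s' failed: %s", st, conditionMessage(e)),
            class = class(e)[1], parent = e)
    })
    manifest$stages[[st]] <- c(
      list(status = if (isTRUE(res$skipped)) "cached" else "ok",
           seconds = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
      res[setdiff(names(res), "skipped")]
    )
  }
  manifest$status <- "ok"
  flush_manifest()
  invisible(manifest)
}

cond_dir <- function(config, cond) file.path(config$out_dir, cond)

stage_inputs <- function(st, config) {
  unlist(lapply(config$conditions, function(cond) {
    d <- cond_dir(config, cond)
    switch(st,
      simulate = character(0),
      segment = file.path(d, "channels.tif"),
      profile = if (config$use_truth_masks) {
        file.path(d, c("cells_truth.tif", "mito_truth.tif", "ld_truth.tif",
                       "veins.tif", "channels.tif"))
      } else {
        file.path(d, c("cells_seg.tif", "mito_seg.tif", "ld_seg.tif",
                       "veins.tif", "channels.tif"))
      },
      zonate = file.path(config$out_dir, paste0("features_", cond, ".csv"))
    )
  }))
}

stage_outputs <- function(st, config) {
  conds <- config$conditions
  switch(st,
    simulate = unlist(lapply(conds, function(cond)
      file.path(cond_dir(config, cond),
                c("channels.tif", "cells_truth.tif", "mito_truth.tif",
                  "ld_truth.tif", "veins.tif")))),
    segment = unlist(lapply(conds, function(cond)
      file.path(cond_dir(config, cond),
                c("cells_seg.tif", "mito_seg.tif", "ld_seg.tif")))),
    profile = file.path(config$out_dir, paste0("features_", conds, ".csv")),
    zonate = file.path(config$out_dir,
                       c(paste0("profile_", conds, ".csv"),
                         "pca_scores.csv", "pca_loadings.csv",
                         "pca_variance.csv", "clustermap_rows.csv",
                         "overlap_heatmap.csv"))
  )
}

run_stage <- function(st, config, prev_manifest = NULL) {
  inputs <- stage_inputs(st, config)
  sums <- md5_of(inputs)
  if (config$resume && !is.null(prev_manifest)) {
    prev <- prev_manifest$stages[[st]]
    if (!is.null(prev) && identical(as.list(prev$input_md5), as.list(sums)) &&
          all(file.exists(stage_outputs(st, config)))) {
      return(list(skipped = TRUE, input_md5 = as.list(sums)))
    }
  }
  if (st != "simulate" && length(inputs) > 0 && !all(file.exists(inputs))) {
    data_error(sprintf("stage '%s' is missing inputs: %s", st,
                       paste(inputs[!file.exists(inputs)], collapse = ", ")))
  }
  out <- switch(st,
    simulate = stage_simulate(config),
    segment = stage_segment(config),
    profile = stage_profile(config),
    zonate = stage_zonate(config)
  )
  c(out, list(input_md5 = as.list(sums)))
}

stage_simulate <- function(config) {
  for (i in seq_along(config$conditions)) {
    cond <- config$conditions[i]
    ov <- config$spec_overrides
    if (!is.null(config$pixel_size_um)) ov$pixel_size_um <- config$pixel_size_um
    spec <- condition_preset(cond, ov)
    sim <- simulate_lobule(spec, seed = config$seed + i - 1L)
    write_lobule_truth(sim, cond_dir(config, cond))
  }
  list(conditions = config$conditions)
}

stage_segment <- function(config) {
  for (cond in config$conditions) {
    d <- cond_dir(config, cond)
    stack <- read_image_stack(file.path(d, "channels.tif"),
                              pixel_size_um = config$pixel_size_um)
    comb <- make_combination_channel(stack$channels$actin, stack$channels$mito,
                                     config$combination_sigma_px)
    cell_img <- if (config$cell_input == "combination") comb else
      stack$channels$actin
    cells <- segment_instances(cell_img, backend_membrane(),
                               config$cell_min_area_px)
    mito <- segment_instances(stack$channels$mito, backend_watershed(),
                              config$mito_min_area_px)
    ld_raw <- segment_instances(stack$channels$ld, backend_watershed(),
                                config$ld_min_area_px)
    flt <- filter_ld_segments(ld_raw, stack$channels$ld, config$ld_threshold)
    write_label_mask(cells, file.path(d, "cells_seg.tif"))
    write_label_mask(mito, file.path(d, "mito_seg.tif"))
    write_label_mask(flt$mask, file.path(d, "ld_seg.tif"))
    write.csv(flt$removed, file.path(d, "ld_removed.csv"), row.names = FALSE)
  }
  list(conditions = config$conditions)
}

stage_profile <- function(config) {
  suffix <- if (config$use_truth_masks) "truth" else "seg"
  n_cells <- integer(0)
  for (cond in config$conditions) {
    d <- cond_dir(config, cond)
    stack <- read_image_stack(file.path(d, "channels.tif"),
                              pixel_size_um = config$pixel_size_um)
    veins <- veins_from_labels(read_label_mask(file.path(d, "veins.tif")))
    tbl <- build_feature_table(
      read_label_mask(file.path(d, paste0("cells_", suffix, ".tif"))),
      read_label_mask(file.path(d, paste0("mito_", suffix, ".tif"))),
      read_label_mask(file.path(d, paste0("ld_", suffix, ".tif"))),
      channels = stack, veins = veins,
      config = list(pixel_size_um = stack$pixel_size_um,
                    n_bins = config$n_bins,
                    min_fraction = config$min_fraction,
                    perimeter = config$perimeter)
    )
    write_feature_table(tbl, file.path(config$out_dir,
                                       paste0("features_", cond, ".csv")))
    n_cells <- c(n_cells, nrow(tbl))
  }
  list(n_cells = as.list(setNames(n_cells, config$conditions)))
}

stage_zonate <- function(config) {
  profiles <- list()
  for (cond in config$conditions) {
    tbl <- read_feature_table(file.path(config$out_dir,
                                        paste0("features_", cond, ".csv")))
    prof <- aggregate_by_bin(tbl, features = config$features,
                             n_bins = config$n_bins, condition = cond)
    write.csv(tidy(prof), file.path(config$out_dir,
                                    paste0("profile_", cond, ".csv")),
              row.names = FALSE, na = "")
    profiles[[cond]] <- prof
  }
  # stack condition profiles row-wise for the joint embedding
  mats <- lapply(profiles, profile_matrix)
  shared <- Reduce(intersect, lapply(mats, colnames))
  stacked <- do.call(rbind, lapply(names(mats), function(cond) {
    m <- mats[[cond]][, shared, drop = FALSE]
    rownames(m) <- paste0(cond, "_", rownames(m))
    m
  }))
  keep_rows <- complete.cases(stacked)
  stacked <- stacked[keep_rows, , drop = FALSE]
  zs <- standardize_profile(stacked)
  pca <- pca_embed(zs, config$n_components)
  write.csv(tidy(pca, "scores"),
            file.path(config$out_dir, "pca_scores.csv"), row.names = FALSE)
  write.csv(tidy(pca, "loadings"),
            file.path(config$out_dir, "pca_loadings.csv"), row.names = FALSE)
  write.csv(tidy(pca, "eigenvalues"),
            file.path(config$out_dir, "pca_variance.csv"), row.names = FALSE)
  cm <- hierarchical_clustermap(zs, k = config$k)
  write.csv(tidy(cm), file.path(config$out_dir, "clustermap_rows.csv"),
            row.names = FALSE)
  if (length(profiles) >= 2) {
    ref <- names(profiles)[1]
    for (other in names(profiles)[-1]) {
      cc <- condition_correlation(profiles[[ref]], profiles[[other]])
      write.csv(tidy(cc),
                file.path(config$out_dir,
                          sprintf("correlation_%s_vs_%s.csv", ref, other)),
                row.names = FALSE)
    }
  }
  oh <- overlap_heatmap(profiles)
  write.csv(as_tibble(oh)[, setdiff(names(oh), "bin_label")],
            file.path(config$out_dir, "overlap_heatmap.csv"),
            row.names = FALSE, na = "")
  list(conditions = names(profiles), n_pca_rows = nrow(stacked))
}
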