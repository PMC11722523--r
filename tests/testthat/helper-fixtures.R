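# shared fixtures: memoized simulations (several test files reuse the same
# lobules) and small hand-built masks

.sim_cache <- new.env(parent = emptyenv())

cached_sim <- function(kind = c("control", "fasted", "western_diet", "zones"),
                       seed = 1L) {
  kind <- match.arg(kind)
  key <- paste(kind, seed, sep = "_")
  if (!is.null(.sim_cache[[key]])) return(.sim_cache[[key]])
  spec <- if (kind == "zones") three_zone_spec() else condition_preset(kind)
  .sim_cache[[key]] <- simulate_lobule(spec, seed = seed)
  .sim_cache[[key]]
}

cached_features <- function(kind = "control", seed = 1L) {
  key <- paste("feat", kind, seed, sep = "_")
  if (!is.null(.sim_cache[[key]])) return(.sim_cache[[key]])
  sim <- cached_sim(kind, seed)
  .sim_cache[[key]] <- build_feature_table(
    sim$truth$cell_mask, sim$truth$mito_mask, sim$truth$ld_mask,
    channels = sim$channels, veins = sim$truth$veins,
    config = list(pixel_size_um = sim$truth$spec$pixel_size_um)
  )
  .sim_cache[[key]]
}

# spec whose gradients step through three distinct zonal regimes, aligned on
# bin boundaries: bins 1-3 (periportal, r >= 0.75), 4-10 (mid), 11-12
# (pericentral, r < 1/6)
three_zone_spec <- function() {
  step3 <- function(pc, mid, pp) {
    force(pc); force(mid); force(pp)
    function(r) ifelse(r < 1 / 6, pc, ifelse(r < 0.75, mid, pp))
  }
  lobule_spec(list(gradients = list(
    ld_count           = step3(16, 8, 2),
    ld_radius_um       = step3(1.0, 0.7, 0.45),
    mito_count         = step3(34, 26, 18),
    mito_elongation    = step3(2.6, 1.8, 1.2),
    mito_area_fraction = step3(0.18, 0.13, 0.08),
    contact_fraction   = step3(0.6, 0.25, 0.02)
  )))
}

planted_zone_labels <- c(rep(1L, 3), rep(2L, 7), rep(3L, 2))

# random blob mask: a few dilated random walks, labeled
random_blob_mask <- function(h, w, n_blobs, seed) {
  set.seed(seed)
  mask <- matrix(0L, h, w)
  for (b in seq_len(n_blobs)) {
    r0 <- sample(3:(h - 3), 1); c0 <- sample(3:(w - 3), 1)
    pts <- cbind(r0, c0)
    for (s in 1:30) {
      nxt <- pts[nrow(pts), ] + sample(c(-1L, 0L, 1L), 2, replace = TRUE)
      nxt <- pmin(pmax(nxt, 2L), c(h - 1L, w - 1L))
      pts <- rbind(pts, nxt)
    }
    for (i in seq_len(nrow(pts))) {
      mask[pts[i, 1] + (-1:1), pts[i, 2] + (-1:1)] <- b
    }
  }
  mask
}

# brute-force oracles -------------------------------------------------------

brute_min_dist <- function(mask_a, mask_b) {
  pa <- which(mask_a > 0, arr.ind = TRUE)
  pb <- which(mask_b > 0, arr.ind = TRUE)
  if (nrow(pa) == 0 || nrow(pb) == 0) return(NA_real_)
  min(sqrt(outer(pa[, 1], pb[, 1], "-")^2 + outer(pa[, 2], pb[, 2], "-")^2))
}

brute_distance_map <- function(vein_mask) {
  vp <- which(vein_mask, arr.ind = TRUE)
  out <- matrix(NA_real_, nrow(vein_mask), ncol(vein_mask))
  for (i in seq_len(nrow(vein_mask))) {
    for (j in seq_len(ncol(vein_mask))) {
      out[i, j] <- sqrt(min((vp[, 1] - i)^2 + (vp[, 2] - j)^2))
    }
  }
  out
}

brute_eccentricity <- function(mask) {
  rc <- which(mask > 0, arr.ind = TRUE)
  dy <- rc[, 1] - mean(rc[, 1]); dx <- rc[, 2] - mean(rc[, 2])
  n <- nrow(rc)
  cm <- matrix(c(sum(dx^2), sum(dx * dy), sum(dx * dy), sum(dy^2)), 2) / n
  ev <- sort(eigen(cm, symmetric = TRUE)$values, decreasing = TRUE)
  if (ev[1] <= 0) return(0)
  sqrt(max(0, 1 - max(0, ev[2]) / ev[1]))
}
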