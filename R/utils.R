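# internal helpers shared across modules

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

config_error <- function(msg, ...) {
  abort(msg, class = "lobulemap_config_error", ...)
}

data_error <- function(msg, ...) {
  abort(msg, class = "lobulemap_data_error", ...)
}

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    config_error(sprintf("`%s` must be a single finite number", name))
  }
  if (positive && x <= 0) {
    config_error(sprintf("`%s` must be > 0", name))
  }
  invisible(x)
}

check_same_shape <- function(a, b, what = "images") {
  if (!identical(dim(a), dim(b))) {
    data_error(sprintf(
      "%s must have identical dimensions (got %s vs %s)",
      what, paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x")
    ))
  }
  invisible(TRUE)
}

# rescale to [0, 1] with percentile clipping; constant images map to 0
rescale01 <- function(x, p_lo = 0, p_hi = 1) {
  qs <- quantile(x, c(p_lo, p_hi), names = FALSE, na.rm = TRUE)
  if (qs[2] <= qs[1]) {
    rng <- range(x, finite = TRUE)
    if (rng[2] <= rng[1]) return(array(0, dim(x)))
    qs <- rng
  }
  clamp((x - qs[1]) / (qs[2] - qs[1]), 0, 1)
}

# pixel lists per label of an instance mask: named list label -> linear indices
label_pixels <- function(mask) {
  idx <- which(mask > 0L)
  if (length(idx) == 0L) return(list())
  split(idx, mask[idx])
}

# relabel an instance mask to consecutive 1..K preserving label order
relabel_mask <- function(mask) {
  labs <- sort(unique(mask[mask > 0L]))
  if (length(labs) == 0L) return(mask)
  out <- mask
  out[mask > 0L] <- match(mask[mask > 0L], labs)
  storage.mode(out) <- "integer"
  out
}

bin_labels <- function(n_bins) paste0("R", seq_len(n_bins))
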