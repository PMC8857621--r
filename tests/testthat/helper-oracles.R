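# Independent brute-force oracles used to check the vectorized
# implementations. These deliberately share no code with the package paths
# they verify.

# Niblack threshold by direct evaluation of mean / population SD over the
# symmetric-reflection-padded window at every pixel.
naive_niblack <- function(x, window, k) {
  lo <- window %/% 2L
  hi <- window - 1L - lo
  refl <- function(n) c(if (lo > 0) lo:1, 1:n, if (hi > 0) n:(n - hi + 1L))
  xp <- x[refl(nrow(x)), refl(ncol(x)), drop = FALSE]
  out <- matrix(NA_real_, nrow(x), ncol(x))
  for (r in seq_len(nrow(x))) {
    for (c in seq_len(ncol(x))) {
      w <- xp[r:(r + window - 1L), c:(c + window - 1L)]
      m <- mean(w)
      s <- sqrt(mean((w - m)^2))   # population SD
      out[r, c] <- m + k * s
    }
  }
  out
}

# Flattening by an explicit double loop over columns and rows.
naive_flatten <- function(px, icb, crop_height) {
  out <- matrix(0L, crop_height, ncol(px))
  for (c in seq_len(ncol(px))) {
    for (r in 0:(crop_height - 1L)) {
      src <- icb[c] + r            # 0-based source row
      if (src < nrow(px)) out[r + 1L, c] <- px[src + 1L, c]
    }
  }
  out
}

# Confusion counts by an exhaustive loop over pixels and classes.
naive_confusion <- function(pred, truth) {
  classes <- 0:2
  tp <- fp <- fn <- setNames(numeric(3), c("interstitial", "lumen", "sclera"))
  for (ci in seq_along(classes)) {
    k <- classes[ci]
    for (i in seq_along(pred)) {
      if (truth[i] == k && pred[i] == k) tp[ci] <- tp[ci] + 1
      if (truth[i] != k && pred[i] == k) fp[ci] <- fp[ci] + 1
      if (truth[i] == k && pred[i] != k) fn[ci] <- fn[ci] + 1
    }
  }
  list(tp = tp, fp = fp, fn = fn)
}

# small random label map
random_labelmap <- function(nr, nc) {
  matrix(sample(0:2, nr * nc, replace = TRUE), nr, nc)
}

# fast phantom spec for tests that only need structure, not realism
small_spec <- function(seed, ...) {
  args <- list(rows = 120, cols = 256, icb_base = 30, icb_amplitude = 12,
               choroid_thickness = 35, thickness_variation = 6,
               vessel_radius_range = c(3, 8), seed = seed)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(phantom_spec, args)
}
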