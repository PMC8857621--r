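#' Niblack local threshold map
#'
#' Computes the per-pixel Niblack threshold `T(i,j) = m(i,j) + k * sigma(i,j)`
#' where `m` and `sigma` are the mean and population standard deviation of
#' the pixels in the square window centred at `(i, j)`. Borders are padded by
#' symmetric reflection so every window is full (Niblack is notoriously noisy
#' in windows that see a single class; reflection at least keeps border
#' statistics well defined). Even window sizes centre at offset
#' `floor(window / 2)`.
#'
#' Local sums use summed-area tables, so the cost is independent of the
#' window size.
#'
#' @param image Numeric matrix, or a [flatten_bscan()] result.
#' @param window Side length of the square window in pixels (>= 3). The
#'   fixed-window baseline is 51; a typical sweep covers 20..75.
#' @param k Weight on the local standard deviation (default -0.05).
#' @return Numeric matrix of thresholds, same shape as the input.
#' @export
niblack_threshold_map <- function(image, window, k = -0.05) {
  px <- if (inherits(image, "flattened_choroid")) image$pixels else image
  if (!is.matrix(px) || !length(px)) abort("`image` must be a non-empty matrix.")
  window <- as.integer(window)
  if (window < 3) abort("`window` must be at least 3 pixels.")
  if (window > 2L * min(dim(px))) {
    abort(sprintf("window %d exceeds twice the smallest image dimension (%d)",
                  window, min(dim(px))))
  }
  x <- matrix(as.numeric(px), nrow(px))
  lo <- window %/% 2L              # pixels taken before the centre
  hi <- window - 1L - lo           # pixels after the centre
  xp <- pad_reflect(x, lo, hi)
  n <- as.numeric(window)^2
  s1 <- box_sum(xp, window)
  s2 <- box_sum(xp * xp, window)
  m <- s1 / n
  v <- pmax(s2 / n - m * m, 0)
  m + k * sqrt(v)
}

# symmetric (edge-including) reflection padding by lo before / hi after
pad_reflect <- function(x, lo, hi) {
  refl <- function(n) {
    c(if (lo > 0) lo:1, 1:n, if (hi > 0) n:(n - hi + 1L))
  }
  x[refl(nrow(x)), refl(ncol(x)), drop = FALSE]
}

# sum over every window x window block of xp, sliding by 1; returns a matrix
# with (nrow(xp) - window + 1) rows
box_sum <- function(xp, window) {
  cs <- apply(xp, 2, cumsum)
  cs <- rbind(0, cs)
  rows <- cs[(window + 1L):nrow(cs), , drop = FALSE] -
    cs[1:(nrow(cs) - window), , drop = FALSE]
  cs2 <- t(apply(rows, 1, cumsum))
  if (nrow(rows) == 1L) cs2 <- matrix(cs2, 1L)
  cs2 <- cbind(0, cs2)
  cs2[, (window + 1L):ncol(cs2), drop = FALSE] -
    cs2[, 1:(ncol(cs2) - window), drop = FALSE]
}

#' Classify choroidal pixels as lumen or interstitium
#'
#' A pixel strictly below its local threshold is vessel lumen
#' (hypo-reflective); a pixel at or above the threshold is interstitial
#' stroma. When the outer choroidal boundary is known, pixels at or below it
#' are marked sclera instead of being thresholded.
#'
#' @param image A [flatten_bscan()] result (its `ocb_flat` is used unless
#'   overridden) or a numeric matrix.
#' @param thresholds Threshold map from [niblack_threshold_map()].
#' @param ocb_flat Optional per-column 0-based row of the flattened OCB;
#'   `NULL` classifies every pixel.
#' @return Integer label map (see [label_levels()]).
#' @export
classify_choroid <- function(image, thresholds, ocb_flat = NULL) {
  px <- if (inherits(image, "flattened_choroid")) image$pixels else image
  if (is.null(ocb_flat) && inherits(image, "flattened_choroid")) {
    ocb_flat <- image$ocb_flat
  }
  if (!all(dim(px) == dim(thresholds))) {
    abort("image and threshold map have different shapes.")
  }
  labels <- matrix(0L, nrow(px), ncol(px))
  labels[px < thresholds] <- 1L
  if (!is.null(ocb_flat)) labels <- mask_sclera(labels, ocb_flat)
  labels
}

#' Mask the scleral region of a label map
#'
#' Every pixel at or below the flattened outer choroidal boundary is set to
#' the sclera category; choroidal pixels are untouched.
#'
#' @param labels Label map.
#' @param ocb_flat Per-column 0-based row index of the flattened OCB.
#' @return Label map with the sclera painted.
#' @export
mask_sclera <- function(labels, ocb_flat) {
  labels <- as_labelmap(labels)
  if (length(ocb_flat) != ncol(labels)) {
    abort("`ocb_flat` must have one entry per label-map column.")
  }
  rows <- matrix(0:(nrow(labels) - 1L), nrow(labels), ncol(labels))
  labels[rows >= matrix(ocb_flat, nrow(labels), ncol(labels), byrow = TRUE)] <- 2L
  labels
}

#' CVI as a function of Niblack window size
#'
#' Runs the full threshold-classify-CVI chain once per window size, exposing
#' how strongly the choroidal vascularity index depends on the analysis
#' window.
#'
#' @param flattened A [flatten_bscan()] result.
#' @param windows Integer vector of window sizes (default 20..75).
#' @param k Niblack weight.
#' @return Tibble with columns `window` and `cvi_percent`, in input order.
#' @export
window_sweep_cvi <- function(flattened, windows = 20:75, k = -0.05) {
  if (!length(windows)) abort("`windows` must be non-empty.")
  cvis <- vapply(windows, function(w) {
    tm <- niblack_threshold_map(flattened, w, k)
    cvi(classify_choroid(flattened, tm))
  }, numeric(1))
  out <- tibble(window = as.integer(windows), cvi_percent = cvis)
  class(out) <- c("window_sweep", class(out))
  out
}

#' Select a window size from a CVI sweep
#'
#' With a known true luminal fraction the window whose CVI is nearest the
#' truth is returned. Without one, the sweep stands in for manual selection:
#' the smallest window inside the curve's first flat plateau is returned --
#' the first window from which the absolute local slope of CVI vs window
#' drops below `tol` (or, if the curve never gets that flat, below its
#' minimum slope). The reasoning mirrors manual adjustment: an observer stops
#' enlarging the window once the binarization stops changing, which happens
#' soon after the window spans both tissue classes, so the selected size
#' tracks the vessel scale.
#'
#' @param sweep Tibble from [window_sweep_cvi()].
#' @param truth Optional true luminal fraction, in percent.
#' @param tol Plateau threshold on `|dCVI/dwindow|`, in percentage points per
#'   pixel.
#' @return Selected window size (integer).
#' @export
select_window <- function(sweep, truth = NULL, tol = 0.05) {
  if (!nrow(sweep)) abort("`sweep` must be non-empty.")
  if (!is.null(truth)) {
    return(sweep$window[which.min(abs(sweep$cvi_percent - truth))])
  }
  if (nrow(sweep) == 1L) return(sweep$window[1])
  o <- order(sweep$window)
  w <- sweep$window[o]; v <- sweep$cvi_percent[o]
  slope <- abs(diff(v) / diff(w))
  thr <- max(min(slope), tol)
  w[which(slope <= thr + 1e-12)[1]]
}
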