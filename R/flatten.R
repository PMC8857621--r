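#' Flatten a B-scan on the inner choroidal boundary
#'
#' The posterior eye is curved, but local binarization works on rectangular
#' regions, so each A-scan (column) is shifted up by its ICB row, placing the
#' inner choroidal boundary on row 0, and the image is cropped to
#' `crop_height` rows. Shifts are whole pixels (no resampling), so 8-bit
#' values are preserved exactly; rows shifted in from beyond the image are
#' filled with 0.
#'
#' @param scan A [bscan()] object or integer matrix.
#' @param boundaries [choroid_boundaries()] with one entry per scan column.
#' @param crop_height Number of rows to retain. Use [compute_crop_height()]
#'   to pick a single value for a whole dataset. If smaller than the deepest
#'   flattened OCB a warning is raised (sclera would be truncated).
#' @return Object of class `flattened_choroid` with fields `pixels`
#'   (`crop_height x n_col` integer matrix), `shift` (per-column shift, equal
#'   to the ICB row), `ocb_flat` (per-column OCB row after flattening,
#'   0-based), `crop_height`, and the scan's scales and identity.
#' @export
flatten_bscan <- function(scan, boundaries, crop_height) {
  px <- if (inherits(scan, "bscan")) scan$pixels else scan
  if (length(boundaries) != ncol(px)) {
    abort(sprintf("boundaries cover %d columns but the scan has %d",
                  length(boundaries), ncol(px)))
  }
  crop_height <- as.integer(crop_height)
  ocb_flat <- boundaries$ocb - boundaries$icb
  if (crop_height < max(ocb_flat)) {
    warn(sprintf("crop_height %d is smaller than the deepest flattened OCB (%d); sclera will be truncated",
                 crop_height, max(ocb_flat)))
  }
  nr <- nrow(px); nc <- ncol(px)
  # target (r, c) <- source (icb[c] + r, c), both 0-based
  src_row <- outer(0:(crop_height - 1L), boundaries$icb, `+`)  # 0-based rows
  in_range <- src_row < nr
  src_col <- matrix(rep(0:(nc - 1L), each = crop_height), crop_height)
  out <- matrix(0L, crop_height, nc)
  idx <- src_row + src_col * nr + 1L
  out[in_range] <- px[idx[in_range]]
  structure(
    list(pixels = out,
         shift = boundaries$icb,
         ocb_flat = ocb_flat,
         crop_height = crop_height,
         axial_scale_um = if (inherits(scan, "bscan")) scan$axial_scale_um else NA_real_,
         lateral_scale_um = if (inherits(scan, "bscan")) scan$lateral_scale_um else NA_real_,
         scan_id = if (inherits(scan, "bscan")) scan$scan_id else NULL),
    class = "flattened_choroid")
}

#' @export
print.flattened_choroid <- function(x, ...) {
  cat(sprintf("<flattened_choroid> %d x %d px, ocb_flat %d..%d\n",
              nrow(x$pixels), ncol(x$pixels), min(x$ocb_flat), max(x$ocb_flat)))
  invisible(x)
}

#' @export
dim.flattened_choroid <- function(x) dim(x$pixels)

#' Dataset-wide crop height after flattening
#'
#' The crop height is the maximum flattened choroid depth (OCB minus ICB)
#' over every column of every image in the dataset, plus a scleral margin,
#' and is then applied identically to each image so all flattened scans share
#' one height.
#'
#' @param all_boundaries A [choroid_boundaries()] object or a list of them.
#' @param scleral_margin Rows of sclera retained below the deepest OCB
#'   (default 15).
#' @return Integer crop height.
#' @export
compute_crop_height <- function(all_boundaries, scleral_margin = 15) {
  if (inherits(all_boundaries, "choroid_boundaries")) {
    all_boundaries <- list(all_boundaries)
  }
  if (!length(all_boundaries)) abort("`all_boundaries` must be non-empty.")
  deepest <- max(vapply(all_boundaries, function(b) max(b$ocb - b$icb), integer(1)))
  as.integer(deepest + scleral_margin)
}

#' Extract the subfoveal strip of a flattened choroid
#'
#' Cuts the horizontally centred strip of a given physical width (default
#' 6 mm) out of a flattened scan, using the lateral pixel scale to convert
#' millimetres to columns.
#'
#' @param flattened A [flatten_bscan()] result.
#' @param width_mm Physical strip width in millimetres.
#' @param lateral_scale_um Lateral scale; defaults to the scan's own.
#' @param center_column 0-based column at the strip centre; defaults to the
#'   image midpoint (the foveal A-scan in a centred acquisition).
#' @return A `flattened_choroid` restricted to the strip.
#' @export
extract_subfoveal <- function(flattened, width_mm = 6,
                              lateral_scale_um = NULL, center_column = NULL) {
  if (is.null(lateral_scale_um)) lateral_scale_um <- flattened$lateral_scale_um
  if (is.null(lateral_scale_um) || is.na(lateral_scale_um)) {
    abort("no lateral scale available; pass `lateral_scale_um`.")
  }
  nc <- ncol(flattened$pixels)
  width_px <- as.integer(round(width_mm * 1000 / lateral_scale_um))
  if (is.null(center_column)) center_column <- nc %/% 2L
  start <- as.integer(center_column - width_px %/% 2L)  # 0-based, half-open
  stop <- start + width_px
  if (start < 0 || stop > nc) {
    abort(sprintf("%g mm strip (%d px) centred at column %d exceeds image bounds [0, %d)",
                  width_mm, width_px, center_column, nc))
  }
  cols <- (start + 1L):stop
  out <- flattened
  out$pixels <- flattened$pixels[, cols, drop = FALSE]
  out$shift <- flattened$shift[cols]
  out$ocb_flat <- flattened$ocb_flat[cols]
  out
}
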