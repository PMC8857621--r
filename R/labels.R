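#' Label categories for choroid segmentation
#'
#' A label map is an integer matrix with one code per pixel:
#' `0` interstitial stroma, `1` vessel lumen, `2` sclera. The on-disk colour
#' encoding is interstitial black (0,0,0), lumen white (255,255,255) and
#' sclera the reserved mask colour (127,0,0), so label images survive only
#' lossless storage (PNG).
#'
#' @return Named integer vector mapping category name to code.
#' @export
#' @examples
#' label_levels()
label_levels <- function() {
  c(interstitial = 0L, lumen = 1L, sclera = 2L)
}

label_names <- function() names(label_levels())

# RGB bytes per category, rows in code order
label_palette <- function() {
  matrix(c(0L, 0L, 0L,
           255L, 255L, 255L,
           127L, 0L, 0L),
         nrow = 3, byrow = TRUE,
         dimnames = list(label_names(), c("r", "g", "b")))
}

#' Validate a label map
#'
#' @param labels Integer matrix with values in `label_levels()`.
#' @return The validated matrix (integer storage mode), invisibly usable in
#'   pipes.
#' @export
as_labelmap <- function(labels) {
  if (!is.matrix(labels)) abort("`labels` must be a matrix.")
  storage.mode(labels) <- "integer"
  bad <- !labels %in% label_levels()
  if (any(bad)) {
    i <- which(bad)[1]
    abort(sprintf(
      "labels contain illegal code %d at (row %d, col %d); allowed codes: 0, 1, 2",
      labels[i], (i - 1L) %% nrow(labels) + 1L, (i - 1L) %/% nrow(labels) + 1L))
  }
  labels
}

#' Encode a label map as a 3-channel colour image
#'
#' Interstitial pixels become (0,0,0), lumen (255,255,255) and sclera
#' (127,0,0) -- byte-exact, so the codec round-trips.
#'
#' @param labels Label map (integer matrix, codes 0/1/2).
#' @return Integer array `nrow x ncol x 3` with values in 0..255.
#' @export
#' @examples
#' encode_labelmap(matrix(c(0L, 1L, 2L, 1L), 2))[1, 2, ]
encode_labelmap <- function(labels) {
  labels <- as_labelmap(labels)
  pal <- label_palette()
  out <- array(0L, c(nrow(labels), ncol(labels), 3L))
  for (ch in 1:3) {
    out[, , ch] <- matrix(pal[labels + 1L, ch], nrow(labels), ncol(labels))
  }
  out
}

#' Decode a 3-channel colour image into a label map
#'
#' Inverse of [encode_labelmap()]. Every pixel must carry one of the three
#' legal colours; anything else is an error naming the offending pixel.
#'
#' @param image Numeric or integer array `H x W x 3`. Values may be bytes
#'   (0..255) or PNG-style fractions in `[0, 1]`.
#' @return Integer label map.
#' @export
decode_labelmap <- function(image) {
  if (length(dim(image)) != 3 || dim(image)[3] < 3) {
    abort("`image` must be an H x W x 3 array.")
  }
  if (is.double(image) && max(image) <= 1) image <- image * 255
  image <- round(image)
  nr <- dim(image)[1]; nc <- dim(image)[2]
  r <- matrix(image[, , 1], nr, nc)
  g <- matrix(image[, , 2], nr, nc)
  b <- matrix(image[, , 3], nr, nc)
  out <- matrix(NA_integer_, nrow(r), ncol(r))
  out[r == 0 & g == 0 & b == 0] <- 0L
  out[r == 255 & g == 255 & b == 255] <- 1L
  out[r == 127 & g == 0 & b == 0] <- 2L
  if (anyNA(out)) {
    i <- which(is.na(out))[1]
    rr <- (i - 1L) %% nrow(out) + 1L
    cc <- (i - 1L) %/% nrow(out) + 1L
    abort(sprintf(
      "pixel (row %d, col %d) has colour (%d,%d,%d), not one of the 3 legal label colours",
      rr, cc, r[rr, cc], g[rr, cc], b[rr, cc]))
  }
  out
}

#' Read / write a label map as a colour PNG
#'
#' @param labels Label map.
#' @param path File path (PNG; the mask colour (127,0,0) requires lossless
#'   storage).
#' @return `write_labelmap()` returns `path` invisibly; `read_labelmap()`
#'   returns the decoded label map.
#' @export
write_labelmap <- function(labels, path) {
  img <- encode_labelmap(labels)
  png::writePNG(img / 255, path)
  invisible(path)
}

#' @rdname write_labelmap
#' @export
read_labelmap <- function(path) {
  decode_labelmap(png::readPNG(path))
}
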