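#' Construct an OCT B-scan object
#'
#' A B-scan is a 2-D grid of 8-bit reflectivity values. Rows run down the
#' image (row 1 = inner retina at the top), columns are A-scans. Axial and
#' lateral pixel scales are carried as metadata together with the scan
#' identity used for subject-grouped splitting and repeatability pairing.
#'
#' @param pixels Integer matrix with values in 0..255.
#' @param axial_scale_um Micrometres per pixel along a column (> 0).
#' @param lateral_scale_um Micrometres per pixel across columns (> 0).
#' @param subject,visit,repetition,orientation Scan identity: subject id,
#'   visit number, repeat index (1 or 2, the two scans taken at one visit),
#'   and scan orientation (`"horizontal"` or `"vertical"`).
#' @return Object of class `bscan`.
#' @export
bscan <- function(pixels, axial_scale_um = 3.9, lateral_scale_um = 14,
                  subject = NA_character_, visit = NA_integer_,
                  repetition = NA_integer_, orientation = NA_character_) {
  if (!is.matrix(pixels) || nrow(pixels) < 1 || ncol(pixels) < 1) {
    abort("`pixels` must be a non-empty matrix.")
  }
  if (min(pixels) < 0 || max(pixels) > 255) {
    abort("`pixels` must lie in [0, 255].")
  }
  if (axial_scale_um <= 0 || lateral_scale_um <= 0) {
    abort("pixel scales must be positive.")
  }
  storage.mode(pixels) <- "integer"
  structure(
    list(pixels = pixels,
         axial_scale_um = axial_scale_um,
         lateral_scale_um = lateral_scale_um,
         scan_id = list(subject = subject, visit = visit,
                        repetition = repetition, orientation = orientation)),
    class = "bscan")
}

#' @export
print.bscan <- function(x, ...) {
  cat(sprintf("<bscan> %d x %d px, %.1f x %.1f um/px, subject=%s visit=%s rep=%s %s\n",
              nrow(x$pixels), ncol(x$pixels), x$axial_scale_um,
              x$lateral_scale_um, x$scan_id$subject, x$scan_id$visit,
              x$scan_id$repetition, x$scan_id$orientation))
  invisible(x)
}

#' @export
dim.bscan <- function(x) dim(x$pixels)

#' Read a grayscale OCT B-scan from PNG or TIFF
#'
#' @param path Path to an 8-bit grayscale PNG or TIFF.
#' @param convert If the file holds a multi-channel image, average the
#'   channels instead of raising a format error.
#' @inheritParams bscan
#' @return A [bscan()] object.
#' @export
read_bscan <- function(path, axial_scale_um = 3.9, lateral_scale_um = 14,
                       subject = NA_character_, visit = NA_integer_,
                       repetition = NA_integer_, orientation = NA_character_,
                       convert = FALSE) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  img <- read_raster(path)
  if (length(dim(img)) == 3) {
    if (!convert) {
      abort(sprintf("%s is multi-channel; pass convert = TRUE to average channels", path))
    }
    img <- apply(img[, , 1:min(3, dim(img)[3]), drop = FALSE], c(1, 2), mean)
  }
  px <- as.integer(round(img * 255))
  bscan(matrix(px, nrow(img), ncol(img)),
        axial_scale_um = axial_scale_um, lateral_scale_um = lateral_scale_um,
        subject = subject, visit = visit, repetition = repetition,
        orientation = orientation)
}

read_raster <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    abort(sprintf("unsupported image format: .%s (PNG/TIFF only)", ext)))
  img
}

#' Write a B-scan to a grayscale PNG
#'
#' @param scan A [bscan()] object or an integer matrix in 0..255.
#' @param path Output path (`.png`).
#' @return `path`, invisibly.
#' @export
write_bscan <- function(scan, path) {
  px <- if (inherits(scan, "bscan")) scan$pixels else scan
  png::writePNG(px / 255, path)
  invisible(path)
}

#' Choroidal boundary traces
#'
#' Per-A-scan row positions of the inner (ICB) and outer (OCB) choroidal
#' boundaries. Row indices are 0-based from the top of the image, matching
#' the file format written by [write_boundaries()].
#'
#' @param icb,ocb Integer vectors of equal length, `0 <= icb <= ocb`.
#' @return Object of class `choroid_boundaries`.
#' @export
choroid_boundaries <- function(icb, ocb) {
  if (length(icb) != length(ocb)) {
    abort("`icb` and `ocb` must have the same length (one entry per A-scan).")
  }
  icb <- as.integer(round(icb)); ocb <- as.integer(round(ocb))
  if (any(icb < 0)) abort("ICB rows must be >= 0.")
  bad <- which(ocb < icb)
  if (length(bad)) {
    abort(sprintf("OCB above ICB at column %d (icb=%d, ocb=%d)",
                  bad[1] - 1L, icb[bad[1]], ocb[bad[1]]))
  }
  structure(list(icb = icb, ocb = ocb), class = "choroid_boundaries")
}

#' @export
length.choroid_boundaries <- function(x) length(x$icb)

#' @export
print.choroid_boundaries <- function(x, ...) {
  cat(sprintf("<choroid_boundaries> %d columns, icb %d..%d, ocb %d..%d\n",
              length(x$icb), min(x$icb), max(x$icb), min(x$ocb), max(x$ocb)))
  invisible(x)
}

#' @export
as_tibble.choroid_boundaries <- function(x, ...) {
  tibble(column = seq_along(x$icb) - 1L, icb_row = x$icb, ocb_row = x$ocb)
}

#' Read boundary traces from CSV or JSON
#'
#' The CSV dialect has a header `column,icb_row,ocb_row` with one line per
#' A-scan; the JSON alternative mirrors the same keys. Row and column
#' indices are 0-based.
#'
#' @param path File path (`.csv` or `.json`).
#' @param n_columns Optional expected number of A-scans; a mismatch is a
#'   shape error.
#' @return A [choroid_boundaries()] object.
#' @export
read_boundaries <- function(path, n_columns = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  df <- switch(ext,
    csv = readr::read_csv(path, show_col_types = FALSE),
    json = as_tibble(jsonlite::fromJSON(path)),
    abort(sprintf("unsupported boundary format: .%s (CSV/JSON only)", ext)))
  need <- c("column", "icb_row", "ocb_row")
  if (!all(need %in% names(df))) {
    abort(sprintf("boundary file must have fields %s", paste(need, collapse = ", ")))
  }
  df <- df[order(df$column), ]
  if (!is.null(n_columns) && nrow(df) != n_columns) {
    abort(sprintf("boundary file has %d columns, expected %d", nrow(df), n_columns))
  }
  choroid_boundaries(df$icb_row, df$ocb_row)
}

#' Write boundary traces to CSV or JSON
#'
#' @param boundaries A [choroid_boundaries()] object.
#' @param path Output path (`.csv` or `.json`).
#' @return `path`, invisibly.
#' @export
write_boundaries <- function(boundaries, path) {
  df <- as_tibble(boundaries)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    csv = readr::write_csv(df, path),
    json = jsonlite::write_json(df, path, dataframe = "columns"),
    abort(sprintf("unsupported boundary format: .%s (CSV/JSON only)", ext)))
  invisible(path)
}
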