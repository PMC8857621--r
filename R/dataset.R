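#' Resample a flattened choroid to the network grid
#'
#' Semantic-segmentation backbones need fixed input geometry; the flattened
#' crop is resampled to `rows x cols` (default 224 x 896, which tiles into
#' four 224 x 224 inputs). Intensities are interpolated bilinearly; the
#' flattened OCB is rescaled axially and resampled across columns by nearest
#' neighbour so the sclera boundary stays a hard edge.
#'
#' @param flattened A [flatten_bscan()] result.
#' @param rows,cols Target grid.
#' @return A `flattened_choroid` on the target grid.
#' @export
resample_flattened <- function(flattened, rows = 224, cols = 896) {
  px <- flattened$pixels
  res <- EBImage::resize(matrix(as.numeric(px), nrow(px)), w = rows, h = cols,
                         filter = "bilinear")
  res <- matrix(as.integer(pmin(pmax(round(res), 0), 255)), rows, cols)
  src_col <- pmin(floor((seq_len(cols) - 0.5) * ncol(px) / cols) + 1L, ncol(px))
  scale_r <- rows / nrow(px)
  out <- flattened
  out$pixels <- res
  out$ocb_flat <- pmin(as.integer(round(flattened$ocb_flat[src_col] * scale_r)), rows)
  out$shift <- flattened$shift[src_col]
  out$crop_height <- rows
  out
}

#' Nearest-neighbour resampling of a label map
#'
#' @param labels Label map.
#' @param rows,cols Target grid.
#' @return Resampled label map (codes preserved exactly).
#' @export
resample_labels <- function(labels, rows = 224, cols = 896) {
  labels <- as_labelmap(labels)
  sr <- pmin(floor((seq_len(rows) - 0.5) * nrow(labels) / rows) + 1L, nrow(labels))
  sc <- pmin(floor((seq_len(cols) - 0.5) * ncol(labels) / cols) + 1L, ncol(labels))
  labels[sr, sc, drop = FALSE]
}

#' Build a network input / ground-truth pair
#'
#' The ground-truth label map is the Niblack classification of the flattened
#' scan with the sclera masked. The network input replicates the grayscale
#' image into three channels and paints the scleral region with the mask
#' colour (127,0,0), the "highlighted region" that lets a network learn the
#' sclera near-perfectly.
#'
#' @param flattened A `flattened_choroid` on the 224 x 896 grid (see
#'   [resample_flattened()]).
#' @param window Niblack window size used for the ground truth.
#' @param k Niblack weight.
#' @param mask_input Paint the sclera into the input channels. Turning this
#'   off reproduces the unmasked-training condition.
#' @param labels Optional label map to use instead of the Niblack
#'   classification (e.g. phantom truth on the same grid).
#' @return List with `input` (integer array `rows x cols x 3`, 0..255) and
#'   `label` (label map).
#' @export
build_ground_truth <- function(flattened, window = 51, k = -0.05,
                               mask_input = TRUE, labels = NULL) {
  px <- flattened$pixels
  if (is.null(labels)) {
    tm <- niblack_threshold_map(px, window, k)
    labels <- classify_choroid(px, tm)
  }
  labels <- mask_sclera(labels, flattened$ocb_flat)
  input <- array(0L, c(nrow(px), ncol(px), 3L))
  for (ch in 1:3) input[, , ch] <- px
  if (mask_input) {
    scl <- labels == 2L
    pal <- label_palette()["sclera", ]
    for (ch in 1:3) {
      plane <- input[, , ch]
      plane[scl] <- pal[ch]
      input[, , ch] <- plane
    }
  }
  list(input = input, label = labels)
}

#' Split an image into four 224-column tiles
#'
#' A 224 x 896 image (or image/label array) is cut into four non-overlapping
#' 224 x 224 tiles at column offsets 0, 224, 448 and 672. The tiles partition
#' the input: [reassemble_tiles()] restores it byte-exactly.
#'
#' @param image Matrix or `H x W x C` array with `H = 224`, `W = 896`.
#' @return List of 4 tiles; the 0-based column offsets are attached as
#'   attribute `"offsets"`.
#' @export
tile_image <- function(image) {
  d <- dim(image)
  if (d[1] != 224 || d[2] != 896) {
    abort(sprintf("expected a 224 x 896 image, got %d x %d", d[1], d[2]))
  }
  offsets <- c(0L, 224L, 448L, 672L)
  tiles <- lapply(offsets, function(o) {
    if (length(d) == 2) image[, (o + 1L):(o + 224L), drop = FALSE]
    else image[, (o + 1L):(o + 224L), , drop = FALSE]
  })
  attr(tiles, "offsets") <- offsets
  tiles
}

#' @rdname tile_image
#' @param tiles List of 4 tiles as produced by [tile_image()].
#' @return `reassemble_tiles()`: the original image.
#' @export
reassemble_tiles <- function(tiles) {
  if (length(tiles) != 4) abort("expected exactly 4 tiles.")
  if (length(dim(tiles[[1]])) == 2) {
    do.call(cbind, tiles)
  } else {
    out <- array(tiles[[1]][1] * 0L, c(dim(tiles[[1]])[1], 896L, dim(tiles[[1]])[3]))
    for (i in 1:4) out[, ((i - 1L) * 224L + 1L):(i * 224L), ] <- tiles[[i]]
    out
  }
}

#' Subject-grouped train / validation / test split
#'
#' Subjects (not scans) are allocated to partitions, so every scan of a
#' subject -- all visits, repeats and orientations -- lands in exactly one
#' partition. The allocation is a seeded random permutation; counts are the
#' rounded fractions of the subject count.
#'
#' @param subjects Vector of unique subject ids.
#' @param fractions Target (train, validation, test) fractions, summing to 1.
#' @param seed Integer seed; the same seed reproduces the same split.
#' @return Tibble with columns `subject` and `partition`
#'   (train/validation/test), carrying `fractions` and `seed` as attributes.
#' @export
split_by_subject <- function(subjects, fractions = c(0.6, 0.2, 0.2), seed = 1L) {
  subjects <- unique(subjects)
  n <- length(subjects)
  if (n < 3) abort("need at least 3 subjects to fill 3 partitions.")
  if (abs(sum(fractions) - 1) > 1e-8) abort("`fractions` must sum to 1.")
  n_val <- round(fractions[2] * n)
  n_test <- round(fractions[3] * n)
  n_train <- n - n_val - n_test
  if (min(n_train, n_val, n_test) < 1) {
    abort("fractions leave an empty partition; add subjects or rebalance.")
  }
  perm <- withr::with_seed(seed, sample(subjects))
  out <- tibble(
    subject = perm,
    partition = rep(c("train", "validation", "test"),
                    times = c(n_train, n_val, n_test)))
  out <- out[order(match(out$subject, subjects)), ]
  attr(out, "fractions") <- fractions
  attr(out, "seed") <- seed
  out
}

#' Per-partition class-proportion summary
#'
#' For each image the percentage of interstitial, lumen and sclera pixels is
#' taken over all pixels; the CVI is taken over choroidal pixels only and is
#' missing (`NA`, excluded from the partition mean) for images without
#' choroid. Partition means and standard deviations summarize the dataset the
#' way a dataset-description table would.
#'
#' @param labelsets List of label maps.
#' @param partitions Character vector, one partition name per label map.
#' @return Tibble: partition, image count, mean and SD of each category
#'   percentage and of the CVI.
#' @export
summarize_proportions <- function(labelsets, partitions) {
  if (length(labelsets) != length(partitions)) {
    abort("`labelsets` and `partitions` must have the same length.")
  }
  per_image <- purrr::map2_dfr(labelsets, partitions, function(l, p) {
    l <- as_labelmap(l)
    n <- length(l)
    tibble(partition = p,
           interstitial = 100 * sum(l == 0L) / n,
           lumen = 100 * sum(l == 1L) / n,
           sclera = 100 * sum(l == 2L) / n,
           cvi = cvi(l))
  })
  per_image |>
    dplyr::group_by(.data$partition) |>
    dplyr::summarise(
      n_images = dplyr::n(),
      dplyr::across(c("interstitial", "lumen", "sclera", "cvi"),
                    list(mean = ~mean(.x, na.rm = TRUE),
                         sd = ~sd(.x, na.rm = TRUE))),
      .groups = "drop")
}

#' @export
autoplot.window_sweep <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$window, y = .data$cvi_percent)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "Niblack window size (px)", y = "CVI (%)",
                  title = "CVI as a function of binarization window size")
}

#' Write a tiled dataset to disk
#'
#' Lays out network-ready tiles as
#' `out_dir/<partition>/{inputs,labels}/<subject>_v<visit>_r<rep>_<orient>_t<tile>.png`
#' with a provenance manifest CSV and an optional config YAML, the layout a
#' training loop can stream from.
#'
#' @param pairs List of [build_ground_truth()] results (224 x 896 input/label
#'   pairs), one per manifest row.
#' @param manifest Tibble with columns subject, visit, repetition,
#'   orientation (one row per scan, same order as `pairs`).
#' @param split A [split_by_subject()] assignment covering every subject.
#' @param out_dir Output directory.
#' @param config Optional list written as `config.yaml`.
#' @return Tibble manifest of written tiles (one row per tile), invisibly.
#' @export
write_dataset <- function(pairs, manifest, split, out_dir, config = NULL) {
  if (length(pairs) != nrow(manifest)) {
    abort("`pairs` and `manifest` must have one entry per scan.")
  }
  manifest <- dplyr::left_join(manifest, split, by = "subject")
  if (anyNA(manifest$partition)) abort("split does not cover every subject.")
  rows <- list()
  for (i in seq_len(nrow(manifest))) {
    part <- manifest$partition[i]
    for (sub in c("inputs", "labels")) {
      dir.create(file.path(out_dir, part, sub), recursive = TRUE,
                 showWarnings = FALSE)
    }
    xt <- tile_image(pairs[[i]]$input)
    yt <- tile_image(pairs[[i]]$label)
    for (t in 1:4) {
      stem <- sprintf("%s_v%s_r%s_%s_t%d.png", manifest$subject[i],
                      manifest$visit[i], manifest$repetition[i],
                      manifest$orientation[i], t)
      png::writePNG(xt[[t]] / 255, file.path(out_dir, part, "inputs", stem))
      write_labelmap(yt[[t]], file.path(out_dir, part, "labels", stem))
      rows[[length(rows) + 1L]] <- dplyr::bind_cols(
        manifest[i, c("subject", "visit", "repetition", "orientation", "partition")],
        tibble(tile = t, column_offset = attr(xt, "offsets")[t], file = stem))
    }
  }
  if (!is.null(config)) {
    yaml::write_yaml(config, file.path(out_dir, "config.yaml"))
  }
  tiles <- dplyr::bind_rows(rows)
  readr::write_csv(tiles, file.path(out_dir, "manifest.csv"))
  invisible(tiles)
}
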