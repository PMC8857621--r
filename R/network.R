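#' Training configuration for the segmentation networks
#'
#' The reference regime is Adam with a constant learning rate of 1e-4,
#' cross-entropy loss, 15 epochs, mini-batches of 10 and reshuffling every
#' epoch, with 64 first-stage filters. `profile = "desk"` is a CPU-sized
#' profile (16 first-stage filters, 5 epochs, learning rate 1e-3 -- with only
#' ~100 optimizer steps the cold reference rate barely moves a randomly
#' initialized network).
#'
#' @param learning_rate Constant Adam step size.
#' @param epochs Training epochs.
#' @param batch_size Mini-batch size.
#' @param shuffle Reshuffle the training tiles every epoch.
#' @param seed Seed for initialization order and shuffling.
#' @param base_filters First-stage filter count; doubled at each pooling.
#' @param encoder_depth Number of pooling stages.
#' @param profile `"reference"` (the full-scale regime) or `"desk"`; presets
#'   overridden by explicit arguments.
#' @return Named list of class `train_config`.
#' @export
train_config <- function(learning_rate = NULL, epochs = NULL,
                         batch_size = 10, shuffle = TRUE, seed = 1L,
                         base_filters = NULL, encoder_depth = 4,
                         profile = c("reference", "desk")) {
  profile <- match.arg(profile)
  defaults <- if (profile == "desk") {
    list(learning_rate = 1e-3, epochs = 5, base_filters = 16)
  } else {
    list(learning_rate = 1e-4, epochs = 15, base_filters = 64)
  }
  cfg <- list(
    learning_rate = learning_rate %||% defaults$learning_rate,
    epochs = as.integer(epochs %||% defaults$epochs),
    batch_size = as.integer(batch_size),
    shuffle = isTRUE(shuffle),
    seed = as.integer(seed),
    base_filters = as.integer(base_filters %||% defaults$base_filters),
    encoder_depth = as.integer(encoder_depth),
    profile = profile)
  if (cfg$epochs < 1 || cfg$batch_size < 1 || cfg$encoder_depth < 1) {
    abort("epochs, batch_size and encoder_depth must be >= 1.")
  }
  structure(cfg, class = "train_config")
}

#' Build a U-Net segmentation model
#'
#' A "U-shaped" encoder-decoder: each of the `encoder_depth` stages is a 3x3
#' convolution + ReLU followed by 2x2 max pooling, with the filter count
#' doubled at each pooling (`base_filters` x 1, 2, 4, 8 and a bottleneck of
#' `base_filters` x 16 at depth 4). The decoder mirrors the encoder with
#' nearest-neighbour upsampling and a skip concatenation from the matching
#' encoder stage before each convolution; a final 1x1 convolution and softmax
#' yield per-pixel probabilities for the three categories.
#'
#' @param base_filters First-stage filter count (64 reference, 16 desk
#'   scale).
#' @param encoder_depth Number of pooling stages (input height/width must be
#'   divisible by `2^encoder_depth`).
#' @param in_channels Input channels (3: grayscale replicated, sclera
#'   painted).
#' @param classes Output categories.
#' @param seed Seed for He-normal weight initialization.
#' @return Object of class `segmodel`.
#' @export
build_unet <- function(base_filters = 64, encoder_depth = 4, in_channels = 3,
                       classes = 3, seed = 1L) {
  new_segmodel("unet", base_filters, encoder_depth, in_channels, classes, seed)
}

#' Build a SegNet-style segmentation model
#'
#' Same encoder as [build_unet()], but the decoder upsamples with
#' max-unpooling: the argmax locations remembered by each encoder pooling
#' stage place the values back, preserving boundary detail without skip
#' concatenation. Trained from random initialization.
#'
#' @inheritParams build_unet
#' @return Object of class `segmodel`.
#' @export
build_segnet <- function(base_filters = 64, encoder_depth = 4, in_channels = 3,
                         classes = 3, seed = 1L) {
  new_segmodel("segnet", base_filters, encoder_depth, in_channels, classes, seed)
}

new_segmodel <- function(arch, base_filters, encoder_depth, in_channels,
                         classes, seed) {
  if (encoder_depth < 1) abort("`encoder_depth` must be >= 1.")
  weights <- .cn_init(as.integer(base_filters), as.integer(encoder_depth),
                      as.integer(in_channels), as.integer(classes), arch,
                      as.integer(seed))
  structure(
    list(arch = arch, base_filters = as.integer(base_filters),
         encoder_depth = as.integer(encoder_depth),
         in_channels = as.integer(in_channels), classes = as.integer(classes),
         weights = weights, trained = FALSE, history = NULL),
    class = "segmodel")
}

#' @export
print.segmodel <- function(x, ...) {
  n_par <- sum(vapply(x$weights$W, length, numeric(1))) +
    sum(vapply(x$weights$b, length, numeric(1)))
  cat(sprintf("<segmodel> %s, depth %d, base filters %d, %d classes, %s (%s parameters)\n",
              x$arch, x$encoder_depth, x$base_filters, x$classes,
              if (x$trained) "trained" else "untrained",
              format(n_par, big.mark = ",")))
  invisible(x)
}

cn_cfg <- function(model, config = NULL) {
  list(arch = model$arch, depth = model$encoder_depth,
       base_filters = model$base_filters, in_channels = model$in_channels,
       classes = model$classes,
       epochs = config$epochs %||% 1L, batch_size = config$batch_size %||% 1L,
       learning_rate = config$learning_rate %||% 1e-4,
       shuffle = config$shuffle %||% TRUE, seed = config$seed %||% 1L)
}

as_input_array <- function(x) {
  if (is.list(x)) {
    d <- dim(x[[1]])
    if (length(d) == 2) d <- c(d, 1L)
    out <- array(0, c(d, length(x)))
    for (i in seq_along(x)) out[, , , i] <- x[[i]]
    x <- out
  }
  if (length(dim(x)) == 3) dim(x) <- c(dim(x), 1L)
  storage.mode(x) <- "double"
  x
}

as_label_array <- function(y) {
  if (is.list(y)) {
    out <- array(0L, c(dim(y[[1]]), length(y)))
    for (i in seq_along(y)) out[, , i] <- y[[i]]
    y <- out
  }
  if (length(dim(y)) == 2) dim(y) <- c(dim(y), 1L)
  storage.mode(y) <- "integer"
  y
}

#' Train a segmentation model
#'
#' Pixel-wise cross-entropy minimized with Adam; mini-batches are reshuffled
#' every epoch. Training is deterministic given `config$seed` (single
#' threaded BLAS up to floating-point reduction order).
#'
#' @param model A [build_unet()] / [build_segnet()] model.
#' @param x Training inputs: list of `H x W x C` arrays or one
#'   `H x W x C x N` array, byte scale 0..255. `H`, `W` must be divisible by
#'   `2^encoder_depth`.
#' @param y Training labels: list of `H x W` label maps or an `H x W x N`
#'   array, codes 0..2.
#' @param config A [train_config()].
#' @return The model with updated weights and a `history` tibble
#'   (epoch, loss, accuracy).
#' @export
train_segmodel <- function(model, x, y, config = train_config(profile = "desk")) {
  if (is.list(x) && !length(x)) abort("empty training set.")
  x <- as_input_array(x); y <- as_label_array(y)
  n <- dim(x)[4]
  if (n < 1) abort("empty training set.")
  if (dim(y)[3] != n) abort("`x` and `y` hold different numbers of images.")
  check_geometry(model, dim(x)[1:2])
  fit <- .cn_train(x, y, model$weights, cn_cfg(model, config))
  model$weights <- fit$weights
  model$trained <- TRUE
  model$history <- tibble(epoch = seq_along(fit$loss),
                          loss = as.numeric(fit$loss),
                          accuracy = as.numeric(fit$accuracy))
  model$config <- config
  model
}

check_geometry <- function(model, hw) {
  if (any(hw %% 2^model$encoder_depth != 0)) {
    abort(sprintf("input %d x %d is not divisible by 2^%d",
                  hw[1], hw[2], model$encoder_depth))
  }
}

#' Train replicate models
#'
#' Trains the same architecture several times with identical
#' hyper-parameters but different seeds and reports each replicate's final
#' metrics, the protocol used to attach a mean and spread to a network's
#' score.
#'
#' @inheritParams train_segmodel
#' @param n Number of replicates.
#' @param seeds Seeds, one per replicate (default `config$seed + 0:(n-1)`).
#' @return List with `models` (list of trained models) and `summary` tibble
#'   (replicate, seed, final loss, final accuracy).
#' @export
train_replicates <- function(model, x, y, config = train_config(profile = "desk"),
                             n = 3, seeds = NULL) {
  seeds <- seeds %||% (config$seed + seq_len(n) - 1L)
  models <- vector("list", n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    cfg <- config
    cfg$seed <- as.integer(seeds[i])
    init <- new_segmodel(model$arch, model$base_filters, model$encoder_depth,
                         model$in_channels, model$classes, seed = cfg$seed)
    models[[i]] <- train_segmodel(init, x, y, cfg)
    h <- models[[i]]$history
    rows[[i]] <- tibble(replicate = i, seed = seeds[i],
                        loss = h$loss[nrow(h)], accuracy = h$accuracy[nrow(h)])
  }
  list(models = models, summary = dplyr::bind_rows(rows))
}

#' Per-pixel class probabilities
#'
#' @param model A trained [train_segmodel()] model.
#' @param x Inputs as in [train_segmodel()].
#' @return Array `H x W x classes x N` of probabilities (each pixel sums
#'   to 1).
#' @export
predict_probs <- function(model, x) {
  x <- as_input_array(x)
  check_geometry(model, dim(x)[1:2])
  .cn_predict(x, model$weights, cn_cfg(model))
}

#' Predicted label maps
#'
#' Argmax of [predict_probs()]; ties resolve to the lowest class code.
#'
#' @inheritParams predict_probs
#' @return List of label maps (one per input image).
#' @export
predict_labels <- function(model, x) {
  p <- predict_probs(model, x)
  d <- dim(p)
  lapply(seq_len(d[4]), function(i) {
    m <- matrix(p[, , , i], d[1] * d[2], d[3])
    matrix(as.integer(max.col(m, ties.method = "first") - 1L), d[1], d[2])
  })
}

#' Predict a full-width scan from its four tiles
#'
#' Applies the model to each 224 x 224 tile and reassembles the argmax label
#' maps at the tile offsets, so evaluation runs on the full 224 x 896 scan
#' rather than on tiles.
#'
#' @param model Trained model.
#' @param tiles List of 4 input tiles from [tile_image()].
#' @return A 224 x 896 label map.
#' @export
predict_full <- function(model, tiles) {
  if (length(tiles) != 4) abort("expected exactly 4 tiles with their offsets.")
  reassemble_tiles(predict_labels(model, tiles))
}
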