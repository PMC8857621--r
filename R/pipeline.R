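#' Pipeline configuration
#'
#' Collects every stage parameter with the reference defaults: Niblack
#' k = -0.05, fixed window 51, sweep 20..75, subject-grouped 60/20/20 split,
#' and the Adam regime (constant learning rate, cross-entropy, shuffling
#' mini-batches). The simulation block sizes the synthetic corpus.
#'
#' @param out_dir Output directory for artifacts (`NULL`: in-memory only).
#' @param seed Master seed for simulation and splitting.
#' @param n_subjects,visits,jitter Corpus design (subjects, visits per
#'   subject, lateral jitter in pixels between repeat scans).
#' @param window Ground-truth window size: an integer for a fixed window, or
#'   `"auto"` to select per image from the CVI sweep plateau.
#' @param k Niblack weight.
#' @param sweep_windows Window sizes for the sweep stage.
#' @param scleral_margin Rows of sclera kept below the deepest OCB.
#' @param fractions Train/validation/test fractions.
#' @param arch `"unet"` or `"segnet"`.
#' @param train Training configuration from [train_config()].
#' @return Named list of class `run_config`.
#' @export
pipeline_config <- function(out_dir = NULL, seed = 1L, n_subjects = 6,
                            visits = 1, jitter = 2, window = 51, k = -0.05,
                            sweep_windows = 20:75, scleral_margin = 15,
                            fractions = c(0.6, 0.2, 0.2), arch = "unet",
                            train = train_config(profile = "desk", seed = seed)) {
  structure(as.list(environment()), class = "run_config")
}

#' Run the full synthetic pipeline
#'
#' Executes simulate, flatten, binarize, build-dataset, train, predict and
#' evaluate in order on a phantom corpus, and returns (and optionally writes)
#' the evaluation report: accuracy and IoU against the ground truth on the
#' full-width test scans, per-class repeatability across repeat pairs, and
#' ICC / Bland-Altman agreement of the CVI between repeats.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress per-stage messages.
#' @return List with the corpus manifest, split, training history, per-image
#'   metrics tibble and the aggregate [metrics_report()].
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- Sys.time()

  say("[simulate] %d subjects x %d visits", config$n_subjects, config$visits)
  corpus <- generate_corpus(config$n_subjects, visits = config$visits,
                            seed = config$seed, jitter = config$jitter)
  manifest <- corpus$manifest

  say("[flatten] %d scans", nrow(manifest))
  crop <- compute_crop_height(lapply(corpus$scans, `[[`, "boundaries"),
                              scleral_margin = config$scleral_margin)
  prepared <- lapply(corpus$scans, function(ph) {
    fl <- flatten_bscan(ph$scan, ph$boundaries, crop)
    resample_flattened(fl, 224, 896)
  })

  say("[binarize] ground truth, window = %s, k = %g", config$window, config$k)
  gt <- lapply(prepared, function(fl) {
    w <- config$window
    if (identical(w, "auto")) {
      w <- select_window(window_sweep_cvi(fl, config$sweep_windows, config$k))
    }
    build_ground_truth(fl, window = w, k = config$k)
  })

  say("[build-dataset] tiling and subject-grouped split")
  split <- split_by_subject(unique(manifest$subject), config$fractions,
                            seed = config$seed)
  manifest <- dplyr::left_join(manifest, split, by = "subject")
  tiles_x <- list(); tiles_y <- list()
  for (i in which(manifest$partition == "train")) {
    tiles_x <- c(tiles_x, tile_image(gt[[i]]$input))
    tiles_y <- c(tiles_y, tile_image(gt[[i]]$label))
  }

  say("[train] %s, %d tiles, %d epochs", config$arch, length(tiles_x),
      config$train$epochs)
  model <- new_segmodel(config$arch, config$train$base_filters,
                        config$train$encoder_depth, 3L, 3L,
                        seed = config$train$seed)
  model <- train_segmodel(model, tiles_x, tiles_y, config$train)

  say("[predict + evaluate] test partition")
  test_idx <- which(manifest$partition == "test")
  preds <- list()
  per_image <- list()
  for (i in test_idx) {
    pred <- predict_full(model, tile_image(gt[[i]]$input))
    preds[[as.character(i)]] <- pred
    cc <- confusion(pred, gt[[i]]$label)
    per_image[[length(per_image) + 1L]] <- dplyr::bind_cols(
      manifest[i, c("subject", "visit", "repetition", "orientation")],
      tibble(total_accuracy = accuracy(cc), mean_iou = mean_iou(cc),
             cvi_pred = cvi(pred), cvi_truth = cvi(gt[[i]]$label)))
  }
  per_image <- dplyr::bind_rows(per_image)

  # repeatability + CVI agreement across repeat pairs of the test partition
  pairs <- manifest[test_idx, ] |>
    dplyr::mutate(idx = test_idx) |>
    tidyr::pivot_wider(id_cols = c("subject", "visit", "orientation"),
                       names_from = "repetition", values_from = "idx")
  cvi1 <- vapply(pairs$`1`, function(i) cvi(preds[[as.character(i)]]), numeric(1))
  cvi2 <- vapply(pairs$`2`, function(i) cvi(preds[[as.character(i)]]), numeric(1))
  rep_R <- purrr::map2(pairs$`1`, pairs$`2`, function(i, j) {
    repeatability_R(preds[[as.character(i)]], preds[[as.character(j)]])
  })
  rep_mean <- colMeans(do.call(rbind, rep_R))

  report <- metrics_report(
    preds[[as.character(test_idx[1])]], gt[[test_idx[1]]]$label,
    cvi_pairs = if (nrow(pairs) >= 3) tibble(s1 = cvi1, s2 = cvi2))
  pooled <- confusion_pool(preds, gt, test_idx)
  summary <- list(
    total_accuracy = accuracy(pooled),
    per_class_accuracy = per_class_accuracy(pooled),
    mean_iou = mean_iou(pooled),
    repeatability_R = rep_mean,
    cvi_pred_mean = mean(cvi1, na.rm = TRUE),
    icc = report$icc, mean_difference = report$mean_difference,
    loa_halfwidth = report$loa_halfwidth)

  out <- list(manifest = manifest, split = split, crop_height = crop,
              history = model$history, model = model, per_image = per_image,
              summary = summary, elapsed_s = as.numeric(Sys.time() - t0, units = "secs"))

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(manifest[, setdiff(names(manifest), "scan")],
                     file.path(config$out_dir, "manifest.csv"))
    readr::write_csv(per_image, file.path(config$out_dir, "per_image_metrics.csv"))
    readr::write_csv(model$history, file.path(config$out_dir, "training_log.csv"))
    jsonlite::write_json(summary, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
    cfg <- config
    cfg$train <- unclass(cfg$train)
    yaml::write_yaml(unclass(cfg), file.path(config$out_dir, "config.yaml"))
  }
  say("[done] %.1f s", out$elapsed_s)
  invisible(out)
}

# pool confusion counts over several images
confusion_pool <- function(preds, gt, idx) {
  tabs <- lapply(idx, function(i) {
    confusion(preds[[as.character(i)]], gt[[i]]$label)$table
  })
  tab <- Reduce(`+`, tabs)
  tp <- diag(tab)
  structure(list(table = tab, tp = tp, fp = colSums(tab) - tp,
                 fn = rowSums(tab) - tp, n_pixels = sum(tab)),
            class = "confusion_counts")
}
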