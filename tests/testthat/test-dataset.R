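test_that("a 224x896 image tiles into 4 partitions that reassemble byte-exactly", {
  withr::with_seed(41, img <- matrix(sample(0:255, 224 * 896, TRUE), 224, 896))
  tiles <- tile_image(img)
  expect_length(tiles, 4)
  expect_identical(attr(tiles, "offsets"), c(0L, 224L, 448L, 672L))
  expect_true(all(vapply(tiles, function(t) all(dim(t) == c(224, 224)), logical(1))))
  expect_identical(reassemble_tiles(tiles), img)
  # tile 3 (0-based tile 2) pixel (r, c) = parent (r, 448 + c), 0-based
  expect_identical(tiles[[3]][10, 17], img[10, 448 + 17])
  expect_error(tile_image(matrix(0L, 100, 100)), "224 x 896")
})

test_that("3-channel arrays tile and reassemble like matrices", {
  withr::with_seed(42, arr <- array(sample(0:255, 224 * 896 * 3, TRUE),
                                    c(224, 896, 3)))
  expect_identical(reassemble_tiles(tile_image(arr)), arr)
})

test_that("ground-truth inputs replicate grayscale and paint the sclera", {
  ph <- generate_phantom(phantom_spec(seed = 43))
  crop <- compute_crop_height(ph$boundaries, 15)
  fl <- resample_flattened(flatten_bscan(ph$scan, ph$boundaries, crop), 224, 896)
  gt <- build_ground_truth(fl, window = 51)
  scl <- gt$label == 2L
  expect_true(any(scl))
  expect_true(all(gt$input[, , 1][scl] == 127L))
  expect_true(all(gt$input[, , 2][scl] == 0L))
  expect_true(all(gt$input[, , 3][scl] == 0L))
  expect_true(all(gt$input[, , 1][!scl] == fl$pixels[!scl]))
  expect_identical(gt$input[, , 2][!scl], gt$input[, , 3][!scl])
  # without sclera in view the three channels are the plain grayscale
  no_scl <- fl; no_scl$ocb_flat <- rep(224L, 896)
  gt2 <- build_ground_truth(no_scl, window = 51)
  for (ch in 1:3) expect_identical(gt2$input[, , ch], fl$pixels)
})

test_that("ground-truth labels agree with the binarization module", {
  ph <- generate_phantom(phantom_spec(seed = 44))
  crop <- compute_crop_height(ph$boundaries, 15)
  fl <- resample_flattened(flatten_bscan(ph$scan, ph$boundaries, crop), 224, 896)
  gt <- build_ground_truth(fl, window = 51)
  tm <- niblack_threshold_map(fl$pixels, 51)
  lab <- mask_sclera(classify_choroid(fl$pixels, tm), fl$ocb_flat)
  expect_identical(gt$label, lab)
  expect_equal(cvi(gt$label), cvi(lab))
})

test_that("label resampling preserves codes and geometry", {
  l <- random_labelmap(59, 429)
  r <- resample_labels(l, 224, 896)
  expect_identical(dim(r), c(224L, 896L))
  expect_true(all(r %in% 0:2))
  # identity when the grid matches
  expect_identical(resample_labels(l, 59, 429), l)
})

test_that("subject-grouped splits have rounded counts, determinism and integrity", {
  subj <- sprintf("P%02d", 1:10)
  sp <- split_by_subject(subj, c(0.6, 0.2, 0.2), seed = 7)
  expect_identical(as.integer(table(sp$partition)[c("train", "validation", "test")]),
                   c(6L, 2L, 2L))
  expect_identical(sp, split_by_subject(subj, c(0.6, 0.2, 0.2), seed = 7))
  expect_false(identical(sp$partition,
                         split_by_subject(subj, seed = 8)$partition) &&
                 identical(sp$subject, split_by_subject(subj, seed = 8)$subject))
  expect_error(split_by_subject(c("a", "b")), "at least 3")
  expect_error(split_by_subject(subj, c(0.5, 0.2, 0.2)), "sum to 1")
})

test_that("no subject's scans straddle partitions in a full corpus", {
  corpus <- generate_corpus(10, visits = 2, seed = 45,
                            spec_sampler = function(i, seed) small_spec(seed))
  sp <- split_by_subject(unique(corpus$manifest$subject), seed = 9)
  joined <- dplyr::left_join(corpus$manifest, sp, by = "subject")
  per_subject <- dplyr::summarise(dplyr::group_by(joined, subject),
                                  n = dplyr::n_distinct(partition))
  expect_true(all(per_subject$n == 1))
  expect_identical(nrow(joined), 10L * 2L * 2L * 2L)
})

test_that("proportion summaries compute per-image percentages and partition stats", {
  half <- matrix(c(rep(1L, 50), rep(0L, 50)), 10, 10)
  out <- summarize_proportions(list(half), "train")
  expect_equal(out$lumen_mean, 50)
  expect_equal(out$lumen_sd, NA_real_)
  expect_equal(out$cvi_mean, 50)
  # all-sclera image: sclera 100%, CVI missing and excluded from the mean
  scl <- matrix(2L, 10, 10)
  out2 <- summarize_proportions(list(half, scl, half), rep("test", 3))
  expect_equal(out2$sclera_mean, 100 / 3, tolerance = 1e-12)
  expect_equal(out2$cvi_mean, 50)
  expect_identical(out2$n_images, 3L)
})

test_that("resampling to the network grid keeps the OCB consistent", {
  ph <- generate_phantom(phantom_spec(seed = 46))
  crop <- compute_crop_height(ph$boundaries, 15)
  fl <- flatten_bscan(ph$scan, ph$boundaries, crop)
  rs <- resample_flattened(fl, 224, 896)
  expect_identical(dim(rs$pixels), c(224L, 896L))
  expect_true(all(rs$ocb_flat >= 0 & rs$ocb_flat <= 224))
  expect_equal(mean(rs$ocb_flat) / 224, mean(fl$ocb_flat) / crop,
               tolerance = 0.02)
})

test_that("the on-disk dataset layout round-trips tiles and provenance", {
  out <- withr::local_tempdir()
  corpus <- generate_corpus(3, visits = 1, seed = 47,
                            spec_sampler = function(i, seed) small_spec(seed))
  crop <- compute_crop_height(lapply(corpus$scans, `[[`, "boundaries"), 10)
  pairs <- lapply(corpus$scans, function(ph) {
    fl <- resample_flattened(flatten_bscan(ph$scan, ph$boundaries, crop), 224, 896)
    build_ground_truth(fl, window = 31)
  })
  split <- split_by_subject(unique(corpus$manifest$subject), seed = 1)
  tiles <- write_dataset(pairs, corpus$manifest, split, out)
  expect_identical(nrow(tiles), nrow(corpus$manifest) * 4L)
  expect_identical(sort(unique(tiles$column_offset)), c(0L, 224L, 448L, 672L))
  expect_true(file.exists(file.path(out, "manifest.csv")))
  # a written label tile decodes back to the in-memory labels
  r1 <- tiles[tiles$tile == 2, ][1, ]
  scan_i <- which(corpus$manifest$subject == r1$subject &
                    corpus$manifest$repetition == r1$repetition &
                    corpus$manifest$orientation == r1$orientation)[1]
  lab <- read_labelmap(file.path(out, r1$partition, "labels", r1$file))
  expect_identical(lab, tile_image(pairs[[scan_i]]$label)[[2]])
  # inputs reload byte-exactly
  x <- png::readPNG(file.path(out, r1$partition, "inputs", r1$file))
  expect_identical(round(x * 255), round(tile_image(pairs[[scan_i]]$input)[[2]] / 1))
})
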