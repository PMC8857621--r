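test_that("constant images threshold at their own value and k = 0 gives the local mean", {
  x <- matrix(37, 12, 15)
  expect_equal(niblack_threshold_map(x, 5, k = -0.05),
               matrix(37, 12, 15))
  withr::with_seed(4, y <- matrix(runif(12 * 15, 0, 255), 12))
  expect_equal(niblack_threshold_map(y, 7, k = 0), naive_niblack(y, 7, 0),
               tolerance = 1e-12)
})

test_that("the hand-computed 5x5 spike example reproduces", {
  x <- matrix(10, 5, 5)
  x[3, 3] <- 100
  tm <- niblack_threshold_map(x, 3, k = -0.05)
  # centre window: mean 20, population SD sqrt(800)
  expect_equal(tm[3, 3], 20 - 0.05 * sqrt(800), tolerance = 1e-12)
  expect_equal(tm[3, 3], 18.58579, tolerance = 1e-5)
  lab <- classify_choroid(x, tm)
  expect_identical(lab[3, 3], 0L)                # 100 >= T -> interstitial
  expect_identical(lab[3, 2], 1L)                # 10 < T -> lumen
})

test_that("sliding-window thresholds equal the naive double-loop oracle", {
  withr::with_seed(11, {
    for (i in 1:5) {
      x <- matrix(runif(32 * 64, 0, 255), 32, 64)
      for (w in c(3, 5, 9, 15)) {
        for (k in c(-0.05, 0, 0.2)) {
          expect_lt(max(abs(niblack_threshold_map(x, w, k) -
                              naive_niblack(x, w, k))), 1e-9)
        }
      }
    }
  })
})

test_that("even windows centre at offset floor(w/2) and match the oracle", {
  withr::with_seed(12, x <- matrix(runif(20 * 25, 0, 255), 20))
  for (w in c(4, 8)) {
    expect_lt(max(abs(niblack_threshold_map(x, w, -0.05) -
                        naive_niblack(x, w, -0.05))), 1e-9)
  }
})

test_that("window bounds are validated", {
  x <- matrix(0, 10, 40)
  expect_error(niblack_threshold_map(x, 2), "at least 3")
  expect_error(niblack_threshold_map(x, 21), "exceeds twice")
})

test_that("a pixel exactly at its threshold is interstitial (tie rule)", {
  x <- matrix(55, 8, 8)
  tm <- niblack_threshold_map(x, 3, k = -0.05)   # equals 55 everywhere
  expect_true(all(classify_choroid(x, tm) == 0L))
})

test_that("decreasing k never increases the lumen count", {
  ph <- generate_phantom(small_spec(13))
  fl <- flatten_bscan(ph$scan, ph$boundaries, compute_crop_height(ph$boundaries, 10))
  counts <- vapply(c(0.2, 0.05, 0, -0.05, -0.2), function(k) {
    sum(classify_choroid(fl$pixels, niblack_threshold_map(fl$pixels, 15, k)) == 1L)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("masking the sclera before or after classification commutes", {
  ph <- generate_phantom(small_spec(14))
  fl <- flatten_bscan(ph$scan, ph$boundaries, compute_crop_height(ph$boundaries, 10))
  tm <- niblack_threshold_map(fl, 15)
  lab_after <- mask_sclera(classify_choroid(fl$pixels, tm), fl$ocb_flat)
  lab_inline <- classify_choroid(fl, tm)         # uses ocb_flat internally
  expect_identical(lab_after, lab_inline)
})

test_that("sclera masking paints exactly the rows at/below the OCB", {
  lab <- matrix(0L, 10, 4)
  expect_identical(mask_sclera(lab, rep(10L, 4)), lab)        # empty sclera
  expect_true(all(mask_sclera(lab, rep(0L, 4)) == 2L))        # total mask
  ph <- generate_phantom(small_spec(15))
  fl <- flatten_bscan(ph$scan, ph$boundaries, compute_crop_height(ph$boundaries, 10))
  masked <- mask_sclera(matrix(0L, nrow(fl$pixels), ncol(fl$pixels)), fl$ocb_flat)
  expect_identical(sum(masked == 2L),
                   sum(pmax(nrow(fl$pixels) - fl$ocb_flat, 0L)))
})

test_that("the window sweep returns one CVI per window, deterministically", {
  ph <- generate_phantom(small_spec(16))
  fl <- flatten_bscan(ph$scan, ph$boundaries, compute_crop_height(ph$boundaries, 10))
  sw <- window_sweep_cvi(fl, windows = c(20, 30, 40))
  expect_identical(nrow(sw), 3L)
  expect_identical(sw$window, c(20L, 30L, 40L))
  sw2 <- window_sweep_cvi(fl, windows = c(30, 30))
  expect_identical(sw2$cvi_percent[1], sw2$cvi_percent[2])
})

test_that("window selection picks the nearest-to-truth or flattest-plateau window", {
  sweep <- tibble::tibble(window = c(20L, 30L, 40L), cvi_percent = c(50, 60, 61))
  expect_identical(select_window(sweep, truth = 60), 30L)
  # monotone rise with a constant tail: first window of the tail
  sweep2 <- tibble::tibble(window = 20:26,
                           cvi_percent = c(40, 45, 50, 55, 57, 57, 57))
  expect_identical(select_window(sweep2), 24L)
  expect_error(select_window(sweep2[0, ]), "non-empty")
})

test_that("selected windows track the programmed vessel size", {
  diam <- numeric(0); sel <- numeric(0)
  for (i in 1:20) {
    r <- 2 + (i - 1) %% 5 * 1.5                 # semi-axes 2 .. 8
    ph <- generate_phantom(small_spec(100 + i, vessel_radius_range = c(r, r + 2)))
    fl <- flatten_bscan(ph$scan, ph$boundaries,
                        compute_crop_height(ph$boundaries, 10))
    sw <- window_sweep_cvi(fl, windows = seq(4, 40, by = 2))
    sel <- c(sel, select_window(sw))            # plateau rule, no truth
    diam <- c(diam, 2 * (r + 1))
  }
  expect_gt(cor(diam, sel, method = "spearman"), 0.5)
})
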