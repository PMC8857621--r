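test_that("confusion counts match hand-enumerated and brute-force values", {
  truth <- matrix(c(1L, 1L, 0L, 0L), 2, byrow = TRUE)
  pred <- matrix(c(1L, 0L, 0L, 0L), 2, byrow = TRUE)
  cc <- confusion(pred, truth)
  expect_equal(unname(cc$tp["lumen"]), 1)
  expect_equal(unname(cc$fn["lumen"]), 1)
  expect_equal(unname(cc$fp["lumen"]), 0)
  expect_equal(accuracy(cc, "lumen"), 0.5)
  expect_equal(accuracy(cc), 0.75)

  cc2 <- confusion(truth, truth)
  expect_true(all(cc2$fp == 0) && all(cc2$fn == 0))
  expect_equal(accuracy(cc2), 1)
  expect_true(all(iou(cc2)[c("interstitial", "lumen")] == 1))

  withr::with_seed(21, {
    p <- random_labelmap(50, 50); t <- random_labelmap(50, 50)
  })
  got <- confusion(p, t)
  want <- naive_confusion(p, t)
  expect_equal(unname(got$tp), unname(want$tp))
  expect_equal(unname(got$fp), unname(want$fp))
  expect_equal(unname(got$fn), unname(want$fn))
  expect_error(confusion(p, t[1:10, ]), "different shapes")
})

test_that("IoU follows its formula and empty classes are missing, not zero", {
  cc <- structure(list(tp = c(interstitial = 1, lumen = 0, sclera = 0),
                       fp = c(interstitial = 1, lumen = 0, sclera = 0),
                       fn = c(interstitial = 1, lumen = 0, sclera = 0),
                       n_pixels = 3), class = "confusion_counts")
  expect_equal(iou(cc, "interstitial"), 1 / 3)
  expect_true(is.na(iou(cc, "lumen")))
  expect_equal(mean_iou(cc), 1 / 3)
  expect_true(is.na(accuracy(cc, "sclera")))
})

test_that("total accuracy is the count-weighted blend of per-class accuracies", {
  withr::with_seed(22, {
    p <- random_labelmap(40, 40); t <- random_labelmap(40, 40)
  })
  cc <- confusion(p, t)
  weights <- cc$tp + cc$fn
  expect_equal(accuracy(cc),
               sum(per_class_accuracy(cc) * weights, na.rm = TRUE) / sum(weights))
})

test_that("IoU never exceeds per-class accuracy", {
  withr::with_seed(23, {
    for (i in 1:100) {
      p <- random_labelmap(12, 12); t <- random_labelmap(12, 12)
      cc <- confusion(p, t)
      ok <- !is.na(iou(cc)) & !is.na(per_class_accuracy(cc))
      expect_true(all(iou(cc)[ok] <= per_class_accuracy(cc)[ok] + 1e-12))
    }
  })
})

test_that("CVI is the luminal share of the choroid, ignoring sclera", {
  expect_equal(cvi(matrix(1L, 5, 5)), 100)
  lab <- matrix(c(rep(1L, 60), rep(0L, 40), rep(2L, 30)), ncol = 1)
  expect_equal(cvi(lab), 60)
  lab2 <- rbind(matrix(lab[1:100], ncol = 1), matrix(2L, 70, 1))
  expect_equal(cvi(lab2), 60)                       # sclera count irrelevant
  expect_true(is.na(cvi(matrix(2L, 4, 4))))         # no choroid -> missing
})

test_that("phantom truth CVI matches the analytic luminal fraction", {
  ph <- generate_phantom(small_spec(24))
  crop <- compute_crop_height(ph$boundaries, 10)
  expect_equal(cvi(phantom_flat_truth(ph, crop)),
               100 * ph$truth$lumen_fraction, tolerance = 0.02)
})

test_that("repeatability R follows its formula and is a pseudometric", {
  a <- matrix(0L, 100, 100)
  expect_true(all(repeatability_R(a, a) == 0))
  b <- a; b[1:150] <- 1L
  expect_equal(unname(repeatability_R(a, b, "lumen")), 1.5)  # |0-150|/10000*100
  withr::with_seed(25, {
    for (i in 1:20) {
      x <- random_labelmap(10, 10); y <- random_labelmap(10, 10)
      expect_equal(repeatability_R(x, y), repeatability_R(y, x))
      expect_true(all(repeatability_R(x, y) >= 0))
    }
  })
  expect_error(repeatability_R(a, a[1:10, ]), "different shapes")
})

test_that("ICC is 1 for identical series and near 0 for independent noise", {
  x <- c(10, 12, 14, 16, 20, 30)
  expect_equal(icc(x, x)$icc, 1)
  withr::with_seed(26, {
    a <- rnorm(1000, 50, 3); b <- rnorm(1000, 50, 3)
  })
  expect_lt(abs(icc(a, b)$icc), 0.1)
})

test_that("ICC recovers the closed-form variance ratio from simulated pairs", {
  withr::with_seed(27, {
    subj <- rnorm(400, 60, 3)
    s1 <- subj + rnorm(400, 0, 1)
    s2 <- subj + rnorm(400, 0, 1)
  })
  expect_equal(icc(s1, s2)$icc, 9 / 10, tolerance = 0.05 / 0.9)
})

test_that("ICC mean squares agree with a two-way ANOVA decomposition", {
  withr::with_seed(28, {
    subj <- rnorm(30, 0, 2)
    y1 <- subj + rnorm(30); y2 <- subj + 0.5 + rnorm(30)
  })
  fit <- icc(y1, y2)
  df <- data.frame(y = c(y1, y2),
                   s = factor(rep(1:30, 2)), r = factor(rep(1:2, each = 30)))
  ms <- summary(stats::aov(y ~ s + r, data = df))[[1]][["Mean Sq"]]
  expect_equal(fit$msr, ms[1], tolerance = 1e-10)
  expect_equal(fit$msc, ms[2], tolerance = 1e-10)
  expect_equal(fit$mse, ms[3], tolerance = 1e-10)
})

test_that("degenerate ICC inputs are handled", {
  expect_true(is.na(icc(rep(1, 5), rep(1, 5))$icc))
  expect_error(icc(1:2, 1:2), "at least 3")
})

test_that("Bland-Altman reproduces a hand-computed 3-pair example", {
  ba <- bland_altman(c(10, 20, 30), c(12, 18, 31))
  d <- c(-2, 2, -1)
  expect_equal(ba$mean_difference, mean(d))
  expect_equal(ba$loa_halfwidth, 1.96 * sd(d))
  expect_equal(ba$loa_upper - ba$loa_lower, 2 * 1.96 * sd(d))
  ident <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ident$mean_difference, 0)
  expect_equal(ident$loa_halfwidth, 0)
  expect_error(bland_altman(1, 2), "at least 2")
})

test_that("Bland-Altman recovers simulation parameters", {
  withr::with_seed(29, {
    base <- rnorm(5000, 60, 3)
    s1 <- base + rnorm(5000, 0.1, 1.2 / sqrt(2))
    s2 <- base + rnorm(5000, 0, 1.2 / sqrt(2))
  })
  ba <- bland_altman(s1, s2)
  expect_equal(ba$mean_difference, 0.1, tolerance = 0.05 / 0.1)
  expect_equal(ba$loa_halfwidth, 1.96 * 1.2, tolerance = 0.1 / (1.96 * 1.2))
})

test_that("tidy/glance/autoplot methods return the expected shapes", {
  ba <- bland_altman(c(10, 20, 30), c(12, 18, 31))
  expect_identical(tidy(ba)$term, c("mean_difference", "loa_lower", "loa_upper"))
  expect_identical(nrow(glance(ba)), 1L)
  expect_s3_class(autoplot(ba), "ggplot")
  fit <- icc(c(1, 2, 3, 4), c(1.1, 2.2, 2.9, 4.3))
  expect_identical(nrow(tidy(fit)), 1L)
  expect_identical(glance(fit)$n, 4L)
})

test_that("metrics_report bundles the full evaluation surface", {
  withr::with_seed(30, {
    t <- random_labelmap(30, 30); p <- t
    p[sample(900, 50)] <- sample(0:2, 50, TRUE)
    pairs <- tibble::tibble(s1 = rnorm(10, 60, 3), s2 = rnorm(10, 60, 3))
  })
  rep <- metrics_report(p, t, pred_repeat = p, cvi_pairs = pairs)
  expect_s3_class(rep, "metrics_report")
  expect_true(all(repeatability_R(p, p) == rep$repeatability_R))
  tb <- tibble::as_tibble(rep)
  expect_identical(nrow(tb), 1L)
  expect_true(all(c("total_accuracy", "mean_iou", "icc", "loa_halfwidth")
                  %in% names(tb)))
})
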