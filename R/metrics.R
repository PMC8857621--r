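#' Pixel-wise confusion counts between two label maps
#'
#' @param pred,truth Label maps of identical shape.
#' @return Object of class `confusion_counts`: the 3 x 3 count matrix (rows =
#'   truth, columns = prediction) plus per-class TP/FP/FN.
#' @export
confusion <- function(pred, truth) {
  pred <- as_labelmap(pred); truth <- as_labelmap(truth)
  if (!all(dim(pred) == dim(truth))) {
    abort("`pred` and `truth` have different shapes.")
  }
  lv <- label_levels()
  tab <- table(factor(truth, levels = lv), factor(pred, levels = lv))
  tab <- matrix(as.numeric(tab), 3, 3, dimnames = list(truth = label_names(),
                                                       pred = label_names()))
  tp <- diag(tab)
  structure(
    list(table = tab,
         tp = tp,
         fp = colSums(tab) - tp,
         fn = rowSums(tab) - tp,
         n_pixels = sum(tab)),
    class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat("<confusion_counts> (rows = truth, cols = prediction)\n")
  print(x$table)
  invisible(x)
}

#' @export
as_tibble.confusion_counts <- function(x, ...) {
  tibble(class = label_names(), tp = unname(x$tp), fp = unname(x$fp),
         fn = unname(x$fn))
}

#' Segmentation accuracy
#'
#' Per class, accuracy is `TP / (TP + FN)` -- the fraction of that class's
#' ground-truth pixels labelled correctly. The total accuracy is the fraction
#' of all pixels labelled correctly. Classes absent from the ground truth
#' yield `NA` rather than 0/0.
#'
#' @param counts A [confusion()] result.
#' @param class Category name (`"interstitial"`, `"lumen"`, `"sclera"`) for a
#'   per-class value; `NULL` for the total.
#' @return Fraction in `[0, 1]`, or `NA` for an empty class.
#' @export
accuracy <- function(counts, class = NULL) {
  if (is.null(class)) return(sum(counts$tp) / counts$n_pixels)
  class <- match.arg(class, label_names())
  denom <- counts$tp[class] + counts$fn[class]
  if (denom == 0) return(NA_real_)
  unname(counts$tp[class] / denom)
}

#' @rdname accuracy
#' @return `per_class_accuracy()`: named numeric vector over all classes.
#' @export
per_class_accuracy <- function(counts) {
  vapply(label_names(), function(cl) accuracy(counts, cl), numeric(1))
}

#' Intersection over union
#'
#' `IoU = TP / (TP + FP + FN)` per class; a class absent from both prediction
#' and truth yields `NA` and is excluded from the mean.
#'
#' @inheritParams accuracy
#' @return `iou()`: scalar for one class or named vector over all classes;
#'   `mean_iou()`: mean of the per-class values, `NA`s removed.
#' @export
iou <- function(counts, class = NULL) {
  one <- function(cl) {
    denom <- counts$tp[cl] + counts$fp[cl] + counts$fn[cl]
    if (denom == 0) return(NA_real_)
    unname(counts$tp[cl] / denom)
  }
  if (!is.null(class)) return(one(match.arg(class, label_names())))
  vapply(label_names(), one, numeric(1))
}

#' @rdname iou
#' @export
mean_iou <- function(counts) {
  mean(iou(counts), na.rm = TRUE)
}

#' Choroidal vascularity index
#'
#' The CVI is the luminal share of the choroid: 100 times the number of lumen
#' pixels over the number of choroidal (lumen + interstitial) pixels. Sclera
#' pixels are excluded. An image with no choroidal pixels has no CVI and
#' returns `NA`.
#'
#' @param labels Label map.
#' @return CVI in percent, or `NA`.
#' @export
cvi <- function(labels) {
  labels <- as_labelmap(labels)
  lum <- sum(labels == 1L)
  chor <- lum + sum(labels == 0L)
  if (chor == 0) return(NA_real_)
  100 * lum / chor
}

#' Between-repeat repeatability of class proportions
#'
#' For two scans of the same eye, `R = |P1 - P2| / p * 100` where `P1`, `P2`
#' are the pixel counts of a category in each scan and `p` is the total pixel
#' count of an image. Zero means perfect agreement.
#'
#' @param labels1,labels2 Label maps of identical shape (the repeat pair).
#' @param class Category name, or `NULL` for all classes.
#' @return Percentage (scalar or named vector).
#' @export
repeatability_R <- function(labels1, labels2, class = NULL) {
  labels1 <- as_labelmap(labels1); labels2 <- as_labelmap(labels2)
  if (!all(dim(labels1) == dim(labels2))) {
    abort("label maps have different shapes.")
  }
  p <- length(labels1)
  one <- function(code) {
    100 * abs(sum(labels1 == code) - sum(labels2 == code)) / p
  }
  lv <- label_levels()
  if (!is.null(class)) return(one(lv[match.arg(class, label_names())]))
  vapply(lv, one, numeric(1))
}

resolve_pairs <- function(pairs, scan2) {
  if (!is.null(scan2)) return(list(s1 = as.numeric(pairs), s2 = as.numeric(scan2)))
  if (is.data.frame(pairs)) {
    if (ncol(pairs) < 2) abort("`pairs` needs two columns of paired measurements.")
    return(list(s1 = as.numeric(pairs[[1]]), s2 = as.numeric(pairs[[2]])))
  }
  abort("supply a two-column data frame or two vectors.")
}

#' Intraclass correlation for test-retest agreement
#'
#' Two-way random effects, absolute agreement, single measures -- ICC(2,1),
#' the standard model for two repeated measurements with the same instrument.
#' Computed from the two-way ANOVA mean squares
#' `(MSR - MSE) / (MSR + (k-1) MSE + k/n (MSC - MSE))`.
#'
#' @param pairs Data frame whose first two columns are the paired
#'   measurements (e.g. per-eye CVI from scan 1 and scan 2), or a numeric
#'   vector if `scan2` is given.
#' @param scan2 Optional second vector of measurements.
#' @return Object of class `icc_fit` with the coefficient and the mean
#'   squares; `NA` coefficient when there is no variance at all.
#' @export
icc <- function(pairs, scan2 = NULL) {
  p <- resolve_pairs(pairs, scan2)
  ok <- is.finite(p$s1) & is.finite(p$s2)
  y <- cbind(p$s1[ok], p$s2[ok])
  n <- nrow(y); k <- ncol(y)
  if (n < 3) abort("ICC needs at least 3 complete pairs.")
  grand <- mean(y)
  msr <- k * var(rowMeans(y))                        # between subjects
  msc <- n * sum((colMeans(y) - grand)^2) / (k - 1)  # between repeats
  sst <- sum((y - grand)^2)
  mse <- (sst - msr * (n - 1) - msc * (k - 1)) / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k / n * (msc - mse)
  est <- if (sst == 0 || denom == 0) NA_real_ else (msr - mse) / denom
  structure(list(icc = est, msr = msr, msc = msc, mse = mse, n = n, k = k),
            class = "icc_fit")
}

#' @export
print.icc_fit <- function(x, ...) {
  cat(sprintf("ICC(2,1) = %.4f  (n = %d pairs)\n", x$icc, x$n))
  invisible(x)
}

#' @export
tidy.icc_fit <- function(x, ...) {
  tibble(term = "ICC(2,1)", estimate = x$icc)
}

#' @export
glance.icc_fit <- function(x, ...) {
  tibble(icc = x$icc, msr = x$msr, msc = x$msc, mse = x$mse, n = x$n, k = x$k)
}

#' Bland-Altman agreement analysis
#'
#' Mean of the paired differences (scan 1 minus scan 2) and the 95% limits of
#' agreement, `mean +/- 1.96 * SD` with the sample (n-1) standard deviation.
#'
#' @inheritParams icc
#' @return Object of class `bland_altman` with `mean_difference`,
#'   `loa_halfwidth` (`1.96 * SD`), the limits, and the per-pair data.
#' @export
bland_altman <- function(pairs, scan2 = NULL) {
  p <- resolve_pairs(pairs, scan2)
  ok <- is.finite(p$s1) & is.finite(p$s2)
  d <- p$s1[ok] - p$s2[ok]
  if (length(d) < 2) abort("Bland-Altman needs at least 2 complete pairs.")
  m <- mean(d); s <- sd(d)
  structure(
    list(mean_difference = m,
         sd_difference = s,
         loa_halfwidth = 1.96 * s,
         loa_lower = m - 1.96 * s,
         loa_upper = m + 1.96 * s,
         n = length(d),
         means = (p$s1[ok] + p$s2[ok]) / 2,
         differences = d),
    class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman: mean difference %.3f, 95%% LOA [%.3f, %.3f] (n = %d)\n",
              x$mean_difference, x$loa_lower, x$loa_upper, x$n))
  invisible(x)
}

#' @export
tidy.bland_altman <- function(x, ...) {
  tibble(term = c("mean_difference", "loa_lower", "loa_upper"),
         estimate = c(x$mean_difference, x$loa_lower, x$loa_upper))
}

#' @export
glance.bland_altman <- function(x, ...) {
  tibble(mean_difference = x$mean_difference, sd_difference = x$sd_difference,
         loa_halfwidth = x$loa_halfwidth, n = x$n)
}

#' @export
autoplot.bland_altman <- function(object, ...) {
  df <- tibble(mean = object$means, difference = object$differences)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean, y = .data$difference)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = object$mean_difference, colour = "blue") +
    ggplot2::geom_hline(yintercept = c(object$loa_lower, object$loa_upper),
                        colour = "red", linetype = "dashed") +
    ggplot2::labs(x = "Mean of pair", y = "Difference (scan 1 - scan 2)",
                  title = "Bland-Altman agreement")
}

#' Bundle of evaluation metrics for one prediction
#'
#' Collects the accuracy family (total and per-class accuracy, per-class and
#' mean IoU), the CVI of the prediction, and -- when a repeat prediction or
#' paired CVI series is supplied -- repeatability and agreement statistics.
#'
#' @param pred,truth Label maps.
#' @param pred_repeat Optional label map of the repeat scan's prediction, for
#'   the repeatability metric.
#' @param cvi_pairs Optional two-column data frame of paired CVI measurements
#'   across a corpus, for ICC and Bland-Altman.
#' @return Object of class `metrics_report` (a named list; `as_tibble()`
#'   flattens it to one row).
#' @export
metrics_report <- function(pred, truth, pred_repeat = NULL, cvi_pairs = NULL) {
  cc <- confusion(pred, truth)
  rep <- list(
    total_accuracy = accuracy(cc),
    per_class_accuracy = per_class_accuracy(cc),
    per_class_iou = iou(cc),
    mean_iou = mean_iou(cc),
    cvi_percent = cvi(pred),
    repeatability_R = if (!is.null(pred_repeat)) repeatability_R(pred, pred_repeat),
    icc = NULL, mean_difference = NULL, loa_halfwidth = NULL)
  if (!is.null(cvi_pairs)) {
    rep$icc <- icc(cvi_pairs)$icc
    ba <- bland_altman(cvi_pairs)
    rep$mean_difference <- ba$mean_difference
    rep$loa_halfwidth <- ba$loa_halfwidth
  }
  structure(rep, class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> total accuracy %.4f, mean IoU %.4f, CVI %.2f%%\n",
              x$total_accuracy, x$mean_iou, x$cvi_percent))
  cat("  per-class accuracy:",
      paste(sprintf("%s %.4f", label_names(), x$per_class_accuracy), collapse = ", "), "\n")
  if (!is.null(x$icc)) cat(sprintf("  ICC %.3f, mean diff %.3f, LOA half-width %.3f\n",
                                   x$icc, x$mean_difference, x$loa_halfwidth))
  invisible(x)
}

#' @export
as_tibble.metrics_report <- function(x, ...) {
  tibble(
    total_accuracy = x$total_accuracy,
    accuracy_interstitial = x$per_class_accuracy[["interstitial"]],
    accuracy_lumen = x$per_class_accuracy[["lumen"]],
    accuracy_sclera = x$per_class_accuracy[["sclera"]],
    iou_interstitial = x$per_class_iou[["interstitial"]],
    iou_lumen = x$per_class_iou[["lumen"]],
    iou_sclera = x$per_class_iou[["sclera"]],
    mean_iou = x$mean_iou,
    cvi_percent = x$cvi_percent,
    r_interstitial = if (!is.null(x$repeatability_R)) x$repeatability_R[["interstitial"]] else NA_real_,
    r_lumen = if (!is.null(x$repeatability_R)) x$repeatability_R[["lumen"]] else NA_real_,
    r_sclera = if (!is.null(x$repeatability_R)) x$repeatability_R[["sclera"]] else NA_real_,
    icc = x$icc %||% NA_real_,
    mean_difference = x$mean_difference %||% NA_real_,
    loa_halfwidth = x$loa_halfwidth %||% NA_real_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
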