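# Evaluation harness: threshold-free ranking quality of the pixel
# classifier (ROC/AUC, cross-validated at frame level), confusion-matrix
# point metrics, field-of-view gain between mosaics, and trajectory
# recovery error against simulator ground truth.

#' ROC curve and AUC
#'
#' Threshold sweep over the unique scores (ties grouped), trapezoidal AUC;
#' on ties-free input this equals the Mann-Whitney concordance
#' probability. The operating point is chosen on the curve by the Youden
#' index (maximal TPR - FPR) by default, or as the point closest to the
#' (0, 1) corner.
#'
#' @param scores numeric classifier scores (higher = more foreground).
#' @param labels binary labels (logical or 0/1); both classes required.
#' @param optimal criterion for the operating point: "youden" or
#'   "closest01".
#' @return object of class `roc_curve`: list with `thresholds`, `tpr`,
#'   `fpr`, `auc`, `optimal_point` (list `threshold, tpr, fpr`).
#' @export
#' @examples
#' roc_auc(c(0.9, 0.8, 0.7, 0.1), c(1, 1, 0, 0))$auc
roc_auc <- function(scores, labels, optimal = c("youden", "closest01")) {
  optimal <- match.arg(optimal)
  labels <- as.logical(labels > 0 | labels == TRUE)
  if (length(scores) != length(labels))
    stop("scores and labels differ in length", call. = FALSE)
  np <- sum(labels); nn <- sum(!labels)
  if (np == 0 || nn == 0)
    stop("both classes must be present to compute a ROC curve",
         call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  # group tied scores: cumulative counts at the end of each tie group
  last <- rev(!duplicated(rev(s)))
  tp <- cumsum(l)[last]; fp <- cumsum(!l)[last]
  tpr <- c(0, tp / np); fpr <- c(0, fp / nn)
  thresholds <- c(Inf, s[last])
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  crit <- switch(optimal,
                 youden = tpr - fpr,
                 closest01 = -sqrt((1 - tpr)^2 + fpr^2))
  oi <- which.max(crit)
  structure(list(thresholds = thresholds, tpr = tpr, fpr = fpr, auc = auc,
                 optimal_point = list(threshold = thresholds[oi],
                                      tpr = tpr[oi], fpr = fpr[oi])),
            class = "roc_curve")
}

#' Confusion-matrix point metrics
#'
#' Precision TP/(TP+FP), accuracy (TP+TN)/total, sensitivity TP/(TP+FN),
#' specificity TN/(TN+FP). A metric with a zero denominator is reported as
#' NA (undefined), never as 0.
#'
#' @param tp,fp,tn,fn confusion counts (total must be positive).
#' @return named list with the four metrics.
#' @export
point_metrics <- function(tp, fp, tn, fn) {
  total <- tp + fp + tn + fn
  if (total <= 0) stop("confusion matrix is empty", call. = FALSE)
  safe <- function(num, den) if (den > 0) num / den else NA_real_
  list(precision = safe(tp, tp + fp),
       accuracy = safe(tp + tn, total),
       sensitivity = safe(tp, tp + fn),
       specificity = safe(tn, tn + fp))
}

#' Frame-level k-fold cross-validation of the pixel classifier
#'
#' Folds are assigned to whole frames (never to pixels, which would leak
#' training pixels into the test set of the same frame). Each fold trains
#' on the remaining frames and scores the held-out frames' pixels; the
#' per-fold ROC curves are averaged vertically (mean TPR on a fixed FPR
#' grid) into a mean curve whose trapezoidal AUC is the headline number.
#'
#' @param frames list of RGB arrays.
#' @param masks list of full-resolution binary annotation masks.
#' @param scenario feature scenario "A", "B" or "C".
#' @param k number of folds (default 10).
#' @param seed RNG seed for the fold assignment.
#' @param config a [boost_config()].
#' @param fpr_grid FPR grid for vertical averaging.
#' @return list with `mean_roc` (data.frame `fpr, tpr`), `auc` (of the
#'   mean curve), `fold_aucs`, `folds` (assignment vector).
#' @export
crossval <- function(frames, masks, scenario = "B", k = 10L, seed = 1L,
                     config = boost_config(),
                     fpr_grid = seq(0, 1, by = 0.005)) {
  n <- length(frames)
  if (k > n) stop("k exceeds the number of annotated frames", call. = FALSE)
  folds <- with_seed(stage_seed(seed, "folds"),
                     sample(rep(seq_len(k), length.out = n)))
  fold_aucs <- numeric(k)
  mean_tpr <- matrix(0, k, length(fpr_grid))
  for (f in seq_len(k)) {
    tr <- which(folds != f); te <- which(folds == f)
    clf <- train_classifier(frames[tr], masks[tr], scenario, config)
    sc <- list(); lb <- list()
    for (t in te) {
      v <- predict_votes(clf, frames[[t]])
      sc[[length(sc) + 1]] <- as.vector(v)
      lb[[length(lb) + 1]] <- as.vector(
        downscale_mean(masks[[t]] * 1, config$downscale_factor) > 0.5)
    }
    roc <- roc_auc(unlist(sc), unlist(lb))
    fold_aucs[f] <- roc$auc
    mean_tpr[f, ] <- approx(roc$fpr, roc$tpr, xout = fpr_grid,
                            ties = max, rule = 2)$y
  }
  tpr_bar <- colMeans(mean_tpr)
  auc <- sum(diff(fpr_grid) *
               (utils::head(tpr_bar, -1) + utils::tail(tpr_bar, -1)) / 2)
  list(mean_roc = data.frame(fpr = fpr_grid, tpr = tpr_bar), auc = auc,
       fold_aucs = fold_aucs, folds = folds)
}

#' Cross-validated ROC of the thresholding baseline
#'
#' The baseline has no trained parameters, so "cross-validation" reduces
#' to pooling the per-fold test pixels scored by the binary `r - 0.7g > 0`
#' rule (votes at full resolution are pooled at the downscaled grid for
#' comparability with the learned classifier).
#'
#' @inheritParams crossval
#' @return as [crossval()], with degenerate single-threshold fold curves.
#' @export
crossval_baseline <- function(frames, masks, k = 10L, seed = 1L,
                              config = boost_config(),
                              fpr_grid = seq(0, 1, by = 0.005)) {
  n <- length(frames)
  folds <- with_seed(stage_seed(seed, "folds"),
                     sample(rep(seq_len(k), length.out = n)))
  fold_aucs <- numeric(k)
  mean_tpr <- matrix(0, k, length(fpr_grid))
  for (f in seq_len(k)) {
    te <- which(folds == f)
    sc <- list(); lb <- list()
    for (t in te) {
      v <- downscale_mean(richa_baseline_mask(frames[[t]])$votes,
                          config$downscale_factor)
      sc[[length(sc) + 1]] <- as.vector(v)
      lb[[length(lb) + 1]] <- as.vector(
        downscale_mean(masks[[t]] * 1, config$downscale_factor) > 0.5)
    }
    roc <- roc_auc(unlist(sc), unlist(lb))
    fold_aucs[f] <- roc$auc
    mean_tpr[f, ] <- approx(roc$fpr, roc$tpr, xout = fpr_grid,
                            ties = max, rule = 2)$y
  }
  tpr_bar <- colMeans(mean_tpr)
  auc <- sum(diff(fpr_grid) *
               (utils::head(tpr_bar, -1) + utils::tail(tpr_bar, -1)) / 2)
  list(mean_roc = data.frame(fpr = fpr_grid, tpr = tpr_bar), auc = auc,
       fold_aucs = fold_aucs, folds = folds)
}

#' Field-of-view gain between two coverage masks
#'
#' Percentage increase in covered area of mask a over mask b:
#' `100 * (area_a - area_b) / area_b`. Negative when a covers less.
#'
#' @param mask_a,mask_b binary coverage masks on a common canvas (sizes
#'   may differ; only areas enter the computation).
#' @return percentage (scalar).
#' @export
fov_gain <- function(mask_a, mask_b) {
  area_a <- sum(mask_a > 0)
  area_b <- sum(mask_b > 0)
  if (area_b == 0) stop("reference mask is empty", call. = FALSE)
  100 * (area_a - area_b) / area_b
}

#' Trajectory recovery error against ground truth
#'
#' Both trajectories are anchored to their first frame (the global
#' translation gauge is unobservable), then per-frame Euclidean errors,
#' their RMSE and the final-frame drift are reported.
#'
#' @param estimated `[n, 2]` positions.
#' @param truth `[n, 2]` ground-truth offsets.
#' @return list `per_frame`, `rmse`, `endpoint_drift`.
#' @export
trajectory_error <- function(estimated, truth) {
  est <- unclass(estimated); tr <- unclass(truth)
  if (nrow(est) != nrow(tr))
    stop("estimated and true trajectories differ in length", call. = FALSE)
  est <- sweep(est, 2, est[1, ])
  tr <- sweep(tr, 2, tr[1, ])
  err <- sqrt(rowSums((est - tr)^2))
  list(per_frame = err, rmse = sqrt(mean(err^2)),
       endpoint_drift = err[length(err)])
}

#' Plot a ROC curve to PNG
#'
#' @param roc a `roc_curve` or the `mean_roc` data.frame of [crossval()].
#' @param path output PNG path.
#' @param main plot title.
#' @return invisibly, `path`.
#' @export
plot_roc <- function(roc, path, main = "ROC") {
  fpr <- if (inherits(roc, "roc_curve")) roc$fpr else roc$fpr
  tpr <- if (inherits(roc, "roc_curve")) roc$tpr else roc$tpr
  grDevices::png(path, width = 600, height = 600)
  on.exit(grDevices::dev.off())
  plot(fpr, tpr, type = "l", xlab = "False positive rate",
       ylab = "True positive rate", main = main, lwd = 2)
  graphics::abline(0, 1, lty = 2, col = "grey")
  invisible(path)
}
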