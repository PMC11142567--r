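# Hard evaluation metrics computed from thresholded predictions: Dice,
# IoU, accuracy, precision and recall, reported per image and aggregated
# both as the per-image mean (primary) and from micro-pooled counts.

#' Threshold a probability map
#'
#' @param p Numeric array/vector of probabilities in \[0, 1\].
#' @param threshold Decision threshold in \[0, 1\]; a pixel with
#'   `p >= threshold` becomes foreground. Default 0.5.
#' @return Binary object of the same shape as `p`.
#' @export
binarize <- function(p, threshold = 0.5) {
  if (!is.numeric(threshold) || length(threshold) != 1 ||
    threshold < 0 || threshold > 1) {
    stop("threshold must be a single value in [0, 1]", call. = FALSE)
  }
  if (any(p < 0 | p > 1)) stop("p must lie in [0, 1]", call. = FALSE)
  (p >= threshold) * 1
}

#' Confusion counts of two binary masks
#'
#' @param y Ground-truth binary mask.
#' @param yhat Predicted binary mask, same shape.
#' @return List with integer tallies `tp`, `fp`, `fn`, `tn` summing to the
#'   pixel count.
#' @export
confusion_counts <- function(y, yhat) {
  if (!identical(dim(y), dim(yhat)) || length(y) != length(yhat)) {
    stop("y and yhat must have identical shape", call. = FALSE)
  }
  if (any(y != 0 & y != 1) || any(yhat != 0 & yhat != 1)) {
    stop("confusion_counts expects binary masks", call. = FALSE)
  }
  tp <- sum(y == 1 & yhat == 1)
  fp <- sum(y == 0 & yhat == 1)
  fn <- sum(y == 1 & yhat == 0)
  tn <- sum(y == 0 & yhat == 0)
  list(tp = tp, fp = fp, fn = fn, tn = tn)
}

safe_ratio <- function(num, den, both_empty) {
  if (den == 0) {
    return(if (both_empty) 1 else 0)
  }
  num / den
}

#' Segmentation metrics from confusion counts
#'
#' Computes accuracy `(tp + tn) / total`, precision `tp / (tp + fp)`,
#' recall `tp / (tp + fn)`, IoU `tp / (tp + fp + fn)` and Dice
#' `2 tp / (2 tp + fp + fn)`. When both ground truth and prediction are
#' empty the overlap ratios are defined as 1; when exactly one is empty a
#' zero-denominator ratio scores 0.
#'
#' @param counts List with `tp`, `fp`, `fn`, `tn` (e.g. from
#'   [confusion_counts()]).
#' @return Named list with `dice`, `iou`, `accuracy`, `precision`,
#'   `recall`, all in \[0, 1\].
#' @export
seg_metrics <- function(counts) {
  tp <- counts$tp
  fp <- counts$fp
  fn <- counts$fn
  tn <- counts$tn
  if (any(c(tp, fp, fn, tn) < 0)) stop("counts must be non-negative", call. = FALSE)
  total <- tp + fp + fn + tn
  if (total == 0) stop("all-zero confusion counts", call. = FALSE)
  both_empty <- (tp + fn) == 0 && (tp + fp) == 0
  list(
    dice = safe_ratio(2 * tp, 2 * tp + fp + fn, both_empty),
    iou = safe_ratio(tp, tp + fp + fn, both_empty),
    accuracy = (tp + tn) / total,
    precision = safe_ratio(tp, tp + fp, both_empty),
    recall = safe_ratio(tp, tp + fn, both_empty)
  )
}

METRIC_NAMES <- c("dice", "iou", "accuracy", "precision", "recall")

#' Evaluate a model over a dataset
#'
#' Predicts every image, thresholds at `threshold` and tabulates the five
#' metrics per image plus two aggregates: the per-image mean (primary) and
#' the metrics of the micro-pooled confusion counts.
#'
#' @param model A `segmodel`.
#' @param pairs Non-empty list of image/mask pairs (as produced by
#'   [generate_phantom()] or [load_image_mask_dir()]).
#' @param threshold Decision threshold, default 0.5.
#' @param batch_size Images forwarded per batch, default 8.
#' @return List with `per_image` (data.frame, one row per image) and
#'   `summary` (data.frame with rows `mean_over_images`, `micro_pooled`).
#' @export
evaluate_dataset <- function(model, pairs, threshold = 0.5, batch_size = 8L) {
  if (!length(pairs)) stop("pairs must be a non-empty list", call. = FALSE)
  n <- length(pairs)
  per <- matrix(NA_real_, n, length(METRIC_NAMES),
    dimnames = list(NULL, METRIC_NAMES)
  )
  pooled <- list(tp = 0, fp = 0, fn = 0, tn = 0)
  i0 <- 1L
  while (i0 <= n) {
    i1 <- min(n, i0 + as.integer(batch_size) - 1L)
    chunk <- pairs[i0:i1]
    probs <- seg_forward(model, stack_images(chunk), training = FALSE)$out
    for (k in seq_along(chunk)) {
      yhat <- binarize(probs[, , , k], threshold)
      ct <- confusion_counts(as.vector(chunk[[k]]$mask), as.vector(yhat))
      per[i0 + k - 1L, ] <- unlist(seg_metrics(ct))
      pooled <- Map(`+`, pooled, ct)
    }
    i0 <- i1 + 1L
  }
  ids <- vapply(
    pairs,
    function(pr) if (is.null(pr$id)) NA_character_ else pr$id,
    character(1)
  )
  per_image <- data.frame(id = ids, per, stringsAsFactors = FALSE)
  summary <- rbind(
    data.frame(
      granularity = "mean_over_images",
      t(colMeans(per))
    ),
    data.frame(
      granularity = "micro_pooled",
      t(unlist(seg_metrics(pooled)))
    )
  )
  list(per_image = per_image, summary = summary)
}

#' Write a metrics report to disk
#'
#' Emits a machine-readable CSV (per-image rows plus aggregate rows) and a
#' small aligned text table of the aggregates.
#'
#' @param report List from [evaluate_dataset()].
#' @param dir Output directory (created if missing).
#' @return Character vector of the two file paths, invisibly.
#' @export
write_metrics <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, "metrics.csv")
  agg <- cbind(
    data.frame(id = paste0("<", report$summary$granularity, ">")),
    report$summary[, METRIC_NAMES]
  )
  utils::write.csv(rbind(report$per_image, agg), csv, row.names = FALSE)
  txt <- file.path(dir, "metrics.txt")
  fmt <- report$summary
  fmt[METRIC_NAMES] <- lapply(fmt[METRIC_NAMES], function(v) sprintf("%.4f", v))
  writeLines(
    c(
      sprintf(
        "%-18s %8s %8s %8s %9s %8s", "granularity",
        "dice", "iou", "accuracy", "precision", "recall"
      ),
      sprintf(
        "%-18s %8s %8s %8s %9s %8s", fmt$granularity, fmt$dice,
        fmt$iou, fmt$accuracy, fmt$precision, fmt$recall
      )
    ),
    txt
  )
  invisible(c(csv, txt))
}
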