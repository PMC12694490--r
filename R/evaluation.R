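# Metrics, ROC/PR curves, cross-validation and the imbalance case-study
# protocol.

#' Confusion counts at a probability threshold
#'
#' Scores at or above the threshold are called positive.
#'
#' @param scores Predicted probabilities.
#' @param labels 0/1 labels, same length.
#' @param threshold Positivity cut-off.
#' @return List of class `pbip_confusion`: `TP`, `TN`, `FP`, `FN`.
#' @export
confusion <- function(scores, labels, threshold = 0.5) {
  if (length(scores) != length(labels)) {
    stop_pbip("scores and labels differ in length")
  }
  if (!all(labels %in% c(0L, 1L))) stop_pbip("labels must be 0 or 1")
  pred <- as.integer(scores >= threshold)
  structure(list(TP = sum(pred == 1L & labels == 1L),
                 TN = sum(pred == 0L & labels == 0L),
                 FP = sum(pred == 1L & labels == 0L),
                 FN = sum(pred == 0L & labels == 1L)),
            class = "pbip_confusion")
}

#' Threshold metrics from confusion counts
#'
#' Accuracy, precision, sensitivity (recall), specificity, F1 and MCC.
#' Degenerate ratios use fixed conventions: precision = 0 when no positive
#' calls; F1 = 0 when precision + recall = 0; MCC = 0 when any denominator
#' factor vanishes.
#'
#' @param counts A `pbip_confusion` (or list with `TP`, `TN`, `FP`, `FN`).
#' @return Named numeric vector.
#' @export
scalar_metrics <- function(counts) {
  TP <- counts$TP; TN <- counts$TN; FP <- counts$FP; FN <- counts$FN
  total <- TP + TN + FP + FN
  if (total == 0L) stop_pbip("no evaluated pairs")
  accuracy <- (TP + TN) / total
  precision <- if (TP + FP > 0L) TP / (TP + FP) else 0
  sensitivity <- if (TP + FN > 0L) TP / (TP + FN) else 0
  specificity <- if (TN + FP > 0L) TN / (TN + FP) else 0
  f1 <- if (precision + sensitivity > 0) {
    2 * precision * sensitivity / (precision + sensitivity)
  } else 0
  denom <- as.numeric(TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
  mcc <- if (denom > 0) {
    (as.numeric(TP) * TN - as.numeric(FP) * FN) / sqrt(denom)
  } else 0
  c(accuracy = accuracy, precision = precision, sensitivity = sensitivity,
    specificity = specificity, f1 = f1, mcc = mcc)
}

#' ROC curve and AUC
#'
#' AUC is computed by the rank (Mann-Whitney) identity -- the probability
#' that a uniformly random positive outscores a uniformly random negative,
#' with ties counted 1/2 -- and the curve by a sweep over all observed
#' score thresholds.
#'
#' @param scores Predicted scores (any monotone scale).
#' @param labels 0/1 labels; both classes must be present.
#' @return List of class `pbip_roc`: `auc` and `curve` (data frame with
#'   `threshold`, `fpr`, `tpr`).
#' @export
roc_auc <- function(scores, labels) {
  if (length(scores) != length(labels)) {
    stop_pbip("scores and labels differ in length")
  }
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) {
    stop_pbip("ROC needs both classes present")
  }
  r <- rank(scores)                       # midranks handle ties as 1/2
  auc <- (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) sum(scores >= t & labels == 1L) / n1,
                numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & labels == 0L) / n0,
                numeric(1))
  structure(list(auc = auc,
                 curve = data.frame(threshold = thr, fpr = fpr, tpr = tpr)),
            class = "pbip_roc")
}

#' Precision-recall curve and AUPR
#'
#' Area under the step-wise (non-interpolated) precision-recall curve:
#' `sum (R_i - R_{i-1}) * P_i` over descending score thresholds, the
#' average-precision form.
#'
#' @param scores Predicted scores.
#' @param labels 0/1 labels; at least one positive required.
#' @return List of class `pbip_pr`: `aupr` and `curve` (data frame with
#'   `threshold`, `recall`, `precision`).
#' @export
pr_auc <- function(scores, labels) {
  if (length(scores) != length(labels)) {
    stop_pbip("scores and labels differ in length")
  }
  n1 <- sum(labels == 1L)
  if (n1 == 0L) stop_pbip("PR curve needs at least one positive")
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]
  s <- scores[ord]
  # evaluate at each distinct threshold (group ties together)
  last_of_group <- which(!duplicated(s, fromLast = TRUE))
  tp <- cumsum(y)[last_of_group]
  npred <- seq_along(y)[last_of_group]
  precision <- tp / npred
  recall <- tp / n1
  aupr <- sum(diff(c(0, recall)) * precision)
  structure(list(aupr = aupr,
                 curve = data.frame(threshold = s[last_of_group],
                                    recall = recall, precision = precision)),
            class = "pbip_pr")
}

#' Full metrics report for one prediction run
#'
#' @param scores Predicted probabilities.
#' @param labels 0/1 labels.
#' @param threshold Classification threshold for the confusion-based
#'   metrics.
#' @return List of class `pbip_metrics`: the six threshold metrics plus
#'   `auc`, `aupr`, and the ROC/PR curve points.
#' @export
evaluate_predictions <- function(scores, labels, threshold = 0.5) {
  cm <- confusion(scores, labels, threshold)
  m <- scalar_metrics(cm)
  roc <- roc_auc(scores, labels)
  pr <- pr_auc(scores, labels)
  structure(list(metrics = c(m, auc = roc$auc, aupr = pr$aupr),
                 confusion = cm, roc_curve = roc$curve, pr_curve = pr$curve),
            class = "pbip_metrics")
}

#' @export
print.pbip_metrics <- function(x, ...) {
  cat("Prediction metrics:\n")
  print(round(x$metrics, 4L))
  invisible(x)
}

#' Stratified fold assignment
#'
#' @param labels 0/1 labels.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer fold id per sample; within each class, sizes differ by
#'   at most one across folds.
#' @export
stratified_folds <- function(labels, k, seed = 1L) {
  with_seed(seed, {
    fold <- integer(length(labels))
    for (cls in unique(labels)) {
      idx <- which(labels == cls)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
    fold
  })
}

#' k-fold cross-validation of the full pipeline
#'
#' Pairs are partitioned into `k` label-stratified folds; each fold is held
#' out once while the remainder is used for fitting.  SMOTE augmentation is
#' applied inside each training split only -- held-out folds are never
#' augmented.
#'
#' @param pairs A `pbip_pairs` object.
#' @param k Number of folds (default 10).
#' @param seed Integer seed (fold assignment and per-fold fits).
#' @param ... Passed on to [pbip_fit()] (e.g. `config`, `train`,
#'   `augment`).
#' @return List of class `pbip_cv`: `fold` (assignment vector),
#'   `per_fold` (metric matrix, one row per fold), `mean`, `sd`.
#' @export
kfold_cv <- function(pairs, k = 10L, seed = 1L, ...) {
  stopifnot(inherits(pairs, "pbip_pairs"))
  n <- nrow(pairs$x)
  if (n < k) stop_pbip("fewer pairs than folds")
  fold <- stratified_folds(pairs$y, k, stage_seed(seed, "folds"))
  per <- NULL
  for (f in seq_len(k)) {
    tr <- pairs[fold != f]
    te <- pairs[fold == f]
    if (length(unique(tr$y)) < 2L || length(unique(te$y)) < 2L) {
      stop_pbip(sprintf(
        "fold %d lacks a class; stratification requires >= %d samples per class",
        f, k))
    }
    fit <- pbip_fit(tr, seed = stage_seed(seed, paste0("fold", f)), ...)
    sc <- predict(fit, te)
    per <- rbind(per, evaluate_predictions(sc, te$y)$metrics)
  }
  rownames(per) <- paste0("fold", seq_len(k))
  structure(list(fold = fold, per_fold = per,
                 mean = colMeans(per), sd = apply(per, 2L, stats::sd)),
            class = "pbip_cv")
}

#' @export
print.pbip_cv <- function(x, ...) {
  k <- nrow(x$per_fold)
  cat(sprintf("%d-fold cross-validation (mean +/- sd):\n", k))
  for (nm in colnames(x$per_fold)) {
    cat(sprintf("  %-12s %.3f +/- %.3f\n", nm, x$mean[nm], x$sd[nm]))
  }
  invisible(x)
}

#' Imbalanced test sets at fixed positive:negative ratios
#'
#' Builds one test set per ratio `1:r`, each containing every positive pair
#' plus `r * n_positives` negatives sampled without replacement from the
#' negative pool.  The protocol spans ratios 1:2 through 1:10 (nine sets);
#' other ratios are refused unless `allow_other_ratios = TRUE`.  MCC is the
#' designated comparison metric on these sets.
#'
#' @param positives A `pbip_pairs` object of positive pairs (labels all 1).
#' @param negative_pool A `pbip_pairs` object of negative pairs.
#' @param ratios Integer negative multipliers (default `2:10`).
#' @param seed Integer seed for the negative sampling.
#' @param allow_other_ratios Permit ratios outside 2..10.
#' @return Named list (`"1:2"`, ...) of `pbip_pairs` test sets.
#' @export
imbalanced_test_sets <- function(positives, negative_pool, ratios = 2:10,
                                 seed = 1L, allow_other_ratios = FALSE) {
  stopifnot(inherits(positives, "pbip_pairs"),
            inherits(negative_pool, "pbip_pairs"))
  if (any(positives$y != 1L)) stop_pbip("'positives' must contain only label-1 pairs")
  if (any(negative_pool$y != 0L)) stop_pbip("'negative_pool' must contain only label-0 pairs")
  if (!allow_other_ratios && (any(ratios < 2L) || any(ratios > 10L))) {
    bad <- ratios[ratios < 2L | ratios > 10L][1]
    stop_pbip(sprintf(
      "ratio 1:%d is outside the 1:2..1:10 protocol (set allow_other_ratios = TRUE to override)",
      bad))
  }
  n_pos <- nrow(positives$x)
  n_pool <- nrow(negative_pool$x)
  need <- max(ratios) * n_pos
  if (n_pool < need) {
    first_bad <- min(ratios[ratios * n_pos > n_pool])
    stop_pbip(sprintf(
      "negative pool (%d) too small for ratio 1:%d (needs %d negatives)",
      n_pool, first_bad, first_bad * n_pos))
  }
  with_seed(seed, {
    sets <- lapply(ratios, function(r) {
      neg_idx <- sample.int(n_pool, r * n_pos)
      neg <- negative_pool[neg_idx]
      structure(list(x = rbind(positives$x, neg$x),
                     y = c(positives$y, neg$y),
                     phage_id = c(positives$phage_id, neg$phage_id),
                     bacterium_id = c(positives$bacterium_id, neg$bacterium_id),
                     synthetic = c(positives$synthetic, neg$synthetic),
                     d_h = positives$d_h),
                class = "pbip_pairs")
    })
    names(sets) <- paste0("1:", ratios)
    sets
  })
}
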