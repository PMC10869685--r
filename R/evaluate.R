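#' Binary confusion matrix with abnormal as the positive class
#'
#' @param labels,predictions Equal-length binary vectors (1 = abnormal).
#' @return An object of class `confusion_matrix` with counts `tp`, `fp`,
#'   `fn`, `tn`.
#' @export
confusion <- function(labels, predictions) {
  if (length(labels) != length(predictions))
    stop("labels and predictions must have equal length")
  if (!all(labels %in% c(0, 1)) || !all(predictions %in% c(0, 1)))
    stop("labels and predictions must be binary (0/1)")
  structure(list(
    tp = sum(labels == 1 & predictions == 1),
    fp = sum(labels == 0 & predictions == 1),
    fn = sum(labels == 1 & predictions == 0),
    tn = sum(labels == 0 & predictions == 0)
  ), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(truth = c("abnormal", "normal"),
                              predicted = c("abnormal", "normal")))
  print(m)
  invisible(x)
}

#' Precision, recall, F1 and accuracy from a confusion matrix
#'
#' Ratios with a zero denominator are reported as 0 and flagged in the
#' `undefined` field, which keeps means over cross-validation folds
#' well-defined while preserving honesty about degenerate folds.
#'
#' @param cm A [confusion()] result.
#' @return List with `precision`, `recall`, `f1`, `accuracy`, and
#'   `undefined` (character vector of metric names that hit a zero
#'   denominator).
#' @export
classification_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  undefined <- character(0)
  safe <- function(num, den, name) {
    if (den == 0) {
      undefined <<- c(undefined, name)
      return(0)
    }
    num / den
  }
  precision <- safe(cm$tp, cm$tp + cm$fp, "precision")
  recall <- safe(cm$tp, cm$tp + cm$fn, "recall")
  f1 <- if (precision + recall == 0) {
    undefined <- c(undefined, "f1"); 0
  } else 2 * precision * recall / (precision + recall)
  total <- cm$tp + cm$fp + cm$fn + cm$tn
  accuracy <- safe(cm$tp + cm$tn, total, "accuracy")
  if (length(undefined) > 0)
    warning("undefined metric(s) reported as 0: ",
            paste(undefined, collapse = ", "))
  list(precision = precision, recall = recall, f1 = f1, accuracy = accuracy,
       undefined = undefined)
}

#' Area under the ROC curve
#'
#' Trapezoidal AUC with tie-averaging, equivalent to the normalized
#' Mann-Whitney U statistic; computed through pROC.
#'
#' @param labels Binary label vector with both classes present.
#' @param scores Numeric scores; larger means more abnormal.
#' @return AUC in `[0, 1]`.
#' @export
auc_roc <- function(labels, scores) {
  if (length(labels) != length(scores))
    stop("labels and scores must have equal length")
  if (length(unique(labels)) < 2)
    stop("AUC needs both classes present")
  r <- pROC::roc(response = labels, predictor = scores,
                 levels = c(0, 1), direction = "<", quiet = TRUE)
  as.numeric(pROC::auc(r))
}

#' Average precision for object detection
#'
#' Predictions are greedily matched, in descending objectness order, to the
#' as-yet-unmatched ground-truth box of the same image with the highest
#' IoU at or above `iou_threshold`. The precision-recall curve over score
#' ranks is integrated with all-point (continuous) interpolation:
#' `AP = sum over recall steps of (r_i - r_{i-1}) * max precision at
#' recall >= r_i`.
#'
#' @param pred_boxes Bounding-box data frame of predictions; an `image_id`
#'   column scopes matching per image (a single shared image is assumed
#'   when absent).
#' @param gt_boxes Ground-truth bounding-box data frame, same convention.
#' @param iou_threshold Matching threshold (default 0.5).
#' @return AP in `[0, 1]`; 1 for empty ground truth with no predictions,
#'   0 for missed nonempty ground truth.
#' @export
average_precision <- function(pred_boxes, gt_boxes, iou_threshold = 0.5) {
  pred_boxes <- as.data.frame(pred_boxes)
  gt_boxes <- as.data.frame(gt_boxes)
  if (!"image_id" %in% names(pred_boxes))
    pred_boxes$image_id <- rep("img", nrow(pred_boxes))
  if (!"image_id" %in% names(gt_boxes))
    gt_boxes$image_id <- rep("img", nrow(gt_boxes))
  n_gt <- nrow(gt_boxes)
  if (nrow(pred_boxes) == 0) return(if (n_gt == 0) 1 else 0)
  if (n_gt == 0) return(0)
  ord <- order(-pred_boxes$objectness, pred_boxes$x_min, pred_boxes$y_min)
  pred_boxes <- pred_boxes[ord, , drop = FALSE]
  gt_mat <- as.matrix(gt_boxes[, c("x_min", "y_min", "x_max", "y_max")])
  matched <- rep(FALSE, n_gt)
  tp <- logical(nrow(pred_boxes))
  for (i in seq_len(nrow(pred_boxes))) {
    cand <- which(gt_boxes$image_id == pred_boxes$image_id[i] & !matched)
    if (length(cand) == 0) next
    ov <- iou_vec(as.numeric(pred_boxes[i, c("x_min", "y_min", "x_max", "y_max")]),
                  gt_mat[cand, , drop = FALSE])
    j <- which.max(ov)
    if (ov[j] >= iou_threshold) {
      matched[cand[j]] <- TRUE
      tp[i] <- TRUE
    }
  }
  cum_tp <- cumsum(tp)
  precision <- cum_tp / seq_along(tp)
  recall <- cum_tp / n_gt
  # all-point interpolation: running max of precision from the right
  prec_interp <- rev(cummax(rev(precision)))
  r_prev <- c(0, recall[-length(recall)])
  sum((recall - r_prev) * prec_interp)
}

#' Mean average precision over classes
#'
#' @inheritParams average_precision
#' @param classes Classes to average over; defaults to those present in the
#'   ground truth.
#' @return mAP in `[0, 1]`.
#' @export
mean_average_precision <- function(pred_boxes, gt_boxes, iou_threshold = 0.5,
                                   classes = NULL) {
  gt_boxes <- as.data.frame(gt_boxes)
  pred_boxes <- as.data.frame(pred_boxes)
  if (is.null(classes)) classes <- unique(gt_boxes$class_name)
  if (length(classes) == 0) stop("no classes to evaluate")
  mean(vapply(classes, function(cl) {
    average_precision(pred_boxes[pred_boxes$class_name == cl, , drop = FALSE],
                      gt_boxes[gt_boxes$class_name == cl, , drop = FALSE],
                      iou_threshold)
  }, numeric(1)))
}

#' Grouped k-fold assignment by study
#'
#' Studies (not breasts) are shuffled under the seed and dealt round-robin
#' into `k` folds, so all views and both breasts of a study share a fold
#' and fold sizes differ by at most one study.
#'
#' @param study_ids Character vector, one entry per record (breast).
#' @param k Number of folds (>= 2).
#' @param seed Shuffle seed.
#' @return Integer fold index per record, with a `studies` attribute
#'   mapping each unique study to its fold.
#' @export
group_kfold <- function(study_ids, k = 5L, seed = 1L) {
  k <- as.integer(k)
  if (k < 2L) stop("k must be at least 2")
  studies <- unique(study_ids)
  if (length(studies) < k)
    stop("need at least k distinct studies (", length(studies), " < ", k, ")")
  set.seed(seed)
  shuffled <- sample(studies)
  study_fold <- stats::setNames(rep_len(seq_len(k), length(shuffled)), shuffled)
  folds <- as.integer(study_fold[study_ids])
  attr(folds, "studies") <- study_fold
  folds
}

#' Grouped cross-validation of the dual-view classifier
#'
#' Reserves a study-level test split first (default 20%, fixed by
#' `seed`), then runs k-fold group cross-validation on the remaining
#' studies: each fold trains [train_dualview()] on the other folds and
#' evaluates on the fold's own studies and on the reserved test set.
#'
#' @param exams List of labelled [breast_exam()] objects.
#' @param cfg A [dualview_config()].
#' @param k Number of folds.
#' @param test_fraction Fraction of studies reserved as the held-out test
#'   set before cross-validation.
#' @param seed Seed for the split and fold shuffle.
#' @param prob_threshold Probability cut used to binarize predictions for
#'   the confusion matrices.
#' @return List with `folds` (per-fold metric data frame), `mean` (column
#'   means over folds), `test_mean`, `confusions`, `roc` (per-fold label /
#'   score vectors), and `test_studies`.
#' @export
cross_validate <- function(exams, cfg = dualview_config(), k = 5L,
                           test_fraction = 0.2, seed = 1L,
                           prob_threshold = 0.5) {
  studies <- vapply(exams, `[[`, "", "study_id")
  uniq <- unique(studies)
  set.seed(seed)
  n_test <- max(1L, round(test_fraction * length(uniq)))
  test_studies <- sample(uniq, n_test)
  test_idx <- studies %in% test_studies
  dev_exams <- exams[!test_idx]
  test_exams <- exams[test_idx]
  dev_studies <- studies[!test_idx]
  folds <- group_kfold(dev_studies, k = k, seed = seed)
  eval_split <- function(model, split_exams) {
    y <- vapply(split_exams, `[[`, numeric(1), "label")
    p <- predict_prob(model, split_exams)
    cm <- confusion(y, as.integer(p > prob_threshold))
    mets <- suppressWarnings(classification_metrics(cm))
    auc <- if (length(unique(y)) == 2) auc_roc(y, p) else NA_real_
    list(cm = cm, metrics = mets, auc = auc, y = y, p = p)
  }
  fold_rows <- vector("list", k)
  test_rows <- vector("list", k)
  confusions <- vector("list", k)
  roc <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- dev_exams[folds != f]
    va <- dev_exams[folds == f]
    leak <- intersect(vapply(tr, `[[`, "", "study_id"),
                      vapply(va, `[[`, "", "study_id"))
    if (length(leak) > 0) stop("study leakage in fold ", f)
    fold_cfg <- cfg
    fold_cfg$seed <- cfg$seed + f
    model <- train_dualview(tr, va, fold_cfg)
    ev <- eval_split(model, va)
    et <- eval_split(model, test_exams)
    fold_rows[[f]] <- data.frame(
      fold = f, n_val = length(va),
      precision = ev$metrics$precision, recall = ev$metrics$recall,
      f1 = ev$metrics$f1, accuracy = ev$metrics$accuracy, auc = ev$auc
    )
    test_rows[[f]] <- data.frame(
      fold = f, n_test = length(test_exams),
      precision = et$metrics$precision, recall = et$metrics$recall,
      f1 = et$metrics$f1, accuracy = et$metrics$accuracy, auc = et$auc
    )
    confusions[[f]] <- ev$cm
    roc[[f]] <- list(labels = ev$y, scores = ev$p)
  }
  fold_df <- do.call(rbind, fold_rows)
  test_df <- do.call(rbind, test_rows)
  list(folds = fold_df,
       mean = colMeans(fold_df[, c("precision", "recall", "f1",
                                   "accuracy", "auc")]),
       test = test_df,
       test_mean = colMeans(test_df[, c("precision", "recall", "f1",
                                        "accuracy", "auc")]),
       confusions = confusions, roc = roc, test_studies = test_studies)
}
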