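test_that("confusion counts match a brute-force tally", {
  cm <- confusion(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(unlist(cm[c("tp", "tn", "fp", "fn")]),
               c(tp = 2L, tn = 2L, fp = 0L, fn = 0L))
  cm2 <- confusion(c(1, 0), c(0, 1))
  expect_equal(cm2$fn, 1L)
  expect_equal(cm2$fp, 1L)
  set.seed(14)
  labels <- rbinom(200, 1, 0.5); preds <- rbinom(200, 1, 0.5)
  cm3 <- confusion(labels, preds)
  tally <- c(tp = 0, fp = 0, fn = 0, tn = 0)
  for (i in 1:200) {
    if (labels[i] == 1 && preds[i] == 1) tally["tp"] <- tally["tp"] + 1
    if (labels[i] == 0 && preds[i] == 1) tally["fp"] <- tally["fp"] + 1
    if (labels[i] == 1 && preds[i] == 0) tally["fn"] <- tally["fn"] + 1
    if (labels[i] == 0 && preds[i] == 0) tally["tn"] <- tally["tn"] + 1
  }
  expect_equal(unlist(cm3[c("tp", "fp", "fn", "tn")]), tally)
  expect_equal(cm3$tp + cm3$fp + cm3$fn + cm3$tn, 200)
  expect_error(confusion(c(1, 0), 1), "length")
})

test_that("precision/recall/F1/accuracy match hand arithmetic with the 0-flag convention", {
  m <- classification_metrics(confusion(c(rep(1, 9), rep(0, 11)),
                                        c(rep(1, 8), 0, rep(1, 2), rep(0, 9))))
  expect_equal(m$precision, 0.8)
  expect_equal(m$recall, 8 / 9, tolerance = 1e-12)
  expect_equal(m$f1, 2 * 0.8 * (8 / 9) / (0.8 + 8 / 9), tolerance = 1e-12)
  expect_equal(m$accuracy, 17 / 20)
  expect_length(m$undefined, 0L)

  expect_warning(z <- classification_metrics(confusion(c(0, 0), c(0, 0))),
                 "undefined")
  expect_equal(z$precision, 0)
  expect_true("precision" %in% z$undefined)

  perfect <- classification_metrics(confusion(c(1, 0, 1), c(1, 0, 1)))
  expect_equal(unlist(perfect[c("precision", "recall", "f1", "accuracy")]),
               c(precision = 1, recall = 1, f1 = 1, accuracy = 1))
})

test_that("AUC matches the exhaustive pairwise U-statistic oracle", {
  expect_equal(auc_roc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9)), 1)
  set.seed(99)
  for (case in 1:100) {
    n <- sample(4:12, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))  # both classes guaranteed
    scores <- sample(round(runif(n), 2))      # ties likely at 2 decimals
    expect_equal(auc_roc(labels, scores), auc_pairwise_oracle(labels, scores),
                 tolerance = 1e-12)
  }
  # label-independent scores hover near 1/2
  set.seed(5)
  labels <- rbinom(4000, 1, 0.5)
  expect_lt(abs(auc_roc(labels, runif(4000)) - 0.5), 0.03)
  expect_error(auc_roc(c(1, 1), c(0.4, 0.6)), "both classes")
})

test_that("average precision traces the PR curve with all-point interpolation", {
  gt <- bounding_box(c(0, 50), c(0, 50), c(10, 60), c(10, 60))
  expect_equal(average_precision(gt, gt), 1)
  expect_equal(average_precision(empty_boxes(), gt), 0)
  # 1 gt box; scores 0.9 hit, 0.8 miss -> precision (1, 0.5), recall (1, 1), AP 1
  one_gt <- bounding_box(0, 0, 10, 10)
  preds <- rbind(bounding_box(0, 0, 10, 10, objectness = 0.9),
                 bounding_box(70, 70, 80, 80, objectness = 0.8))
  expect_equal(average_precision(preds, one_gt), 1)
  # reversed scores: the miss ranks first -> AP = 0.5
  preds2 <- rbind(bounding_box(0, 0, 10, 10, objectness = 0.8),
                  bounding_box(70, 70, 80, 80, objectness = 0.9))
  expect_equal(average_precision(preds2, one_gt), 0.5)
  # a low-scoring unmatched extra prediction never increases AP
  set.seed(3)
  for (case in 1:20) {
    gt <- random_boxes(4, classes = "suspicious_mass")
    pr <- random_boxes(6, classes = "suspicious_mass")
    base <- average_precision(pr, gt)
    extra <- rbind(pr, bounding_box(90, 90, 99, 99, objectness = min(pr$objectness) / 2))
    expect_lte(average_precision(extra, gt), base + 1e-12)
  }
})

test_that("mean average precision averages per-class AP", {
  gt <- rbind(bounding_box(0, 0, 10, 10, "suspicious_mass"),
              bounding_box(30, 30, 40, 40, "lymph_node"))
  pred <- bounding_box(0, 0, 10, 10, "suspicious_mass", objectness = 0.9)
  expect_equal(mean_average_precision(pred, gt), 0.5)  # (1 + 0) / 2
})

test_that("grouped folds never split a study and deal studies evenly", {
  sids <- rep(sprintf("S%02d", 1:10), each = 4)
  f <- group_kfold(sids, k = 5, seed = 3)
  expect_length(f, 40L)
  per_study <- tapply(f, sids, function(x) length(unique(x)))
  expect_true(all(per_study == 1))
  expect_true(all(table(attr(f, "studies")) == 2))
  expect_identical(f, group_kfold(sids, k = 5, seed = 3))
  expect_error(group_kfold(sids, k = 11), "at least k")
  # uneven counts differ by at most one study
  f2 <- group_kfold(rep(sprintf("S%02d", 1:13), each = 2), k = 5, seed = 1)
  sizes <- table(attr(f2, "studies"))
  expect_lte(diff(range(sizes)), 1)
})

test_that("cross-validation reports per-fold matrices, means, and a clean test split", {
  co <- make_cohort(40, seed = 37)
  cv <- cross_validate(co$exams, fast_config(max_epochs = 60, patience = 15),
                       k = 5, test_fraction = 0.2, seed = 4)
  expect_equal(nrow(cv$folds), 5L)
  expect_length(cv$confusions, 5L)
  expect_true(all(c("precision", "recall", "f1", "accuracy", "auc") %in%
                  names(cv$mean)))
  expect_length(cv$test_studies, 8L)
  # the reserved test studies never appear in any fold
  dev_studies <- setdiff(unique(exam_studies(co$exams)), cv$test_studies)
  expect_length(intersect(cv$test_studies, dev_studies), 0L)
  # separable synthetic signal: validation recall stays high
  expect_gte(cv$mean[["recall"]], 0.85)
})

test_that("shuffled labels drive cross-validated AUC to chance", {
  co <- make_cohort(20, seed = 43)
  exams <- co$exams
  set.seed(101)
  labs <- exam_labels(exams)
  shuffled <- sample(labs)
  for (i in seq_along(exams)) exams[[i]]$label <- shuffled[i]
  cv <- cross_validate(exams, fast_config(max_epochs = 10), k = 4,
                       test_fraction = 0.2, seed = 8)
  expect_gte(mean(cv$folds$auc, na.rm = TRUE), 0.3)
  expect_lte(mean(cv$folds$auc, na.rm = TRUE), 0.7)
})
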