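test_that("IoU matches hand-computed overlaps and its defining properties", {
  a <- bounding_box(0, 0, 2, 2)
  b <- bounding_box(1, 1, 3, 3)
  expect_equal(iou(a, a), 1)
  expect_equal(iou(a, bounding_box(5, 5, 6, 6)), 0)
  expect_equal(iou(a, b), 1 / 7, tolerance = 1e-12)
  set.seed(2)
  bx <- random_boxes(30)
  for (i in 1:15) {
    p <- sample(30, 2)
    expect_equal(iou(bx[p[1], ], bx[p[2], ]), iou(bx[p[2], ], bx[p[1], ]))
  }
})

test_that("NMS suppresses greedily per class and matches examples", {
  expect_equal(nrow(nms(empty_boxes(), 0.5)), 0L)
  two <- rbind(bounding_box(0, 0, 10, 10, objectness = 0.9),
               bounding_box(1, 0, 11, 10, objectness = 0.7))
  expect_gt(iou(two[1, ], two[2, ]), 0.5)
  kept <- nms(two, 0.5)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$objectness, 0.9)
  # different classes never suppress each other
  mixed <- rbind(bounding_box(0, 0, 10, 10, "suspicious_mass", 0.9),
                 bounding_box(0, 0, 10, 10, "lymph_node", 0.2))
  expect_equal(nrow(nms(mixed, 0.5)), 2L)
  expect_error(nms(two, 0), "iou_threshold")
})

test_that("NMS agrees with the brute-force pairwise oracle on random instances", {
  set.seed(123)
  for (case in 1:200) {
    n <- sample(1:20, 1)
    thr <- runif(1, 0.2, 0.8)
    boxes <- random_boxes(n, size = 60)
    kept <- nms(boxes, thr)
    got <- sort(match(
      do.call(paste, c(kept[, c("x_min", "y_min", "x_max", "y_max", "class_name")], sep = "|")),
      do.call(paste, c(boxes[, c("x_min", "y_min", "x_max", "y_max", "class_name")], sep = "|"))))
    expect_equal(got, nms_bruteforce_oracle(boxes, thr))
    # survivors are an antichain within each class
    if (nrow(kept) > 1) for (i in seq_len(nrow(kept) - 1))
      for (j in (i + 1):nrow(kept))
        if (kept$class_name[i] == kept$class_name[j])
          expect_lt(iou(kept[i, ], kept[j, ]), thr)
    # survivors are a subset of the input
    expect_true(all(kept$objectness %in% boxes$objectness))
  }
})

test_that("ensembling concatenates models then suppresses, keeping the max score", {
  a <- bounding_box(0, 0, 10, 10, objectness = 0.6, source_model = "m1")
  b <- bounding_box(0, 0, 10, 10, objectness = 0.8, source_model = "m2")
  one <- ensemble_detections(list(a), 0.45)
  expect_equal(one, nms(a, 0.45))
  fused <- ensemble_detections(list(a, b), 0.45)
  expect_equal(nrow(fused), 1L)
  expect_equal(fused$objectness, 0.8)
  expect_equal(fused$source_model, "m2")
  disjoint <- ensemble_detections(list(a, bounding_box(50, 50, 60, 60, objectness = 0.3)), 0.45)
  expect_equal(nrow(disjoint), 2L)
  # k identical copies behave like one model
  expect_equal(ensemble_detections(list(a, a, a), 0.45), nms(a, 0.45))
})

test_that("the reference blob detector finds bright components deterministically", {
  expect_equal(nrow(blob_detect(matrix(0.4, 60, 60))), 0L)

  m <- matrix(0, 100, 100)
  m[41:50, 21:30] <- 1  # rows y=40..49, cols x=20..29
  found <- blob_detect(m, min_area = 10)
  expect_equal(nrow(found), 1L)
  expect_lte(max(abs(as.numeric(found[1, c("x_min", "y_min", "x_max", "y_max")]) -
                     c(20, 40, 30, 50))), 1)
  expect_equal(found$objectness, 1)

  m[71:80, 61:70] <- 0.9
  expect_equal(nrow(blob_detect(m, min_area = 10)), 2L)
  # tiny specks below min_area are ignored
  speck <- matrix(0, 50, 50); speck[10, 10] <- 1
  expect_equal(nrow(blob_detect(speck, min_area = 5)), 0L)
})

test_that("exam detection maps boxes back to source coordinates on right breasts", {
  p <- synth_params(seed = 41, abnormal_fraction = 1, blob_count_range = c(1, 1),
                    blob_radius_range = c(9, 11))
  det <- blob_detector()
  for (lat in c("L", "R")) {
    g <- generate_exam(p, "SD", lat)
    boxes <- detect_exam(det, g$exam)
    for (view in c("boxes_cc", "boxes_mlo")) {
      hits <- boxes[[view]]
      gt <- g$truth[[view]]
      expect_gte(nrow(hits), 1L)
      best <- max(vapply(seq_len(nrow(hits)), function(i)
        iou(hits[i, ], gt[1, ]), numeric(1)))
      expect_gte(best, 0.3)
    }
  }
  # blank views produce nothing
  blank <- breast_exam(mammogram_view(matrix(0, 64, 64), "L", "CC", "B"),
                       mammogram_view(matrix(0, 64, 64), "L", "MLO", "B"))
  none <- detect_exam(det, blank)
  expect_equal(nrow(none$boxes_cc) + nrow(none$boxes_mlo), 0L)
})

test_that("mirror mapping arithmetic is exact for right-laterality views", {
  img <- matrix(0, 64, 100)
  img[11:20, 91:100] <- 1  # in source coords: x in [90,100)
  exam <- breast_exam(mammogram_view(img, "R", "CC", "S"),
                      mammogram_view(img, "R", "MLO", "S"))
  boxes <- detect_exam(blob_detector(min_area = 10), exam)$boxes_cc
  expect_equal(nrow(boxes), 1L)
  expect_equal(as.numeric(boxes[1, c("x_min", "x_max")]), c(90, 100))
  expect_equal(as.numeric(boxes[1, c("y_min", "y_max")]), c(10, 20))
})

test_that("breast-level objectness takes the class-restricted max over views", {
  expect_equal(max_objectness(empty_boxes(), empty_boxes()), 0)
  cc <- bounding_box(0, 0, 5, 5, "suspicious_mass", 0.3)
  mlo <- bounding_box(0, 0, 5, 5, "suspicious_mass", 0.7)
  expect_equal(max_objectness(cc, mlo), 0.7)
  ln <- bounding_box(0, 0, 5, 5, "lymph_node", 0.9)
  expect_equal(max_objectness(ln, empty_boxes(), "suspicious_mass"), 0)
  expect_equal(max_objectness(ln, empty_boxes(), "lymph_node"), 0.9)
})

test_that("YOLO prediction files enter the pipeline through the adapter", {
  dir <- withr::local_tempdir()
  p <- synth_params(seed = 2, abnormal_fraction = 1)
  co <- generate_cohort(p, 1, out_dir = dir)
  # write predictions next to images: echo the ground-truth annotation files
  pred_dir <- file.path(dir, "preds")
  dir.create(pred_dir)
  for (f in list.files(dir, pattern = "\\.txt$", full.names = TRUE)) {
    lines <- readLines(f)
    writeLines(if (length(lines)) paste(lines, "0.88") else character(0),
               file.path(pred_dir, basename(f)))
  }
  exams <- read_manifest(file.path(dir, "manifest.csv"))
  det <- yolo_file_detector(pred_dir)
  boxes <- detect_exam(det, exams[["S00001_L"]])
  truth <- co$truths[["S00001_L"]]
  expect_equal(nrow(boxes$boxes_cc), nrow(truth$boxes_cc))
  if (nrow(boxes$boxes_cc) > 0) {
    expect_equal(boxes$boxes_cc$objectness, rep(0.88, nrow(boxes$boxes_cc)))
    expect_lte(max(abs(boxes$boxes_cc$x_min - truth$boxes_cc$x_min)), 0.5)
  }
})
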