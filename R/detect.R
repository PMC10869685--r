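#' The six detector finding classes
#'
#' Class indices in YOLO annotation files are 0-based positions in this
#' vector. `suspicious_mass` (mass with BI-RADS 3 or higher) is the class
#' that gates top-priority triage.
#'
#' @return Character vector of class names.
#' @export
detector_classes <- function() {
  c("suspicious_mass", "lymph_node", "calcification",
    "architectural_distortion", "skin_thickening", "nipple_retraction")
}

#' Construct bounding boxes
#'
#' Boxes are rows of a data frame in 0-based, half-open pixel coordinates
#' (origin top-left, x = column): a box covers pixels with
#' `x_min <= x < x_max`, `y_min <= y < y_max`.
#'
#' @param x_min,y_min,x_max,y_max Numeric box extents, `x_min < x_max` and
#'   `y_min < y_max`.
#' @param class_name One of [detector_classes()] per box.
#' @param objectness Detector confidence in `[0, 1]`.
#' @param source_model Identifier of the emitting model.
#' @return A data frame of class `bounding_boxes`.
#' @export
bounding_box <- function(x_min, y_min, x_max, y_max,
                         class_name = "suspicious_mass",
                         objectness = 1, source_model = "unknown") {
  df <- data.frame(x_min = x_min, y_min = y_min, x_max = x_max, y_max = y_max,
                   class_name = class_name, objectness = objectness,
                   source_model = source_model, stringsAsFactors = FALSE)
  validate_boxes(df)
}

#' @rdname bounding_box
#' @export
empty_boxes <- function() {
  validate_boxes(data.frame(
    x_min = numeric(0), y_min = numeric(0),
    x_max = numeric(0), y_max = numeric(0),
    class_name = character(0), objectness = numeric(0),
    source_model = character(0), stringsAsFactors = FALSE))
}

validate_boxes <- function(boxes) {
  cols <- c("x_min", "y_min", "x_max", "y_max", "class_name",
            "objectness", "source_model")
  if (!is.data.frame(boxes) || !all(cols %in% names(boxes)))
    stop("boxes must be a data frame with columns ", paste(cols, collapse = ", "))
  if (nrow(boxes) > 0) {
    if (any(boxes$x_min >= boxes$x_max) || any(boxes$y_min >= boxes$y_max))
      stop("degenerate box: require x_min < x_max and y_min < y_max")
    if (any(boxes$objectness < 0 | boxes$objectness > 1))
      stop("objectness must lie in [0, 1]")
    if (!all(boxes$class_name %in% detector_classes()))
      stop("unknown class_name; see detector_classes()")
  }
  class(boxes) <- c("bounding_boxes", "data.frame")
  boxes
}

# Mirror boxes left-right within an image of the given width.
mirror_boxes <- function(boxes, width) {
  if (nrow(boxes) == 0) return(boxes)
  new_min <- width - boxes$x_max
  boxes$x_max <- width - boxes$x_min
  boxes$x_min <- new_min
  boxes
}

#' Intersection over union of two boxes
#'
#' @param a,b Single-row box data frames or numeric vectors
#'   `(x_min, y_min, x_max, y_max)`.
#' @return IoU in `[0, 1]`; 0 for disjoint boxes.
#' @export
iou <- function(a, b) {
  a <- as.numeric(a[c("x_min", "y_min", "x_max", "y_max")])
  b <- as.numeric(b[c("x_min", "y_min", "x_max", "y_max")])
  iw <- min(a[3], b[3]) - max(a[1], b[1])
  ih <- min(a[4], b[4]) - max(a[2], b[2])
  if (iw <= 0 || ih <= 0) return(0)
  inter <- iw * ih
  union <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter
  inter / union
}

# Vectorized IoU of one box (numeric length-4) against a box matrix (n x 4).
iou_vec <- function(box, mat) {
  if (nrow(mat) == 0) return(numeric(0))
  iw <- pmin(box[3], mat[, 3]) - pmax(box[1], mat[, 1])
  ih <- pmin(box[4], mat[, 4]) - pmax(box[2], mat[, 2])
  inter <- pmax(iw, 0) * pmax(ih, 0)
  union <- (box[3] - box[1]) * (box[4] - box[2]) +
    (mat[, 3] - mat[, 1]) * (mat[, 4] - mat[, 2]) - inter
  inter / union
}

#' Per-class greedy non-maximum suppression
#'
#' Within each class, repeatedly keeps the highest-objectness box and
#' removes boxes overlapping it with IoU at or above the threshold. Ties in
#' objectness break deterministically toward the lower `(x_min, y_min)`
#' pair. Boxes of different classes never suppress each other, preserving
#' e.g. the mass vs lymph-node distinction. Output is sorted by descending
#' objectness.
#'
#' @param boxes Bounding-box data frame.
#' @param iou_threshold Suppression threshold in `(0, 1)`.
#' @return Surviving subset of `boxes`.
#' @export
nms <- function(boxes, iou_threshold = 0.45) {
  boxes <- validate_boxes(boxes)
  if (iou_threshold <= 0 || iou_threshold >= 1)
    stop("iou_threshold must lie in (0, 1)")
  if (nrow(boxes) == 0) return(boxes)
  keep <- integer(0)
  for (cls in unique(boxes$class_name)) {
    idx <- which(boxes$class_name == cls)
    ord <- idx[order(-boxes$objectness[idx], boxes$x_min[idx], boxes$y_min[idx])]
    mat <- as.matrix(boxes[, c("x_min", "y_min", "x_max", "y_max")])
    alive <- rep(TRUE, length(ord))
    for (i in seq_along(ord)) {
      if (!alive[i]) next
      keep <- c(keep, ord[i])
      if (i < length(ord)) {
        rest <- ord[(i + 1):length(ord)]
        ov <- iou_vec(mat[ord[i], ], mat[rest, , drop = FALSE])
        alive[(i + 1):length(ord)][ov >= iou_threshold] <- FALSE
      }
    }
  }
  out <- boxes[keep, , drop = FALSE]
  out <- out[order(-out$objectness, out$x_min, out$y_min), , drop = FALSE]
  rownames(out) <- NULL
  validate_boxes(out)
}

#' Ensemble detections from several models
#'
#' Concatenates all models' boxes and applies per-class NMS, so overlapping
#' detections of the same finding collapse to the highest-confidence one
#' while each survivor keeps its `source_model` tag.
#'
#' @param per_model_boxes List of bounding-box data frames, one per model.
#' @inheritParams nms
#' @return A bounding-box data frame.
#' @export
ensemble_detections <- function(per_model_boxes, iou_threshold = 0.45) {
  stopifnot(is.list(per_model_boxes), length(per_model_boxes) >= 1)
  all_boxes <- do.call(rbind, lapply(per_model_boxes, validate_boxes))
  nms(all_boxes, iou_threshold)
}

#' Detector contracts
#'
#' A detector is any function from an intensity matrix in `[0, 1]` to a
#' bounding-box data frame; `detector()` wraps one with a descriptor.
#' [blob_detector()] builds the reference intensity-blob detector:
#' thresholding at the larger of an intensity quantile and an absolute
#' floor, connected-component labelling, and one box per component above a
#' minimum area, with objectness = mean component intensity. It is
#' deterministic and serves desk-scale runs in place of a trained deep
#' detector. [yolo_file_detector()] adapts externally computed YOLO-format
#' prediction files (`class cx cy w h conf`, one file per image, named
#' `<image stem>.txt`) into the same contract.
#'
#' @param fn Function `(pixels, view = NULL) -> bounding_boxes`.
#' @param descriptor Short identifier string.
#' @return An object of class `dv_detector`.
#' @export
detector <- function(fn, descriptor) {
  stopifnot(is.function(fn))
  structure(list(fn = fn, descriptor = descriptor), class = "dv_detector")
}

#' @rdname detector
#' @param quantile Intensity quantile defining the threshold.
#' @param min_intensity Absolute intensity floor for the threshold; pixels
#'   must exceed `max(quantile value, min_intensity)` strictly.
#' @param min_area Minimum component area in pixels.
#' @param class_name Class assigned to emitted boxes.
#' @export
blob_detector <- function(quantile = 0.95, min_intensity = 0.7,
                          min_area = 20, class_name = "suspicious_mass") {
  force(quantile); force(min_intensity); force(min_area); force(class_name)
  detector(function(pixels, view = NULL) {
    blob_detect(pixels, quantile = quantile, min_intensity = min_intensity,
                min_area = min_area, class_name = class_name)
  }, descriptor = sprintf("blob(q=%g,floor=%g,area>=%g)",
                          quantile, min_intensity, min_area))
}

#' @rdname detector
#' @param dir Directory holding `<image stem>.txt` prediction files.
#' @export
yolo_file_detector <- function(dir) {
  force(dir)
  detector(function(pixels, view = NULL) {
    if (is.null(view) || is.na(view$source_path))
      stop("yolo_file_detector needs views with a source_path")
    stem <- tools::file_path_sans_ext(basename(view$source_path))
    path <- file.path(dir, paste0(stem, ".txt"))
    if (!file.exists(path)) return(empty_boxes())
    boxes <- read_yolo_annotations(path, ncol(pixels), source_model = "yolo_file")
    # Prediction files are in source-image coordinates; detect_exam mirrors
    # detector output back for right breasts, so pre-mirror to compensate.
    if (view$laterality == "R") boxes <- mirror_boxes(boxes, ncol(pixels))
    boxes
  }, descriptor = paste0("yolo-files:", dir))
}

#' Reference blob detection on one image
#'
#' @param image Intensity matrix in `[0, 1]`.
#' @inheritParams blob_detector
#' @return A bounding-box data frame.
#' @export
blob_detect <- function(image, quantile = 0.95, min_intensity = 0.7,
                        min_area = 20, class_name = "suspicious_mass") {
  thr <- max(stats::quantile(image, quantile, names = FALSE), min_intensity)
  mask <- image > thr
  if (!any(mask)) return(empty_boxes())
  lab <- t(EBImage::imageData(EBImage::bwlabel(EBImage::Image(t(mask * 1)))))
  out <- empty_boxes()
  for (comp in seq_len(max(lab))) {
    idx <- which(lab == comp, arr.ind = TRUE)
    if (nrow(idx) < min_area) next
    out <- rbind(out, bounding_box(
      x_min = min(idx[, 2]) - 1, y_min = min(idx[, 1]) - 1,
      x_max = max(idx[, 2]), y_max = max(idx[, 1]),
      class_name = class_name,
      objectness = min(mean(image[idx]), 1),
      source_model = "blob_detector"
    ))
  }
  validate_boxes(out)
}

#' Run a detector on both views of a breast exam
#'
#' Views are standardized (right breasts mirrored) before detection, and the
#' resulting boxes are mapped back to the original image coordinates so
#' overlays render on the source pixels.
#'
#' @param det A [detector()] contract.
#' @param exam A [breast_exam()].
#' @return List with `boxes_cc` and `boxes_mlo`.
#' @export
detect_exam <- function(det, exam) {
  stopifnot(inherits(det, "dv_detector"), inherits(exam, "breast_exam"))
  run <- function(v) {
    sv <- if (v$standardized) v else standardize_orientation(v)
    boxes <- tryCatch(validate_boxes(det$fn(sv$pixels, sv)),
                      error = function(e) stop("detector failed on ", v$view,
                                               " view: ", conditionMessage(e)))
    if (v$laterality == "R") boxes <- mirror_boxes(boxes, ncol(v$pixels))
    boxes
  }
  list(boxes_cc = run(exam$cc), boxes_mlo = run(exam$mlo))
}

#' Breast-level objectness score for one class
#'
#' The maximum objectness over both views among boxes of `class_name`; 0
#' when no such box exists. The max (rather than mean) across views keeps
#' the OR-like sensitivity of the screening rule: a finding visible in one
#' projection is enough.
#'
#' @param boxes_cc,boxes_mlo Bounding-box data frames.
#' @param class_name Class to score.
#' @return Numeric scalar in `[0, 1]`.
#' @export
max_objectness <- function(boxes_cc, boxes_mlo, class_name = "suspicious_mass") {
  all_boxes <- rbind(validate_boxes(boxes_cc), validate_boxes(boxes_mlo))
  sel <- all_boxes$objectness[all_boxes$class_name == class_name]
  if (length(sel) == 0) 0 else max(sel)
}
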