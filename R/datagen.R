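#' Synthetic cohort generation parameters
#'
#' Bundles the knobs of the synthetic mammogram generator. The generator
#' renders paired CC/MLO views of one breast that share a latent abnormality
#' state: a bright breast region on a dark background, a pectoral-muscle
#' wedge in the MLO view, and, in abnormal breasts, bright Gaussian-profile
#' elliptical blobs present in both views with ground-truth bounding boxes.
#' Right-laterality breasts are rendered horizontally mirrored.
#'
#' @param image_size Side of the square image in pixels.
#' @param abnormal_fraction Probability that a breast carries an abnormality,
#'   in `[0, 1]`.
#' @param blob_count_range Integer pair `(min, max)`: number of mass blobs
#'   per abnormal breast.
#' @param blob_radius_range Pixel pair `(min, max)`: blob radius. The
#'   rendered blob is a Gaussian brightness profile with `sigma = radius/2`;
#'   the ground-truth box is the square of half-side `radius` around the
#'   centre.
#' @param blob_amplitude Peak added brightness of a blob (before clipping to
#'   `[0, 1]`).
#' @param noise_sd Standard deviation of additive Gaussian pixel noise.
#' @param tissue_intensity Intensity of the breast disc.
#' @param wedge_intensity Intensity of the MLO pectoral wedge.
#' @param extra_finding_prob Probability that an abnormal breast additionally
#'   carries a small high-intensity `lymph_node` dot (exercises the
#'   multi-class detector path).
#' @param seed Integer master seed; per-exam seeds are derived from it so a
#'   cohort is reproducible independent of generation order.
#'
#' @return An object of class `synth_params`.
#' @export
synth_params <- function(image_size = 128L,
                         abnormal_fraction = 0.3,
                         blob_count_range = c(1L, 3L),
                         blob_radius_range = c(6, 11),
                         blob_amplitude = 0.5,
                         noise_sd = 0.02,
                         tissue_intensity = 0.45,
                         wedge_intensity = 0.55,
                         extra_finding_prob = 0,
                         seed = 1L) {
  image_size <- as.integer(image_size)
  stopifnot(length(image_size) == 1L, image_size >= 32L)
  if (abnormal_fraction < 0 || abnormal_fraction > 1)
    stop("abnormal_fraction must lie in [0, 1]")
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  blob_count_range <- as.integer(blob_count_range)
  stopifnot(length(blob_count_range) == 2L,
            blob_count_range[1] >= 1L,
            blob_count_range[1] <= blob_count_range[2])
  stopifnot(length(blob_radius_range) == 2L,
            blob_radius_range[1] > 0,
            blob_radius_range[1] <= blob_radius_range[2])
  if (max(blob_radius_range) >= image_size / 2)
    stop("blob radii must be smaller than image_size / 2")
  structure(list(
    image_size = image_size,
    abnormal_fraction = abnormal_fraction,
    blob_count_range = blob_count_range,
    blob_radius_range = blob_radius_range,
    blob_amplitude = blob_amplitude,
    noise_sd = noise_sd,
    tissue_intensity = tissue_intensity,
    wedge_intensity = wedge_intensity,
    extra_finding_prob = extra_finding_prob,
    seed = as.integer(seed)
  ), class = "synth_params")
}

# Deterministic per-exam seed: a small polynomial hash of the study id and
# laterality folded into the master seed, kept inside 32-bit integer range.
exam_seed <- function(seed, study_id, laterality) {
  h <- 0
  for (ch in utf8ToInt(paste0(study_id, "|", laterality)))
    h <- (h * 31 + ch) %% 2147483563
  as.integer((h + as.numeric(seed) * 7919) %% 2147483563) + 1L
}

# Latent abnormality state of one breast, sampled without rendering pixels.
# Blob geometry is expressed in the left-laterality canonical frame (chest
# wall at x = 0); rendering mirrors it for right breasts.
sample_exam_state <- function(params, study_id, laterality) {
  set.seed(exam_seed(params$seed, study_id, laterality))
  abnormal <- stats::runif(1) < params$abnormal_fraction
  s <- params$image_size
  blobs <- NULL
  birads <- 1L
  if (abnormal) {
    # BI-RADS >= 2 marks an abnormal study; categories weighted roughly as
    # screening populations skew (mostly benign findings).
    birads <- sample(2:5, 1L, prob = c(0.68, 0.16, 0.12, 0.04))
    rng <- params$blob_count_range
    n_blob <- rng[1] + sample.int(rng[2] - rng[1] + 1L, 1L) - 1L
    radius <- stats::runif(n_blob, params$blob_radius_range[1], params$blob_radius_range[2])
    # Shared radial position from the chest wall; independent transverse
    # jitter per view stands in for the different projection geometry.
    margin <- ceiling(max(radius)) + 2
    rad_pos <- stats::runif(n_blob, 0.15, 0.55) * s
    rad_pos <- pmin(pmax(rad_pos, margin), s - margin)
    y_cc  <- stats::runif(n_blob, 0.30, 0.70) * s
    y_cc  <- pmin(pmax(y_cc, margin), s - margin)
    y_mlo <- y_cc + stats::rnorm(n_blob, 0, 0.06 * s)
    y_mlo <- pmin(pmax(y_mlo, max(0.30 * s, margin)), min(0.85 * s, s - margin))
    blobs <- data.frame(
      x = rad_pos, y_cc = y_cc, y_mlo = y_mlo,
      radius = radius, class_name = "suspicious_mass",
      stringsAsFactors = FALSE
    )
    if (stats::runif(1) < params$extra_finding_prob) {
      r <- stats::runif(1, 2.5, 4)
      blobs <- rbind(blobs, data.frame(
        x = stats::runif(1, 0.2, 0.5) * s,
        y_cc = stats::runif(1, 0.35, 0.65) * s,
        y_mlo = stats::runif(1, 0.45, 0.75) * s,
        radius = r, class_name = "lymph_node",
        stringsAsFactors = FALSE
      ))
    }
  }
  list(abnormal = abnormal, birads = birads, blobs = blobs,
       noise_seed = sample.int(.Machine$integer.max, 1L))
}

# Breast disc + optional pectoral wedge in the left canonical frame.
render_base_view <- function(params, view) {
  s <- params$image_size
  xs <- matrix(rep(seq_len(s) - 0.5, each = s), nrow = s)   # column coord
  ys <- matrix(rep(seq_len(s) - 0.5, times = s), nrow = s)  # row coord
  img <- matrix(0.02, s, s)
  if (view == "CC") {
    a <- 0.82 * s; b <- 0.40 * s; cy <- 0.5 * s
    inside <- (xs / a)^2 + ((ys - cy) / b)^2 <= 1
  } else {
    # MLO: breast half-ellipse shifted downward, wedge added above.
    a <- 0.78 * s; b <- 0.44 * s; cy <- 0.58 * s
    inside <- (xs / a)^2 + ((ys - cy) / b)^2 <= 1
  }
  img[inside] <- params$tissue_intensity
  if (view == "MLO") {
    wedge <- (xs / (0.42 * s) + ys / (0.55 * s)) <= 1
    img[wedge] <- params$wedge_intensity
  }
  list(img = img, xs = xs, ys = ys)
}

# Render one view of one breast from its latent state; returns the pixel
# matrix plus ground-truth boxes in emitted (possibly mirrored) coordinates.
render_view <- function(params, state, view, laterality) {
  s <- params$image_size
  base <- render_base_view(params, view)
  img <- base$img
  boxes <- empty_boxes()
  if (!is.null(state$blobs)) {
    for (i in seq_len(nrow(state$blobs))) {
      bl <- state$blobs[i, ]
      cy <- if (view == "CC") bl$y_cc else bl$y_mlo
      sigma <- bl$radius / 2
      amp <- if (bl$class_name == "lymph_node") 0.55 else params$blob_amplitude
      img <- img + amp * exp(-(((base$xs - bl$x)^2 + (base$ys - cy)^2) / (2 * sigma^2)))
      boxes <- rbind(boxes, bounding_box(
        x_min = max(0, bl$x - bl$radius), y_min = max(0, cy - bl$radius),
        x_max = min(s, bl$x + bl$radius), y_max = min(s, cy + bl$radius),
        class_name = bl$class_name, objectness = 1, source_model = "ground_truth"
      ))
    }
  }
  if (params$noise_sd > 0)
    img <- img + matrix(stats::rnorm(s * s, 0, params$noise_sd), s, s)
  img <- pmin(pmax(img, 0), 1)
  if (laterality == "R") {
    img <- img[, rev(seq_len(ncol(img))), drop = FALSE]
    boxes <- mirror_boxes(boxes, s)
  }
  list(pixels = img, boxes = boxes)
}

#' Generate one synthetic breast exam (CC + MLO pair) with ground truth
#'
#' Both views share the breast's latent abnormality state: abnormal breasts
#' carry the same blobs at the same distance from the chest wall in both
#' projections (with transverse jitter), so the label is consistent across
#' views. Output is bit-reproducible given `(params, study_id, laterality)`.
#'
#' @param params A [synth_params()] object.
#' @param study_id Study identifier string.
#' @param laterality `"L"` or `"R"`; right breasts are rendered horizontally
#'   mirrored.
#' @return A list with `exam` (a [breast_exam()]) and `truth` (label, birads,
#'   `boxes_cc`, `boxes_mlo` in emitted pixel coordinates).
#' @export
generate_exam <- function(params, study_id, laterality = c("L", "R")) {
  stopifnot(inherits(params, "synth_params"))
  laterality <- match.arg(laterality)
  state <- sample_exam_state(params, study_id, laterality)
  set.seed(state$noise_seed)
  cc  <- render_view(params, state, "CC", laterality)
  mlo <- render_view(params, state, "MLO", laterality)
  label <- as.integer(state$abnormal)
  exam <- breast_exam(
    cc  = mammogram_view(cc$pixels, laterality, "CC", study_id),
    mlo = mammogram_view(mlo$pixels, laterality, "MLO", study_id),
    label = label, birads = state$birads
  )
  list(exam = exam,
       truth = list(label = label, birads = state$birads,
                    boxes_cc = cc$boxes, boxes_mlo = mlo$boxes))
}

#' Generate a synthetic screening cohort
#'
#' Emits the four-view exam structure of a screening study (L-CC, L-MLO,
#' R-CC, R-MLO). When `out_dir` is given, images are written as 8-bit
#' grayscale PNG, boxes as YOLO-format annotation files, and a CSV manifest
#' (`study_id, laterality, view, path, birads, label`) indexes them. Without
#' `out_dir` the cohort is returned in memory (exams + truths + manifest),
#' which the training and screening code consume directly.
#'
#' @param params A [synth_params()] object.
#' @param n_studies Number of studies (two breasts each).
#' @param out_dir Optional output directory.
#' @return Invisibly (written) or visibly (in memory), a list with `exams`,
#'   `truths`, and the `manifest` data frame.
#' @export
generate_cohort <- function(params, n_studies, out_dir = NULL) {
  stopifnot(inherits(params, "synth_params"), n_studies >= 1)
  study_ids <- sprintf("S%05d", seq_len(n_studies))
  exams <- list(); truths <- list()
  rows <- vector("list", 4L * n_studies)
  k <- 0L
  if (!is.null(out_dir) && !dir.exists(out_dir))
    if (!dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
      stop("cannot create output directory: ", out_dir)
  for (sid in study_ids) {
    for (lat in c("L", "R")) {
      g <- generate_exam(params, sid, lat)
      key <- paste0(sid, "_", lat)
      exams[[key]] <- g$exam
      truths[[key]] <- g$truth
      for (vw in c("CC", "MLO")) {
        k <- k + 1L
        stem <- sprintf("%s_%s_%s", sid, lat, vw)
        path <- paste0(stem, ".png")
        if (!is.null(out_dir)) {
          view <- if (vw == "CC") g$exam$cc else g$exam$mlo
          png::writePNG(view$pixels, file.path(out_dir, path))
          boxes <- if (vw == "CC") g$truth$boxes_cc else g$truth$boxes_mlo
          write_yolo_annotations(boxes, params$image_size,
                                 file.path(out_dir, paste0(stem, ".txt")))
        }
        rows[[k]] <- data.frame(
          study_id = sid, laterality = lat, view = vw, path = path,
          birads = g$truth$birads, label = g$truth$label,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
    return(invisible(list(exams = exams, truths = truths, manifest = manifest,
                          out_dir = out_dir)))
  }
  list(exams = exams, truths = truths, manifest = manifest)
}

#' Write bounding boxes as YOLO-format annotations
#'
#' One line per box: `class_index center_x center_y width height`, all
#' normalized to `[0, 1]` by the image side. Class indices follow
#' [detector_classes()]. An empty box set produces an empty file.
#'
#' @param boxes Bounding-box data frame (see [bounding_box()]).
#' @param image_size Image side in pixels (square images).
#' @param path Output file path.
#' @export
write_yolo_annotations <- function(boxes, image_size, path) {
  boxes <- validate_boxes(boxes)
  if (nrow(boxes) > 0) {
    if (any(boxes$x_min < 0 | boxes$y_min < 0 |
            boxes$x_max > image_size | boxes$y_max > image_size))
      stop("box outside image bounds")
    cls <- match(boxes$class_name, detector_classes()) - 1L
    if (anyNA(cls)) stop("unknown class name in boxes")
    lines <- sprintf("%d %.6f %.6f %.6f %.6f", cls,
                     (boxes$x_min + boxes$x_max) / 2 / image_size,
                     (boxes$y_min + boxes$y_max) / 2 / image_size,
                     (boxes$x_max - boxes$x_min) / image_size,
                     (boxes$y_max - boxes$y_min) / image_size)
  } else lines <- character(0)
  writeLines(lines, path)
  invisible(path)
}

#' Read YOLO-format annotation or prediction files
#'
#' Accepts 5-column annotation lines (`class cx cy w h`) or 6-column
#' prediction lines (`class cx cy w h conf`); normalized coordinates are
#' mapped back to pixels.
#'
#' @param path Annotation file path.
#' @param image_size Image side in pixels.
#' @param source_model Tag recorded in the `source_model` column.
#' @return A bounding-box data frame.
#' @export
read_yolo_annotations <- function(path, image_size, source_model = "yolo_file") {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(empty_boxes())
  fields <- lapply(strsplit(trimws(lines), "\\s+"), as.numeric)
  nf <- lengths(fields)
  if (!all(nf %in% c(5L, 6L))) stop("malformed YOLO line in ", path)
  m <- do.call(rbind, lapply(fields, function(f) c(f, if (length(f) == 5L) 1 else NULL)))
  cx <- m[, 2] * image_size; cy <- m[, 3] * image_size
  w <- m[, 4] * image_size; h <- m[, 5] * image_size
  bounding_box(
    x_min = cx - w / 2, y_min = cy - h / 2,
    x_max = cx + w / 2, y_max = cy + h / 2,
    class_name = detector_classes()[m[, 1] + 1L],
    objectness = m[, 6], source_model = source_model
  )
}
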