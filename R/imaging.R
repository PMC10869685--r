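#' A single mammographic view
#'
#' Holds one grayscale image with its acquisition metadata. Pixels are a
#' numeric matrix in `[0, 1]`, rows = image rows (y, top to bottom),
#' columns = x. Pixel coordinates throughout the package are 0-based,
#' half-open, origin top-left, x = column.
#'
#' @param pixels Numeric matrix of nonnegative intensities.
#' @param laterality `"L"` or `"R"`.
#' @param view `"CC"` or `"MLO"`.
#' @param study_id Study identifier.
#' @param source_path Optional path the image was read from.
#' @param standardized Logical: has [standardize_orientation()] been applied?
#' @return An object of class `mammogram_view`.
#' @export
mammogram_view <- function(pixels, laterality, view, study_id,
                           source_path = NA_character_, standardized = FALSE) {
  if (!is.matrix(pixels) || length(pixels) == 0)
    stop("pixels must be a nonempty matrix")
  if (any(pixels < 0)) stop("pixel intensities must be nonnegative")
  laterality <- match.arg(laterality, c("L", "R"))
  view <- match.arg(view, c("CC", "MLO"))
  structure(list(pixels = pixels, laterality = laterality, view = view,
                 study_id = study_id, source_path = source_path,
                 standardized = isTRUE(standardized)),
            class = "mammogram_view")
}

#' A breast exam: paired CC and MLO views of one breast
#'
#' @param cc,mlo [mammogram_view()] objects with matching study and
#'   laterality.
#' @param label Optional binary label (1 = abnormal).
#' @param birads Optional BI-RADS category 1--6.
#' @return An object of class `breast_exam`.
#' @export
breast_exam <- function(cc, mlo, label = NA_integer_, birads = NA_integer_) {
  stopifnot(inherits(cc, "mammogram_view"), inherits(mlo, "mammogram_view"))
  if (cc$view != "CC" || mlo$view != "MLO")
    stop("cc must be a CC view and mlo an MLO view")
  if (cc$laterality != mlo$laterality)
    stop("views of one breast must share laterality")
  if (!identical(cc$study_id, mlo$study_id))
    stop("views of one breast must share study_id")
  if (!is.na(birads) && (birads < 1 || birads > 6))
    stop("birads must lie in 1..6")
  structure(list(cc = cc, mlo = mlo, laterality = cc$laterality,
                 study_id = cc$study_id, label = label, birads = birads),
            class = "breast_exam")
}

#' @export
print.breast_exam <- function(x, ...) {
  cat(sprintf("<breast_exam %s %s  label=%s birads=%s  cc %dx%d mlo %dx%d>\n",
              x$study_id, x$laterality, x$label, x$birads,
              nrow(x$cc$pixels), ncol(x$cc$pixels),
              nrow(x$mlo$pixels), ncol(x$mlo$pixels)))
  invisible(x)
}

#' Load a mammographic view from disk
#'
#' Reads grayscale PNG or single-frame uncompressed DICOM. PNG intensities
#' arrive in `[0, 1]` from the 8/16-bit encoding; DICOM pixel values are
#' divided by the per-image maximum so each image spans `[0, 1]` regardless
#' of vendor bit depth.
#'
#' @param path Image file path.
#' @inheritParams mammogram_view
#' @return A [mammogram_view()].
#' @export
load_view <- function(path, laterality, view, study_id) {
  if (!file.exists(path)) stop("file not found: ", path)
  magic <- readBin(path, "raw", n = 8)
  if (length(magic) >= 8 &&
      identical(magic[1:4], as.raw(c(0x89, 0x50, 0x4e, 0x47)))) {
    px <- png::readPNG(path)
    if (length(dim(px)) == 3L) px <- px[, , 1L]  # grayscale channel
  } else {
    px <- read_dicom_pixels(path)
    mx <- max(px)
    if (mx > 0) px <- px / mx
  }
  mammogram_view(px, laterality, view, study_id, source_path = path)
}

# Minimal single-frame DICOM reader: little-endian, uncompressed, explicit
# or implicit VR. Enough for the screening manifest use case; anything else
# (big endian, encapsulated/compressed syntaxes, multi-frame) is rejected.
read_dicom_pixels <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 140 || rawToChar(raw[129:132]) != "DICM")
    stop("not a DICOM file (missing DICM marker): ", path)
  u16 <- function(i) as.integer(raw[i]) + 256L * as.integer(raw[i + 1L])
  u32 <- function(i) as.numeric(u16(i)) + 65536 * as.numeric(u16(i + 2L))
  pos <- 133L
  explicit <- TRUE
  transfer <- "1.2.840.10008.1.2.1"
  rows <- cols <- bits <- n_frames <- NA_integer_
  pixel_raw <- NULL
  in_meta <- TRUE
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  while (pos + 8L <= length(raw) + 1L) {
    group <- u16(pos); elem <- u16(pos + 2L)
    if (in_meta && group != 0x0002) {
      in_meta <- FALSE
      explicit <- transfer != "1.2.840.10008.1.2"
      if (!(transfer %in% c("1.2.840.10008.1.2", "1.2.840.10008.1.2.1")))
        stop("unsupported DICOM transfer syntax: ", transfer)
    }
    use_explicit <- explicit || group == 0x0002  # meta group is always explicit
    if (use_explicit) {
      vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
      if (vr %in% long_vrs) {
        len <- u32(pos + 8L); hdr <- 12L
      } else {
        len <- u16(pos + 6L); hdr <- 8L
      }
    } else {
      vr <- ""; len <- u32(pos + 4L); hdr <- 8L
    }
    if (len == 4294967295) stop("undefined-length DICOM element unsupported")
    val <- pos + hdr
    if (group == 0x0002 && elem == 0x0010)
      transfer <- gsub("[^0-9.]", "", rawToChar(raw[val:(val + len - 1L)]))
    if (group == 0x0028) {
      if (elem == 0x0010) rows <- u16(val)
      if (elem == 0x0011) cols <- u16(val)
      if (elem == 0x0100) bits <- u16(val)
      if (elem == 0x0008)
        n_frames <- as.integer(gsub("[^0-9]", "", rawToChar(raw[val:(val + len - 1L)])))
    }
    if (group == 0x7fe0 && elem == 0x0010) {
      pixel_raw <- raw[val:(val + len - 1L)]
      break
    }
    pos <- val + len
  }
  if (is.null(pixel_raw) || is.na(rows) || is.na(cols) || is.na(bits))
    stop("incomplete DICOM image data: ", path)
  if (!is.na(n_frames) && n_frames > 1L) stop("multi-frame DICOM unsupported")
  vals <- if (bits <= 8) {
    as.integer(pixel_raw[seq_len(rows * cols)])
  } else {
    idx <- seq_len(rows * cols)
    as.integer(pixel_raw[2L * idx - 1L]) + 256L * as.integer(pixel_raw[2L * idx])
  }
  matrix(vals, nrow = rows, ncol = cols, byrow = TRUE)
}

#' Standardize view orientation
#'
#' Views of right-laterality breasts are mirrored left--right so both
#' lateralities present the chest wall on the same side; left views pass
#' through unchanged. Applying the flip twice restores the original pixels.
#'
#' @param v A [mammogram_view()].
#' @return The view, flipped if right-sided and flagged `standardized`.
#' @export
standardize_orientation <- function(v) {
  stopifnot(inherits(v, "mammogram_view"))
  if (v$laterality == "R")
    v$pixels <- v$pixels[, rev(seq_len(ncol(v$pixels))), drop = FALSE]
  v$standardized <- !v$standardized
  v
}

#' Map a BI-RADS category to the binary screening label
#'
#' Category 1 (negative, no abnormal findings) maps to normal (0); all
#' categories 2--6 map to abnormal (1).
#'
#' @param birads Integer vector with values in 1..6.
#' @return Integer vector, 0 = normal, 1 = abnormal.
#' @export
birads_to_label <- function(birads) {
  if (any(is.na(birads)) || any(birads < 1 | birads > 6) ||
      any(birads != as.integer(birads)))
    stop("BI-RADS categories must be integers in 1..6")
  as.integer(birads >= 2)
}

#' Assemble breast exams from a cohort manifest
#'
#' Reads the CSV manifest (`study_id, laterality, view, path`, plus `birads`
#' and/or `label`), loads each image, and groups rows into one
#' [breast_exam()] per (study, laterality). Breasts missing either view are
#' excluded; the exclusion count and keys are attached as attributes. When
#' the `label` column is absent it is derived via [birads_to_label()].
#'
#' @param csv_path Manifest path.
#' @param image_root Directory that `path` entries are relative to; defaults
#'   to the manifest's directory.
#' @return A list of [breast_exam()] objects with attributes `n_excluded`
#'   and `excluded`.
#' @export
read_manifest <- function(csv_path, image_root = dirname(csv_path)) {
  m <- utils::read.csv(csv_path, stringsAsFactors = FALSE)
  required <- c("study_id", "laterality", "view", "path")
  if (!all(required %in% names(m)))
    stop("manifest must contain columns: ", paste(required, collapse = ", "))
  if (!"label" %in% names(m)) {
    if (!"birads" %in% names(m))
      stop("manifest needs a label or birads column")
    m$label <- birads_to_label(m$birads)
  }
  if (!"birads" %in% names(m)) m$birads <- NA_integer_
  keys <- unique(m[, c("study_id", "laterality")])
  exams <- list(); excluded <- character(0)
  for (i in seq_len(nrow(keys))) {
    sub <- m[m$study_id == keys$study_id[i] & m$laterality == keys$laterality[i], ]
    cc_row <- sub[sub$view == "CC", ]; mlo_row <- sub[sub$view == "MLO", ]
    key <- paste0(keys$study_id[i], "_", keys$laterality[i])
    if (nrow(cc_row) != 1L || nrow(mlo_row) != 1L) {
      excluded <- c(excluded, key)
      next
    }
    exams[[key]] <- breast_exam(
      cc  = load_view(file.path(image_root, cc_row$path),
                      keys$laterality[i], "CC", keys$study_id[i]),
      mlo = load_view(file.path(image_root, mlo_row$path),
                      keys$laterality[i], "MLO", keys$study_id[i]),
      label = cc_row$label, birads = cc_row$birads
    )
  }
  if (length(excluded) > 0)
    message(length(excluded), " breast(s) excluded for missing views")
  attr(exams, "n_excluded") <- length(excluded)
  attr(exams, "excluded") <- excluded
  exams
}

#' Resize a view to a square model input
#'
#' Scales so the longer side matches `side` (bilinear, aspect preserved) and
#' zero-pads the remainder. Content is anchored at the top-left corner: with
#' standardized orientation the chest wall sits at x = 0, so padding falls on
#' the side away from the chest wall.
#'
#' @param v A [mammogram_view()] or a plain numeric matrix.
#' @param side Output side in pixels (>= 8).
#' @return A `side` x `side` numeric matrix in `[0, 1]`.
#' @export
resize_for_model <- function(v, side) {
  if (side < 8) stop("side must be at least 8")
  m <- if (inherits(v, "mammogram_view")) v$pixels else v
  h <- nrow(m); w <- ncol(m)
  f <- side / max(h, w)
  nh <- max(1L, round(h * f)); nw <- max(1L, round(w * f))
  if (nh != h || nw != w) {
    # EBImage images index (x, y): transpose in and out.
    img <- EBImage::resize(EBImage::Image(t(m)), w = nw, h = nh)
    m <- t(EBImage::imageData(img))
  }
  out <- matrix(0, side, side)
  out[seq_len(nrow(m)), seq_len(ncol(m))] <- m
  pmin(pmax(out, 0), 1)
}
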