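# Independent oracles and fixture builders used across the suite.

# Exhaustive pairwise AUC: the normalized Mann-Whitney U statistic, counting
# every (abnormal, normal) score pair directly; ties count one half.
auc_pairwise_oracle <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (n in neg)
    total <- total + if (p > n) 1 else if (p == n) 0.5 else 0
  total / (length(pos) * length(neg))
}

# Brute-force per-class greedy NMS working directly on plain vectors with
# quadratic pair checks, written independently of the package's vectorized
# implementation.
nms_bruteforce_oracle <- function(boxes, thr) {
  iou_one <- function(a, b) {
    iw <- min(a[3], b[3]) - max(a[1], b[1])
    ih <- min(a[4], b[4]) - max(a[2], b[2])
    if (iw <= 0 || ih <= 0) return(0)
    i <- iw * ih
    i / ((a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - i)
  }
  keep <- integer(0)
  for (cls in unique(boxes$class_name)) {
    idx <- which(boxes$class_name == cls)
    idx <- idx[order(-boxes$objectness[idx], boxes$x_min[idx], boxes$y_min[idx])]
    while (length(idx) > 0) {
      best <- idx[1]
      keep <- c(keep, best)
      surv <- integer(0)
      for (j in idx[-1]) {
        a <- as.numeric(boxes[best, c("x_min", "y_min", "x_max", "y_max")])
        b <- as.numeric(boxes[j, c("x_min", "y_min", "x_max", "y_max")])
        if (iou_one(a, b) < thr) surv <- c(surv, j)
      }
      idx <- surv
    }
  }
  sort(keep)
}

random_boxes <- function(n, size = 100, classes = c("suspicious_mass", "lymph_node")) {
  x1 <- runif(n, 0, size - 10); y1 <- runif(n, 0, size - 10)
  bounding_box(
    x_min = x1, y_min = y1,
    x_max = pmin(x1 + runif(n, 2, 30), size),
    y_max = pmin(y1 + runif(n, 2, 30), size),
    class_name = sample(classes, n, replace = TRUE),
    objectness = round(runif(n), 3),
    source_model = sample(c("m1", "m2"), n, replace = TRUE)
  )
}

# Minimal single-frame explicit-VR little-endian DICOM writer: just enough
# structure (preamble, DICM marker, meta group, rows/cols/bits, pixel data)
# to exercise the package's reader. Synthetic fixture, built in code.
write_synthetic_dicom <- function(path, pixels, bits = 16L) {
  u16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  u32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  elem_short <- function(group, el, vr, value_raw) {
    u16(group); u16(el); writeChar(vr, con, eos = NULL)
    u16(length(value_raw)); writeBin(value_raw, con)
  }
  elem_long <- function(group, el, vr, value_raw) {
    u16(group); u16(el); writeChar(vr, con, eos = NULL)
    u16(0); u32(length(value_raw)); writeBin(value_raw, con)
  }
  str_raw <- function(s) {
    r <- charToRaw(s)
    if (length(r) %% 2 == 1) r <- c(r, as.raw(0))
    r
  }
  us_raw <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeChar("DICM", con, eos = NULL)
  ts <- str_raw("1.2.840.10008.1.2.1")   # explicit VR little endian
  # meta group length element (value = bytes of the one following element)
  elem_short(0x0002, 0x0000, "UL",
             writeBin(as.integer(8 + length(ts)), raw(), size = 4, endian = "little"))
  elem_short(0x0002, 0x0010, "UI", ts)
  elem_short(0x0028, 0x0008, "IS", str_raw("1"))
  elem_short(0x0028, 0x0010, "US", us_raw(nrow(pixels)))
  elem_short(0x0028, 0x0011, "US", us_raw(ncol(pixels)))
  elem_short(0x0028, 0x0100, "US", us_raw(bits))
  vals <- as.integer(t(pixels))            # row-major pixel order
  pix <- if (bits <= 8) as.raw(vals) else
    writeBin(vals, raw(), size = 2, endian = "little")
  elem_long(0x7fe0, 0x0010, "OW", pix)
  invisible(path)
}

# Small labelled cohort in memory; higher contrast than defaults is not
# needed -- defaults already carry the planted-mass signal.
make_cohort <- function(n_studies, seed = 1, abnormal_fraction = 0.5, ...) {
  generate_cohort(synth_params(seed = seed, abnormal_fraction = abnormal_fraction, ...),
                  n_studies)
}

exam_labels <- function(exams) vapply(exams, `[[`, numeric(1), "label")
exam_studies <- function(exams) vapply(exams, `[[`, "", "study_id")

fast_config <- function(...) {
  args <- utils::modifyList(
    list(learning_rate = 0.05, max_epochs = 40, patience = 8, seed = 2),
    list(...))
  do.call(dualview_config, args)
}
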