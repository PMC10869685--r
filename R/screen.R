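#' Screening decision thresholds
#'
#' Defaults follow the screening rule: classifier probability strictly
#' above 0.5, or suspicious-mass objectness of 0.25 or higher.
#'
#' @param prob_threshold Classifier probability threshold in `(0, 1)`;
#'   triggered by strict `>`.
#' @param objectness_threshold Suspicious-mass objectness threshold in
#'   `(0, 1)`; triggered by `>=`.
#' @return An object of class `screening_thresholds`.
#' @export
screening_thresholds <- function(prob_threshold = 0.5,
                                 objectness_threshold = 0.25) {
  if (prob_threshold <= 0 || prob_threshold >= 1 ||
      objectness_threshold <= 0 || objectness_threshold >= 1)
    stop("thresholds must lie in (0, 1)")
  structure(list(prob_threshold = prob_threshold,
                 objectness_threshold = objectness_threshold),
            class = "screening_thresholds")
}

#' Binary screening decision for one breast
#'
#' Fuses the classifier probability with the breast-level suspicious-mass
#' objectness. Under the default OR logic a breast is called abnormal when
#' either trigger fires, so the detector can rescue classifier misses —
#' the behaviour that raises ensemble sensitivity above the classifier
#' alone. The conjunctive reading is available via `logic = "and"`.
#'
#' @param prob Classifier abnormality probability in `[0, 1]`.
#' @param mass_objectness Breast-level suspicious-mass objectness in
#'   `[0, 1]` (see [max_objectness()]).
#' @param thresholds A [screening_thresholds()].
#' @param logic `"or"` (default) or `"and"`.
#' @return `"abnormal"` or `"normal"`.
#' @export
decide <- function(prob, mass_objectness,
                   thresholds = screening_thresholds(),
                   logic = c("or", "and")) {
  logic <- match.arg(logic)
  stopifnot(prob >= 0, prob <= 1, mass_objectness >= 0, mass_objectness <= 1)
  cls <- prob > thresholds$prob_threshold
  det <- mass_objectness >= thresholds$objectness_threshold
  hit <- if (logic == "or") cls || det else cls && det
  if (hit) "abnormal" else "normal"
}

#' Priority tier for radiologist review
#'
#' Tier 1: detected suspicious mass (objectness at/above threshold) —
#' screened first. Tier 2: classifier-abnormal without a tier-1 mass.
#' Tier 3: findings from the all-abnormality detector only (these inform
#' prioritization but never flip the binary decision). Tier 4: nothing
#' flagged.
#'
#' @inheritParams decide
#' @param n_other_findings Count of boxes from the all-abnormality
#'   detector.
#' @return Integer tier in 1..4.
#' @export
assign_tier <- function(prob, mass_objectness, n_other_findings = 0L,
                        thresholds = screening_thresholds()) {
  if (mass_objectness >= thresholds$objectness_threshold) return(1L)
  if (prob > thresholds$prob_threshold) return(2L)
  if (n_other_findings > 0) return(3L)
  4L
}

#' Screen a cohort and build the radiologist priority queue
#'
#' Runs the full pipeline per breast: classifier probability from the
#' dual-view model, suspicious-mass detection on both views, optional
#' all-abnormality detection, the binary decision, and the priority tier.
#' Breasts are ordered by tier (ascending) then by descending
#' `max(prob, mass_objectness)`, with `(study_id, laterality)` as the
#' deterministic tie-break; each patient additionally carries the best
#' (lowest) tier over their breasts as `patient_tier`.
#'
#' @param exams List of [breast_exam()] objects.
#' @param model A trained [dualview_model()].
#' @param mass_detector [detector()] for suspicious masses.
#' @param abnormality_detector Optional [detector()] for the wider finding
#'   classes; its boxes populate `n_other_findings` and tier 3.
#' @param thresholds A [screening_thresholds()].
#' @param logic Decision logic, `"or"` or `"and"`.
#' @return An object of class `screening_report`: `decisions` (ordered data
#'   frame) and `detections` (per-breast box lists for overlays).
#' @export
screen_cohort <- function(exams, model, mass_detector,
                          abnormality_detector = NULL,
                          thresholds = screening_thresholds(),
                          logic = c("or", "and")) {
  logic <- match.arg(logic)
  stopifnot(length(exams) >= 1)
  probs <- predict_prob(model, exams)
  rows <- vector("list", length(exams))
  detections <- vector("list", length(exams))
  for (i in seq_along(exams)) {
    ex <- exams[[i]]
    det <- detect_exam(mass_detector, ex)
    obj <- max_objectness(det$boxes_cc, det$boxes_mlo, "suspicious_mass")
    other <- if (!is.null(abnormality_detector)) {
      o <- detect_exam(abnormality_detector, ex)
      rbind(o$boxes_cc, o$boxes_mlo)
    } else empty_boxes()
    dec <- decide(probs[i], obj, thresholds, logic)
    tier <- assign_tier(probs[i], obj, nrow(other), thresholds)
    reasons <- c(
      if (obj >= thresholds$objectness_threshold)
        sprintf("suspicious mass objectness %.3f >= %.2f", obj,
                thresholds$objectness_threshold),
      if (probs[i] > thresholds$prob_threshold)
        sprintf("classifier probability %.3f > %.2f", probs[i],
                thresholds$prob_threshold),
      if (tier == 3L)
        sprintf("%d finding(s) from abnormality detector", nrow(other))
    )
    key <- paste0(ex$study_id, "_", ex$laterality)
    rows[[i]] <- data.frame(
      study_id = ex$study_id, laterality = ex$laterality,
      prob = probs[i], mass_objectness = obj,
      n_other_findings = nrow(other), decision = dec, tier = tier,
      reasons = paste(reasons, collapse = "; "),
      stringsAsFactors = FALSE
    )
    detections[[key]] <- list(mass = det, other = other)
  }
  decisions <- do.call(rbind, rows)
  score <- pmax(decisions$prob, decisions$mass_objectness)
  ord <- order(decisions$tier, -score, decisions$study_id, decisions$laterality)
  decisions <- decisions[ord, , drop = FALSE]
  rownames(decisions) <- NULL
  pt <- tapply(decisions$tier, decisions$study_id, min)
  decisions$patient_tier <- as.integer(pt[decisions$study_id])
  structure(list(decisions = decisions, detections = detections,
                 thresholds = thresholds, logic = logic),
            class = "screening_report")
}

#' @export
print.screening_report <- function(x, ...) {
  cat(sprintf("<screening_report: %d breasts, logic=%s>\n",
              nrow(x$decisions), x$logic))
  print(table(tier = x$decisions$tier))
  invisible(x)
}

#' Write a screening report to disk
#'
#' Emits a JSON-lines file (one object per breast, including overlay box
#' coordinates) and a CSV review queue in priority order.
#'
#' @param report A [screen_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the two file paths.
#' @export
write_screening_report <- function(report, dir) {
  stopifnot(inherits(report, "screening_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  jsonl <- file.path(dir, "screening_report.jsonl")
  con <- file(jsonl, "w"); on.exit(close(con))
  for (i in seq_len(nrow(report$decisions))) {
    row <- report$decisions[i, ]
    key <- paste0(row$study_id, "_", row$laterality)
    det <- report$detections[[key]]
    obj <- c(as.list(row), list(
      boxes_cc = det$mass$boxes_cc, boxes_mlo = det$mass$boxes_mlo,
      other_findings = det$other
    ))
    writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), con)
  }
  queue <- file.path(dir, "review_queue.csv")
  utils::write.csv(report$decisions, queue, row.names = FALSE)
  invisible(c(jsonl = jsonl, queue = queue))
}
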