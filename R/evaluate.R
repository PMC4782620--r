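box_iou <- function(a, b) {
  # half-open boxes r0 r1 c0 c1
  ih <- max(0, min(a[2], b[2]) - max(a[1], b[1]))
  iw <- max(0, min(a[4], b[4]) - max(a[3], b[3]))
  inter <- ih * iw
  union <- (a[2] - a[1]) * (a[4] - a[3]) + (b[2] - b[1]) * (b[4] - b[3]) - inter
  if (union <= 0) 0 else inter / union
}

center_in <- function(box, of) {
  cy <- (of[1] + of[2]) / 2; cx <- (of[3] + of[4]) / 2
  cy >= box[1] && cy < box[2] && cx >= box[3] && cx < box[4]
}

#' Score cluster detections against ground truth
#'
#' Per image, candidate matches between merged detections and true cluster
#' boxes are formed under the chosen rule. A true cluster is counted as
#' detected if at least one detection matches it, and is credited to the
#' single detection with the largest box overlap (IoU) among its matches —
#' each truth is claimed by at most one detection, while one detection may
#' claim several truths (a merged box spanning two true clusters detects
#' both). Detections matching no true cluster are false positives. Results
#' are summarized by the true-positive rate over all true clusters and the
#' mean number of false detections per image — the standard CAD
#' operating-point metrics.
#'
#' @param detections_per_image List (one element per image) of detection
#'   data frames as returned by [merge_detections()].
#' @param truths_per_image List of the same length of true-cluster boxes:
#'   data frames with half-open pixel columns `r0`, `r1`, `c0`, `c1` (e.g.
#'   `truth$cluster_boxes_px` from [generate_phantom()]).
#' @param match_rule `"center_in_box"` (default): a detection matches a
#'   truth if either box's centre lies inside the other box — tolerant of
#'   block-grid quantization. `"box_overlap"`: IoU at least `min_iou`.
#' @param min_iou Minimum IoU for `"box_overlap"` (default 0.2).
#' @return An object of class `mc_eval`: list with `n_true_clusters`,
#'   `n_detected_true`, `tpr_percent` (`NA` when there are no true
#'   clusters), `n_false_detections`, `n_images`, `fp_per_image`, and
#'   `per_image_records` (data frame: image, counts of truths, detections,
#'   matches and false positives).
#' @export
match_and_score <- function(detections_per_image, truths_per_image,
                            match_rule = c("center_in_box", "box_overlap"),
                            min_iou = 0.2) {
  match_rule <- match.arg(match_rule)
  if (length(detections_per_image) != length(truths_per_image))
    stop("detection and truth lists must have equal length")
  n_img <- length(detections_per_image)
  if (n_img < 1L) stop("at least one image is required")
  rec <- vector("list", n_img)
  for (i in seq_len(n_img)) {
    det <- as.data.frame(detections_per_image[[i]])
    tru <- as.data.frame(truths_per_image[[i]])
    nd <- nrow(det); nt <- nrow(tru)
    pairs <- NULL
    if (nd > 0L && nt > 0L) {
      for (a in seq_len(nd)) {
        db <- c(det$r0[a], det$r1[a], det$c0[a], det$c1[a])
        for (b in seq_len(nt)) {
          tb <- c(tru$r0[b], tru$r1[b], tru$c0[b], tru$c1[b])
          hit <- switch(match_rule,
            center_in_box = center_in(db, tb) || center_in(tb, db),
            box_overlap = box_iou(db, tb) >= min_iou)
          if (hit)
            pairs <- rbind(pairs, c(a, b, box_iou(db, tb)))
        }
      }
    }
    det_hit <- logical(nd); tru_hit <- logical(nt)
    if (!is.null(pairs)) {
      pairs <- pairs[order(-pairs[, 3]), , drop = FALSE]
      det_hit[unique(pairs[, 1])] <- TRUE
      # each truth is claimed once, by its highest-overlap detection
      tru_hit[unique(pairs[, 2])] <- TRUE
    }
    rec[[i]] <- data.frame(image = i, n_truth = nt, n_detections = nd,
                           n_matched = sum(tru_hit),
                           n_matched_det = sum(det_hit),
                           n_false = sum(!det_hit))
  }
  rec <- do.call(rbind, rec)
  n_true <- sum(rec$n_truth)
  n_det_true <- sum(rec$n_matched)
  n_fp <- sum(rec$n_false)
  structure(list(
    n_true_clusters = n_true,
    n_detected_true = n_det_true,
    tpr_percent = if (n_true > 0L) 100 * n_det_true / n_true else NA_real_,
    n_false_detections = n_fp,
    n_images = n_img,
    fp_per_image = n_fp / n_img,
    per_image_records = rec),
    class = "mc_eval")
}

#' @export
print.mc_eval <- function(x, ...) {
  tpr <- if (is.na(x$tpr_percent)) "undefined (no true clusters)"
         else sprintf("%.1f%% (%d/%d)", x$tpr_percent, x$n_detected_true,
                      x$n_true_clusters)
  cat("<mc_eval>\n")
  cat("  true positive rate: ", tpr, "\n", sep = "")
  cat(sprintf("  false positives:    %.2f per image (%d over %d images)\n",
              x$fp_per_image, x$n_false_detections, x$n_images))
  invisible(x)
}

#' Tidy an evaluation result into a one-row data frame
#' @param x An `mc_eval` object.
#' @param ... Unused.
#' @return A one-row data frame of the summary fields.
#' @export
as.data.frame.mc_eval <- function(x, ...) {
  data.frame(n_true_clusters = x$n_true_clusters,
             n_detected_true = x$n_detected_true,
             tpr_percent = x$tpr_percent,
             n_false_detections = x$n_false_detections,
             n_images = x$n_images,
             fp_per_image = x$fp_per_image)
}
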