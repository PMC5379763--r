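## Detection-quality evaluation against ground-truth label masks.

#' Match detections to ground-truth labels
#'
#' A detected cell is a true positive iff its centroid falls inside exactly
#' one still-unclaimed truth label and that label's centroid falls inside
#' the detected region (mutual centroid containment); every truth label can
#' be claimed at most once. Remaining detections are false positives
#' (noise artifacts or fragments of over-segmented cells), unclaimed truth
#' labels are false negatives.
#'
#' @param det_label integer matrix of detected cell labels (one id per
#'   detected cell, 0 background), e.g. `segment_frame()$label`.
#' @param truth_label integer ground-truth label mask of the same shape.
#' @return list(TP, FP, FN).
#' @export
match_detections <- function(det_label, truth_label) {
  if (!all(dim(det_label) == dim(truth_label)))
    stop("detected and truth masks differ in shape")
  det_ids <- sort(unique(det_label[det_label > 0]))
  truth_ids <- sort(unique(truth_label[truth_label > 0]))
  t_cent <- lapply(truth_ids, function(id) {
    w <- which(truth_label == id, arr.ind = TRUE)
    pmin(pmax(round(colMeans(w)), 1), dim(truth_label))
  })
  names(t_cent) <- as.character(truth_ids)
  claimed <- setNames(rep(FALSE, length(truth_ids)), as.character(truth_ids))
  TP <- 0L
  for (d in det_ids) {
    w <- which(det_label == d, arr.ind = TRUE)
    cen <- pmin(pmax(round(colMeans(w)), 1), dim(det_label))
    t_id <- truth_label[cen[1], cen[2]]
    if (t_id == 0 || claimed[as.character(t_id)]) next
    tc <- t_cent[[as.character(t_id)]]
    if (det_label[tc[1], tc[2]] == d) {
      claimed[as.character(t_id)] <- TRUE
      TP <- TP + 1L
    }
  }
  list(TP = TP, FP = length(det_ids) - TP, FN = sum(!claimed))
}

#' Detection metrics from confusion counts
#'
#' Recall `TPR = TP/(TP+FN)`, precision `PPV = TP/(TP+FP)` and their
#' harmonic mean `F = 2 * PPV * TPR / (PPV + TPR)`.
#'
#' @param TP,FP,FN non-negative counts; `TP + FN` must be positive.
#' @param scope label recorded in the report ("frame", "colony", "movie").
#' @return data.frame of class `eval_report` with counts, TPR, PPV, F (as
#'   fractions) and percentage columns rounded to 1 decimal.
#' @export
eval_metrics <- function(TP, FP, FN, scope = "frame") {
  stopifnot(TP >= 0, FP >= 0, FN >= 0, TP + FN > 0)
  TPR <- TP / (TP + FN)
  PPV <- if (TP + FP > 0) TP / (TP + FP) else NA_real_
  F1 <- if (!is.na(PPV) && PPV + TPR > 0) 2 * PPV * TPR / (PPV + TPR) else NA_real_
  structure(data.frame(scope = scope, TP = TP, FP = FP, FN = FN,
                       TPR = TPR, PPV = PPV, F = F1,
                       TPR_pct = round(100 * TPR, 1),
                       PPV_pct = round(100 * PPV, 1),
                       F_pct = round(100 * F1, 1)),
            class = c("eval_report", "data.frame"))
}

#' Evaluate segmentation of several frames against truth masks
#'
#' @param det_labels list of detection label matrices.
#' @param truth_labels list of matching ground-truth masks.
#' @param frames frame indices for per-frame reporting.
#' @return list with `per_frame` (one eval row per frame) and `pooled`
#'   (counts summed over frames, "movie" scope).
#' @export
evaluate_segmentation <- function(det_labels, truth_labels,
                                  frames = seq_along(det_labels)) {
  stopifnot(length(det_labels) == length(truth_labels))
  rows <- list(); tp <- fp <- fn <- 0L
  for (i in seq_along(det_labels)) {
    m <- match_detections(det_labels[[i]], truth_labels[[i]])
    r <- eval_metrics(m$TP, m$FP, m$FN, scope = "frame")
    r$frame <- frames[i]
    rows[[i]] <- r
    tp <- tp + m$TP; fp <- fp + m$FP; fn <- fn + m$FN
  }
  list(per_frame = do.call(rbind, rows),
       pooled = eval_metrics(tp, fp, fn, scope = "movie"))
}
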