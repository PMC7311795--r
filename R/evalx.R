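# Detection evaluation: IoU matching, precision/recall/F, interpolated
# average precision and the two-IoU report layout.
#
# AP uses all-point interpolation: with P(R0) defined as the maximum
# precision among operating points whose recall is at least R0, AP is the
# exact integral of the piecewise-constant P(R0) over R0 in [0, 1]. mAP is
# the mean over classes (a single "nodule" class here).

# Deterministic ranking of detections: score desc, then x0, y0 asc.
order_detections <- function(dets) {
  order(-dets$score, dets$x0, dets$y0)
}

#' Match detections to ground-truth boxes
#'
#' Greedy one-to-one matching: in descending score order, each detection is
#' matched to the unmatched ground-truth box of highest IoU provided that
#' IoU reaches the threshold (a true positive); otherwise it is a false
#' positive. Unmatched ground-truth boxes are false negatives.
#'
#' @param dets data frame with columns `x0, y0, x1, y1, score`.
#' @param gts matrix (or list) of ground-truth boxes, one `c(x0,y0,x1,y1)`
#'   per row.
#' @param iou_thresh IoU threshold.
#' @return List with `counts` (`c(TP, FP, FN)`) and `tp` (logical flag per
#'   detection, in the ranked order given by `ranking`).
#' @export
match_detections <- function(dets, gts, iou_thresh) {
  if (is.list(gts) && !is.matrix(gts)) gts <- do.call(rbind, gts)
  n_gt <- NROW(gts)
  if (NROW(dets) == 0) {
    return(list(counts = c(TP = 0L, FP = 0L, FN = n_gt),
                tp = logical(0), ranking = integer(0)))
  }
  rk <- order_detections(dets)
  d <- dets[rk, , drop = FALSE]
  used <- logical(n_gt)
  tp <- logical(nrow(d))
  for (i in seq_len(nrow(d))) {
    if (n_gt == 0) break
    box <- as.numeric(d[i, c("x0", "y0", "x1", "y1")])
    ious <- vapply(seq_len(n_gt), function(j) {
      if (used[j]) -1 else box_iou(box, gts[j, ])
    }, numeric(1))
    j <- which.max(ious)
    if (ious[j] >= iou_thresh) {
      tp[i] <- TRUE
      used[j] <- TRUE
    }
  }
  list(counts = c(TP = sum(tp), FP = sum(!tp), FN = sum(!used)),
       tp = tp, ranking = rk)
}

#' Precision, recall and F-score from match counts
#'
#' `P = TP/(TP+FP)`, `R = TP/(TP+FN)`, `F = 2PR/(P+R)` (0 when `P+R = 0`).
#' When both denominators are zero the metrics are undefined and returned
#' as `NA` with a warning.
#'
#' @param counts named vector or list with `TP`, `FP`, `FN`.
#' @return List with `precision`, `recall`, `f_score`.
#' @export
precision_recall_f <- function(counts) {
  TP <- counts[["TP"]]; FP <- counts[["FP"]]; FN <- counts[["FN"]]
  stop_if_not(TP >= 0 && FP >= 0 && FN >= 0, "counts must be non-negative")
  if (TP + FP == 0 && TP + FN == 0) {
    warning("no detections and no ground truth: metrics undefined",
            call. = FALSE)
    return(list(precision = NA_real_, recall = NA_real_, f_score = NA_real_))
  }
  P <- if (TP + FP > 0) TP / (TP + FP) else 0
  R <- if (TP + FN > 0) TP / (TP + FN) else 0
  f <- if (P + R > 0) 2 * P * R / (P + R) else 0
  list(precision = P, recall = R, f_score = f)
}

# Ranked TP flags pooled over a list of per-image detections, matching
# within each image. Returns flags in global score order plus n_gt.
pooled_tp_flags <- function(dets_list, gts_list, iou_thresh) {
  stopifnot(length(dets_list) == length(gts_list))
  rows <- list()
  for (im in seq_along(dets_list)) {
    dets <- dets_list[[im]]
    m <- match_detections(dets, gts_list[[im]], iou_thresh)
    if (length(m$tp) > 0) {
      d <- dets[m$ranking, , drop = FALSE]
      rows[[length(rows) + 1L]] <- data.frame(
        score = d$score, x0 = d$x0, y0 = d$y0, image = im, tp = m$tp)
    }
  }
  n_gt <- sum(vapply(gts_list, NROW, integer(1)))
  if (length(rows) == 0) {
    return(list(tp = logical(0), score = numeric(0), n_gt = n_gt))
  }
  all <- do.call(rbind, rows)
  o <- order(-all$score, all$image, all$x0, all$y0)
  list(tp = all$tp[o], score = all$score[o], n_gt = n_gt)
}

# AP from ranked TP flags via all-point interpolation.
ap_from_flags <- function(tp, n_gt) {
  if (n_gt == 0) stop("ground truth must be non-empty", call. = FALSE)
  if (length(tp) == 0) return(0)
  cum_tp <- cumsum(tp)
  rec <- cum_tp / n_gt
  prec <- cum_tp / seq_along(tp)
  # interpolated precision: max precision at recall >= r
  pint <- rev(cummax(rev(prec)))
  ap <- 0
  prev_r <- 0
  for (i in seq_along(tp)) {
    if (rec[i] > prev_r) {
      ap <- ap + (rec[i] - prev_r) * pint[i]
      prev_r <- rec[i]
    }
  }
  ap
}

#' Interpolated average precision
#'
#' @param dets a detection data frame (single image) or list of data frames
#'   (one per image).
#' @param gts a box matrix/list (single image) or list thereof.
#' @param iou_thresh IoU threshold for matching.
#' @return AP in `[0, 1]`.
#' @export
average_precision <- function(dets, gts, iou_thresh) {
  if (is.data.frame(dets)) {
    dets <- list(dets)
    gts <- list(gts)
  }
  fl <- pooled_tp_flags(dets, gts, iou_thresh)
  ap_from_flags(fl$tp, fl$n_gt)
}

#' Evaluate detections at one or more IoU settings
#'
#' Produces the per-IoU summary used by the condition-grid report: mAP
#' (single class, so mAP = AP), plus recall and F-score at the score
#' threshold that maximizes F over the ranked operating points (the default
#' operating point) and at a fixed threshold of 0.5.
#'
#' @param dets_list list of per-image detection data frames.
#' @param gts_list list of per-image ground-truth box matrices.
#' @param iou_thresholds numeric vector of IoU settings.
#' @return Data frame with one row per IoU setting: `iou, mAP, recall,
#'   f_score, precision, recall_fixed, f_fixed`.
#' @export
evaluate_detections <- function(dets_list, gts_list,
                                iou_thresholds = c(0.3, 0.4)) {
  out <- lapply(iou_thresholds, function(th) {
    fl <- pooled_tp_flags(dets_list, gts_list, th)
    ap <- ap_from_flags(fl$tp, fl$n_gt)
    if (length(fl$tp) == 0) {
      return(data.frame(iou = th, mAP = ap, recall = 0, f_score = 0,
                        precision = 0, recall_fixed = 0, f_fixed = 0))
    }
    cum_tp <- cumsum(fl$tp)
    k <- seq_along(fl$tp)
    P <- cum_tp / k
    R <- cum_tp / fl$n_gt
    f <- ifelse(P + R > 0, 2 * P * R / (P + R), 0)
    best <- which.max(f)
    fixed <- sum(fl$score >= 0.5)
    if (fixed > 0) {
      Pf <- cum_tp[fixed] / fixed; Rf <- cum_tp[fixed] / fl$n_gt
      ff <- if (Pf + Rf > 0) 2 * Pf * Rf / (Pf + Rf) else 0
    } else {
      Rf <- 0; ff <- 0
    }
    data.frame(iou = th, mAP = ap, recall = R[best], f_score = f[best],
               precision = P[best], recall_fixed = Rf, f_fixed = ff)
  })
  do.call(rbind, out)
}
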