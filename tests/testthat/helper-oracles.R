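# Independent oracle implementations used to cross-check the package's
# matching, AP and NMS code, plus small fixture builders. These are written
# from the definitions, not from the package internals.

# Greedy one-to-one matching, enumerated step by step.
oracle_match <- function(dets, gts, iou_thresh) {
  if (is.list(gts) && !is.matrix(gts)) gts <- do.call(rbind, gts)
  ord <- order(-dets$score, dets$x0, dets$y0)
  d <- dets[ord, , drop = FALSE]
  matched_gt <- rep(FALSE, NROW(gts))
  tp <- 0L; fp <- 0L
  flags <- logical(nrow(d))
  for (i in seq_len(nrow(d))) {
    best_j <- 0L; best_iou <- -1
    for (j in seq_len(NROW(gts))) {
      if (matched_gt[j]) next
      v <- box_iou(as.numeric(d[i, c("x0", "y0", "x1", "y1")]), gts[j, ])
      if (v > best_iou) { best_iou <- v; best_j <- j }
    }
    if (best_j > 0L && best_iou >= iou_thresh) {
      matched_gt[best_j] <- TRUE
      tp <- tp + 1L
      flags[i] <- TRUE
    } else {
      fp <- fp + 1L
    }
  }
  list(counts = c(TP = tp, FP = fp, FN = sum(!matched_gt)), tp = flags)
}

# Interpolated AP enumerated directly from its definition: for every
# achieved recall level R0, P(R0) is the maximum precision over all
# operating points with recall >= R0; AP is the exact piecewise-constant
# integral over R0 in [0, 1].
oracle_ap <- function(tp_flags, n_gt) {
  if (length(tp_flags) == 0) return(0)
  P <- numeric(length(tp_flags)); R <- numeric(length(tp_flags))
  tp <- 0L
  for (i in seq_along(tp_flags)) {
    if (tp_flags[i]) tp <- tp + 1L
    P[i] <- tp / i
    R[i] <- tp / n_gt
  }
  levels <- sort(unique(R[R > 0]))
  ap <- 0
  prev <- 0
  for (r0 in levels) {
    pmax_r <- 0
    for (i in seq_along(P)) if (R[i] >= r0) pmax_r <- max(pmax_r, P[i])
    ap <- ap + (r0 - prev) * pmax_r
    prev <- r0
  }
  ap
}

# Un-interpolated (trapezoidal) AP for the interpolation property.
trapezoid_ap <- function(tp_flags, n_gt) {
  if (length(tp_flags) == 0) return(0)
  cum_tp <- cumsum(tp_flags)
  R <- c(0, cum_tp / n_gt)
  P <- c(1, cum_tp / seq_along(tp_flags))
  sum(diff(R) * (head(P, -1) + P[-1]) / 2)
}

# Greedy NMS enumerated from the stated rule.
oracle_nms <- function(dets, iou_thresh) {
  d <- dets[order(-dets$score, dets$x0, dets$y0), , drop = FALSE]
  kept <- list()
  while (nrow(d) > 0) {
    top <- d[1, , drop = FALSE]
    kept[[length(kept) + 1L]] <- top
    if (nrow(d) == 1) break
    keep_rows <- vapply(2:nrow(d), function(j) {
      box_iou(as.numeric(top[c("x0", "y0", "x1", "y1")]),
              as.numeric(d[j, c("x0", "y0", "x1", "y1")])) < iou_thresh
    }, logical(1))
    d <- d[c(FALSE, keep_rows), , drop = FALSE]
  }
  out <- do.call(rbind, kept)
  rownames(out) <- NULL
  out
}

random_detections <- function(n, extent = 60, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x0 <- runif(n, 0, extent - 12)
  y0 <- runif(n, 0, extent - 12)
  w <- runif(n, 4, 12); h <- runif(n, 4, 12)
  data.frame(x0 = x0, y0 = y0, x1 = x0 + w, y1 = y0 + h,
             score = round(runif(n), 3))
}

random_boxes <- function(n, extent = 60) {
  d <- random_detections(n, extent)
  as.matrix(d[, c("x0", "y0", "x1", "y1")])
}

# Small annotated phantom fixture shared across tests.
tiny_annotated <- function(seed = 5, n_nod = 1, size = 96) {
  cfg <- phantom_config(n_train = 1, n_test = 0, height = size, width = size,
                        nodules_per_image = n_nod)
  ds <- render_dataset(cfg, seed = seed)
  it <- ds$items[[1]]
  ann <- annotate_image(it$image, it$nodules, seed = seed + 1)
  list(raw = it$image, nodules = it$nodules, ann = ann)
}
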