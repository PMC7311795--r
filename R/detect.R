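# Desk-scale nodule detector: multi-scale sliding-window patch scoring with
# a crop classifier, score thresholding and greedy NMS. This stands in for
# a full region-proposal detector at a size where the marker-shortcut
# phenomenon can be reproduced on one CPU.

#' Detector configuration
#'
#' @param windows sliding-window side lengths in pixels (ascending).
#' @param stride window stride in pixels.
#' @param margin fractional context margin added around harvested crops
#'   (per side, relative to box size).
#' @param score_threshold minimum positive-class probability for a window
#'   to be emitted as a detection.
#' @param nms_iou IoU threshold of greedy non-maximum suppression.
#' @param neg_per_image background crops harvested per training image.
#' @param pos_jitter extra jittered positive crops harvested per
#'   ground-truth box (windows with IoU at least 0.55 with the box), so the
#'   classifier sees the same imperfect framings the sliding window
#'   produces at test time.
#' @param classifier a [classifier_config()] for the patch classifier.
#' @return A `detector_config` list.
#' @export
detector_config <- function(windows = c(24, 40), stride = 6, margin = 0.25,
                            score_threshold = 0.5, nms_iou = 0.3,
                            neg_per_image = 3L, pos_jitter = 2L,
                            classifier = classifier_config(crop_size = 32)) {
  stop_if_not(all(diff(windows) > 0), "windows must be ascending")
  stop_if_not(nms_iou > 0 && nms_iou < 1, "nms_iou must be in (0, 1)")
  structure(as.list(environment()), class = "detector_config")
}

expand_box <- function(box, margin, height, width) {
  bw <- box[3] - box[1]; bh <- box[4] - box[2]
  c(max(0, box[1] - margin * bw), max(0, box[2] - margin * bh),
    min(width, box[3] + margin * bw), min(height, box[4] + margin * bh))
}

# Extract one resized crop (vector) for a box with context margin.
crop_for_box <- function(image, box, margin, crop_size) {
  eb <- expand_box(box, margin, nrow(image), ncol(image))
  .cpp_crop_resize(image, matrix(eb, nrow = 1), crop_size, crop_size)[1, ]
}

#' Harvest training crops from annotated images
#'
#' Positives are the ground-truth boxes (with context margin); negatives
#' are random windows whose IoU with every ground-truth box is exactly 0.
#'
#' @param images list of image matrices.
#' @param gts list of ground-truth box matrices (one row per nodule).
#' @param config a [detector_config()].
#' @param seed integer seed.
#' @return List with `x` (crop matrix), `y` (labels, 1 = nodule) and
#'   `manifest` (data frame of image index, box, label).
#' @export
harvest_crops <- function(images, gts, config = detector_config(),
                          seed = 1L) {
  cs <- config$classifier$crop_size
  rows <- list(); xs <- list()
  all_sizes <- do.call(rbind, lapply(gts, function(g) {
    if (NROW(g) == 0) return(NULL)
    cbind(g[, 3] - g[, 1], g[, 4] - g[, 2])
  }))
  stop_if_not(NROW(all_sizes) > 0, "no positive boxes in the dataset")
  size_rng <- range(all_sizes)
  seeds <- child_seeds(seed, length(images))
  for (im in seq_along(images)) {
    img <- images[[im]]
    h <- nrow(img); w <- ncol(img)
    g <- gts[[im]]
    for (j in seq_len(NROW(g))) {
      xs[[length(xs) + 1L]] <- crop_for_box(img, g[j, ], config$margin, cs)
      rows[[length(rows) + 1L]] <- data.frame(
        image = im, x0 = g[j, 1], y0 = g[j, 2], x1 = g[j, 3], y1 = g[j, 4],
        label = 1L)
    }
    with_seed(seeds[im] + 1L, {
      for (j in seq_len(NROW(g))) {
        placed <- 0L
        for (attempt in seq_len(50L * config$pos_jitter)) {
          if (placed >= config$pos_jitter) break
          bw <- g[j, 3] - g[j, 1]; bh <- g[j, 4] - g[j, 2]
          sc <- runif(1, 0.92, 1.1)
          dx <- runif(1, -0.08, 0.08) * bw
          dy <- runif(1, -0.08, 0.08) * bh
          cx <- (g[j, 1] + g[j, 3]) / 2 + dx
          cy <- (g[j, 2] + g[j, 4]) / 2 + dy
          box <- c(cx - sc * bw / 2, cy - sc * bh / 2,
                   cx + sc * bw / 2, cy + sc * bh / 2)
          box <- c(pmax(box[1:2], 0), pmin(box[3], w), pmin(box[4], h))
          if (box[3] - box[1] < 4 || box[4] - box[2] < 4) next
          if (box_iou(box, g[j, ]) < 0.65) next
          xs[[length(xs) + 1L]] <- crop_for_box(img, box, config$margin, cs)
          rows[[length(rows) + 1L]] <- data.frame(
            image = im, x0 = box[1], y0 = box[2], x1 = box[3], y1 = box[4],
            label = 1L)
          placed <- placed + 1L
        }
      }
    })
    with_seed(seeds[im], {
      placed <- 0L
      for (attempt in seq_len(200L * config$neg_per_image)) {
        if (placed >= config$neg_per_image) break
        s <- runif(2, size_rng[1], size_rng[2])
        if (s[1] > w - 2 || s[2] > h - 2) next
        x0 <- runif(1, 0, w - s[1]); y0 <- runif(1, 0, h - s[2])
        box <- c(x0, y0, x0 + s[1], y0 + s[2])
        ok <- all(vapply(seq_len(NROW(g)), function(j) {
          box_iou(box, g[j, ]) == 0
        }, logical(1)))
        if (!ok) next
        xs[[length(xs) + 1L]] <- crop_for_box(img, box, config$margin, cs)
        rows[[length(rows) + 1L]] <- data.frame(
          image = im, x0 = box[1], y0 = box[2], x1 = box[3], y1 = box[4],
          label = 0L)
        placed <- placed + 1L
      }
    })
  }
  manifest <- do.call(rbind, rows)
  list(x = do.call(rbind, xs), y = manifest$label, manifest = manifest)
}

#' Train the sliding-window detector
#'
#' @param images list of training image matrices.
#' @param gts list of ground-truth box matrices.
#' @param config a [detector_config()].
#' @param seed integer seed.
#' @return A `sono_detector` holding the patch classifier and window
#'   settings.
#' @export
train_detector <- function(images, gts, config = detector_config(),
                           seed = 1L) {
  seeds <- child_seeds(seed, 2L)
  hv <- harvest_crops(images, gts, config, seeds[1])
  stop_if_not(any(hv$y == 1), "no positive crops harvested")
  clf <- train_classifier(hv$x, hv$y, config$classifier, seeds[2])
  structure(list(classifier = clf, config = config,
                 harvest_manifest = hv$manifest),
            class = "sono_detector")
}

#' Greedy non-maximum suppression
#'
#' Repeatedly keeps the highest-score detection (ties broken by smaller
#' `x0`, then smaller `y0`) and discards all detections with IoU at or
#' above the threshold against it.
#'
#' @param dets detection data frame (`x0, y0, x1, y1, score`).
#' @param iou_thresh suppression threshold in `(0, 1)`.
#' @return The surviving detections, sorted by descending score.
#' @export
nms <- function(dets, iou_thresh) {
  if (NROW(dets) <= 1) return(dets)
  d <- dets[order_detections(dets), , drop = FALSE]
  keep <- logical(nrow(d))
  alive <- rep(TRUE, nrow(d))
  for (i in seq_len(nrow(d))) {
    if (!alive[i]) next
    keep[i] <- TRUE
    bi <- as.numeric(d[i, c("x0", "y0", "x1", "y1")])
    for (j in seq_len(nrow(d))) {
      if (j == i || !alive[j]) next
      if (box_iou(bi, as.numeric(d[j, c("x0", "y0", "x1", "y1")])) >=
          iou_thresh) {
        alive[j] <- FALSE
      }
    }
    alive[i] <- FALSE
  }
  out <- d[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# All sliding-window boxes for an image at the configured scales.
sliding_boxes <- function(height, width, windows, stride) {
  rows <- list()
  for (win in windows) {
    if (win > height || win > width) next
    xs <- seq(0, width - win, by = stride)
    ys <- seq(0, height - win, by = stride)
    if (xs[length(xs)] < width - win) xs <- c(xs, width - win)
    if (ys[length(ys)] < height - win) ys <- c(ys, height - win)
    gr <- expand.grid(x0 = xs, y0 = ys)
    rows[[length(rows) + 1L]] <- cbind(gr$x0, gr$y0, gr$x0 + win,
                                       gr$y0 + win)
  }
  do.call(rbind, rows)
}

#' Run the detector on an image
#'
#' Multi-scale sliding-window scoring with the patch classifier, score
#' thresholding, then greedy NMS. Deterministic given model and image.
#'
#' @param image matrix in `[0, 1]`.
#' @param model a `sono_detector`.
#' @return Detection data frame (`x0, y0, x1, y1, score`), sorted by
#'   descending score; possibly empty.
#' @export
detect <- function(image, model) {
  cfg <- model$config
  stop_if_not(min(cfg$windows) <= min(dim(image)),
              "image smaller than the smallest window")
  boxes <- sliding_boxes(nrow(image), ncol(image), cfg$windows, cfg$stride)
  cs <- cfg$classifier$crop_size
  eb <- t(apply(boxes, 1, expand_box, margin = cfg$margin,
                height = nrow(image), width = ncol(image)))
  crops <- .cpp_crop_resize(image, eb, cs, cs)
  probs <- predict_classifier(model$classifier, crops, mode = "mean")
  score <- probs[, 2]
  keep <- score >= cfg$score_threshold
  dets <- data.frame(x0 = boxes[keep, 1], y0 = boxes[keep, 2],
                     x1 = boxes[keep, 3], y1 = boxes[keep, 4],
                     score = score[keep])
  if (nrow(dets) == 0) return(dets)
  nms(dets, cfg$nms_iou)
}
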