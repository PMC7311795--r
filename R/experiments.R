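# Experiment orchestration: the training-condition grid (marker-layered,
# marker-removed by oracle mask, marker-removed by automatic localization,
# marker-mixup) evaluated on marker-layered and marker-free test sets, and
# the six-case crop-classification grid comparing the baseline and VIB
# models. These runners are the package's phenomenon-level acceptance
# surface: they reproduce, at desk scale, the collapse of a marker-trained
# detector on marker-free data and its suppression by inpainting and VIB.

#' Build the training/testing condition grid
#'
#' From one phantom dataset, derives:
#' \describe{
#'   \item{A0}{marker-layered training images (caliper groups burned at
#'     every nodule).}
#'   \item{A1}{A0 with markers removed by texture inpainting under the
#'     oracle mask (stand-in for careful manual removal).}
#'   \item{A2}{A0 with markers removed under an automatically located mask
#'     (template matching).}
#'   \item{A3}{A0 after random marker mixup (keep 1 of 2, or 1--3 of 4,
#'     markers; scatter replacements away from nodules).}
#'   \item{B1}{marker-layered test images.}
#'   \item{B2}{the raw, marker-free test images.}
#' }
#' All six variants share the same underlying phantoms and ground truth.
#'
#' @param dataset a `sono_phantom_dataset` with train and test items.
#' @param seed integer seed.
#' @param glyph the [marker_glyph()] to burn.
#' @param params [texsynth_params()] for the inpainting conditions.
#' @param mask_dilation dilation applied to the oracle mask before
#'   inpainting (covers anti-aliasing halos).
#' @param locate_threshold correlation threshold of the marker localizer.
#' @return A `sono_condition_grid` list with per-condition image lists,
#'   the A0/B1 annotations, and shared ground-truth box lists.
#' @export
build_condition_grid <- function(dataset, seed = 1L,
                                 glyph = marker_glyph(),
                                 params = texsynth_params(),
                                 mask_dilation = 1,
                                 locate_threshold = 0.8) {
  tr <- which(dataset$split == "train")
  te <- which(dataset$split == "test")
  stop_if_not(length(tr) > 0 && length(te) > 0,
              "dataset must have train and test items")
  seeds <- child_seeds(seed, 4L)
  an_seeds <- child_seeds(seeds[1], length(tr) + length(te))
  ip_seeds <- child_seeds(seeds[2], 2L * length(tr))
  mx_seeds <- child_seeds(seeds[3], length(tr))

  boxes_of <- function(item) {
    b <- do.call(rbind, lapply(item$nodules, `[[`, "bbox"))
    matrix(b, ncol = 4)
  }
  train_gt <- lapply(dataset$items[tr], boxes_of)
  test_gt <- lapply(dataset$items[te], boxes_of)

  A0 <- vector("list", length(tr))
  A1 <- vector("list", length(tr))
  A2 <- vector("list", length(tr))
  A3 <- vector("list", length(tr))
  for (i in seq_along(tr)) {
    it <- dataset$items[[tr[i]]]
    ann <- annotate_image(it$image, it$nodules, glyph, an_seeds[i])
    A0[[i]] <- ann
    oracle <- .cpp_dilate(ann$mask, as.integer(mask_dilation))
    A1[[i]] <- inpaint_texture(ann$image, oracle, params,
                               ip_seeds[2 * i - 1])$image
    loc <- locate_markers(ann$image, list(glyph), locate_threshold)
    A2[[i]] <- if (sum(loc) > 0) {
      inpaint_texture(ann$image, loc, params, ip_seeds[2 * i])$image
    } else ann$image
    A3[[i]] <- mixup_markers(ann, glyph, mx_seeds[i], params)$image
  }
  B1 <- vector("list", length(te))
  for (i in seq_along(te)) {
    it <- dataset$items[[te[i]]]
    B1[[i]] <- annotate_image(it$image, it$nodules, glyph,
                              an_seeds[length(tr) + i])
  }
  structure(list(
    A0 = A0, A1 = A1, A2 = A2, A3 = A3,
    B1 = B1, B2 = lapply(dataset$items[te], `[[`, "image"),
    train_gt = train_gt, test_gt = test_gt,
    glyph = glyph, seed = as.integer(seed)
  ), class = "sono_condition_grid")
}

grid_train_images <- function(grid, condition) {
  switch(condition,
         A0 = lapply(grid$A0, `[[`, "image"),
         A1 = grid$A1, A2 = grid$A2, A3 = grid$A3,
         stop("unknown training condition ", condition))
}

one_sided_sign_test <- function(successes, n) {
  if (n == 0) return(NA_real_)
  stats::binom.test(successes, n, p = 0.5, alternative = "greater")$p.value
}

#' Run the detection condition study
#'
#' Trains one detector per training condition (A0--A3) per seed, evaluates
#' each on the marker-layered (B1) and marker-free (B2) test sets at the
#' configured IoU settings, and computes the marker-shortcut ordering
#' statistics: the A0 generalization gap `mAP(B1) - mAP(B2)`, the A2 gap,
#' the per-seed comparison `mAP(B2|A2) > mAP(B2|A0)`, and whether A3 falls
#' between A0 and A2 on marker-free mAP.
#'
#' @param grid a `sono_condition_grid`.
#' @param config a [detector_config()].
#' @param seeds integer vector of at least 3 training seeds.
#' @param iou_thresholds IoU settings for evaluation.
#' @param conditions training conditions to run.
#' @return A `sono_run_report`: `metrics` (per seed/condition/test/IoU data
#'   frame, metrics in percent), `summary` (seed means), `ordering` (gap
#'   and sign-test statistics at the first IoU setting), `seeds`.
#' @export
run_detection_study <- function(grid, config = detector_config(),
                                seeds = c(1L, 2L, 3L),
                                iou_thresholds = c(0.3, 0.4),
                                conditions = c("A0", "A1", "A2", "A3")) {
  stop_if_not(length(seeds) >= 3, "at least 3 seeds required")
  B1 <- lapply(grid$B1, `[[`, "image")
  B2 <- grid$B2
  rows <- list()
  for (s in seeds) {
    for (cond in conditions) {
      det <- train_detector(grid_train_images(grid, cond), grid$train_gt,
                            config, seed = s)
      for (test in c("B1", "B2")) {
        imgs <- if (test == "B1") B1 else B2
        dets <- lapply(imgs, detect, model = det)
        ev <- evaluate_detections(dets, grid$test_gt, iou_thresholds)
        for (k in seq_len(nrow(ev))) {
          rows[[length(rows) + 1L]] <- data.frame(
            seed = s, train = cond, test = test, iou = ev$iou[k],
            mAP = 100 * ev$mAP[k], recall = 100 * ev$recall[k],
            f_score = 100 * ev$f_score[k])
        }
      }
    }
  }
  metrics <- do.call(rbind, rows)
  summary <- stats::aggregate(cbind(mAP, recall, f_score) ~ train + test + iou,
                              data = metrics, FUN = mean)
  ordering <- detection_ordering(metrics, iou_thresholds[1])
  structure(list(metrics = metrics, summary = summary, ordering = ordering,
                 seeds = seeds, config = config),
            class = "sono_run_report")
}

# Gap statistics at one IoU setting (percent scale).
detection_ordering <- function(metrics, iou) {
  m <- metrics[metrics$iou == iou, ]
  val <- function(cond, test) {
    x <- m[m$train == cond & m$test == test, ]
    x$mAP[order(x$seed)]
  }
  seeds <- sort(unique(m$seed))
  n <- length(seeds)
  have <- function(cond) any(m$train == cond)
  out <- list(iou = iou, n_seeds = n)
  if (have("A0")) {
    gap0 <- val("A0", "B1") - val("A0", "B2")
    out$A0_gap_per_seed <- gap0
    out$A0_gap_mean <- mean(gap0)
    out$A0_gap_all_positive <- all(gap0 > 0)
    out$A0_gap_sign_p <- one_sided_sign_test(sum(gap0 > 0), n)
  }
  if (have("A2")) {
    gap2 <- val("A2", "B1") - val("A2", "B2")
    out$A2_gap_per_seed <- gap2
    out$A2_gap_mean <- mean(gap2)
  }
  if (have("A0") && have("A2")) {
    d <- val("A2", "B2") - val("A0", "B2")
    out$A2_beats_A0_on_B2_per_seed <- d
    out$A2_beats_A0_on_B2_all <- all(d > 0)
  }
  if (have("A0") && have("A2") && have("A3")) {
    m0 <- mean(val("A0", "B2")); m2 <- mean(val("A2", "B2"))
    m3 <- mean(val("A3", "B2"))
    out$B2_mAP_means <- c(A0 = m0, A2 = m2, A3 = m3)
    out$A3_between <- (m3 > m0) && (m3 < m2)
  }
  out
}

#' Configuration of the crop-classification study
#'
#' The crop benchmark mirrors the clinical design: training positives are
#' marker-layered nodule crops, training negatives are nodule-free crops
#' with pseudo caliper groups added; the test set is manipulated into the
#' six evaluation cases.
#'
#' @param n_train,n_test number of crops per class in train/test (the
#'   near-balanced clinical ratio, magnitude scaled).
#' @param phantom a [phantom_config()] for the underlying images (one
#'   nodule per image so each positive crop has exactly one caliper group).
#' @param baseline,vib [classifier_config()]s for the two models.
#' @param glyph the [marker_glyph()].
#' @param margin crop context margin.
#' @param n_neg_candidates pseudo-rect draws per negative; the one with the
#'   darkest centre is kept so that negatives resemble proposal-stage
#'   look-alike regions.
#' @param lookalike_frac fraction of negative crops that receive a centred
#'   nodule look-alike (a soft hypoechoic ellipse whose parameters overlap
#'   the nodule distribution). Look-alikes make tissue alone insufficient
#'   for those crops, as in real proposal-stage negatives.
#' @param lookalike_contrast,lookalike_ratio contrast and aspect-ratio
#'   ranges of the look-alikes.
#' @return A `classification_study_config` list.
#' @export
classification_study_config <- function(
    n_train = 200L, n_test = 200L,
    phantom = phantom_config(n_train = 200L, n_test = 200L,
                             nodules_per_image = 1L),
    baseline = classifier_config(use_vib = FALSE, crop_size = 32),
    vib = classifier_config(use_vib = TRUE, crop_size = 32, beta = 0.05),
    glyph = marker_glyph(), margin = 0.25, n_neg_candidates = 8L,
    lookalike_frac = 0.5, lookalike_contrast = c(0.22, 0.38),
    lookalike_ratio = c(0.5, 0.85)) {
  structure(as.list(environment()), class = "classification_study_config")
}

# Negative crops emulate "suspicious regions": among several admissible
# pseudo-rect draws, the one whose centre is darkest relative to its border
# ring is annotated, so negatives resemble the centred hypoechoic
# look-alikes a proposal stage would emit rather than plain speckle.
darkest_pseudo_group <- function(image, nodules, max_dims, seed,
                                 n_cand = 8L) {
  seeds <- child_seeds(seed, n_cand)
  best <- NULL; best_score <- Inf
  for (k in seq_len(n_cand)) {
    g <- generate_pseudo_group(image, nodules, max_dims, seeds[k])
    r <- g$rect
    sub <- image[(r[2] + 1):r[4], (r[1] + 1):r[3], drop = FALSE]
    qh <- max(1L, nrow(sub) %/% 4L); qw <- max(1L, ncol(sub) %/% 4L)
    core <- sub[(qh + 1):(nrow(sub) - qh), (qw + 1):(ncol(sub) - qw),
                drop = FALSE]
    score <- mean(core) - 0.5 * mean(sub) # centre dark, ring bright
    if (score < best_score) { best <- g; best_score <- score }
  }
  best
}

# Build the crop sets for one seed: returns train x/y and the test crop
# variants (pos_layered, pos_free, neg_pseudo, neg_asis).
build_crop_benchmark <- function(cfg, seed) {
  ph <- cfg$phantom
  ph$n_train <- cfg$n_train
  ph$n_test <- cfg$n_test
  ds <- render_dataset(ph, seed)
  seeds <- child_seeds(seed + 1L, length(ds$items) * 3L)
  cs <- cfg$baseline$crop_size
  max_dims <- c(0, 0)
  for (it in ds$items) {
    for (nd in it$nodules) {
      max_dims <- pmax(max_dims, c(nd$bbox[3] - nd$bbox[1],
                                   nd$bbox[4] - nd$bbox[2]))
    }
  }
  crop_one <- function(image, box) {
    crop_for_box(image, box, cfg$margin, cs)
  }
  make <- function(idx) {
    pos_layered <- list(); pos_free <- list()
    neg_pseudo <- list(); neg_asis <- list()
    for (k in seq_along(idx)) {
      it <- ds$items[[idx[k]]]
      nd <- it$nodules[[1]]
      s3 <- seeds[3 * (idx[k] - 1) + 1:3]
      gs <- with_seed(s3[1], sample(c(2L, 4L), 1))
      ann <- annotate_nodule(it$image, nd, cfg$glyph, gs, s3[1])
      pos_layered[[k]] <- crop_one(ann$image, nd$bbox)
      pos_free[[k]] <- crop_one(it$image, nd$bbox)
      pg <- darkest_pseudo_group(it$image, it$nodules, max_dims, s3[2],
                                 n_cand = cfg$n_neg_candidates)
      # A balanced fraction of negatives carries a centred nodule
      # look-alike, present identically in the marked and as-is variants.
      base <- with_seed(s3[3], {
        if (runif(1) < cfg$lookalike_frac) {
          r <- pg$rect
          ctr <- c((r[2] + r[4]) / 2, (r[1] + r[3]) / 2)
          a <- 0.42 * max(r[3] - r[1], r[4] - r[2])
          bax <- max(2.5, a * runif(1, cfg$lookalike_ratio[1],
                                    cfg$lookalike_ratio[2]))
          soft_ellipse_darken(it$image, ctr, c(a, bax), runif(1, 0, pi),
                              runif(1, cfg$lookalike_contrast[1],
                                    cfg$lookalike_contrast[2]),
                              feather = 4)
        } else it$image
      })
      pimg <- base
      for (j in seq_len(nrow(pg$points))) {
        b <- burn_glyph(pimg, pg$points[j, ], cfg$glyph, warn_clip = FALSE)
        pimg <- b$image
      }
      neg_pseudo[[k]] <- crop_one(pimg, pg$rect)
      neg_asis[[k]] <- crop_one(base, pg$rect)
    }
    list(pos_layered = do.call(rbind, pos_layered),
         pos_free = do.call(rbind, pos_free),
         neg_pseudo = do.call(rbind, neg_pseudo),
         neg_asis = do.call(rbind, neg_asis))
  }
  train <- make(which(ds$split == "train"))
  test <- make(which(ds$split == "test"))
  list(
    x_train = rbind(train$pos_layered, train$neg_pseudo),
    y_train = rep(c(1L, 0L), c(nrow(train$pos_layered),
                               nrow(train$neg_pseudo))),
    test = test
  )
}

case_accuracy <- function(model, pos, neg) {
  x <- rbind(pos, neg)
  y <- rep(c(1L, 0L), c(nrow(pos), nrow(neg)))
  p <- predict_classifier(model, x, mode = "mean")
  mean((p[, 2] >= 0.5) == (y == 1L))
}

#' Run the six-case crop-classification study
#'
#' Per seed: builds the crop benchmark, trains the baseline and the VIB
#' model on identical marker-layered-positive / pseudo-marker-negative
#' training crops, and evaluates the six test cases — for each model:
#' (pseudo-marker negatives, marker-layered positives), (as-is negatives,
#' marker-layered positives), (as-is negatives, marker-free positives).
#'
#' @param config a [classification_study_config()].
#' @param seeds integer vector of at least 5 seeds.
#' @return A `sono_run_report` with per-case accuracies (percent), seed
#'   summaries, and the ordering statistics (baseline case1 > case2 >
#'   case3 sign tests; VIB stability comparison).
#' @export
run_classification_study <- function(config = classification_study_config(),
                                     seeds = 1:5) {
  stop_if_not(length(seeds) >= 5, "at least 5 seeds required")
  case_defs <- data.frame(
    case = 1:6,
    model = rep(c("baseline", "vib"), each = 3),
    negative = rep(c("pseudo", "asis", "asis"), 2),
    positive = rep(c("layered", "layered", "free"), 2)
  )
  rows <- list()
  for (s in seeds) {
    bench <- build_crop_benchmark(config, s)
    models <- list(
      baseline = train_classifier(bench$x_train, bench$y_train,
                                  config$baseline, seed = s),
      vib = train_classifier(bench$x_train, bench$y_train,
                             config$vib, seed = s)
    )
    for (k in seq_len(nrow(case_defs))) {
      cd <- case_defs[k, ]
      neg <- if (cd$negative == "pseudo") bench$test$neg_pseudo else
        bench$test$neg_asis
      pos <- if (cd$positive == "layered") bench$test$pos_layered else
        bench$test$pos_free
      acc <- case_accuracy(models[[cd$model]], pos, neg)
      rows[[length(rows) + 1L]] <- data.frame(
        seed = s, case = cd$case, model = cd$model,
        negative = cd$negative, positive = cd$positive,
        accuracy = 100 * acc)
    }
  }
  metrics <- do.call(rbind, rows)
  summary <- stats::aggregate(accuracy ~ case + model + negative + positive,
                              data = metrics, FUN = function(v) {
                                c(mean = mean(v), sd = stats::sd(v))
                              })
  ordering <- classification_ordering(metrics)
  structure(list(metrics = metrics, summary = summary, ordering = ordering,
                 seeds = seeds, config = config),
            class = "sono_run_report")
}

classification_ordering <- function(metrics) {
  acc <- function(case) {
    x <- metrics[metrics$case == case, ]
    x$accuracy[order(x$seed)]
  }
  n <- length(unique(metrics$seed))
  c12 <- sum(acc(1) > acc(2))
  c23 <- sum(acc(2) > acc(3))
  base_drop <- acc(1) - acc(3)
  vib_drop <- acc(4) - acc(6)
  list(
    n_seeds = n,
    case1_gt_case2 = c12, case1_gt_case2_p = one_sided_sign_test(c12, n),
    case2_gt_case3 = c23, case2_gt_case3_p = one_sided_sign_test(c23, n),
    baseline_drop_per_seed = base_drop,
    vib_drop_per_seed = vib_drop,
    baseline_drop_mean = mean(base_drop),
    vib_drop_mean = mean(vib_drop),
    vib_more_stable = abs(mean(vib_drop)) < abs(mean(base_drop)),
    vib_drop_smaller_per_seed = sum(vib_drop < base_drop),
    vib_drop_smaller_p = one_sided_sign_test(sum(vib_drop < base_drop), n)
  )
}

#' @export
print.sono_run_report <- function(x, ...) {
  cat("<sono_run_report>\n")
  print(x$summary)
  invisible(x)
}
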