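# Detection metrics: IoU, greedy matching, precision/recall/F and
# interpolated average precision, each checked against independent
# enumeration oracles.

test_that("box IoU matches direct area arithmetic", {
  expect_equal(box_iou(c(0, 0, 10, 10), c(0, 0, 10, 10)), 1.0)
  expect_equal(box_iou(c(0, 0, 10, 10), c(20, 20, 30, 30)), 0.0)
  expect_equal(box_iou(c(0, 0, 10, 10), c(5, 0, 15, 10)), 1 / 3)
  expect_error(box_iou(c(0, 0, 0, 10), c(0, 0, 10, 10)), "degenerate")
})

test_that("greedy matching handles the perfect and double-count cases", {
  gt <- matrix(c(10, 10, 30, 30), 1)
  one <- data.frame(x0 = 10, y0 = 10, x1 = 30, y1 = 30, score = 0.9)
  m <- match_detections(one, gt, 0.3)
  expect_equal(unname(m$counts), c(1L, 0L, 0L))

  two <- rbind(one, data.frame(x0 = 11, y0 = 11, x1 = 31, y1 = 31,
                               score = 0.8))
  m2 <- match_detections(two, gt, 0.3)
  expect_equal(unname(m2$counts), c(1L, 1L, 0L))

  none <- match_detections(one[0, ], gt, 0.3)
  expect_equal(unname(none$counts), c(0L, 0L, 1L))
})

test_that("matching agrees with brute-force enumeration on random fixtures", {
  set.seed(401)
  for (rep in 1:40) {
    dets <- random_detections(sample(1:6, 1))
    gts <- random_boxes(sample(1:4, 1))
    th <- sample(c(0.3, 0.4, 0.5), 1)
    got <- match_detections(dets, gts, th)
    want <- oracle_match(dets, gts, th)
    expect_equal(got$counts, want$counts)
    expect_equal(got$tp, want$tp)
  }
})

test_that("precision, recall and F follow their defining ratios", {
  m <- precision_recall_f(c(TP = 2, FP = 1, FN = 1))
  expect_equal(m$precision, 2 / 3)
  expect_equal(m$recall, 2 / 3)
  expect_equal(m$f_score, 2 / 3)

  perfect <- precision_recall_f(c(TP = 5, FP = 0, FN = 0))
  expect_equal(unlist(perfect), c(precision = 1, recall = 1, f_score = 1))

  miss <- precision_recall_f(c(TP = 0, FP = 3, FN = 2))
  expect_equal(unlist(miss), c(precision = 0, recall = 0, f_score = 0))

  expect_warning(und <- precision_recall_f(c(TP = 0, FP = 0, FN = 0)),
                 "undefined")
  expect_true(all(is.na(unlist(und))))
})

test_that("hand-computable AP cases are exact", {
  gt <- matrix(c(10, 10, 30, 30), 1)
  hit <- data.frame(x0 = 10, y0 = 10, x1 = 30, y1 = 30, score = 0.9)
  expect_equal(average_precision(hit, gt, 0.3), 1.0)

  wrong <- data.frame(x0 = 50, y0 = 50, x1 = 58, y1 = 58, score = 0.9)
  expect_equal(average_precision(wrong, gt, 0.3), 0.0)

  # 2 ground truths; a true positive at score 0.9 and a false positive at
  # 0.8: interpolated precision is 1 up to recall 0.5 and 0 beyond.
  gt2 <- rbind(c(10, 10, 30, 30), c(50, 50, 70, 70))
  dets <- data.frame(
    x0 = c(10, 80), y0 = c(10, 80), x1 = c(30, 90), y1 = c(30, 90),
    score = c(0.9, 0.8))
  expect_equal(average_precision(dets, gt2, 0.3), 0.5)

  expect_error(average_precision(hit, matrix(numeric(0), 0, 4), 0.3),
               "non-empty")
})

test_that("AP equals the enumeration oracle on random small fixtures", {
  set.seed(402)
  for (rep in 1:200) {
    n_det <- sample(0:6, 1)
    dets <- random_detections(n_det)
    gts <- random_boxes(sample(1:4, 1))
    got <- average_precision(dets, gts, 0.3)
    fl <- sonomark:::pooled_tp_flags(list(dets), list(gts), 0.3)
    expect_equal(got, oracle_ap(fl$tp, fl$n_gt), tolerance = 1e-12)
    expect_gte(got, 0); expect_lte(got, 1)
  }
})

test_that("AP is invariant to monotone score transforms and dominates the trapezoid", {
  set.seed(403)
  for (rep in 1:25) {
    dets <- random_detections(sample(2:6, 1))
    gts <- random_boxes(sample(1:3, 1))
    base <- average_precision(dets, gts, 0.3)
    warped <- dets
    warped$score <- plogis(3 * dets$score - 1) # strictly increasing
    expect_equal(average_precision(warped, gts, 0.3), base, tolerance = 1e-12)
    fl <- sonomark:::pooled_tp_flags(list(dets), list(gts), 0.3)
    expect_gte(base + 1e-12, trapezoid_ap(fl$tp, fl$n_gt))
  }
})

test_that("multi-image evaluation pools detections and reports per-IoU rows", {
  set.seed(404)
  gts <- replicate(4, random_boxes(2), simplify = FALSE)
  dets <- lapply(gts, function(g) {
    jit <- data.frame(x0 = g[, 1] + 1, y0 = g[, 2] + 1, x1 = g[, 3] + 1,
                      y1 = g[, 4] + 1, score = runif(nrow(g), 0.6, 1))
    extra <- random_detections(1)
    rbind(jit, extra)
  })
  ev <- evaluate_detections(dets, gts, c(0.3, 0.4))
  expect_equal(nrow(ev), 2)
  expect_equal(ev$iou, c(0.3, 0.4))
  expect_true(all(ev$mAP >= 0 & ev$mAP <= 1))
  # F consistency at the reported operating point: F = 2PR/(P+R)
  f_check <- 2 * ev$precision * ev$recall / (ev$precision + ev$recall)
  expect_equal(ev$f_score, f_check, tolerance = 1e-12)
  # stricter IoU can never help
  expect_lte(ev$mAP[2], ev$mAP[1] + 1e-12)
})
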