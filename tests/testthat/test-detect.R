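# Sliding-window detector: NMS against its enumeration oracle, crop
# harvesting contracts, thresholding and determinism.

test_that("NMS matches brute-force enumeration and is idempotent", {
  single <- data.frame(x0 = 1, y0 = 1, x1 = 10, y1 = 10, score = 0.7)
  expect_equal(nms(single, 0.5), single)

  dup <- data.frame(x0 = c(1, 1), y0 = c(1, 1), x1 = c(10, 10),
                    y1 = c(10, 10), score = c(0.9, 0.8))
  kept <- nms(dup, 0.5)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$score, 0.9)

  set.seed(71)
  for (rep in 1:30) {
    d <- random_detections(5)
    th <- sample(c(0.2, 0.4, 0.6), 1)
    got <- nms(d, th)
    want <- oracle_nms(d, th)
    expect_equal(got, want)
    expect_equal(nms(got, th), got)
    # survivors are pairwise below the suppression threshold
    if (nrow(got) > 1) {
      for (i in 1:(nrow(got) - 1)) {
        for (j in (i + 1):nrow(got)) {
          expect_lt(box_iou(as.numeric(got[i, 1:4]),
                            as.numeric(got[j, 1:4])), th)
        }
      }
    }
  }
})

make_mini_dataset <- function(n_train = 8, n_test = 4, seed = 81) {
  cfg <- phantom_config(n_train = n_train, n_test = n_test,
                        height = 96, width = 96)
  ds <- render_dataset(cfg, seed = seed)
  imgs <- lapply(ds$items, `[[`, "image")
  gts <- lapply(ds$items, function(it) {
    matrix(do.call(rbind, lapply(it$nodules, `[[`, "bbox")), ncol = 4)
  })
  list(imgs = imgs, gts = gts, split = ds$split)
}

test_that("harvested negatives avoid every ground-truth box", {
  mini <- make_mini_dataset()
  cfg <- detector_config(classifier = classifier_config(crop_size = 16, encoder = "mlp"))
  hv <- harvest_crops(mini$imgs, mini$gts, cfg, seed = 2)
  expect_true(all(hv$y %in% c(0L, 1L)))
  neg <- hv$manifest[hv$manifest$label == 0L, ]
  for (k in seq_len(nrow(neg))) {
    g <- mini$gts[[neg$image[k]]]
    for (j in seq_len(nrow(g))) {
      expect_equal(box_iou(as.numeric(neg[k, c("x0", "y0", "x1", "y1")]),
                           g[j, ]), 0)
    }
  }
  # per-image negative quota honoured
  expect_true(all(table(neg$image) <= cfg$neg_per_image))
  hv2 <- harvest_crops(mini$imgs, mini$gts, cfg, seed = 2)
  expect_identical(hv$manifest, hv2$manifest)
})

test_that("an untrained scorer with threshold 1 yields no detections", {
  mini <- make_mini_dataset(n_train = 4, n_test = 0)
  cfg <- detector_config(
    score_threshold = 1.0,
    classifier = classifier_config(crop_size = 16, epochs = 0, encoder = "mlp"))
  det <- train_detector(mini$imgs, mini$gts, cfg, seed = 1)
  out <- detect(matrix(0.5, 96, 96), det)
  expect_equal(nrow(out), 0)
})

test_that("detection is deterministic and monotone in the score threshold", {
  mini <- make_mini_dataset(n_train = 10, n_test = 3, seed = 85)
  tr <- mini$split == "train"
  cfg <- detector_config(
    classifier = classifier_config(crop_size = 16, epochs = 15, encoder = "mlp"))
  det <- train_detector(mini$imgs[tr], mini$gts[tr], cfg, seed = 3)
  det2 <- train_detector(mini$imgs[tr], mini$gts[tr], cfg, seed = 3)
  expect_identical(det$classifier$params, det2$classifier$params)

  img <- mini$imgs[[which(!tr)[1]]]
  d1 <- detect(img, det)
  expect_identical(d1, detect(img, det))
  if (nrow(d1) > 1) expect_true(all(diff(d1$score) <= 0))

  higher <- det
  higher$config$score_threshold <- 0.9
  d2 <- detect(img, higher)
  expect_lte(nrow(d2), nrow(d1))

  small <- det
  small$config$windows <- c(200)
  expect_error(detect(img, small), "smaller")
})

test_that("a trained detector localizes marker-free nodules", {
  mini <- make_mini_dataset(n_train = 14, n_test = 10, seed = 91)
  tr <- mini$split == "train"
  cfg <- detector_config(
    classifier = classifier_config(crop_size = 32, epochs = 25))
  det <- train_detector(mini$imgs[tr], mini$gts[tr], cfg, seed = 5)
  hits <- 0L
  idx_test <- which(!tr)
  for (i in idx_test) {
    d <- detect(mini$imgs[[i]], det)
    if (nrow(d) == 0) next
    top <- as.numeric(d[1, c("x0", "y0", "x1", "y1")])
    ious <- apply(mini$gts[[i]], 1, box_iou, boxA = top)
    if (max(ious) >= 0.3) hits <- hits + 1L
  }
  expect_gte(hits, ceiling(0.7 * length(idx_test)))
})
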