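# Caliper-marker model: edge placement, burn/mask bookkeeping, pseudo-group
# constraints and marker mixup.

test_that("edge marker placement obeys the group-size rules", {
  rect <- c(10, 10, 50, 40)
  p2 <- tangency_points(rect, 2L, seed = 1)
  expect_equal(nrow(p2), 2)
  expect_setequal(p2[, "col"], c(10, 49))
  expect_true(all(p2[, "row"] >= 10 & p2[, "row"] <= 39))

  p4 <- tangency_points(rect, 4L, seed = 2)
  expect_equal(nrow(p4), 4)
  # four distinct edges: left, right, top, bottom
  expect_equal(p4["left", "col"], 10)
  expect_equal(p4["right", "col"], 49)
  expect_equal(p4["top", "row"], 10)
  expect_equal(p4["bottom", "row"], 39)

  expect_error(tangency_points(rect, 3L, 1), "2 or 4")
  expect_error(tangency_points(c(0, 0, 5, 5), 2L, 1), "8 x 8")
  expect_identical(tangency_points(rect, 4L, 9), tangency_points(rect, 4L, 9))
})

test_that("burned annotations are local, bookkept and reversible", {
  fx <- tiny_annotated(seed = 8)
  ann <- fx$ann
  expect_s3_class(ann, "sono_annotated")
  # pixels outside the mask are exactly the original image
  expect_identical(ann$image[ann$mask == 0], fx$raw[ann$mask == 0])
  # mask pixel count equals the written glyph footprint pixels
  expect_equal(sum(ann$mask), sum(ann$image != fx$raw | ann$mask == 1))
  expect_true(all(ann$image[ann$mask == 1] == marker_glyph()$intensity))

  # group-size bookkeeping: a 4-group records exactly 4 centres
  nd <- fx$nodules[[1]]
  a4 <- annotate_nodule(fx$raw, nd, group_size = 4L, seed = 3)
  expect_equal(nrow(a4$groups[[1]]$points), 4)

  # contour placement: markers sit on the bbox perimeter band
  bb <- nd$bbox
  pts <- a4$groups[[1]]$points
  on_band <- apply(pts, 1, function(p) {
    (abs(p["col"] - bb[1]) <= 1) || (abs(p["col"] - (bb[3] - 1)) <= 1) ||
      (abs(p["row"] - bb[2]) <= 1) || (abs(p["row"] - (bb[4] - 1)) <= 1)
  })
  expect_true(all(on_band))
})

test_that("pseudo groups satisfy the IoU-zero and size-bound constraints", {
  fx <- tiny_annotated(seed = 9, n_nod = 2, size = 128)
  boxes <- lapply(fx$nodules, `[[`, "bbox")
  max_dims <- c(
    max(vapply(boxes, function(b) b[3] - b[1], numeric(1))),
    max(vapply(boxes, function(b) b[4] - b[2], numeric(1))))
  max_dims <- pmax(max_dims, 9)
  for (s in 1:100) {
    g <- generate_pseudo_group(fx$raw, fx$nodules, max_dims, seed = s)
    expect_true(g$is_pseudo)
    expect_lte(g$rect[3] - g$rect[1], max_dims[1])
    expect_lte(g$rect[4] - g$rect[2], max_dims[2])
    for (b in boxes) expect_equal(box_iou(g$rect, b), 0)
    expect_true(g$group_size %in% c(2L, 4L))
    expect_lte(nrow(g$points), g$group_size)
  }
  # infeasible case: a nodule box covering the whole admissible area
  big <- list(structure(list(bbox = c(0, 0, 64, 64)), class = "sono_nodule"))
  expect_error(
    generate_pseudo_group(matrix(0.5, 64, 64), big, c(20, 20), seed = 1,
                          max_attempts = 25L),
    "placement")
})

test_that("marker masks reproduce footprints and grow monotonically", {
  fx <- tiny_annotated(seed = 12)
  ann <- fx$ann
  g <- marker_glyph()
  m0 <- marker_mask(ann$groups, g, dim(ann$image), dilation = 0)
  expect_identical(m0, ann$mask)
  prev <- sum(m0)
  for (d in 1:3) {
    md <- marker_mask(ann$groups, g, dim(ann$image), dilation = d)
    expect_gte(sum(md), prev)
    prev <- sum(md)
  }
  empty <- marker_mask(list(), g, c(32, 32))
  expect_equal(sum(empty), 0)
})

test_that("mixup keeps the required markers and scatters the rest off-nodule", {
  fx2 <- tiny_annotated(seed = 21)
  nd <- fx2$nodules[[1]]
  ann2 <- annotate_nodule(fx2$raw, nd, group_size = 2L, seed = 5)
  ann4 <- annotate_nodule(fx2$raw, nd, group_size = 4L, seed = 5)
  arm <- marker_glyph()$arm_length

  for (s in 1:25) {
    mx <- mixup_markers(ann2, seed = s)
    kept <- mx$groups[[1]]$points
    expect_equal(nrow(kept), 1)
    # the kept point is one of the originals
    orig <- ann2$groups[[1]]$points
    expect_true(any(apply(orig, 1, function(p) all(p == kept[1, ]))))
    expect_equal(NROW(mx$scatter), 1)

    mx4 <- mixup_markers(ann4, seed = s)
    k4 <- nrow(mx4$groups[[1]]$points)
    expect_true(k4 >= 1 && k4 <= 3)
    expect_equal(NROW(mx4$scatter), 4 - k4)
    # every replacement glyph footprint has IoU 0 with the nodule box
    for (i in seq_len(NROW(mx4$scatter))) {
      p <- mx4$scatter[i, ]
      fp <- c(p["col"] - arm, p["row"] - arm,
              p["col"] + arm + 1, p["row"] + arm + 1)
      expect_equal(box_iou(fp, nd$bbox), 0)
    }
  }

  # determinism
  expect_identical(serialize(mixup_markers(ann4, seed = 3), NULL),
                   serialize(mixup_markers(ann4, seed = 3), NULL))
  no_groups <- ann2; no_groups$groups <- list()
  expect_error(mixup_markers(no_groups), "at least one real group")
})
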