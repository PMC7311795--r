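# Texture-synthesis inpainting, marker localization, quality metrics and
# the learned coarse reconstruction model.

test_that("an empty mask is the bit-exact identity", {
  img <- generate_background(48, 48, seed = 1)
  res <- inpaint_texture(img, matrix(0L, 48, 48), seed = 2)
  expect_identical(res$image, img)
  expect_equal(sum(res$fill_order), 0)
})

test_that("the chosen source patch equals the brute-force SSD argmin", {
  set.seed(61)
  for (rep in 1:5) {
    img <- generate_background(40, 40, seed = 60 + rep)
    mask <- matrix(0L, 40, 40)
    ti <- sample(10:30, 1); tj <- sample(10:30, 1)
    mask[ti, tj] <- 1L
    res <- inpaint_texture(img, mask, texsynth_params(tolerance = 0),
                           seed = 1)
    # brute force: SSD over the 8-neighbourhood-complete window, excluding
    # the missing centre, across all fully-known candidate patches
    r <- 4
    best <- Inf; best_val <- NA
    for (ci in (r + 1):(40 - r)) {
      for (cj in (r + 1):(40 - r)) {
        if (abs(ci - ti) <= r && abs(cj - tj) <= r) {
          # candidate windows overlapping the missing pixel are excluded
          # from the original-known candidate set
          next
        }
        ssd <- 0
        for (di in -r:r) {
          for (dj in -r:r) {
            ii <- ti + di; jj <- tj + dj
            if (ii < 1 || jj < 1 || ii > 40 || jj > 40) next
            if (ii == ti && jj == tj) next
            ssd <- ssd + (img[ci + di, cj + dj] - img[ii, jj])^2
          }
        }
        if (ssd < best) { best <- ssd; best_val <- img[ci, cj] }
      }
    }
    expect_equal(res$image[ti, tj], best_val)
  }
})

test_that("a periodic texture hole is refilled exactly", {
  set.seed(62)
  tile <- matrix(runif(36, 0.2, 0.8), 6, 6)
  img <- tile[rep(1:6, 8), rep(1:6, 8)] # 48 x 48, period 6
  mask <- matrix(0L, 48, 48)
  mask[20:25, 20:25] <- 1L
  res <- inpaint_texture(img, mask, seed = 3)
  mse <- mean((res$image[mask == 1] - img[mask == 1])^2)
  expect_lt(mse, 1e-6)
  # pixels outside the mask are untouched for every backend
  expect_identical(res$image[mask == 0], img[mask == 0])
})

test_that("glyph refill beats the mean-fill baseline on speckle phantoms", {
  wins <- 0L
  n_fix <- 10L
  for (s in seq_len(n_fix)) {
    fx <- tiny_annotated(seed = 300 + s)
    oracle <- sonomark:::.cpp_dilate(fx$ann$mask, 1L)
    res <- inpaint_texture(fx$ann$image, oracle, seed = s)
    q_tex <- inpaint_quality(fx$raw, res$image, oracle)$masked_mse
    mf <- fx$ann$image
    mf[oracle == 1] <- mean(fx$ann$image[oracle == 0])
    q_mf <- inpaint_quality(fx$raw, mf, oracle)$masked_mse
    if (q_tex < q_mf) wins <- wins + 1L
  }
  expect_gte(wins, n_fix - 1L)
})

test_that("masked MSE degrades monotonically with mask dilation on average", {
  mse_at <- function(dilation) {
    vals <- vapply(1:8, function(s) {
      fx <- tiny_annotated(seed = 500 + s)
      m <- sonomark:::.cpp_dilate(fx$ann$mask, as.integer(dilation))
      res <- inpaint_texture(fx$ann$image, m, seed = s)
      inpaint_quality(fx$raw, res$image, m)$masked_mse
    }, numeric(1))
    mean(vals)
  }
  expect_lte(mse_at(1), mse_at(4) + 1e-4)
})

test_that("the localizer recovers burned glyphs and ignores clean phantoms", {
  for (s in 1:5) {
    fx <- tiny_annotated(seed = 100 + s, n_nod = 2, size = 128)
    loc <- locate_markers(fx$ann$image)
    oracle <- sonomark:::.cpp_dilate(fx$ann$mask, 1L)
    dice <- 2 * sum(loc & oracle) / (sum(loc) + sum(oracle))
    expect_gte(dice, 0.9)
    # marker-free phantom: false-positive area below 0.5% of the image
    fp <- locate_markers(fx$raw, threshold = 0.8)
    expect_lt(sum(fp) / length(fp), 0.005)
  }
  blank <- matrix(0.5, 64, 64)
  expect_equal(sum(locate_markers(blank)), 0)
  expect_error(locate_markers(blank, list()), "non-empty")
})

test_that("masked quality metrics follow their definitions", {
  img <- generate_background(32, 32, seed = 5)
  mask <- matrix(0L, 32, 32); mask[10:14, 10:14] <- 1L
  q0 <- inpaint_quality(img, img, mask)
  expect_equal(q0$masked_mse, 0)
  expect_equal(q0$masked_psnr, 99)

  shifted <- img; shifted[mask == 1] <- img[mask == 1] + 0.1
  q1 <- inpaint_quality(img, shifted, mask)
  expect_equal(q1$masked_mse, 0.01, tolerance = 1e-12)

  # independence from pixels outside the mask
  garbled <- shifted; garbled[mask == 0] <- 0
  expect_equal(inpaint_quality(img, garbled, mask), q1)
  expect_error(inpaint_quality(img, img, matrix(0L, 32, 32)), "non-empty")
})

test_that("the coarse model trains, improves and stays deterministic", {
  set.seed(63)
  pairs <- lapply(1:60, function(s) {
    fx <- tiny_annotated(seed = 700 + s, size = 64)
    list(corrupted = fx$ann$image,
         mask = sonomark:::.cpp_dilate(fx$ann$mask, 1L),
         original = fx$raw)
  })
  cfg <- coarse_net_config(epochs = 8, samples_per_image = 20)
  net <- train_coarse_net(pairs[1:50], cfg, seed = 2)
  # training loss decreases on average over epochs
  k <- length(net$loss_log)
  expect_lt(mean(net$loss_log[(k - 2):k]), net$loss_log[1])

  untrained <- net
  untrained$net <- sonomark:::mlp_init(
    c(2 * (2 * cfg$context_radius + 1)^2, cfg$hidden, 1L), 99)
  holdout <- pairs[51:60]
  expect_lt(coarse_net_masked_l1(net, holdout),
            coarse_net_masked_l1(untrained, holdout))

  net2 <- train_coarse_net(pairs[1:50], cfg, seed = 2)
  expect_identical(net$net, net2$net)

  # inpaint_coarse only touches the mask
  res <- inpaint_coarse(holdout[[1]]$corrupted, holdout[[1]]$mask, net)
  m <- holdout[[1]]$mask
  expect_identical(res$image[m == 0], holdout[[1]]$corrupted[m == 0])
  expect_true(all(res$image >= 0 & res$image <= 1))
  expect_error(train_coarse_net(pairs[1:10], cfg, 1), "at least 50")
})
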