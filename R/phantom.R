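# Speckle-phantom generator: ultrasound-like backgrounds with ground-truth
# hypoechoic nodules. Every downstream stage (annotation, inpainting,
# classification, detection, evaluation) runs on these phantoms, so image
# formation is deliberately simple: a smooth low-frequency echogenicity base
# multiplied by unit-mean gamma noise, the standard fully-developed-speckle
# approximation.

#' Speckle model parameters
#'
#' @param shape gamma shape of the multiplicative noise; the raw noise has
#'   mean 1 and variance `1/shape`. `Inf` disables the noise (image equals
#'   its smooth base).
#' @param base_mean mean intensity of the smooth base field.
#' @param base_amp half-range of the base field's slow modulation.
#' @param base_scale approximate correlation length of the base, in pixels.
#' @param grain speckle grain: Gaussian correlation length (sigma, pixels)
#'   of the noise field, emulating the finite resolution cell that makes
#'   real ultrasound speckle spatially correlated. `0` gives pixel-wise
#'   independent noise.
#' @return A `speckle_params` list.
#' @export
speckle_params <- function(shape = 4, base_mean = 0.5, base_amp = 0.12,
                           base_scale = 16, grain = 1) {
  stop_if_not(shape > 0, "speckle shape must be positive")
  stop_if_not(base_mean > 0 && base_scale > 0, "speckle parameters must be positive")
  stop_if_not(base_amp >= 0 && grain >= 0, "base_amp and grain must be non-negative")
  structure(list(shape = shape, base_mean = base_mean, base_amp = base_amp,
                 base_scale = base_scale, grain = grain),
            class = "speckle_params")
}

# Separable Gaussian blur with replicated edges.
gaussian_blur <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-r:r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  pad_conv <- function(m) {
    # pad rows by replication, convolve down columns
    padded <- rbind(m[rep(1L, r), , drop = FALSE], m,
                    m[rep(nrow(m), r), , drop = FALSE])
    out <- matrix(0, nrow(m), ncol(m))
    for (i in seq_along(k)) {
      out <- out + k[i] * padded[i:(i + nrow(m) - 1L), , drop = FALSE]
    }
    out
  }
  t(pad_conv(t(pad_conv(mat))))
}

# Unit-mean speckle noise field at the configured grain.
speckle_noise <- function(height, width, params) {
  if (!is.finite(params$shape)) return(matrix(1, height, width))
  raw <- matrix(rgamma(height * width, shape = params$shape,
                       rate = params$shape), height, width)
  gaussian_blur(raw, params$grain)
}

# Smooth base field: bilinear upsample of a coarse uniform random grid.
speckle_base <- function(height, width, params) {
  gs <- params$base_scale
  gh <- max(2L, ceiling(height / gs) + 1L)
  gw <- max(2L, ceiling(width / gs) + 1L)
  grid <- matrix(params$base_mean +
                   params$base_amp * (2 * runif(gh * gw) - 1), gh, gw)
  # map pixel centers onto the grid
  ry <- seq(0, gh - 1, length.out = height)
  rx <- seq(0, gw - 1, length.out = width)
  y0 <- pmin(floor(ry), gh - 2); fy <- ry - y0
  x0 <- pmin(floor(rx), gw - 2); fx <- rx - x0
  a <- grid[cbind(rep(y0 + 1, width), rep(x0 + 1, each = height))]
  b <- grid[cbind(rep(y0 + 1, width), rep(x0 + 2, each = height))]
  d <- grid[cbind(rep(y0 + 2, width), rep(x0 + 1, each = height))]
  e <- grid[cbind(rep(y0 + 2, width), rep(x0 + 2, each = height))]
  fyv <- rep(fy, width); fxv <- rep(fx, each = height)
  matrix(a * (1 - fyv) * (1 - fxv) + b * (1 - fyv) * fxv +
           d * fyv * (1 - fxv) + e * fyv * fxv, height, width)
}

#' Generate a speckle background
#'
#' Multiplicative-speckle field: a smooth low-frequency base times unit-mean
#' gamma noise, clipped to `[0, 1]`. Deterministic given `seed`.
#'
#' @param height,width image dimensions in pixels (at least 32).
#' @param speckle a [speckle_params()] object.
#' @param seed integer seed.
#' @param return_parts if `TRUE`, also return the smooth base and the noise
#'   factor (before clipping) for diagnostics.
#' @return A `height x width` matrix in `[0, 1]`, or a list with elements
#'   `image`, `base`, `noise` when `return_parts = TRUE`.
#' @export
generate_background <- function(height, width, speckle = speckle_params(),
                                seed = 1L, return_parts = FALSE) {
  stop_if_not(height >= 32 && width >= 32,
              "image dimensions must be at least 32 x 32")
  with_seed(seed, {
    base <- speckle_base(height, width, speckle)
    noise <- speckle_noise(height, width, speckle)
    img <- clip01(base * noise)
    if (return_parts) list(image = img, base = base, noise = noise) else img
  })
}

#' Construct a nodule
#'
#' A rotated ellipse with a relative darkening (hypoechoic contrast) and its
#' tight axis-aligned enclosing rectangle.
#'
#' @param center `c(row, col)` in pixels (0-based).
#' @param semi_axes `c(a, b)` semi-axis lengths in pixels, both at least 3.
#' @param rotation radians.
#' @param contrast relative darkening in `(0, 1]` (0 allowed as the identity
#'   degenerate case).
#' @return A `sono_nodule` list with fields `center`, `semi_axes`,
#'   `rotation`, `contrast`, `bbox`.
#' @export
nodule <- function(center, semi_axes, rotation = 0, contrast = 0.45) {
  stop_if_not(all(semi_axes >= 3), "nodule semi-axes must be at least 3 px")
  stop_if_not(contrast >= 0 && contrast <= 1, "contrast must be in [0, 1]")
  structure(list(
    center = as.numeric(center), semi_axes = as.numeric(semi_axes),
    rotation = as.numeric(rotation), contrast = as.numeric(contrast),
    bbox = ellipse_bbox(center, semi_axes, rotation)
  ), class = "sono_nodule")
}

#' Darken a nodule into an image
#'
#' Pixels inside the ellipse are multiplied by `1 - contrast`, with a
#' feathered (soft) boundary of the given width so the edge is not a trivial
#' step the detector could key on. Pixels farther than the feather width
#' outside the ellipse are untouched.
#'
#' @param image matrix in `[0, 1]`.
#' @param nod a [nodule()].
#' @param feather transition width in pixels at the ellipse boundary.
#' @return The modified image matrix.
#' @export
place_nodule <- function(image, nod, feather = 2) {
  h <- nrow(image); w <- ncol(image)
  stop_if_not(box_inside_image(nod$bbox, h, w),
              "nodule bbox must lie fully inside the image")
  if (nod$contrast == 0) return(image)
  soft_ellipse_darken(image, nod$center, nod$semi_axes, nod$rotation,
                      nod$contrast, feather)
}

#' Phantom dataset configuration
#'
#' @param n_train,n_test number of images per split.
#' @param height,width image size in pixels.
#' @param nodules_per_image integer vector of allowed per-image nodule
#'   counts (drawn uniformly).
#' @param semi_axis_range `c(min, max)` for the major semi-axis; the minor
#'   semi-axis is drawn as a fraction of the major one.
#' @param axis_ratio_range `c(min, max)` minor/major semi-axis ratio.
#' @param contrast nodule darkening; a single value or `c(min, max)` range.
#' @param speckle a [speckle_params()] object.
#' @param margin minimum distance of a nodule bbox from the image border.
#' @param max_attempts rejection-sampling cap for nodule placement.
#' @param n_distractors `c(min, max)` count of hypoechoic distractor
#'   structures per image (elongated dark bands and streaks emulating
#'   vessels, fascia and shadowing). Real ultrasound backgrounds contain
#'   many dark non-nodule structures; without them, "dark blob" would be an
#'   unrealistically sufficient detection cue. Set `c(0, 0)` to disable.
#' @param distractor_axis_range `c(min, max)` major semi-axis of
#'   distractors in pixels.
#' @param distractor_ratio_range `c(min, max)` minor/major ratio of
#'   distractors (strongly elongated, unlike nodules).
#' @param distractor_contrast `c(min, max)` darkening of distractors.
#' @param n_blobs `c(min, max)` count of rounded hypoechoic look-alike
#'   blobs per image: pseudo-nodular structures (cysts, vessels in cross
#'   section) with softer edges than true nodules. These make nodule
#'   discrimination a genuine texture/shape task rather than a brightness
#'   threshold.
#' @param blob_axis_range,blob_ratio_range,blob_contrast blob geometry and
#'   darkening ranges.
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(n_train = 200, n_test = 100, height = 128,
                           width = 128, nodules_per_image = c(1L, 2L),
                           semi_axis_range = c(8, 16),
                           axis_ratio_range = c(0.55, 0.95),
                           contrast = c(0.25, 0.4),
                           speckle = speckle_params(shape = 3, grain = 1.2),
                           margin = 4, max_attempts = 200L,
                           n_distractors = c(2L, 5L),
                           distractor_axis_range = c(12, 28),
                           distractor_ratio_range = c(0.1, 0.3),
                           distractor_contrast = c(0.15, 0.35),
                           n_blobs = c(1L, 3L),
                           blob_axis_range = c(5, 13),
                           blob_ratio_range = c(0.4, 0.8),
                           blob_contrast = c(0.15, 0.3)) {
  structure(as.list(environment()), class = "phantom_config")
}

# A dark elongated non-nodule structure; centre may fall anywhere inside
# the image, with the ellipse clipped at the borders.
place_distractor <- function(image, cfg) {
  h <- nrow(image); w <- ncol(image)
  a <- runif(1, cfg$distractor_axis_range[1], cfg$distractor_axis_range[2])
  b <- max(1.5, a * runif(1, cfg$distractor_ratio_range[1],
                          cfg$distractor_ratio_range[2]))
  th <- runif(1, 0, pi)
  ctr <- c(runif(1, 0, h - 1), runif(1, 0, w - 1))
  contrast <- runif(1, cfg$distractor_contrast[1], cfg$distractor_contrast[2])
  soft_ellipse_darken(image, ctr, c(a, b), th, contrast)
}

# A rounded nodule look-alike with a wide soft edge.
place_blob <- function(image, cfg) {
  h <- nrow(image); w <- ncol(image)
  a <- runif(1, cfg$blob_axis_range[1], cfg$blob_axis_range[2])
  b <- max(2, a * runif(1, cfg$blob_ratio_range[1], cfg$blob_ratio_range[2]))
  th <- runif(1, 0, pi)
  ctr <- c(runif(1, 4, h - 5), runif(1, 4, w - 5))
  contrast <- runif(1, cfg$blob_contrast[1], cfg$blob_contrast[2])
  soft_ellipse_darken(image, ctr, c(a, b), th, contrast, feather = 5)
}

# Shared soft-ellipse darkening used by nodules and distractors, clipped to
# the image.
soft_ellipse_darken <- function(image, center, semi_axes, rotation,
                                contrast, feather = 2) {
  h <- nrow(image); w <- ncol(image)
  f <- max(feather, 1e-6)
  he <- ellipse_half_extents(semi_axes[1], semi_axes[2], rotation)
  pad <- ceiling(f)
  y0 <- max(0, floor(center[1] - he[["hh"]]) - pad)
  y1 <- min(h, ceiling(center[1] + he[["hh"]]) + pad)
  x0 <- max(0, floor(center[2] - he[["hw"]]) - pad)
  x1 <- min(w, ceiling(center[2] + he[["hw"]]) + pad)
  if (y0 >= y1 || x0 >= x1) return(image)
  rows <- (y0 + 1):y1; cols <- (x0 + 1):x1
  rr <- matrix(rows - 1, length(rows), length(cols))
  cc <- matrix(cols - 1, length(rows), length(cols), byrow = TRUE)
  dy <- rr - center[1]; dx <- cc - center[2]
  u <- dx * cos(rotation) + dy * sin(rotation)
  v <- -dx * sin(rotation) + dy * cos(rotation)
  rad <- sqrt((u / semi_axes[1])^2 + (v / semi_axes[2])^2)
  s <- (rad - 1) * min(semi_axes)
  wgt <- pmin(pmax(0.5 - s / f, 0), 1)
  image[rows, cols] <- image[rows, cols] * (1 - contrast * wgt)
  image
}

sample_nodule <- function(cfg, existing_boxes) {
  h <- cfg$height; w <- cfg$width
  for (attempt in seq_len(cfg$max_attempts)) {
    a <- runif(1, cfg$semi_axis_range[1], cfg$semi_axis_range[2])
    b <- max(3, a * runif(1, cfg$axis_ratio_range[1], cfg$axis_ratio_range[2]))
    th <- runif(1, 0, pi)
    he <- ellipse_half_extents(a, b, th)
    lo_c <- cfg$margin + he[["hw"]] + 1
    hi_c <- w - cfg$margin - he[["hw"]] - 2
    lo_r <- cfg$margin + he[["hh"]] + 1
    hi_r <- h - cfg$margin - he[["hh"]] - 2
    if (lo_c >= hi_c || lo_r >= hi_r) next
    ctr <- c(runif(1, lo_r, hi_r), runif(1, lo_c, hi_c))
    contr <- if (length(cfg$contrast) == 2) {
      runif(1, cfg$contrast[1], cfg$contrast[2])
    } else cfg$contrast
    nd <- nodule(ctr, c(a, b), th, contr)
    if (!box_inside_image(nd$bbox, h, w)) next
    ok <- all(vapply(existing_boxes,
                     function(bx) box_iou(bx, nd$bbox) == 0, logical(1)))
    if (ok) return(nd)
  }
  NULL
}

#' Render a full phantom dataset
#'
#' Generates `n_train + n_test` speckle images, each with non-overlapping
#' ground-truth nodules (pairwise bbox IoU exactly 0), reproducible from the
#' seed.
#'
#' @param config a [phantom_config()].
#' @param seed integer seed.
#' @return A `sono_phantom_dataset`: list with `items` (each
#'   `list(image, nodules)`), `split` (`"train"`/`"test"` per item),
#'   `seed` and `config`.
#' @export
render_dataset <- function(config = phantom_config(), seed = 1L) {
  n <- config$n_train + config$n_test
  seeds <- child_seeds(seed, n + 1L)
  items <- vector("list", n)
  for (i in seq_len(n)) {
    items[[i]] <- with_seed(seeds[i], {
      img <- speckle_base(config$height, config$width, config$speckle)
      img <- clip01(img * speckle_noise(config$height, config$width,
                                        config$speckle))
      nd_count <- if (length(config$n_distractors) > 1) {
        sample(seq.int(config$n_distractors[1], config$n_distractors[2]), 1)
      } else config$n_distractors
      for (d in seq_len(nd_count)) img <- place_distractor(img, config)
      nb_count <- if (length(config$n_blobs) > 1) {
        sample(seq.int(config$n_blobs[1], config$n_blobs[2]), 1)
      } else config$n_blobs
      for (d in seq_len(nb_count)) img <- place_blob(img, config)
      k <- if (length(config$nodules_per_image) > 1) {
        sample(config$nodules_per_image, 1)
      } else config$nodules_per_image
      nods <- list()
      for (j in seq_len(k)) {
        nd <- sample_nodule(config, lapply(nods, `[[`, "bbox"))
        if (is.null(nd)) {
          stop(sprintf("could not place nodule %d in image %d without overlap after %d attempts",
                       j, i, config$max_attempts), call. = FALSE)
        }
        img <- place_nodule(img, nd)
        nods[[j]] <- nd
      }
      list(image = img, nodules = nods)
    })
  }
  structure(list(
    items = items,
    split = rep(c("train", "test"), c(config$n_train, config$n_test)),
    seed = as.integer(seed), config = config
  ), class = "sono_phantom_dataset")
}

#' @export
print.sono_phantom_dataset <- function(x, ...) {
  cat(sprintf("<sono_phantom_dataset> %d items (%d train / %d test), %dx%d px, seed %d\n",
              length(x$items), sum(x$split == "train"), sum(x$split == "test"),
              x$config$height, x$config$width, x$seed))
  invisible(x)
}
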