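# Marker removal: exemplar-based texture synthesis (learning-free), an
# optional learned coarse reconstruction model, and a template-matching
# marker localizer for mask-free inputs.

#' Texture-synthesis parameters
#'
#' @param patch_radius half-width of the square comparison window.
#' @param search_stride stride of the candidate-patch scan (1 = every
#'   fully-known patch in the image).
#' @param tolerance relative SSD slack: candidates within
#'   `(1 + tolerance) * min SSD` are accepted and tie-broken by a seeded
#'   uniform draw.
#' @param fill_strategy `"onion_peel"` (boundary-inward, row-major) or
#'   `"priority"` (most-context-first within each boundary layer).
#' @return A `texsynth_params` list.
#' @export
texsynth_params <- function(patch_radius = 4, search_stride = 1,
                            tolerance = 0.1,
                            fill_strategy = c("onion_peel", "priority")) {
  stop_if_not(patch_radius >= 1, "patch_radius must be at least 1")
  stop_if_not(tolerance >= 0, "tolerance must be non-negative")
  structure(list(patch_radius = as.integer(patch_radius),
                 search_stride = as.integer(search_stride),
                 tolerance = tolerance,
                 fill_strategy = match.arg(fill_strategy)),
            class = "texsynth_params")
}

#' Fill masked pixels by exemplar-based texture synthesis
#'
#' Masked pixels are synthesized boundary-inward; each pixel is copied from
#' the centre of the best-SSD matching patch among all fully-known patches
#' of the same image, comparing only window positions that are currently
#' known (original or already filled). The seed only breaks SSD ties.
#'
#' @param image matrix in `[0, 1]`.
#' @param mask 0/1 matrix, 1 = pixel to fill; must be strictly smaller than
#'   the image.
#' @param params a [texsynth_params()].
#' @param seed integer seed.
#' @return An `InpaintResult` list: `image`, `mask`, `backend = "texture"`,
#'   `fill_order` (matrix of synthesis ranks, 0 outside the mask).
#' @export
inpaint_texture <- function(image, mask, params = texsynth_params(),
                            seed = 1L) {
  stop_if_not(all(dim(image) == dim(mask)), "image and mask shapes must match")
  storage.mode(mask) <- "integer"
  stop_if_not(sum(mask) < length(mask), "mask must be strictly smaller than the image")
  res <- with_seed(seed, {
    .cpp_tex_inpaint(image, mask, params$patch_radius, params$search_stride,
                     params$tolerance, params$fill_strategy == "priority")
  })
  structure(list(image = res$image, mask = mask, backend = "texture",
                 fill_order = res$order), class = "sono_inpaint_result")
}

#' Locate burned-in markers by template matching
#'
#' Runs normalized cross-correlation of each glyph template against the
#' image; local maxima above the threshold become glyph-footprint mask
#' components, dilated by 1 px.
#'
#' @param image matrix in `[0, 1]`.
#' @param glyph_bank list of [marker_glyph()]s to search for.
#' @param threshold correlation threshold in `[0, 1]`.
#' @return An integer 0/1 mask (possibly empty).
#' @export
locate_markers <- function(image, glyph_bank = list(marker_glyph()),
                           threshold = 0.6) {
  stop_if_not(length(glyph_bank) > 0, "glyph_bank must be non-empty")
  h <- nrow(image); w <- ncol(image)
  mask <- matrix(0L, h, w)
  for (glyph in glyph_bank) {
    arm <- glyph$arm_length
    tmpl <- matrix(0, 2 * arm + 1, 2 * arm + 1)
    off <- glyph_offsets(glyph)
    tmpl[cbind(off[, "dr"] + arm + 1L, off[, "dc"] + arm + 1L)] <- 1
    ncc <- .cpp_ncc(image, tmpl)
    # strict local maxima over a 3x3 neighbourhood, above threshold
    for (i in 2:(h - 1)) {
      cand <- which(ncc[i, ] >= threshold)
      for (j in cand) {
        if (j < 2 || j > w - 1) next
        nb <- ncc[(i - 1):(i + 1), (j - 1):(j + 1)]
        if (ncc[i, j] >= max(nb)) {
          b <- burn_glyph(mask, c(i - 1L, j - 1L), marker_glyph(
            glyph$shape, glyph$arm_length, glyph$thickness, 1),
            warn_clip = FALSE)
          mask <- b$image
          mask[b$pixels] <- 1L
        }
      }
    }
  }
  storage.mode(mask) <- "integer"
  .cpp_dilate(mask, 1L)
}

#' Masked reconstruction quality
#'
#' MSE and PSNR over masked pixels only. A perfect reconstruction has
#' infinite PSNR, reported as the capped sentinel 99 dB.
#'
#' @param original,restored matrices of equal shape.
#' @param mask 0/1 matrix with at least one masked pixel.
#' @return List with `masked_mse` and `masked_psnr` (dB, capped at 99).
#' @export
inpaint_quality <- function(original, restored, mask) {
  stop_if_not(all(dim(original) == dim(restored)) &&
                all(dim(original) == dim(mask)), "shapes must match")
  idx <- mask == 1
  stop_if_not(any(idx), "mask must be non-empty")
  mse <- mean((original[idx] - restored[idx])^2)
  psnr <- if (mse <= 0) 99 else min(99, 10 * log10(1 / mse))
  list(masked_mse = mse, masked_psnr = psnr)
}

# --- learned coarse reconstruction model -----------------------------------

#' Coarse reconstruction model configuration
#'
#' The coarse model predicts a masked pixel from its masked square
#' neighbourhood (pixel values with masked entries zeroed, plus a mask
#' channel) with a small fully-connected network trained on reconstruction
#' (L1) loss only; at inference it is applied onion-peel, so earlier
#' predictions provide context for later ones.
#'
#' @param context_radius neighbourhood half-width in pixels.
#' @param hidden hidden-layer width.
#' @param epochs,lr,batch_size Adam training settings.
#' @param samples_per_image training neighbourhoods drawn per image pair.
#' @return A `coarse_net_config` list.
#' @export
coarse_net_config <- function(context_radius = 4, hidden = 32, epochs = 20,
                              lr = 1e-3, batch_size = 64,
                              samples_per_image = 40) {
  structure(as.list(environment()), class = "coarse_net_config")
}

coarse_features <- function(image, known, ti, tj, r) {
  h <- nrow(image); w <- ncol(image)
  rows <- (ti - r):(ti + r); cols <- (tj - r):(tj + r)
  vals <- matrix(0, 2 * r + 1, 2 * r + 1)
  km <- matrix(0, 2 * r + 1, 2 * r + 1)
  inr <- rows >= 1 & rows <= h
  inc <- cols >= 1 & cols <= w
  vr <- rows[inr]; vc <- cols[inc]
  kk <- known[vr, vc, drop = FALSE] == 1
  vv <- image[vr, vc, drop = FALSE]
  vv[!kk] <- 0
  vals[inr, inc] <- vv
  km[inr, inc] <- kk
  c(as.numeric(vals), as.numeric(km))
}

#' Train the coarse reconstruction model
#'
#' @param pairs list of `list(corrupted, mask, original)` training triples
#'   (at least 50).
#' @param config a [coarse_net_config()].
#' @param seed integer seed.
#' @return A `sono_coarse_net` with the fitted weights and the per-epoch
#'   training-loss log.
#' @export
train_coarse_net <- function(pairs, config = coarse_net_config(), seed = 1L) {
  stop_if_not(length(pairs) >= 50, "need at least 50 training pairs")
  r <- config$context_radius
  seeds <- child_seeds(seed, 2L)
  # Harvest (features, target) examples at masked pixels.
  X <- list(); y <- numeric(0)
  with_seed(seeds[1], {
    for (p in pairs) {
      idx <- which(p$mask == 1, arr.ind = TRUE)
      if (nrow(idx) == 0) next
      take <- idx[sample.int(nrow(idx), min(config$samples_per_image,
                                            nrow(idx))), , drop = FALSE]
      known <- 1L - p$mask
      for (k in seq_len(nrow(take))) {
        X[[length(X) + 1L]] <- coarse_features(p$corrupted, known,
                                               take[k, 1], take[k, 2], r)
        y <- c(y, p$original[take[k, 1], take[k, 2]])
      }
    }
  })
  stop_if_not(length(y) > 0, "training pairs contained no masked pixels")
  X <- do.call(rbind, X)
  net <- mlp_init(c(ncol(X), config$hidden, 1L), seeds[2])
  log <- numeric(config$epochs)
  state <- adam_init(net)
  with_seed(seeds[2], {
    n <- nrow(X)
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; nb <- 0
      for (start in seq(1, n, by = config$batch_size)) {
        bidx <- ord[start:min(start + config$batch_size - 1, n)]
        fw <- mlp_forward(net, X[bidx, , drop = FALSE])
        pred <- fw$out[, 1]
        resid <- pred - y[bidx]
        loss <- mean(abs(resid))
        dout <- matrix(sign(resid) / length(bidx), ncol = 1)
        gr <- mlp_backward(net, fw, dout)
        state <- adam_step(net, gr, state, config$lr)
        net <- state$params
        ep_loss <- ep_loss + loss; nb <- nb + 1
      }
      log[ep] <- ep_loss / nb
    }
  })
  structure(list(net = net, config = config, loss_log = log),
            class = "sono_coarse_net")
}

#' Evaluate the coarse model's masked L1 loss on image pairs
#'
#' @param model a `sono_coarse_net` (or `NULL` weights via [mlp_init()] for
#'   an untrained reference).
#' @param pairs list of `list(corrupted, mask, original)` triples.
#' @return Mean absolute error over all masked pixels.
#' @export
coarse_net_masked_l1 <- function(model, pairs) {
  tot <- 0; n <- 0
  for (p in pairs) {
    res <- inpaint_coarse(p$corrupted, p$mask, model)
    idx <- p$mask == 1
    tot <- tot + sum(abs(res$image[idx] - p$original[idx]))
    n <- n + sum(idx)
  }
  tot / n
}

#' Inpaint with the learned coarse model
#'
#' Applies the model onion-peel: boundary pixels of the unknown region are
#' predicted first (row-major), then become context for inner pixels.
#'
#' @param image matrix in `[0, 1]`.
#' @param mask 0/1 matrix of pixels to fill.
#' @param model a trained `sono_coarse_net`.
#' @return An `InpaintResult` list with `backend = "coarse_net"`.
#' @export
inpaint_coarse <- function(image, mask, model) {
  stop_if_not(all(dim(image) == dim(mask)), "image and mask shapes must match")
  r <- model$config$context_radius
  out <- image
  known <- 1L - mask
  order_m <- matrix(0L, nrow(image), ncol(image))
  counter <- 0L
  repeat {
    unknown <- which(known == 0, arr.ind = TRUE)
    if (nrow(unknown) == 0) break
    on_boundary <- vapply(seq_len(nrow(unknown)), function(k) {
      i <- unknown[k, 1]; j <- unknown[k, 2]
      ri <- max(1, i - 1):min(nrow(known), i + 1)
      rj <- max(1, j - 1):min(ncol(known), j + 1)
      any(known[ri, rj] == 1)
    }, logical(1))
    layer <- unknown[on_boundary, , drop = FALSE]
    if (nrow(layer) == 0) stop("unknown region is not reachable", call. = FALSE)
    feats <- t(vapply(seq_len(nrow(layer)), function(k) {
      coarse_features(out, known, layer[k, 1], layer[k, 2], r)
    }, numeric(2 * (2 * r + 1)^2)))
    pred <- clip01(mlp_forward(model$net, feats)$out[, 1])
    for (k in seq_len(nrow(layer))) {
      out[layer[k, 1], layer[k, 2]] <- pred[k]
      known[layer[k, 1], layer[k, 2]] <- 1L
      counter <- counter + 1L
      order_m[layer[k, 1], layer[k, 2]] <- counter
    }
  }
  structure(list(image = out, mask = mask, backend = "coarse_net",
                 fill_order = order_m), class = "sono_inpaint_result")
}
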