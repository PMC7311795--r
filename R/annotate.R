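# Caliper-marker model: glyph rendering, tangency placement in groups of 2
# or 4, pseudo-marker groups away from true nodules, and the random
# marker-mixup preprocessing that destroys the marker/nodule spatial
# association.

#' Caliper glyph description
#'
#' Clinical calipers are bright burned-in plus or cross glyphs; appearance
#' defaults mimic the common point caliper.
#'
#' @param shape `"plus"` (axis-aligned arms) or `"cross"` (diagonal arms).
#' @param arm_length arm length in pixels from the centre (at least 2).
#' @param thickness arm thickness in pixels.
#' @param intensity burned-in intensity in `[0, 1]`; markers are bright, so
#'   this should exceed the background mean.
#' @return A `marker_glyph` list.
#' @export
marker_glyph <- function(shape = c("plus", "cross"), arm_length = 4,
                         thickness = 1, intensity = 1.0) {
  shape <- match.arg(shape)
  stop_if_not(arm_length >= 2, "glyph arm_length must be at least 2")
  stop_if_not(intensity >= 0 && intensity <= 1, "glyph intensity must be in [0, 1]")
  structure(list(shape = shape, arm_length = arm_length,
                 thickness = thickness, intensity = intensity),
            class = "marker_glyph")
}

# (row, col) offsets of the glyph footprint around its centre.
glyph_offsets <- function(glyph) {
  arm <- glyph$arm_length
  half <- (glyph$thickness - 1) %/% 2
  d <- -arm:arm
  g <- expand.grid(dr = d, dc = d)
  keep <- if (glyph$shape == "plus") {
    (abs(g$dr) <= half) | (abs(g$dc) <= half)
  } else {
    (abs(g$dr - g$dc) <= half) | (abs(g$dr + g$dc) <= half)
  }
  as.matrix(g[keep, c("dr", "dc")])
}

# Burn one glyph; returns the updated image and the (row, col) pixels written.
burn_glyph <- function(image, center, glyph, warn_clip = TRUE) {
  off <- glyph_offsets(glyph)
  rr <- round(center[1]) + off[, "dr"]
  cc <- round(center[2]) + off[, "dc"]
  inb <- rr >= 0 & cc >= 0 & rr < nrow(image) & cc < ncol(image)
  if (warn_clip && any(!inb)) {
    warning("glyph footprint clipped at the image border", call. = FALSE)
  }
  px <- cbind(rr[inb] + 1L, cc[inb] + 1L)
  image[px] <- glyph$intensity
  list(image = image, pixels = px)
}

#' Marker positions on the edges of an annotation rectangle
#'
#' Groups of two place one marker on the left and one on the right edge;
#' groups of four place one marker on each of the four edges. Each marker
#' sits at a seeded-random position along its edge.
#'
#' @param rect half-open box `c(x0, y0, x1, y1)`, at least 8 x 8 px.
#' @param group_size 2 or 4.
#' @param seed integer seed.
#' @return A `group_size x 2` matrix of `(row, col)` glyph centres.
#' @export
tangency_points <- function(rect, group_size, seed = 1L) {
  stop_if_not(group_size %in% c(2L, 4L), "group_size must be 2 or 4")
  stop_if_not(rect[3] - rect[1] >= 8 && rect[4] - rect[2] >= 8,
              "rect must be at least 8 x 8 px")
  with_seed(seed, {
    rows <- sample(seq.int(rect[2], rect[4] - 1L), 2, replace = TRUE)
    pts <- rbind(
      left  = c(rows[1], rect[1]),
      right = c(rows[2], rect[3] - 1L)
    )
    if (group_size == 4L) {
      cols <- sample(seq.int(rect[1], rect[3] - 1L), 2, replace = TRUE)
      pts <- rbind(pts,
                   top    = c(rect[2], cols[1]),
                   bottom = c(rect[4] - 1L, cols[2]))
    }
    colnames(pts) <- c("row", "col")
    pts
  })
}

new_marker_group <- function(rect, points, group_size, is_pseudo) {
  structure(list(rect = as.numeric(rect), points = points,
                 group_size = as.integer(group_size),
                 is_pseudo = isTRUE(is_pseudo)), class = "sono_marker_group")
}

#' Burn a clinician-style caliper group at a nodule
#'
#' Marker centres default to the geometric tangency points where the nodule
#' contour touches the sides of its tight external rectangle — the positions
#' clinicians use — so that real annotations carry the contour-tied spatial
#' structure that pseudo groups (random position along each edge) lack.
#' `placement = "edge"` instead draws a seeded-random position along each
#' edge, matching [tangency_points()].
#'
#' @param image matrix in `[0, 1]`.
#' @param nod a [nodule()] whose bbox lies inside the image.
#' @param glyph a [marker_glyph()].
#' @param group_size 2 (left/right) or 4 (all sides).
#' @param seed integer seed (used by `placement = "edge"`).
#' @param placement `"contour"` or `"edge"`.
#' @return A `sono_annotated` list: `image` (glyphs burned in), `groups`
#'   (list of marker groups), `mask` (0/1 matrix of written pixels).
#' @export
annotate_nodule <- function(image, nod, glyph = marker_glyph(),
                            group_size = 2L, seed = 1L,
                            placement = c("contour", "edge")) {
  placement <- match.arg(placement)
  stop_if_not(box_inside_image(nod$bbox, nrow(image), ncol(image)),
              "nodule bbox must lie inside the image")
  pts <- if (placement == "contour") {
    tp <- ellipse_tangency_points(nod$center, nod$semi_axes, nod$rotation)
    if (group_size == 2L) tp[c("left", "right"), , drop = FALSE] else tp
  } else {
    tangency_points(nod$bbox, group_size, seed)
  }
  stop_if_not(nrow(pts) == group_size, "group_size must be 2 or 4")
  burn_group(image, nod$bbox, pts, glyph, is_pseudo = FALSE)
}

# Burn a set of glyphs belonging to one group and assemble a sono_annotated.
burn_group <- function(image, rect, pts, glyph, is_pseudo) {
  mask <- matrix(0L, nrow(image), ncol(image))
  for (i in seq_len(nrow(pts))) {
    b <- burn_glyph(image, pts[i, ], glyph)
    image <- b$image
    mask[b$pixels] <- 1L
  }
  grp <- new_marker_group(rect, pts, nrow(pts), is_pseudo)
  structure(list(image = image, groups = list(grp), mask = mask),
            class = "sono_annotated")
}

#' Annotate every nodule of a phantom image
#'
#' Convenience wrapper over [annotate_nodule()]: one caliper group per
#' nodule, with group size drawn uniformly from `{2, 4}`.
#'
#' @param image matrix in `[0, 1]`.
#' @param nodules list of [nodule()] objects.
#' @inheritParams annotate_nodule
#' @return A `sono_annotated` with one group per nodule.
#' @export
annotate_image <- function(image, nodules, glyph = marker_glyph(), seed = 1L,
                           placement = c("contour", "edge")) {
  placement <- match.arg(placement)
  seeds <- child_seeds(seed, length(nodules) + 1L)
  gsizes <- with_seed(seeds[length(nodules) + 1L],
                      sample(c(2L, 4L), length(nodules), replace = TRUE))
  groups <- list()
  mask <- matrix(0L, nrow(image), ncol(image))
  for (i in seq_along(nodules)) {
    a <- annotate_nodule(image, nodules[[i]], glyph, gsizes[i], seeds[i],
                         placement)
    image <- a$image
    mask <- pmax(mask, a$mask)
    groups <- c(groups, a$groups)
  }
  structure(list(image = image, groups = groups, mask = mask),
            class = "sono_annotated")
}

#' Generate a pseudo marker group away from all true nodules
#'
#' Draws a pseudo annotation rectangle whose width and height do not exceed
#' the largest nodule box dimensions and whose IoU with every existing
#' nodule box is exactly 0, then places a caliper group of size 2 or 4
#' (drawn uniformly) at random edge positions.
#'
#' @param image matrix (defines the admissible area).
#' @param nodules list of [nodule()]s whose boxes must stay untouched (may
#'   be empty).
#' @param max_dims `c(w, h)`: dimensions of the largest nodule box in the
#'   training set.
#' @param seed integer seed.
#' @param max_attempts rejection-sampling cap.
#' @return A `sono_marker_group` with `is_pseudo = TRUE`.
#' @export
generate_pseudo_group <- function(image, nodules, max_dims, seed = 1L,
                                  max_attempts = 200L) {
  h <- nrow(image); w <- ncol(image)
  boxes <- lapply(nodules, `[[`, "bbox")
  stop_if_not(all(max_dims >= 8), "max_dims must allow at least an 8 x 8 rect")
  with_seed(seed, {
    for (attempt in seq_len(max_attempts)) {
      rw <- sample(seq.int(8L, max(8L, floor(max_dims[1]))), 1)
      rh <- sample(seq.int(8L, max(8L, floor(max_dims[2]))), 1)
      if (rw > w - 2 || rh > h - 2) next
      x0 <- sample(seq.int(1L, w - rw - 1L), 1)
      y0 <- sample(seq.int(1L, h - rh - 1L), 1)
      rect <- c(x0, y0, x0 + rw, y0 + rh)
      ok <- all(vapply(boxes, function(b) box_iou(rect, b) == 0, logical(1)))
      if (!ok) next
      gs <- sample(c(2L, 4L), 1)
      pts <- tangency_points(rect, gs,
                             sample.int(.Machine$integer.max - 1L, 1))
      return(new_marker_group(rect, pts, gs, is_pseudo = TRUE))
    }
    stop(sprintf("no valid pseudo-group placement after %d attempts", max_attempts),
         call. = FALSE)
  })
}

#' Rasterize marker groups into a binary mask
#'
#' Union of the glyph footprints of all group points, optionally dilated by
#' a Chebyshev radius. With `dilation = 0` the exact burned footprint is
#' reproduced.
#'
#' @param groups list of marker groups (or a single group).
#' @param glyph the [marker_glyph()] that was burned.
#' @param shape `c(h, w)` of the mask.
#' @param dilation dilation radius in pixels (non-negative).
#' @param extra_points optional `(row, col)` matrix of loose glyph centres
#'   (e.g. mixup scatter markers) to include.
#' @return An integer 0/1 matrix.
#' @export
marker_mask <- function(groups, glyph, shape, dilation = 0,
                        extra_points = NULL) {
  stop_if_not(dilation >= 0, "dilation must be non-negative")
  if (inherits(groups, "sono_marker_group")) groups <- list(groups)
  mask <- matrix(0L, shape[1], shape[2])
  pts <- do.call(rbind, c(lapply(groups, `[[`, "points"), list(extra_points)))
  if (!is.null(pts) && nrow(pts) > 0) {
    for (i in seq_len(nrow(pts))) {
      b <- burn_glyph(mask, pts[i, ], marker_glyph(glyph$shape,
                                                   glyph$arm_length,
                                                   glyph$thickness, 1),
                      warn_clip = FALSE)
      mask <- b$image
      mask[b$pixels] <- 1L
    }
  }
  storage.mode(mask) <- "integer"
  if (dilation > 0) mask <- .cpp_dilate(mask, as.integer(dilation))
  mask
}

#' Destroy the marker/nodule spatial association by random mixup
#'
#' For each real caliper group, keeps exactly one of two markers (or a
#' uniformly drawn 1--3 of four markers), erases the removed glyphs by
#' texture-synthesis inpainting, and burns the same number of replacement
#' glyphs at seeded-random positions whose footprints have IoU 0 with every
#' nodule box.
#'
#' @param annotated a `sono_annotated` with at least one real group.
#' @param glyph the [marker_glyph()] that was burned.
#' @param seed integer seed.
#' @param params [texsynth_params()] for erasing removed glyphs.
#' @param max_attempts placement cap per replacement glyph.
#' @return A `sono_annotated` whose groups retain only the kept points, with
#'   an extra `scatter` element (`(row, col)` matrix of replacement glyph
#'   centres) and the mask updated consistently.
#' @export
mixup_markers <- function(annotated, glyph = marker_glyph(), seed = 1L,
                          params = texsynth_params(), max_attempts = 200L) {
  real <- Filter(function(g) !g$is_pseudo, annotated$groups)
  stop_if_not(length(real) >= 1, "annotated must contain at least one real group")
  nod_boxes <- lapply(real, `[[`, "rect")
  h <- nrow(annotated$image); w <- ncol(annotated$image)
  seeds <- child_seeds(seed, 3L)

  kept_groups <- list()
  removed_pts <- NULL
  n_removed_per_group <- integer(0)
  with_seed(seeds[1], {
    for (g in annotated$groups) {
      if (g$is_pseudo) { kept_groups <- c(kept_groups, list(g)); next }
      n <- nrow(g$points)
      n_keep <- if (g$group_size == 2L) 1L else sample(1:3, 1)
      n_keep <- min(n_keep, n)
      keep_idx <- sort(sample.int(n, n_keep))
      kept <- g$points[keep_idx, , drop = FALSE]
      removed <- g$points[setdiff(seq_len(n), keep_idx), , drop = FALSE]
      removed_pts <- rbind(removed_pts, removed)
      n_removed_per_group <- c(n_removed_per_group, nrow(removed))
      kept_groups <- c(kept_groups,
                       list(new_marker_group(g$rect, kept, g$group_size,
                                             g$is_pseudo)))
    }
  })

  image <- annotated$image
  kept_mask <- marker_mask(kept_groups, glyph, c(h, w), dilation = 0)
  if (!is.null(removed_pts) && nrow(removed_pts) > 0) {
    rem_mask <- marker_mask(list(), glyph, c(h, w), extra_points = removed_pts)
    rem_mask[kept_mask == 1L] <- 0L  # do not erase pixels shared with kept glyphs
    rem_mask <- .cpp_dilate(rem_mask, 1L)
    rem_mask[kept_mask == 1L] <- 0L
    res <- inpaint_texture(image, rem_mask, params, seed = seeds[2])
    image <- res$image
  }

  # Replacement glyphs at random positions, footprint IoU 0 with all nodules.
  arm <- glyph$arm_length
  scatter <- NULL
  n_add <- sum(n_removed_per_group)
  with_seed(seeds[3], {
    for (k in seq_len(n_add)) {
      placed <- FALSE
      for (attempt in seq_len(max_attempts)) {
        r <- sample(seq.int(arm, h - arm - 1L), 1)
        cc <- sample(seq.int(arm, w - arm - 1L), 1)
        fp <- c(cc - arm, r - arm, cc + arm + 1L, r + arm + 1L)
        ok <- all(vapply(nod_boxes, function(b) box_iou(fp, b) == 0,
                         logical(1)))
        if (ok) {
          scatter <- rbind(scatter, c(row = r, col = cc))
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        stop(sprintf("no valid replacement-marker position after %d attempts",
                     max_attempts), call. = FALSE)
      }
    }
  })

  for (i in seq_len(NROW(scatter))) {
    b <- burn_glyph(image, scatter[i, ], glyph)
    image <- b$image
  }
  mask <- marker_mask(kept_groups, glyph, c(h, w), extra_points = scatter)
  structure(list(image = image, groups = kept_groups, mask = mask,
                 scatter = scatter), class = "sono_annotated")
}
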