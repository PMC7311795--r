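# Box and ellipse geometry shared by every module.
#
# Conventions (package-wide): 0-based (row, col) pixel indices; boxes are
# half-open integer rectangles c(x0, y0, x1, y1) with x = col and y = row,
# covering columns x0..x1-1 and rows y0..y1-1.

#' Intersection over union of two boxes
#'
#' Boxes are half-open `c(x0, y0, x1, y1)` rectangles in pixels. Disjoint
#' boxes have IoU 0; degenerate (zero-area) boxes are rejected, since both
#' the marker-placement constraints and the detection matching rule are
#' defined on proper rectangles.
#'
#' @param boxA,boxB numeric length-4 vectors `c(x0, y0, x1, y1)`, half-open.
#' @return IoU in `[0, 1]`.
#' @examples
#' box_iou(c(0, 0, 10, 10), c(5, 0, 15, 10)) # 1/3
#' @export
box_iou <- function(boxA, boxB) {
  stop_if_not(length(boxA) == 4 && length(boxB) == 4, "boxes must have length 4")
  aA <- box_area(boxA)
  aB <- box_area(boxB)
  stop_if_not(aA > 0 && aB > 0, "degenerate (zero-area) box")
  ix0 <- max(boxA[1], boxB[1]); iy0 <- max(boxA[2], boxB[2])
  ix1 <- min(boxA[3], boxB[3]); iy1 <- min(boxA[4], boxB[4])
  iw <- max(0, ix1 - ix0); ih <- max(0, iy1 - iy0)
  inter <- iw * ih
  inter / (aA + aB - inter)
}

box_area <- function(box) {
  max(0, box[3] - box[1]) * max(0, box[4] - box[2])
}

box_inside_image <- function(box, height, width) {
  box[1] >= 0 && box[2] >= 0 && box[3] <= width && box[4] <= height &&
    box[1] < box[3] && box[2] < box[4]
}

# Continuous half-extents of a rotated ellipse along x (col) and y (row).
ellipse_half_extents <- function(a, b, rotation) {
  c(
    hw = sqrt((a * cos(rotation))^2 + (b * sin(rotation))^2),
    hh = sqrt((a * sin(rotation))^2 + (b * cos(rotation))^2)
  )
}

#' Tight axis-aligned bounding box of a rotated ellipse
#'
#' @param center `c(row, col)` ellipse centre in pixels.
#' @param semi_axes `c(a, b)` semi-axis lengths in pixels.
#' @param rotation radians, counter-clockwise about the centre.
#' @return integer half-open box `c(x0, y0, x1, y1)`.
#' @export
ellipse_bbox <- function(center, semi_axes, rotation) {
  he <- ellipse_half_extents(semi_axes[1], semi_axes[2], rotation)
  cx <- center[2]; cy <- center[1]
  c(
    floor(cx - he[["hw"]]), floor(cy - he[["hh"]]),
    floor(cx + he[["hw"]]) + 1, floor(cy + he[["hh"]]) + 1
  )
}

# Parametric boundary points of a rotated ellipse: t in [0, 2*pi).
ellipse_boundary <- function(center, semi_axes, rotation, n = 2048L) {
  t <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  a <- semi_axes[1]; b <- semi_axes[2]
  x <- center[2] + a * cos(rotation) * cos(t) - b * sin(rotation) * sin(t)
  y <- center[1] + a * sin(rotation) * cos(t) + b * cos(rotation) * sin(t)
  cbind(row = y, col = x)
}

# Contour tangency points: where the ellipse touches the four sides of its
# tight external rectangle (the classic clinician caliper positions).
# Returns a 4 x 2 (row, col) matrix named left, right, top, bottom.
ellipse_tangency_points <- function(center, semi_axes, rotation) {
  p <- ellipse_boundary(center, semi_axes, rotation)
  out <- rbind(
    left   = p[which.min(p[, "col"]), ],
    right  = p[which.max(p[, "col"]), ],
    top    = p[which.min(p[, "row"]), ],
    bottom = p[which.max(p[, "row"]), ]
  )
  round(out)
}
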