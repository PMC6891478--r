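#' Axis-aligned box algebra: IoU, GIoU and the GIoU coordinate loss
#'
#' Boxes are axis-aligned rectangles in a shared continuous frame (pixel or
#' normalized coordinates), represented as numeric vectors
#' `c(x_min, y_min, x_max, y_max)` or as n x 4 matrices with one box per row.
#' Degenerate (zero-area) boxes are permitted and can be flagged with
#' [is_degenerate_box()]; ratios involving a zero-area union are an error.
#'
#' @name geometry
NULL

.box_mat <- function(b) {
  if (is.matrix(b)) {
    if (ncol(b) != 4L) stop("box matrix must have 4 columns")
    storage.mode(b) <- "double"
    return(b)
  }
  b <- as.numeric(b)
  if (length(b) != 4L) stop("a box is c(x_min, y_min, x_max, y_max)")
  matrix(b, ncol = 4L)
}

#' Construct and validate a box
#'
#' @param x_min,y_min,x_max,y_max corners; `x_min <= x_max`, `y_min <= y_max`.
#' @return numeric vector `c(x_min, y_min, x_max, y_max)`.
#' @export
box <- function(x_min, y_min, x_max, y_max) {
  b <- c(x_min, y_min, x_max, y_max)
  validate_box(b)
  b
}

#' @rdname box
#' @param b a box vector or n x 4 matrix.
#' @export
validate_box <- function(b) {
  m <- .box_mat(b)
  if (anyNA(m)) stop("box coordinates must be finite")
  if (any(m[, 3] < m[, 1]) || any(m[, 4] < m[, 2]))
    stop("invalid box: x_min > x_max or y_min > y_max")
  invisible(b)
}

#' Box area
#' @param b box vector or n x 4 matrix
#' @return numeric vector of areas (>= 0)
#' @export
box_area <- function(b) {
  m <- .box_mat(b)
  (m[, 3] - m[, 1]) * (m[, 4] - m[, 2])
}

#' Flag degenerate (zero-area) boxes
#' @inheritParams box_area
#' @return logical vector
#' @export
is_degenerate_box <- function(b) box_area(b) <= 0

.pair_prep <- function(b, g) {
  bm <- .box_mat(b); gm <- .box_mat(g)
  n <- max(nrow(bm), nrow(gm))
  if (nrow(bm) == 1L && n > 1L) bm <- bm[rep(1L, n), , drop = FALSE]
  if (nrow(gm) == 1L && n > 1L) gm <- gm[rep(1L, n), , drop = FALSE]
  if (nrow(bm) != nrow(gm)) stop("box counts do not match and neither is 1")
  list(b = bm, g = gm)
}

.intersect_area <- function(bm, gm) {
  iw <- pmin(bm[, 3], gm[, 3]) - pmax(bm[, 1], gm[, 1])
  ih <- pmin(bm[, 4], gm[, 4]) - pmax(bm[, 2], gm[, 2])
  pmax(iw, 0) * pmax(ih, 0)
}

#' Intersection over union of two boxes
#'
#' `|B intersect G| / |B union G|`. A degenerate box against a non-degenerate
#' one has IoU 0; two degenerate boxes (zero union area) are an error of
#' class `"poppydetect_undefined_ratio"`.
#'
#' @param b,g boxes (vector or n x 4 matrix; one side may be a single box).
#' @return numeric vector in \[0, 1\].
#' @export
box_iou <- function(b, g) {
  p <- .pair_prep(b, g)
  ab <- box_area(p$b); ag <- box_area(p$g)
  inter <- .intersect_area(p$b, p$g)
  un <- ab + ag - inter
  if (any(un <= 0)) {
    stop(errorCondition("IoU undefined: both boxes degenerate (zero union area)",
                        class = c("poppydetect_undefined_ratio", "error")))
  }
  inter / un
}

.enclosing_mat <- function(bm, gm) {
  cbind(pmin(bm[, 1], gm[, 1]), pmin(bm[, 2], gm[, 2]),
        pmax(bm[, 3], gm[, 3]), pmax(bm[, 4], gm[, 4]))
}

#' Smallest axis-aligned box enclosing two boxes
#' @inheritParams box_iou
#' @return box vector (or n x 4 matrix for matrix input)
#' @export
enclosing_box <- function(b, g) {
  p <- .pair_prep(b, g)
  e <- .enclosing_mat(p$b, p$g)
  if (nrow(e) == 1L) as.numeric(e) else e
}

#' Generalized intersection over union
#'
#' `GIoU = IoU - (|C| - |B union G|) / |C|` where `C` is the smallest
#' enclosing axis-aligned rectangle. Range `(-1, 1]`; equals IoU when the
#' enclosing box coincides with the union, and tends to -1 as two fixed-size
#' boxes are pulled infinitely far apart.
#'
#' @inheritParams box_iou
#' @return numeric vector in (-1, 1\].
#' @export
box_giou <- function(b, g) {
  p <- .pair_prep(b, g)
  iou <- box_iou(p$b, p$g)
  e <- .enclosing_mat(p$b, p$g)
  ca <- (e[, 3] - e[, 1]) * (e[, 4] - e[, 2])
  if (any(ca <= 0)) {
    stop(errorCondition("GIoU undefined: zero enclosing area",
                        class = c("poppydetect_undefined_ratio", "error")))
  }
  un <- box_area(p$b) + box_area(p$g) - .intersect_area(p$b, p$g)
  iou - (ca - un) / ca
}

#' GIoU coordinate loss, `1 - GIoU`
#'
#' Zero iff the boxes coincide; strictly below 2 for any finite pair.
#' @inheritParams box_iou
#' @return numeric vector in \[0, 2).
#' @export
coord_loss <- function(b, g) 1 - box_giou(b, g)

#' Analytic gradient of GIoU with respect to the first box's corners
#'
#' Piecewise-exact subgradient used by the training loss; validated against
#' central finite differences in the test suite.
#'
#' @inheritParams box_iou
#' @return n x 4 matrix `d GIoU / d (x_min, y_min, x_max, y_max)` of `b`.
#' @export
box_giou_grad <- function(b, g) {
  p <- .pair_prep(b, g)
  bm <- p$b; gm <- p$g
  iw <- pmin(bm[, 3], gm[, 3]) - pmax(bm[, 1], gm[, 1])
  ih <- pmin(bm[, 4], gm[, 4]) - pmax(bm[, 2], gm[, 2])
  inter_pos <- iw > 0 & ih > 0
  iwp <- pmax(iw, 0); ihp <- pmax(ih, 0)
  inter <- iwp * ihp
  ab <- box_area(bm); ag <- box_area(gm)
  un <- ab + ag - inter
  ew <- pmax(bm[, 3], gm[, 3]) - pmin(bm[, 1], gm[, 1])
  eh <- pmax(bm[, 4], gm[, 4]) - pmin(bm[, 2], gm[, 2])
  ca <- ew * eh

  # dI/d corner (zero unless the corner is the active bound and inter > 0)
  dI <- cbind(-(bm[, 1] > gm[, 1]) * ihp,
              -(bm[, 2] > gm[, 2]) * iwp,
              (bm[, 3] < gm[, 3]) * ihp,
              (bm[, 4] < gm[, 4]) * iwp)
  dI <- dI * inter_pos
  # dAb/d corner
  dA <- cbind(-(bm[, 4] - bm[, 2]), -(bm[, 3] - bm[, 1]),
              bm[, 4] - bm[, 2], bm[, 3] - bm[, 1])
  dU <- dA - dI
  dIoU <- (dI * un - inter * dU) / un^2
  # dC/d corner (active when b's corner defines the enclosing box)
  dC <- cbind(-(bm[, 1] < gm[, 1]) * eh,
              -(bm[, 2] < gm[, 2]) * ew,
              (bm[, 3] > gm[, 3]) * eh,
              (bm[, 4] > gm[, 4]) * ew)
  # d[(C - U)/C] = (dC*U - dU*C)/C^2  ... since (C-U)/C = 1 - U/C
  dPen <- (dC * un - dU * ca) / ca^2
  dIoU - dPen
}

#' Convert between corner and center/width/height box forms
#'
#' @param cx,cy,w,h center coordinates and sizes
#' @return `box_from_cwh()` a corner box; `box_to_cwh()` a vector/matrix
#'   `(cx, cy, w, h)`.
#' @export
box_from_cwh <- function(cx, cy, w, h) {
  m <- cbind(cx - w / 2, cy - h / 2, cx + w / 2, cy + h / 2)
  if (nrow(m) == 1L) as.numeric(m) else m
}

#' @rdname box_from_cwh
#' @param b corner box (vector or matrix)
#' @export
box_to_cwh <- function(b) {
  m <- .box_mat(b)
  out <- cbind((m[, 1] + m[, 3]) / 2, (m[, 2] + m[, 4]) / 2,
               m[, 3] - m[, 1], m[, 4] - m[, 2])
  if (nrow(out) == 1L) as.numeric(out) else out
}

#' Clip a box to bounds
#' @param b box (vector or matrix)
#' @param x_max,y_max upper bounds (lower bounds are 0)
#' @export
clip_box <- function(b, x_max, y_max) {
  m <- .box_mat(b)
  out <- cbind(pmin(pmax(m[, 1], 0), x_max), pmin(pmax(m[, 2], 0), y_max),
               pmin(pmax(m[, 3], 0), x_max), pmin(pmax(m[, 4], 0), y_max))
  if (nrow(out) == 1L) as.numeric(out) else out
}
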