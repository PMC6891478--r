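#' Sliding-window inference
#'
#' Full UAV frames (e.g. 5472 x 3648) are far larger than the 416 x 416
#' detector input; resizing would destroy the few-pixel texture that
#' separates poppy plots from background. Frames are therefore tiled with
#' non-overlapping 416 px windows (stride = window size); when a frame
#' dimension is not a multiple of the stride, one final column/row of
#' windows is anchored flush to the right/bottom edge so every pixel is
#' covered without injecting synthetic padding. Per-window detections are
#' translated to frame coordinates and a second NMS pass removes
#' duplicates across window seams.
#'
#' @name inference
NULL

#' Plan sliding windows over a frame
#'
#' @param W,H frame size in pixels
#' @param w window side (default 416)
#' @param s stride (default 416: non-overlapping)
#' @return data frame of 0-based `(x, y)` window offsets; attribute
#'   `fallback_resize` is `TRUE` when the frame is smaller than the window
#'   (a single resized window is then used, with a warning)
#' @export
plan_windows <- function(W, H, w = 416L, s = 416L) {
  W <- as.integer(W); H <- as.integer(H); w <- as.integer(w); s <- as.integer(s)
  if (w > W || w > H) {
    warning("frame ", W, " x ", H, " smaller than window ", w,
            "; falling back to a single resized window")
    plan <- data.frame(x = 0L, y = 0L)
    attr(plan, "window") <- w
    attr(plan, "fallback_resize") <- TRUE
    return(plan)
  }
  offsets <- function(total) {
    xs <- seq.int(0L, total - w, by = s)
    if (max(xs) + w < total) xs <- c(xs, total - w)  # edge-anchored remainder
    xs
  }
  plan <- expand.grid(x = offsets(W), y = offsets(H))
  attr(plan, "window") <- w
  attr(plan, "fallback_resize") <- FALSE
  plan
}

#' Greedy non-maximum suppression
#'
#' @param boxes n x 4 corner matrix
#' @param scores numeric scores
#' @param iou_thresh suppression threshold (default 0.45)
#' @return integer indices of kept boxes, in decreasing score order
#' @export
nms <- function(boxes, scores, iou_thresh = 0.45) {
  if (NROW(boxes) == 0L) return(integer(0))
  boxes <- .box_mat(boxes)
  ord <- order(scores, seq_along(scores), decreasing = c(TRUE, FALSE),
               method = "radix")
  keep <- integer(0)
  while (length(ord)) {
    i <- ord[1]
    keep <- c(keep, i)
    ord <- ord[-1]
    if (!length(ord)) break
    iou <- box_iou(boxes[ord, , drop = FALSE], boxes[i, , drop = FALSE])
    ord <- ord[iou <= iou_thresh]
  }
  keep
}

.empty_detections <- function() {
  data.frame(x_min = numeric(0), y_min = numeric(0), x_max = numeric(0),
             y_max = numeric(0), score = numeric(0), label = character(0),
             stringsAsFactors = FALSE)
}

#' Raw prediction grids for an input image
#'
#' S3 entry point so tests can substitute an oracle scorer: the method for
#' `poppy_detector` runs the network; the method for `function` calls the
#' function (which must return the list of raw grids).
#'
#' @param object a `poppy_detector` or a stub `function(img) -> grids`
#' @param img input raster
#' @param ... unused
#' @export
predict_grids <- function(object, img, ...) UseMethod("predict_grids")

#' @export
predict_grids.poppy_detector <- function(object, img, ...) {
  forward_detector(object, img)$grids
}

#' @export
predict_grids.function <- function(object, img, ...) object(img)

.detector_cfg <- function(object) {
  if (inherits(object, "poppy_detector")) object$cfg
  else attr(object, "cfg")
}

#' Detect objects in one detector-sized window
#'
#' Decodes all three grids, keeps detections whose score
#' (objectness x best class probability) reaches `conf_thresh`, and
#' applies greedy per-class NMS.
#'
#' @param detector a `poppy_detector` (or stub, see [predict_grids()])
#' @param window `[S, S, 3]` raster of the detector's input size
#' @param conf_thresh score threshold (default 0.3)
#' @param nms_iou NMS IoU threshold (default 0.45)
#' @return detection data frame: `x_min,y_min,x_max,y_max` (window pixels),
#'   `score`, `label`
#' @export
detect_window <- function(detector, window, conf_thresh = 0.3,
                          nms_iou = 0.45) {
  cfg <- .detector_cfg(detector)
  grids <- predict_grids(detector, window)
  all <- lapply(seq_along(grids), function(s) {
    dec <- decode_grid(grids[[s]], scale_anchors(cfg, s))
    cls <- max.col(dec$class_probs, ties.method = "first")
    sc <- dec$confidence * dec$class_probs[cbind(seq_along(cls), cls)]
    keep <- which(sc >= conf_thresh)
    if (!length(keep)) return(NULL)
    data.frame(x_min = dec$boxes[keep, 1], y_min = dec$boxes[keep, 2],
               x_max = dec$boxes[keep, 3], y_max = dec$boxes[keep, 4],
               score = sc[keep], label = cfg$labels[cls[keep]],
               stringsAsFactors = FALSE)
  })
  dets <- do.call(rbind, all)
  if (is.null(dets) || nrow(dets) == 0L) return(.empty_detections())
  size <- cfg$input_size
  dets[, 1:4] <- clip_box(as.matrix(dets[, 1:4]) * size, size, size)
  out <- lapply(split(dets, dets$label), function(d) {
    d[nms(as.matrix(d[, 1:4]), d$score, nms_iou), , drop = FALSE]
  })
  out <- do.call(rbind, out)
  out <- out[order(-out$score, out$x_min, out$y_min), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect objects in a full frame via sliding windows
#'
#' @param detector a `poppy_detector` (or stub)
#' @param frame `[H, W, 3]` raster
#' @param plan window plan from [plan_windows()]; `NULL` plans
#'   automatically with the detector input size as window and stride
#' @param conf_thresh,nms_iou as in [detect_window()]
#' @return detections in frame pixel coordinates, ordered by decreasing
#'   score then x, y
#' @export
detect_frame <- function(detector, frame, plan = NULL, conf_thresh = 0.3,
                         nms_iou = 0.45) {
  cfg <- .detector_cfg(detector)
  d <- dim(frame)
  size <- cfg$input_size
  if (is.null(plan)) plan <- plan_windows(d[2], d[1], size, size)
  if (isTRUE(attr(plan, "fallback_resize"))) {
    win <- resize_image(frame, size, size)
    dets <- detect_window(detector, win, conf_thresh, nms_iou)
    if (nrow(dets)) {
      dets$x_min <- dets$x_min * d[2] / size; dets$x_max <- dets$x_max * d[2] / size
      dets$y_min <- dets$y_min * d[1] / size; dets$y_max <- dets$y_max * d[1] / size
    }
    return(dets)
  }
  all <- lapply(seq_len(nrow(plan)), function(k) {
    x0 <- plan$x[k]; y0 <- plan$y[k]
    win <- frame[(y0 + 1):(y0 + size), (x0 + 1):(x0 + size), , drop = FALSE]
    dets <- detect_window(detector, win, conf_thresh, nms_iou)
    if (nrow(dets)) {
      dets$x_min <- dets$x_min + x0; dets$x_max <- dets$x_max + x0
      dets$y_min <- dets$y_min + y0; dets$y_max <- dets$y_max + y0
    }
    dets
  })
  dets <- do.call(rbind, all)
  if (is.null(dets) || nrow(dets) == 0L) return(.empty_detections())
  # cross-seam NMS: objects straddling window borders are detected twice
  out <- lapply(split(dets, dets$label), function(dd) {
    dd[nms(as.matrix(dd[, 1:4]), dd$score, nms_iou), , drop = FALSE]
  })
  out <- do.call(rbind, out)
  out <- out[order(-out$score, out$x_min, out$y_min), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write detections as a tab-separated table
#' @param dets detection data frame
#' @param path output path
#' @param image image identifier stored in the first column
#' @export
write_detections <- function(dets, path, image = "") {
  out <- cbind(image = rep(image, nrow(dets)), dets)
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
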