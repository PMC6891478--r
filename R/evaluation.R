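#' Detector evaluation: matching, PR curve, AP50, F2
#'
#' Detections are matched to ground truths greedily in descending score: a
#' detection is a true positive when its best-IoU *unmatched* ground truth
#' reaches the IoU threshold (0.5 for AP50), otherwise a false positive;
#' each ground truth can be matched at most once and unmatched ground
#' truths are false negatives. The average precision is the area under the
#' confidence-swept PR curve with the monotone precision envelope
#' (all-points interpolation, an exact rectangle sum). The F-beta score
#' `(1 + beta^2) P R / (beta^2 P + R)` with `beta = 2` weights recall —
#' missing an illicit plot costs more than a false alarm — and the
#' summary statistic is its maximum over confidence cutoffs.
#'
#' @name evaluation
NULL

#' Match detections against ground truths at an IoU threshold
#'
#' @param dets detection data frame (`x_min..y_max`, `score`) or n x 4
#'   matrix plus `scores`
#' @param gts m x 4 matrix of ground-truth boxes
#' @param iou_thresh matching threshold (default 0.5)
#' @param scores scores when `dets` is a matrix
#' @return list: `tp` logical per detection (in the original order),
#'   `matched_gt` index or NA per detection, `gt_matched` logical per
#'   ground truth, counts `TP`, `FP`, `FN`
#' @export
match_detections <- function(dets, gts, iou_thresh = 0.5, scores = NULL) {
  if (is.data.frame(dets)) {
    scores <- dets$score
    dets <- as.matrix(dets[, c("x_min", "y_min", "x_max", "y_max")])
  }
  ngt <- NROW(gts)
  nd <- NROW(dets)
  tp <- logical(nd)
  matched_gt <- rep(NA_integer_, nd)
  gt_taken <- logical(ngt)
  if (nd > 0L) {
    gts <- if (ngt) .box_mat(gts) else gts
    ord <- order(-scores, seq_len(nd))
    for (i in ord) {
      if (!ngt) break
      iou <- box_iou(gts, matrix(dets[i, ], 1))
      iou[gt_taken] <- -1
      j <- which.max(iou)
      if (iou[j] >= iou_thresh) {
        tp[i] <- TRUE
        matched_gt[i] <- j
        gt_taken[j] <- TRUE
      }
    }
  }
  list(tp = tp, matched_gt = matched_gt, gt_matched = gt_taken,
       TP = sum(tp), FP = nd - sum(tp), FN = ngt - sum(gt_taken))
}

#' Precision and recall from a match result
#'
#' Zero denominators yield 0 with the corresponding flag set.
#'
#' @param m result of [match_detections()] (or any list with `TP`, `FP`,
#'   `FN`)
#' @return list `P`, `R`, and flags `undefined_P`, `undefined_R`
#' @export
precision_recall <- function(m) {
  undef_p <- (m$TP + m$FP) == 0
  undef_r <- (m$TP + m$FN) == 0
  list(P = if (undef_p) 0 else m$TP / (m$TP + m$FP),
       R = if (undef_r) 0 else m$TP / (m$TP + m$FN),
       undefined_P = undef_p, undefined_R = undef_r)
}

#' F-beta score
#'
#' @param P,R precision and recall in \[0, 1\]
#' @param beta harmonic weighting; `beta = 2` (the default) emphasises
#'   recall: `F2 = 5PR / (4P + R)`
#' @return score in \[0, 1\]; 0 when `P = R = 0`
#' @export
f_score <- function(P, R, beta = 2) {
  stopifnot(all(P >= 0 & P <= 1), all(R >= 0 & R <= 1), beta > 0)
  num <- (1 + beta^2) * P * R
  den <- beta^2 * P + R
  ifelse(den == 0, 0, num / den)
}

# pooled sweep machinery: dets across images, greedy-matched per image,
# then swept over score cutoffs.
.sweep_curve <- function(det_list, gt_list, iou_thresh) {
  stopifnot(length(det_list) == length(gt_list))
  n_gt <- sum(vapply(gt_list, NROW, 0L))
  if (n_gt == 0L)
    stop("average precision undefined: no ground truths")
  flags <- list(); scores <- list()
  for (k in seq_along(det_list)) {
    d <- det_list[[k]]
    nd <- if (is.null(d)) 0L else NROW(d)
    if (!nd) next
    m <- match_detections(d, gt_list[[k]], iou_thresh)
    sc <- if (is.data.frame(d)) d$score else attr(d, "scores")
    flags[[length(flags) + 1L]] <- m$tp
    scores[[length(scores) + 1L]] <- sc
  }
  tp <- unlist(flags); sc <- unlist(scores)
  if (is.null(tp)) tp <- logical(0)
  if (is.null(sc)) sc <- numeric(0)
  ord <- order(-sc, seq_along(sc))
  tp <- tp[ord]; sc <- sc[ord]
  ctp <- cumsum(tp); cfp <- cumsum(!tp)
  prec <- if (length(tp)) ctp / (ctp + cfp) else numeric(0)
  rec <- if (length(tp)) ctp / n_gt else numeric(0)
  list(score = sc, precision = prec, recall = rec, n_gt = n_gt)
}

#' Average precision (area under the PR curve)
#'
#' @param det_list detections: one data frame per image (a single data
#'   frame is treated as one image)
#' @param gt_list ground truths: one n x 4 matrix per image
#' @param iou_thresh matching threshold; 0.5 gives AP50
#' @return AP in \[0, 1\]
#' @export
average_precision <- function(det_list, gt_list, iou_thresh = 0.5) {
  if (is.data.frame(det_list)) det_list <- list(det_list)
  if (!is.list(gt_list) || is.data.frame(gt_list)) gt_list <- list(gt_list)
  cv <- .sweep_curve(det_list, gt_list, iou_thresh)
  if (!length(cv$recall)) return(0)
  # monotone precision envelope + exact rectangle sum over recall steps
  env <- rev(cummax(rev(cv$precision)))
  r_prev <- c(0, cv$recall[-length(cv$recall)])
  sum((cv$recall - r_prev) * env)
}

#' Mean average precision over classes
#'
#' With a single class this equals [average_precision()].
#'
#' @param det_list,gt_list as in [average_precision()], with a `label`
#'   column / attribute per entry when multi-class
#' @param labels class labels to average over
#' @param iou_thresh matching threshold
#' @export
mean_average_precision <- function(det_list, gt_list, labels = NULL,
                                   iou_thresh = 0.5) {
  if (is.null(labels)) return(average_precision(det_list, gt_list, iou_thresh))
  aps <- vapply(labels, function(lb) {
    dl <- lapply(det_list, function(d) d[d$label == lb, , drop = FALSE])
    gl <- lapply(gt_list, function(g) {
      if (is.data.frame(g))
        as.matrix(g[g$label == lb, c("x_min", "y_min", "x_max", "y_max")])
      else g
    })
    average_precision(dl, gl, iou_thresh)
  }, 0)
  mean(aps)
}

#' Confidence-swept precision/recall/F2 curve
#'
#' @inheritParams average_precision
#' @param beta F-score weighting (default 2)
#' @return object of class `eval_curve`: data frame columns `score`,
#'   `precision`, `recall`, `f`, plus scalars `ap` and `max_f`
#' @export
f2_recall_curve <- function(det_list, gt_list, iou_thresh = 0.5, beta = 2) {
  if (is.data.frame(det_list)) det_list <- list(det_list)
  if (!is.list(gt_list) || is.data.frame(gt_list)) gt_list <- list(gt_list)
  cv <- .sweep_curve(det_list, gt_list, iou_thresh)
  f <- if (length(cv$precision)) f_score(cv$precision, cv$recall, beta)
       else numeric(0)
  structure(list(curve = data.frame(score = cv$score,
                                    precision = cv$precision,
                                    recall = cv$recall, f = f),
                 ap = average_precision(det_list, gt_list, iou_thresh),
                 max_f = if (length(f)) max(f) else 0,
                 beta = beta, n_gt = cv$n_gt),
            class = "eval_curve")
}

#' @export
print.eval_curve <- function(x, ...) {
  cat(sprintf("<eval_curve> %d sweep points, AP %.4f, max F%g %.4f (%d ground truths)\n",
              nrow(x$curve), x$ap, x$beta, x$max_f, x$n_gt))
  invisible(x)
}
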