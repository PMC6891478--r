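# Independent oracles used across the suite. These deliberately avoid the
# package's closed-form code paths.

# Lattice-counting IoU/GIoU: rasterize both boxes on a fine grid of cell
# centres spanning their enclosing box and count cells.
lattice_iou_giou <- function(b, g, res = 200L) {
  ex <- c(min(b[1], g[1]), min(b[2], g[2]), max(b[3], g[3]), max(b[4], g[4]))
  xs <- seq(ex[1], ex[3], length.out = res + 1L)
  ys <- seq(ex[2], ex[4], length.out = res + 1L)
  cx <- (xs[-1] + xs[-length(xs)]) / 2
  cy <- (ys[-1] + ys[-length(ys)]) / 2
  inb <- outer(cy >= b[2] & cy <= b[4], cx >= b[1] & cx <= b[3], "&")
  ing <- outer(cy >= g[2] & cy <= g[4], cx >= g[1] & cx <= g[3], "&")
  cell <- ((ex[3] - ex[1]) / res) * ((ex[4] - ex[2]) / res)
  inter <- sum(inb & ing) * cell
  un <- sum(inb | ing) * cell
  carea <- (ex[3] - ex[1]) * (ex[4] - ex[2])
  list(iou = inter / un, giou = inter / un - (carea - un) / carea)
}

# Brute-force AP: enumerate every score cutoff, compute (P, R) from the
# full match at that cutoff, integrate the staircase with the precision
# envelope computed by exhaustive max over higher-recall points.
brute_force_ap <- function(scores, is_tp, n_gt) {
  ord <- order(-scores, seq_along(scores))
  tp <- is_tp[ord]
  recalls <- cumsum(tp) / n_gt
  precisions <- cumsum(tp) / seq_along(tp)
  ap <- 0
  r_prev <- 0
  for (k in seq_along(tp)) {
    p_env <- max(precisions[k:length(tp)])  # envelope by enumeration
    ap <- ap + (recalls[k] - r_prev) * p_env
    r_prev <- recalls[k]
  }
  ap
}

brute_force_max_f <- function(scores, is_tp, n_gt, beta = 2) {
  cuts <- sort(unique(scores))
  best <- 0
  for (ct in cuts) {
    sel <- scores >= ct
    tp <- sum(is_tp[sel]); fp <- sum(sel) - tp
    P <- if (tp + fp == 0) 0 else tp / (tp + fp)
    R <- tp / n_gt
    f <- if (beta^2 * P + R == 0) 0 else (1 + beta^2) * P * R / (beta^2 * P + R)
    best <- max(best, f)
  }
  best
}

# Max-filter oracle for the SPP pooling (direct window scan, stride 1,
# floor((k-1)/2) top/left padding)
max_filter_oracle <- function(mat, k) {
  S <- nrow(mat)
  pt <- (k - 1) %/% 2
  out <- matrix(-Inf, S, S)
  for (i in seq_len(S)) for (j in seq_len(S)) {
    rows <- max(1, i - pt):min(S, i - pt + k - 1)
    cols <- max(1, j - pt):min(S, j - pt + k - 1)
    out[i, j] <- max(mat[rows, cols])
  }
  out
}

random_box <- function(lim = 10) {
  x <- sort(runif(2, 0, lim)); y <- sort(runif(2, 0, lim))
  c(x[1], y[1], x[2], y[2])
}

# small detector configuration used across network/training tests
tiny_cfg <- function(...) {
  detector_config(input_size = 96L, width_mult = 0.15, ...)
}

# deterministic stub detector: one perfect box per planted object,
# implemented as a function + cfg attribute (see predict_grids.function)
stub_from_boxes <- function(cfg, boxes_norm, score_logit = 4) {
  force(boxes_norm)
  f <- function(img) {
    sizes <- grid_sizes(cfg)
    grids <- lapply(seq_len(3), function(s) {
      S <- sizes[s]
      array(-20, c(S, S, cfg$n_anchors, 5L + cfg$classes))
    })
    if (NROW(boxes_norm)) {
      for (i in seq_len(nrow(boxes_norm))) {
        b <- boxes_norm[i, ]
        anc <- scale_anchors(cfg, 1)[1, ]
        enc <- encode_box(b, sizes[1], anc)
        grids[[1]][enc$row, enc$col, 1, 1:4] <- enc$raw
        grids[[1]][enc$row, enc$col, 1, 5] <- score_logit
        grids[[1]][enc$row, enc$col, 1, 6] <- 10
      }
    }
    grids
  }
  attr(f, "cfg") <- cfg
  f
}
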