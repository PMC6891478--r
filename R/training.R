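#' Loss assembly and the training protocol
#'
#' The composite loss is `Loss = Coordloss + Confloss + Classloss`:
#' the coordinate term sums `1 - GIoU` between each responsible predictor's
#' decoded box and its ground truth (an MSE ablation switch reproduces the
#' classic parameterized regression); the confidence term is a squared
#' error on sigmoid objectness with weight `lambda_noobj` on the
#' object-free predictors; the classification term is a squared error on
#' sigmoid class scores at responsible predictors. Each ground truth is
#' owned by exactly one (scale, cell, anchor): the anchor of highest shape
#' IoU at the cell containing the box center.
#'
#' Training follows an Adam + plateau protocol: learning rate times 0.1
#' when validation loss has not improved for `patience_lr` epochs, early
#' stop after `patience_stop` epochs, optional warm start in which a first
#' phase trains with the MSE coordinate loss and the GIoU phase starts
#' from those weights (GIoU from random initialization is prone to
#' vanishing gradients).
#'
#' @name training
NULL

#' Training protocol settings
#'
#' Defaults: Adam (`beta1` 0.9, `beta2` 0.999, weight decay 1e-4), initial
#' learning rate 0.001, times 0.1 after 20 stagnant epochs, early stop
#' after 50, at most 500 epochs, batch size 8.
#'
#' @param learning_rate,beta1,beta2,weight_decay Adam settings
#' @param patience_lr epochs of stagnant validation loss before the
#'   learning rate is multiplied by `lr_factor`
#' @param lr_factor multiplicative plateau factor (default 0.1)
#' @param patience_stop epochs of stagnation before early stop; must
#'   exceed `patience_lr`
#' @param max_epochs,batch_size run length and minibatch size
#' @return object of class `train_protocol`
#' @export
train_protocol <- function(learning_rate = 0.001, beta1 = 0.9, beta2 = 0.999,
                           weight_decay = 1e-4, patience_lr = 20L,
                           lr_factor = 0.1, patience_stop = 50L,
                           max_epochs = 500L, batch_size = 8L) {
  if (patience_stop <= patience_lr)
    stop("patience_stop must exceed patience_lr")
  if (learning_rate <= 0) stop("learning_rate must be positive")
  structure(list(learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 weight_decay = weight_decay, patience_lr = patience_lr,
                 lr_factor = lr_factor, patience_stop = patience_stop,
                 max_epochs = max_epochs, batch_size = batch_size),
            class = "train_protocol")
}

.shape_iou_vec <- function(wh, anchors) {
  iw <- outer(wh[, 1], anchors[, 1], pmin)
  ih <- outer(wh[, 2], anchors[, 2], pmin)
  inter <- iw * ih
  un <- outer(wh[, 1] * wh[, 2], anchors[, 1] * anchors[, 2], "+") - inter
  inter / un
}

#' Assign ground truths to responsible predictors
#'
#' @param boxes n x 4 matrix of normalized corner boxes
#' @param classes integer class ids (1-based), recycled if length 1
#' @param cfg a `detector_config`
#' @return list of per-scale targets: `obj` `[S,S,B]` logical mask,
#'   `gt` `[S,S,B,4]` normalized corner boxes, `cls` `[S,S,B]` integer,
#'   plus a `collisions` count attribute
#' @export
assign_targets <- function(boxes, classes = 1L, cfg) {
  stopifnot(inherits(cfg, "detector_config"))
  sizes <- grid_sizes(cfg)
  tg <- lapply(sizes, function(S) {
    list(obj = array(FALSE, c(S, S, cfg$n_anchors)),
         gt = array(NA_real_, c(S, S, cfg$n_anchors, 4L)),
         cls = array(NA_integer_, c(S, S, cfg$n_anchors)))
  })
  collisions <- 0L
  if (!is.null(boxes) && NROW(boxes) > 0L) {
    m <- .box_mat(boxes)
    classes <- rep_len(as.integer(classes), nrow(m))
    cwh <- box_to_cwh(m)
    if (nrow(m) == 1L) cwh <- matrix(cwh, 1L)
    sh <- .shape_iou_vec(cwh[, 3:4, drop = FALSE], cfg$anchors)
    best <- max.col(sh, ties.method = "first")
    # anchors rows 7:9 -> scale 1 (coarse), 4:6 -> 2, 1:3 -> 3
    scale_of <- c(3L, 3L, 3L, 2L, 2L, 2L, 1L, 1L, 1L)
    a_in_scale <- c(1L, 2L, 3L, 1L, 2L, 3L, 1L, 2L, 3L)
    for (i in seq_len(nrow(m))) {
      s <- scale_of[best[i]]; a <- a_in_scale[best[i]]
      S <- sizes[s]
      col <- min(floor(cwh[i, 1] * S), S - 1) + 1L
      row <- min(floor(cwh[i, 2] * S), S - 1) + 1L
      if (tg[[s]]$obj[row, col, a]) {
        collisions <- collisions + 1L
        old_area <- box_area(tg[[s]]$gt[row, col, a, ])
        if (box_area(m[i, , drop = FALSE]) <= old_area) next
      }
      tg[[s]]$obj[row, col, a] <- TRUE
      tg[[s]]$gt[row, col, a, ] <- m[i, ]
      tg[[s]]$cls[row, col, a] <- classes[i]
    }
  }
  if (collisions > 0L)
    message("assign_targets: ", collisions,
            " ground truth(s) collided with an occupied predictor")
  attr(tg, "collisions") <- collisions
  tg
}

.decode_arrays <- function(grid, anchors) {
  d <- dim(grid)
  S <- d[1]; B <- d[3]
  rows <- array(rep(seq_len(S) - 1L, times = S * B), c(S, S, B))
  cols <- array(rep(rep(seq_len(S) - 1L, each = S), times = B), c(S, S, B))
  anc_w <- array(rep(anchors[, 1], each = S * S), c(S, S, B))
  anc_h <- array(rep(anchors[, 2], each = S * S), c(S, S, B))
  sx <- sigmoid(grid[, , , 1]); sy <- sigmoid(grid[, , , 2])
  bw <- anc_w * exp(pmin(grid[, , , 3], 12)); bh <- anc_h * exp(pmin(grid[, , , 4], 12))
  list(bx = (sx + cols) / S, by = (sy + rows) / S, bw = bw, bh = bh,
       sx = sx, sy = sy, rows = rows, cols = cols,
       anc_w = anc_w, anc_h = anc_h)
}

#' Compute the composite detection loss and its gradients
#'
#' @param grids list of raw `[S, S, B, 5 + C]` prediction arrays (coarse
#'   to fine), e.g. from [forward_detector()]
#' @param targets output of [assign_targets()]
#' @param cfg a `detector_config`
#' @param lambda_noobj weight of the no-object confidence term
#'   (default 0.5)
#' @param coord_mode `"giou"` (coordinate term `1 - GIoU` on decoded
#'   boxes) or `"mse"` (squared error on the raw-space parameterization)
#' @param conf_target `"iou"`: the objectness target of a responsible
#'   predictor is its decoded box's IoU with the matched ground truth
#'   (treated as a constant); `"one"`: constant 1
#' @return list with `breakdown` (`coord`, `conf`, `class`, `total`,
#'   `n_obj`) and `grads` (per-scale `[S, S, B, 5 + C]` arrays of
#'   d loss / d raw output)
#' @export
compute_loss <- function(grids, targets, cfg, lambda_noobj = 0.5,
                         coord_mode = c("giou", "mse"),
                         conf_target = c("iou", "one")) {
  coord_mode <- match.arg(coord_mode)
  conf_target <- match.arg(conf_target)
  coord <- conf <- clss <- 0
  n_obj <- 0L
  grads <- vector("list", length(grids))
  for (s in seq_along(grids)) {
    grid <- grids[[s]]
    if (anyNA(grid) || any(!is.finite(grid)))
      stop("NaN/Inf in predictions of scale ", s)
    d <- dim(grid)
    S <- d[1]; B <- d[3]; C <- d[4] - 5L
    anchors <- scale_anchors(cfg, s)
    dec <- .decode_arrays(grid, anchors)
    g <- array(0, d)
    tgt <- targets[[s]]
    obj_idx <- which(tgt$obj)
    n_obj <- n_obj + length(obj_idx)

    # ---- confidence -------------------------------------------------------
    sc <- sigmoid(grid[, , , 5])
    ctar <- array(0, c(S, S, B))
    if (length(obj_idx)) {
      gt <- matrix(tgt$gt, ncol = 4L)[obj_idx, , drop = FALSE]
      pb <- box_from_cwh(dec$bx[obj_idx], dec$by[obj_idx],
                         dec$bw[obj_idx], dec$bh[obj_idx])
      pb <- .box_mat(pb)
      ctar[obj_idx] <- if (conf_target == "iou") box_iou(pb, gt) else 1
    }
    wgt <- array(lambda_noobj, c(S, S, B))
    wgt[obj_idx] <- 1
    resid <- sc - ctar
    conf <- conf + sum(wgt * resid^2)
    g[, , , 5] <- 2 * wgt * resid * sc * (1 - sc)

    # ---- classification ---------------------------------------------------
    if (length(obj_idx)) {
      for (c_i in seq_len(C)) {
        p <- sigmoid(grid[, , , 5 + c_i])
        tcls <- as.integer(tgt$cls[obj_idx] == c_i)
        r <- p[obj_idx] - tcls
        clss <- clss + sum(r^2)
        gc <- array(0, c(S, S, B))
        gc[obj_idx] <- 2 * r * p[obj_idx] * (1 - p[obj_idx])
        g[, , , 5 + c_i] <- gc
      }
    }

    # ---- coordinates ------------------------------------------------------
    if (length(obj_idx)) {
      gt <- matrix(tgt$gt, ncol = 4L)[obj_idx, , drop = FALSE]
      if (coord_mode == "giou") {
        pb <- .box_mat(box_from_cwh(dec$bx[obj_idx], dec$by[obj_idx],
                                    dec$bw[obj_idx], dec$bh[obj_idx]))
        gi <- box_giou(pb, gt)
        coord <- coord + sum(1 - gi)
        dG <- box_giou_grad(pb, gt)        # d GIoU / d corners
        dL <- -dG                          # d (1 - GIoU)
        sig_x <- dec$sx[obj_idx]; sig_y <- dec$sy[obj_idx]
        bw <- dec$bw[obj_idx]; bh <- dec$bh[obj_idx]
        gtx <- (dL[, 1] + dL[, 3]) * sig_x * (1 - sig_x) / S
        gty <- (dL[, 2] + dL[, 4]) * sig_y * (1 - sig_y) / S
        gtw <- (-dL[, 1] + dL[, 3]) * bw / 2
        gth <- (-dL[, 2] + dL[, 4]) * bh / 2
      } else {
        gcwh <- box_to_cwh(gt)
        if (nrow(gt) == 1L) gcwh <- matrix(gcwh, 1L)
        ox <- gcwh[, 1] * S - (dec$cols[obj_idx])
        oy <- gcwh[, 2] * S - (dec$rows[obj_idx])
        tw_t <- log(pmax(gcwh[, 3], 1e-9) / dec$anc_w[obj_idx])
        th_t <- log(pmax(gcwh[, 4], 1e-9) / dec$anc_h[obj_idx])
        sig_x <- dec$sx[obj_idx]; sig_y <- dec$sy[obj_idx]
        rx <- sig_x - ox; ry <- sig_y - oy
        rw <- grid[, , , 3][obj_idx] - tw_t
        rh <- grid[, , , 4][obj_idx] - th_t
        coord <- coord + sum(rx^2 + ry^2 + rw^2 + rh^2)
        gtx <- 2 * rx * sig_x * (1 - sig_x)
        gty <- 2 * ry * sig_y * (1 - sig_y)
        gtw <- 2 * rw
        gth <- 2 * rh
      }
      for (k in 1:4) {
        comp <- array(0, c(S, S, B))
        comp[obj_idx] <- switch(k, gtx, gty, gtw, gth)
        g[, , , k] <- g[, , , k] + comp
      }
    }
    grads[[s]] <- g
  }
  list(breakdown = list(coord = coord, conf = conf, class = clss,
                        total = coord + conf + clss, n_obj = n_obj),
       grads = grads)
}

# map a [S,S,B,K] gradient back to the raw [S,S,B*K] head layout
.grid_grad_to_raw <- function(g) {
  d <- dim(g)
  array(aperm(g, c(1, 2, 4, 3)), c(d[1], d[2], d[3] * d[4]))
}

# ---- Adam ------------------------------------------------------------------

.adam_new <- function(params) {
  st <- list(t = 0L, m = list(), v = list())
  for (nm in names(params)) {
    st$m[[nm]] <- list(w = params[[nm]]$w * 0, b = params[[nm]]$b * 0)
    st$v[[nm]] <- list(w = params[[nm]]$w * 0, b = params[[nm]]$b * 0)
  }
  st
}

.adam_step <- function(params, grads, st, lr, proto) {
  st$t <- st$t + 1L
  b1 <- proto$beta1; b2 <- proto$beta2; eps <- 1e-8
  bc1 <- 1 - b1^st$t; bc2 <- 1 - b2^st$t
  for (nm in names(grads)) {
    for (comp in names(grads[[nm]])) {
      gr <- grads[[nm]][[comp]] + proto$weight_decay * params[[nm]][[comp]]
      st$m[[nm]][[comp]] <- b1 * st$m[[nm]][[comp]] + (1 - b1) * gr
      st$v[[nm]][[comp]] <- b2 * st$v[[nm]][[comp]] + (1 - b2) * gr^2
      mhat <- st$m[[nm]][[comp]] / bc1
      vhat <- st$v[[nm]][[comp]] / bc2
      params[[nm]][[comp]] <- params[[nm]][[comp]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(params = params, state = st)
}

#' Plateau learning-rate / early-stopping bookkeeping
#'
#' Pure state machine used by [fit_detector()]; exposed for testing and
#' custom loops. Call once per epoch with the validation loss.
#'
#' @param state `NULL` to initialize, else the previous state
#' @param val_loss validation loss of the finished epoch
#' @param proto a `train_protocol`
#' @return updated state: `lr`, `best`, `wait_lr`, `wait_stop`,
#'   `reduced` (LR was cut this epoch), `stop` (early stop now)
#' @export
schedule_step <- function(state, val_loss, proto) {
  if (is.null(state))
    state <- list(lr = proto$learning_rate, best = Inf,
                  wait_lr = 0L, wait_stop = 0L, reduced = FALSE, stop = FALSE)
  state$reduced <- FALSE
  if (val_loss < state$best - 1e-12) {
    state$best <- val_loss
    state$wait_lr <- 0L
    state$wait_stop <- 0L
  } else {
    state$wait_lr <- state$wait_lr + 1L
    state$wait_stop <- state$wait_stop + 1L
    if (state$wait_lr >= proto$patience_lr) {
      state$lr <- state$lr * proto$lr_factor
      state$wait_lr <- 0L
      state$reduced <- TRUE
    }
    if (state$wait_stop >= proto$patience_stop) state$stop <- TRUE
  }
  state
}

#' Convert a labeled image into a training sample
#'
#' Resizes to the detector input and normalizes boxes to the unit square.
#'
#' @param limg a `labeled_image`
#' @param cfg a `detector_config`
#' @return list with `image`, `boxes` (n x 4 normalized), `classes`
#' @export
as_training_sample <- function(limg, cfg) {
  r <- .resize_labeled(limg, cfg$input_size)
  ann <- r$annotations
  if (nrow(ann)) {
    boxes <- as.matrix(ann[, c("x_min", "y_min", "x_max", "y_max")]) /
      cfg$input_size
    classes <- match(ann$label, cfg$labels)
    classes[is.na(classes)] <- 1L
  } else {
    boxes <- matrix(numeric(0), 0, 4)
    classes <- integer(0)
  }
  list(image = r$image, boxes = boxes, classes = classes)
}

.sample_loss <- function(detector, sample, tg, lambda_noobj, coord_mode,
                         with_grad = FALSE, conf_target = "iou") {
  fw <- forward_detector(detector, sample$image)
  ls <- compute_loss(fw$grids, tg, detector$cfg, lambda_noobj = lambda_noobj,
                     coord_mode = coord_mode, conf_target = conf_target)
  if (!with_grad) return(list(breakdown = ls$breakdown))
  seeds <- lapply(ls$grads, .grid_grad_to_raw)
  tape_backward(fw$tape, as.list(fw$out_ids), seeds)
  list(breakdown = ls$breakdown, pgrad = fw$tape$pgrad)
}

.zero_grads <- function(params) {
  lapply(params, function(p) list(w = p$w * 0, b = p$b * 0))
}

.acc_grads <- function(acc, pg) {
  for (nm in names(pg)) for (comp in names(pg[[nm]]))
    acc[[nm]][[comp]] <- acc[[nm]][[comp]] + pg[[nm]][[comp]]
  acc
}

#' Train a detector
#'
#' @param detector a `poppy_detector`
#' @param train,val lists of training samples (see [as_training_sample()])
#' @param proto a `train_protocol`
#' @param seed RNG seed controlling shuffling (reproducible trace)
#' @param lambda_noobj no-object confidence weight
#' @param coord_mode `"giou"` or `"mse"` for the main phase
#' @param conf_target objectness target for responsible predictors:
#'   `"iou"` (decoded-box IoU with the matched ground truth, the paper's
#'   definition of confidence) or `"one"` (constant 1, the common YOLOv3
#'   training simplification; a steadier signal for short desk-scale runs)
#' @param warm_start_epochs when > 0, a first phase of this many epochs is
#'   trained with the MSE coordinate loss and the main (GIoU) phase starts
#'   from the phase-1 weights
#' @param verbose print per-epoch lines
#' @return list with `detector` (trained), `trace` (per-epoch data frame:
#'   phase, losses, validation loss, learning rate, events)
#' @export
fit_detector <- function(detector, train, val, proto = train_protocol(),
                         seed = 1L, lambda_noobj = 0.5,
                         coord_mode = c("giou", "mse"),
                         conf_target = c("iou", "one"),
                         warm_start_epochs = 0L, verbose = FALSE) {
  coord_mode <- match.arg(coord_mode)
  conf_target <- match.arg(conf_target)
  if (!length(train) || !length(val)) stop("train and val must be non-empty")
  set.seed(as.integer(seed))
  cfg <- detector$cfg
  tg_train <- lapply(train, function(s) assign_targets(s$boxes, s$classes, cfg))
  tg_val <- lapply(val, function(s) assign_targets(s$boxes, s$classes, cfg))
  params <- detector$params
  trace <- list()
  run_phase <- function(params, phase, mode, n_epochs) {
    opt <- .adam_new(params)
    sched <- NULL
    det <- detector; det$params <- params
    for (ep in seq_len(n_epochs)) {
      ord <- sample(length(train))
      ep_loss <- c(coord = 0, conf = 0, class = 0, total = 0)
      i <- 1L
      while (i <= length(ord)) {
        batch <- ord[i:min(i + proto$batch_size - 1L, length(ord))]
        acc <- .zero_grads(params)
        for (b in batch) {
          r <- .sample_loss(det, train[[b]], tg_train[[b]], lambda_noobj,
                            mode, with_grad = TRUE,
                            conf_target = conf_target)
          acc <- .acc_grads(acc, r$pgrad)
          ep_loss <- ep_loss + unlist(r$breakdown[c("coord", "conf", "class",
                                                    "total")])
        }
        acc <- lapply(acc, function(p) lapply(p, function(x) x / length(batch)))
        lr_now <- if (is.null(sched)) proto$learning_rate else sched$lr
        st <- .adam_step(params, acc, opt, lr_now, proto)
        params <- st$params; opt <- st$state
        det$params <- params
        i <- i + proto$batch_size
      }
      ep_loss <- ep_loss / length(train)
      vl <- mean(vapply(seq_along(val), function(k)
        .sample_loss(det, val[[k]], tg_val[[k]], lambda_noobj, mode,
                     conf_target = conf_target)$breakdown$total,
        0))
      if (!is.finite(vl))
        stop("validation loss is not finite at epoch ", ep, " (phase ", phase, ")")
      sched <- schedule_step(sched, vl, proto)
      ev <- if (sched$reduced) "lr_reduced" else ""
      trace[[length(trace) + 1L]] <<- data.frame(
        phase = phase, epoch = ep, coord = ep_loss["coord"],
        conf = ep_loss["conf"], class = ep_loss["class"],
        train_loss = ep_loss["total"], val_loss = vl, lr = sched$lr,
        event = ev, row.names = NULL)
      if (verbose)
        message(sprintf("[%s] epoch %d train %.4f val %.4f lr %.2g %s",
                        phase, ep, ep_loss["total"], vl, sched$lr, ev))
      if (sched$stop) {
        trace[[length(trace)]]$event <<- "early_stop"
        break
      }
    }
    params
  }
  if (warm_start_epochs > 0L)
    params <- run_phase(params, "warmup_mse", "mse", warm_start_epochs)
  params <- run_phase(params, paste0("main_", coord_mode), coord_mode,
                      proto$max_epochs)
  detector$params <- params
  list(detector = detector, trace = do.call(rbind, trace))
}
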