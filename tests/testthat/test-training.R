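# naive per-element reference loss: explicit loops and scalar formulas,
# independent of the vectorized implementation
naive_loss <- function(grids, targets, cfg, lambda_noobj = 0.5) {
  sig <- function(z) 1 / (1 + exp(-z))
  coord <- conf <- cls <- 0
  for (s in seq_along(grids)) {
    g <- grids[[s]]
    S <- dim(g)[1]; B <- dim(g)[3]; C <- dim(g)[4] - 5
    anchors <- scale_anchors(cfg, s)
    for (i in seq_len(S)) for (j in seq_len(S)) for (a in seq_len(B)) {
      raw <- g[i, j, a, ]
      bx <- (sig(raw[1]) + (j - 1)) / S
      by <- (sig(raw[2]) + (i - 1)) / S
      bw <- anchors[a, 1] * exp(raw[3]); bh <- anchors[a, 2] * exp(raw[4])
      pb <- c(bx - bw / 2, by - bh / 2, bx + bw / 2, by + bh / 2)
      if (targets[[s]]$obj[i, j, a]) {
        gt <- targets[[s]]$gt[i, j, a, ]
        coord <- coord + (1 - box_giou(pb, gt))
        conf <- conf + (sig(raw[5]) - box_iou(pb, gt))^2
        for (c_i in seq_len(C)) {
          tc <- as.numeric(targets[[s]]$cls[i, j, a] == c_i)
          cls <- cls + (sig(raw[5 + c_i]) - tc)^2
        }
      } else {
        conf <- conf + lambda_noobj * sig(raw[5])^2
      }
    }
  }
  list(coord = coord, conf = conf, class = cls, total = coord + conf + cls)
}

toy_targets <- function(cfg, S, boxes = NULL, classes = 1L) {
  # single-scale toy: hand-build the target structure
  tg <- list(list(obj = array(FALSE, c(S, S, 3)),
                  gt = array(NA_real_, c(S, S, 3, 4)),
                  cls = array(NA_integer_, c(S, S, 3))))
  if (!is.null(boxes)) {
    for (r in seq_len(nrow(boxes$at))) {
      i <- boxes$at[r, 1]; j <- boxes$at[r, 2]; a <- boxes$at[r, 3]
      tg[[1]]$obj[i, j, a] <- TRUE
      tg[[1]]$gt[i, j, a, ] <- boxes$gt[r, ]
      tg[[1]]$cls[i, j, a] <- classes
    }
  }
  tg
}

test_that("each ground truth gets exactly one responsible predictor", {
  cfg <- detector_config()
  tg <- assign_targets(rbind(c(0.4, 0.4, 0.6, 0.6)), 1L, cfg)
  expect_equal(sum(sapply(tg, function(x) sum(x$obj))), 1)
  # empty ground truth: all-noobj masks
  tg0 <- assign_targets(NULL, 1L, cfg)
  expect_equal(sum(sapply(tg0, function(x) sum(x$obj))), 0)
})

test_that("anchor choice matches exhaustive IoU enumeration", {
  cfg <- detector_config()
  shapes <- rbind(c(0.30, 0.06), c(0.06, 0.30), c(0.12, 0.12),
                  c(0.70, 0.50), c(0.02, 0.03))
  for (r in seq_len(nrow(shapes))) {
    w <- shapes[r, 1]; h <- shapes[r, 2]
    b <- c(0.5 - w / 2, 0.5 - h / 2, 0.5 + w / 2, 0.5 + h / 2)
    # brute force over all 9 anchors as centred boxes
    ious <- apply(cfg$anchors, 1, function(a)
      box_iou(b, c(0.5 - a[1] / 2, 0.5 - a[2] / 2, 0.5 + a[1] / 2, 0.5 + a[2] / 2)))
    best <- which.max(ious)
    exp_scale <- c(3, 3, 3, 2, 2, 2, 1, 1, 1)[best]
    exp_anchor <- c(1, 2, 3, 1, 2, 3, 1, 2, 3)[best]
    tg <- assign_targets(rbind(b), 1L, cfg)
    hit <- which(tg[[exp_scale]]$obj, arr.ind = TRUE)
    expect_equal(nrow(hit), 1)
    expect_equal(unname(hit[1, 3]), exp_anchor)
  }
})

test_that("predictor collisions keep the larger box", {
  cfg <- detector_config()
  # both shapes have the same best anchor and share the centre cell
  big <- c(0.35, 0.35, 0.65, 0.65)
  small <- c(0.37, 0.37, 0.63, 0.63)
  suppressMessages({
    tg <- assign_targets(rbind(small, big), c(1L, 1L), cfg)
  })
  s <- which(sapply(tg, function(x) sum(x$obj)) > 0)
  expect_equal(sum(tg[[s]]$obj), 1)
  idx <- which(tg[[s]]$obj)
  got <- matrix(tg[[s]]$gt, ncol = 4)[idx, ]
  expect_equal(got, big)
})

test_that("loss matches the naive reference on toy grids", {
  cfg <- detector_config()
  set.seed(12)
  for (S in c(1L, 2L)) {
    grid <- array(rnorm(S * S * 3 * 6, 0, 0.8), c(S, S, 3, 6))
    tg <- toy_targets(cfg, S,
                      boxes = list(at = rbind(c(1, 1, 2)),
                                   gt = rbind(c(0.1, 0.2, 0.5, 0.7))))
    got <- compute_loss(list(grid), tg, cfg)$breakdown
    ref <- naive_loss(list(grid), tg, cfg)
    expect_equal(got$coord, ref$coord, tolerance = 1e-6)
    expect_equal(got$conf, ref$conf, tolerance = 1e-6)
    expect_equal(got$class, ref$class, tolerance = 1e-6)
    expect_equal(got$total, got$coord + got$conf + got$class)
  }
})

test_that("perfect predictions and lambda_noobj = 0 give zero loss", {
  cfg <- detector_config()
  S <- 2L
  gt <- c(0.3, 0.3, 0.7, 0.8)
  anc <- scale_anchors(cfg, 1)
  enc <- encode_box(gt, S, anc[2, ])
  grid <- array(0, c(S, S, 3, 6))
  grid[, , , 5] <- -40          # confidence ~0 everywhere
  grid[enc$row, enc$col, 2, 1:4] <- enc$raw
  grid[enc$row, enc$col, 2, 5] <- 40   # sigmoid ~1 = IoU of a perfect box
  grid[enc$row, enc$col, 2, 6] <- 40   # class prob ~1
  tg <- toy_targets(cfg, S, boxes = list(at = rbind(c(enc$row, enc$col, 2)),
                                         gt = rbind(gt)))
  bd <- compute_loss(list(grid), tg, cfg)$breakdown
  # floor set by the 1e-6 offset clamp in encode_box at cell boundaries
  expect_lt(bd$total, 1e-4)
  # no objects anywhere + lambda 0: total 0 regardless of confidences
  grid2 <- array(rnorm(S * S * 3 * 6), c(S, S, 3, 6))
  bd2 <- compute_loss(list(grid2), toy_targets(cfg, S), cfg,
                      lambda_noobj = 0)$breakdown
  expect_equal(bd2$total, 0)
  expect_error(compute_loss(list(grid * NA), tg, cfg), "NaN")
})

test_that("loss gradients match finite differences (GIoU and MSE modes)", {
  cfg <- detector_config()
  set.seed(21)
  S <- 2L
  tg <- toy_targets(cfg, S, boxes = list(at = rbind(c(2, 1, 1)),
                                         gt = rbind(c(0.05, 0.55, 0.35, 0.95))))
  for (mode in c("giou", "mse")) {
    grid <- array(rnorm(S * S * 3 * 6, 0, 0.5), c(S, S, 3, 6))
    # conf target depends on the decoded box; freeze it for the diff check
    r <- compute_loss(list(grid), tg, cfg, coord_mode = mode,
                      conf_target = "one")
    h <- 1e-6
    for (probe in 1:12) {
      k <- sample(length(grid), 1)
      gp <- grid; gm <- grid
      gp[k] <- gp[k] + h; gm[k] <- gm[k] - h
      num <- (compute_loss(list(gp), tg, cfg, coord_mode = mode,
                           conf_target = "one")$breakdown$total -
              compute_loss(list(gm), tg, cfg, coord_mode = mode,
                           conf_target = "one")$breakdown$total) / (2 * h)
      expect_equal(r$grads[[1]][k], num, tolerance = 1e-4)
    }
  }
})

test_that("moving the decoded box toward the target lowers the coord term", {
  cfg <- detector_config()
  S <- 2L
  gt <- c(0.1, 0.1, 0.45, 0.45)
  tg <- toy_targets(cfg, S, boxes = list(at = rbind(c(1, 1, 3)),
                                         gt = rbind(gt)))
  grid <- array(0, c(S, S, 3, 6))
  r0 <- compute_loss(list(grid), tg, cfg)
  # one gradient step on the coordinate channels only
  grid2 <- grid
  grid2[, , , 1:4] <- grid[, , , 1:4] - 0.05 * r0$grads[[1]][, , , 1:4]
  r1 <- compute_loss(list(grid2), tg, cfg)
  expect_lt(r1$breakdown$coord, r0$breakdown$coord)
  # switching GIoU -> MSE leaves conf and class terms unchanged
  rg <- compute_loss(list(grid), tg, cfg, coord_mode = "giou")$breakdown
  rm <- compute_loss(list(grid), tg, cfg, coord_mode = "mse")$breakdown
  expect_equal(rg$conf, rm$conf)
  expect_equal(rg$class, rm$class)
})

test_that("plateau schedule cuts the LR once after 20 stagnant epochs and stops after 50", {
  proto <- train_protocol()
  st <- NULL
  st <- schedule_step(st, 1.0, proto)   # first epoch sets the best
  reductions <- 0; stopped_at <- NA
  for (ep in 2:60) {
    st <- schedule_step(st, 1.0, proto) # never improves
    if (st$reduced) reductions <- reductions + 1
    if (st$stop) { stopped_at <- ep; break }
  }
  expect_equal(reductions, 2)           # epochs 21 and 41
  expect_equal(stopped_at, 51)
  expect_equal(st$lr, 0.001 * 0.1^2)
  # improvement resets both counters
  st2 <- schedule_step(NULL, 1, proto)
  for (i in 1:19) st2 <- schedule_step(st2, 1, proto)
  st2 <- schedule_step(st2, 0.5, proto)
  expect_equal(st2$wait_lr, 0L)
  expect_equal(st2$lr, proto$learning_rate)
  expect_error(train_protocol(patience_lr = 50, patience_stop = 50))
})

test_that("fit runs, records phases, and decreases the training loss", {
  cfg <- detector_config(input_size = 64L, width_mult = 0.1,
                         anchors = matrix(rep(c(0.2, 0.2), 9), ncol = 2,
                                          byrow = TRUE) *
                           seq(0.5, 2.5, length.out = 9))
  det <- build_detector(cfg, seed = 1)
  mk <- function(seed) {
    set.seed(seed)
    img <- array(runif(64 * 64 * 3, 0, 0.3), c(64, 64, 3))
    cx <- runif(1, 0.3, 0.7); cy <- runif(1, 0.3, 0.7)
    r <- 0.1
    px <- round(64 * c(cx - r, cy - r, cx + r, cy + r))
    img[(px[2] + 1):px[4], (px[1] + 1):px[3], 1] <- 1
    list(image = img, boxes = rbind(px / 64), classes = 1L)
  }
  train <- lapply(1:6, mk); val <- lapply(7:8, mk)
  proto <- train_protocol(batch_size = 4L, max_epochs = 4L,
                          learning_rate = 0.003)
  fit <- fit_detector(det, train, val, proto, seed = 3,
                      warm_start_epochs = 2L)
  expect_s3_class(fit$detector, "poppy_detector")
  expect_equal(unique(fit$trace$phase), c("warmup_mse", "main_giou"))
  expect_equal(nrow(fit$trace), 6)
  warm <- fit$trace$train_loss[fit$trace$phase == "warmup_mse"]
  expect_lt(warm[2], warm[1])
  expect_true(all(is.finite(fit$trace$val_loss)))
})
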