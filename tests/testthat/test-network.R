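test_that("SPP filter size reproduces the printed table", {
  sizes <- sapply(1:3, function(n) sapply(c(13L, 26L, 52L), spp_filter_size, n = n))
  expect_equal(sizes, rbind(c(13, 7, 5), c(26, 13, 9), c(52, 26, 18)),
               ignore_attr = TRUE)
  expect_true(all(sapply(1:5, spp_filter_size, map_size = 1) == 1))
})

test_that("SPP unit preserves shape, widens channels, and pools correctly", {
  for (S in c(13L, 26L, 52L)) for (lv in 1:3) {
    x <- array(rnorm(S * S * 2), c(S, S, 2L))
    y <- spp_unit(x, levels = lv)
    expect_identical(dim(y), c(S, S, (lv + 1L) * 2L))
  }
  # constant map stays constant in every pooled copy
  xc <- array(0.7, c(13, 13, 3))
  yc <- spp_unit(xc, 3)
  expect_true(all(yc == 0.7))
  # global level (k = S): centre pixel sees the whole map; edge windows are
  # clipped (framework 'same'-padding convention), never exceeding the max
  set.seed(1)
  x <- array(rnorm(13 * 13), c(13, 13, 1))
  y <- spp_unit(x, 1)
  expect_equal(y[7, 7, 2], max(x))
  expect_equal(max(y[, , 2]), max(x))
  expect_equal(y[, , 2], max_filter_oracle(x[, , 1], 13))
  # single bright pixel, filter 5 -> 5x5 plateau; checked against the
  # direct max-filter oracle
  x <- array(-1, c(13, 13, 1)); x[7, 7, 1] <- 5
  y <- spp_unit(x, 3)  # level 3 has filter ceiling(13/3) = 5
  expect_equal(y[, , 4], max_filter_oracle(x[, , 1], 5))
  expect_equal(sum(y[, , 4] == 5), 25)
  set.seed(2)
  x <- array(rnorm(26 * 26), c(26, 26, 1))
  y <- spp_unit(x, 3)
  for (n in 1:3)
    expect_equal(y[, , 1 + n], max_filter_oracle(x[, , 1], spp_filter_size(26, n)))
  expect_error(spp_unit(array(0, c(13, 26, 1))), "square")
})

test_that("detector emits three grids with SPP widening where placed", {
  for (spp in c("none", "first", "all")) {
    cfg <- tiny_cfg(spp = spp)
    det <- build_detector(cfg, seed = 1)
    fw <- forward_detector(det, new_image(96, 96, 0.5))
    expect_equal(sapply(fw$grids, function(g) dim(g)[1]), c(3, 6, 12),
                 ignore_attr = TRUE)
    expect_true(all(sapply(fw$grids, function(g) all(is.finite(g)))))
  }
  expect_error(build_detector(detector_config(backbone = "nope")),
               "registered: mobilenetv2")
  expect_error(detector_config(input_size = 100), "divisible by 32")
})

test_that("parameter count ordering: plain < one-unit < three-unit", {
  n_none <- n_parameters(build_detector(tiny_cfg(spp = "none")))
  n_first <- n_parameters(build_detector(tiny_cfg(spp = "first")))
  n_all <- n_parameters(build_detector(tiny_cfg(spp = "all")))
  expect_lt(n_none, n_first)
  expect_lt(n_first, n_all)
})

test_that("decode follows the YOLOv3 convention and inverts encode", {
  cfg <- tiny_cfg()
  S <- 3L
  anchors <- scale_anchors(cfg, 1)
  # zero raw outputs: cell-centred box with anchor size, confidence 0.5
  grid <- array(0, c(S, S, 3, 6))
  dec <- decode_grid(grid, anchors)
  expect_equal(dec$confidence, rep(0.5, S * S * 3))
  first <- which(dec$cell[, "row"] == 1 & dec$cell[, "col"] == 1 &
                 dec$cell[, "anchor"] == 1)
  cwh <- box_to_cwh(dec$boxes[first, ])
  expect_equal(cwh[1:2], c(0.5 / S, 0.5 / S))
  expect_equal(cwh[3:4], as.numeric(anchors[1, ]))
  # encode-then-decode round-trip on random boxes
  set.seed(6)
  for (i in 1:50) {
    b <- random_box(1) / 3 + 0.3  # keep sizes moderate
    enc <- encode_box(b, S, anchors[2, ])
    grid <- array(0, c(S, S, 3, 6))
    grid[enc$row, enc$col, 2, 1:4] <- enc$raw
    dec <- decode_grid(grid, anchors)
    idx <- which(dec$cell[, "row"] == enc$row & dec$cell[, "col"] == enc$col &
                 dec$cell[, "anchor"] == 2)
    expect_equal(as.numeric(dec$boxes[idx, ]), as.numeric(b), tolerance = 1e-6)
  }
  # monotonicity: larger size logit -> strictly wider decoded box
  g1 <- array(0, c(S, S, 3, 6)); g2 <- g1
  g2[1, 1, 1, 3] <- 0.5
  w1 <- box_to_cwh(decode_grid(g1, anchors)$boxes[1, ])[3]
  w2 <- box_to_cwh(decode_grid(g2, anchors)$boxes[1, ])[3]
  expect_gt(w2, w1)
})

test_that("tape gradients match finite differences through the full graph", {
  cfg <- detector_config(input_size = 32L, width_mult = 0.1, spp = "first",
                         spp_levels = 2L)
  det <- build_detector(cfg, seed = 2)
  img <- array(runif(32 * 32 * 3), c(32, 32, 3))
  loss_of <- function(d) {
    fw <- forward_detector(d, img)
    sum(vapply(fw$grids, function(g) sum(g^2), 0)) / 2
  }
  fw <- forward_detector(det, img)
  seeds <- lapply(fw$grids, poppydetect:::.grid_grad_to_raw)
  poppydetect:::tape_backward(fw$tape, as.list(fw$out_ids), seeds)
  pg <- fw$tape$pgrad
  set.seed(4)
  h <- 1e-5
  # probe a handful of random scalars across parameter tensors
  for (nm in sample(names(pg), 6)) {
    comp <- sample(names(pg[[nm]]), 1)
    k <- sample(length(det$params[[nm]][[comp]]), 1)
    dp <- det; dm <- det
    dp$params[[nm]][[comp]][k] <- dp$params[[nm]][[comp]][k] + h
    dm$params[[nm]][[comp]][k] <- dm$params[[nm]][[comp]][k] - h
    num <- (loss_of(dp) - loss_of(dm)) / (2 * h)
    ana <- pg[[nm]][[comp]][k]
    expect_equal(ana, num, tolerance = 1e-3)
  }
})

test_that("weights save/load round-trips and rejects mismatched graphs", {
  det <- build_detector(tiny_cfg(), seed = 3)
  p <- tempfile(fileext = ".rds")
  save_weights(det, p)
  back <- load_weights(p)
  expect_equal(back$params, det$params)
  expect_identical(arch_fingerprint(back$cfg), arch_fingerprint(det$cfg))
  # tamper with the stored fingerprint
  obj <- readRDS(p); obj$fingerprint <- "bogus"; saveRDS(obj, p)
  expect_error(load_weights(p), "fingerprint")
})

test_that("k-means anchors recover planted shape clusters", {
  set.seed(5)
  wh <- rbind(matrix(runif(60, 0.05, 0.07), ncol = 2),
              matrix(runif(60, 0.25, 0.30), ncol = 2),
              matrix(runif(60, 0.60, 0.70), ncol = 2))
  a <- kmeans_anchors(wh, k = 9, seed = 1)
  expect_equal(dim(a), c(9L, 2L))
  expect_true(all(diff(a[, 1] * a[, 2]) >= 0))  # ascending area
  expect_lt(max(a), 0.75)
  expect_gt(min(a), 0.04)
})
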