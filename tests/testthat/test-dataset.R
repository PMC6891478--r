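# pipeline fixtures are built in code: small rasters with known boxes

fixture_limg <- function(h = 600, w = 900, boxes = NULL, label = "poppy") {
  img <- new_image(h, w, c(0.3, 0.4, 0.2))
  ann <- if (is.null(boxes)) NULL else
    data.frame(x_min = boxes[, 1], y_min = boxes[, 2], x_max = boxes[, 3],
               y_max = boxes[, 4], label = label, stringsAsFactors = FALSE)
  labeled_image(img, ann, height_tag = 30, stage_tag = "flowering")
}

test_that("VOC XML round-trips integer boxes exactly", {
  limg <- fixture_limg(boxes = rbind(c(10, 20, 50, 70), c(100, 200, 140, 260)))
  path <- tempfile(fileext = ".xml")
  write_voc_xml(limg, path, image_filename = "img.ppm")
  back <- read_voc_xml(path)
  expect_equal(back$width, 900)
  expect_equal(back$height, 600)
  expect_equal(back$annotations[, 1:4], limg$annotations[, 1:4],
               ignore_attr = TRUE)
  expect_equal(back$annotations$label, c("poppy", "poppy"))
})

test_that("PPM write/read round-trips at 8-bit precision, P6 and P3", {
  set.seed(1)
  img <- array(runif(24 * 18 * 3), c(24, 18, 3))
  for (ascii in c(FALSE, TRUE)) {
    p <- tempfile(fileext = ".ppm")
    write_ppm(img, p, ascii = ascii)
    back <- read_ppm(p)
    expect_equal(dim(back), dim(img))
    expect_lt(max(abs(back - img)), 1 / 255 + 1e-9)
  }
})

test_that("cropping emits one window per isolated object", {
  # image with 0 objects -> empty list
  expect_length(crop_around_objects(fixture_limg(), crop_px = 100), 0)
  # two objects farther apart than the window in both axes -> 2 crops
  limg <- fixture_limg(boxes = rbind(c(10, 10, 40, 40), c(500, 400, 540, 440)))
  crops <- crop_around_objects(limg, crop_px = 100, seed = 3)
  expect_length(crops, 2)
  expect_true(all(vapply(crops, function(cr) nrow(cr$annotations), 0L) == 1))
  expect_true(all(vapply(crops, function(cr)
    identical(dim(cr$image), c(100L, 100L, 3L)), TRUE)))
})

test_that("clustered objects are dequeued into a shared crop", {
  # second object adjacent: any window containing the first contains it too
  limg <- fixture_limg(boxes = rbind(c(300, 300, 340, 340), c(345, 300, 385, 340)))
  crops <- crop_around_objects(limg, crop_px = 200, seed = 7)
  expect_length(crops, 1)
  expect_equal(nrow(crops[[1]]$annotations), 2)
  # literal-IoU reading: a 200 px window never reaches IoU 0.5 with a 40 px
  # object, so nothing is dequeued -> 2 crops
  crops_iou <- crop_around_objects(limg, crop_px = 200, seed = 7,
                                   criterion = "iou")
  expect_length(crops_iou, 2)
})

test_that("crop errors when an object exceeds the window", {
  limg <- fixture_limg(boxes = rbind(c(0, 0, 450, 90)))
  expect_error(crop_around_objects(limg, crop_px = 100), "larger than")
})

test_that("every object lands in exactly one crop's annotations when isolated", {
  set.seed(9)
  n <- 6
  xs <- seq(20, 800, length.out = n)
  boxes <- cbind(xs, 100 + 60 * seq_len(n), xs + 30, 130 + 60 * seq_len(n))
  limg <- fixture_limg(boxes = boxes)
  crops <- crop_around_objects(limg, crop_px = 100, seed = 2, keep_frac = 0.99)
  expect_lte(length(crops), n)
  expect_equal(sum(vapply(crops, function(cr) nrow(cr$annotations), 0L)), n)
})

test_that("balancing reproduces the bundled preset totals", {
  counts <- default_cell_counts()
  man <- do.call(rbind, lapply(rownames(counts), function(st)
    do.call(rbind, lapply(colnames(counts), function(ht)
      data.frame(image = sprintf("%s_%s_%03d", st, ht, seq_len(counts[st, ht])),
                 height_tag = as.numeric(ht), stage_tag = st)))))
  expect_equal(nrow(man), 1040)  # the selected-photo total
  bal <- balance_by_replication(man, default_cell_counts(TRUE), seed = 1)
  expect_equal(nrow(bal), 1235)
  # cell 42 -> 126 adds exactly 84 duplicates
  cell <- bal$stage_tag == "seedling" & bal$height_tag == 150
  expect_equal(sum(cell), 126)
  expect_equal(sum(bal$replica[cell]), 84)
  # identity when targets equal current counts
  same <- balance_by_replication(man, default_cell_counts(), seed = 1)
  expect_equal(nrow(same), nrow(man))
  expect_error(balance_by_replication(bal[0, ], default_cell_counts(TRUE)),
               "empty cell")
  shrunk <- default_cell_counts(TRUE); shrunk["flowering", "30"] <- 10L
  expect_error(balance_by_replication(man, shrunk, seed = 1), "below current")
})

test_that("mixup branches give the ground truth the dominant weight", {
  gt <- fixture_limg(h = 20, w = 20, boxes = rbind(c(2, 2, 8, 8)))
  set.seed(4)
  bg <- array(runif(20 * 20 * 3), c(20, 20, 3))
  # mu = 0.5: branches coincide
  f5 <- mixup_fuse(gt, bg, mu = 0.5)
  expect_equal(f5$image, 0.5 * bg + 0.5 * gt$image)
  # mu < 0.5: mu*bg + (1-mu)*gt
  f2 <- mixup_fuse(gt, bg, mu = 0.2)
  expect_equal(f2$image, 0.2 * bg + 0.8 * gt$image)
  # mu >= 0.5: (1-mu)*bg + mu*gt
  f7 <- mixup_fuse(gt, bg, mu = 0.7)
  expect_equal(f7$image, 0.3 * bg + 0.7 * gt$image)
  expect_equal(f7$annotations, gt$annotations)
  expect_error(mixup_fuse(gt, bg[1:10, , , drop = FALSE]), "shapes differ")
})

test_that("mixup preserves range and the exact mean identity", {
  gt <- fixture_limg(h = 16, w = 16)
  set.seed(8)
  bg <- array(runif(16 * 16 * 3), c(16, 16, 3))
  for (mu in c(0.1, 0.33, 0.5, 0.81)) {
    f <- mixup_fuse(gt, bg, mu = mu)
    w_bg <- min(mu, 1 - mu)
    expect_gte(min(f$image), min(pmin(bg, gt$image)))
    expect_lte(max(f$image), max(pmax(bg, gt$image)))
    expect_equal(mean(f$image), w_bg * mean(bg) + (1 - w_bg) * mean(gt$image))
  }
  # drawn mu is reproducible and always leaves gt weight >= 0.5
  fa <- mixup_fuse(gt, bg, seed = 33)
  fb <- mixup_fuse(gt, bg, seed = 33)
  expect_identical(fa$image, fb$image)
})

test_that("augmentation bounds, output size, and flip round-trip", {
  set.seed(2)
  imgs <- lapply(1:4, function(i)
    fixture_limg(h = 120, w = 120, boxes = rbind(c(30, 30, 70, 70))))
  out <- augment_dataset(imgs, seed = 5, size = 64L)
  n <- length(imgs)
  expect_gte(length(out), 3 * n - 2)  # a couple of drops tolerated
  expect_lte(length(out), 5 * n)
  for (o in out) expect_identical(dim(o$image), c(64L, 64L, 3L))
  # double horizontal flip is the identity on image and boxes
  l1 <- poppydetect:::.tf_hflip(imgs[[1]])
  l2 <- poppydetect:::.tf_hflip(l1)
  expect_equal(l2$image, imgs[[1]]$image)
  expect_equal(l2$annotations, imgs[[1]]$annotations)
})

test_that("pure geometric transforms move boxes with the pixels", {
  # delta-image: bright patch exactly inside the annotated box
  img <- new_image(80, 100, 0)
  img[31:50, 21:40, ] <- 1
  limg <- labeled_image(img, data.frame(x_min = 20, y_min = 30, x_max = 40,
                                        y_max = 50, label = "p"))
  for (tf in list(poppydetect:::.tf_hflip, poppydetect:::.tf_vflip)) {
    tr <- tf(limg)
    a <- tr$annotations
    patch <- tr$image[(a$y_min + 1):a$y_max, (a$x_min + 1):a$x_max, 1]
    expect_true(all(patch == 1))         # box still covers the patch
    expect_equal(sum(tr$image[, , 1]), sum(img[, , 1]))
  }
  set.seed(10)
  tr <- poppydetect:::.tf_rot90(limg)
  a <- tr$annotations
  expect_true(all(tr$image[(a$y_min + 1):a$y_max, (a$x_min + 1):a$x_max, 1] == 1))
})

test_that("splitting uses largest-remainder rounding and is disjoint", {
  man <- data.frame(image = sprintf("im%04d", 1:4250))
  sp <- split_dataset(man, seed = 1)
  expect_equal(as.numeric(table(sp$split)), c(2975, 425, 850))
  sp10 <- split_dataset(data.frame(image = letters[1:10]), seed = 2)
  expect_equal(as.numeric(table(sp10$split)), c(7, 1, 2))
  all_train <- split_dataset(man, fractions = c(1, 0, 0), seed = 1)
  expect_true(all(all_train$split == "train"))
  expect_error(split_dataset(man[0, , drop = FALSE]), "empty")
  # deterministic under a fixed seed
  expect_identical(split_dataset(man, seed = 9)$split,
                   split_dataset(man, seed = 9)$split)
})
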