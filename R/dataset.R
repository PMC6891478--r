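#' Dataset construction pipeline
#'
#' Builds a detector-ready dataset from large labeled frames: one random
#' fixed-size crop per object (with deduplication of clustered objects),
#' oversampling to balance flying-height x growth-stage cells, Beta-mixup
#' fusion with object-free background crops, randomized augmentation to
#' 416 x 416, and a disjoint 70/10/20 train/validation/test split.
#'
#' A *manifest* is a data frame with columns `image` (path or id),
#' `height_tag`, `stage_tag`, and optionally `split`.
#'
#' @name dataset_pipeline
NULL

#' Per-cell image counts of the bundled UAV corpus preset
#'
#' Counts of labeled 416 x 416 images per flying-height (30/60/150 m) x
#' growth-stage (seedling/flowering) cell, before balancing and the
#' oversampling targets used to balance them. The targets are exogenous
#' configuration (not formula-derived); the balanced preset totals 1235.
#'
#' @param balanced return the oversampling targets instead of raw counts
#' @return 2 x 3 integer matrix, rows seedling/flowering, cols 30/60/150 m
#' @export
default_cell_counts <- function(balanced = FALSE) {
  m <- if (balanced) {
    rbind(seedling = c(216L, 234L, 126L), flowering = c(279L, 252L, 128L))
  } else {
    rbind(seedling = c(216L, 143L, 42L), flowering = c(279L, 252L, 108L))
  }
  colnames(m) <- c("30", "60", "150")
  m
}

.obj_coverage <- function(obj_box, crop_box) {
  a <- box_area(obj_box)
  if (a <= 0) return(0)
  p <- .pair_prep(obj_box, crop_box)
  .intersect_area(p$b, p$g) / a
}

#' Crop fixed-size training images around labeled objects
#'
#' For each still-queued object, place one random `crop_px` x `crop_px`
#' window fully containing that object's box; any other queued object
#' sufficiently covered by the window is dequeued so clustered objects do
#' not generate near-duplicate crops. With `criterion = "coverage"`
#' (default) "sufficiently covered" means more than `coverage_thresh` of
#' the *object's* area falls inside the window; `criterion = "iou"` uses
#' the literal window/object IoU, which for a small object in a 416 px
#' window can never exceed 0.5 and therefore never dequeues.
#'
#' @param limg a `labeled_image`
#' @param crop_px window side in pixels (default 416)
#' @param coverage_thresh dequeue threshold in (0, 1\] (default 0.5)
#' @param seed integer RNG seed
#' @param criterion `"coverage"` or `"iou"` (see Details)
#' @param keep_frac an annotation is kept in a crop when at least this
#'   fraction of its area lies inside (default 0.5); kept boxes are clipped
#'   to the window
#' @return list of `labeled_image` crops, each `crop_px` x `crop_px`
#' @export
crop_around_objects <- function(limg, crop_px = 416L, coverage_thresh = 0.5,
                                seed = 1L, criterion = c("coverage", "iou"),
                                keep_frac = 0.5) {
  stopifnot(inherits(limg, "labeled_image"))
  criterion <- match.arg(criterion)
  if (coverage_thresh <= 0 || coverage_thresh > 1)
    stop("coverage_thresh must be in (0, 1]")
  d <- dim(limg$image)
  H <- d[1]; W <- d[2]
  if (crop_px > min(W, H)) stop("crop_px exceeds image size")
  ann <- limg$annotations
  out <- list()
  if (nrow(ann) == 0L) return(out)
  wobj <- ann$x_max - ann$x_min
  hobj <- ann$y_max - ann$y_min
  too_big <- which(wobj > crop_px | hobj > crop_px)
  if (length(too_big))
    stop(sprintf("object %d ('%s') is larger than the %d px crop window",
                 too_big[1], ann$label[too_big[1]], crop_px))
  set.seed(as.integer(seed))
  queued <- rep(TRUE, nrow(ann))
  for (i in seq_len(nrow(ann))) {
    if (!queued[i]) next
    queued[i] <- FALSE
    # window offset range keeping object i fully inside and window in frame
    x_lo <- max(0, ceiling(ann$x_max[i]) - crop_px)
    x_hi <- min(floor(ann$x_min[i]), W - crop_px)
    y_lo <- max(0, ceiling(ann$y_max[i]) - crop_px)
    y_hi <- min(floor(ann$y_min[i]), H - crop_px)
    x0 <- if (x_hi > x_lo) sample(x_lo:x_hi, 1L) else x_lo
    y0 <- if (y_hi > y_lo) sample(y_lo:y_hi, 1L) else y_lo
    crop_box <- c(x0, y0, x0 + crop_px, y0 + crop_px)
    # dequeue other queued objects sufficiently covered by this window
    for (j in which(queued)) {
      ob <- as.numeric(ann[j, c("x_min", "y_min", "x_max", "y_max")])
      cov <- if (criterion == "coverage") .obj_coverage(ob, crop_box)
             else box_iou(ob, crop_box)
      if (cov > coverage_thresh) queued[j] <- FALSE
    }
    # annotations sufficiently inside the window, re-expressed in crop coords
    keep <- vapply(seq_len(nrow(ann)), function(j) {
      ob <- as.numeric(ann[j, c("x_min", "y_min", "x_max", "y_max")])
      .obj_coverage(ob, crop_box) >= keep_frac
    }, TRUE)
    sub <- ann[keep, , drop = FALSE]
    sub$x_min <- pmax(sub$x_min - x0, 0); sub$x_max <- pmin(sub$x_max - x0, crop_px)
    sub$y_min <- pmax(sub$y_min - y0, 0); sub$y_max <- pmin(sub$y_max - y0, crop_px)
    crop_img <- limg$image[(y0 + 1):(y0 + crop_px), (x0 + 1):(x0 + crop_px), ,
                           drop = FALSE]
    out[[length(out) + 1L]] <- labeled_image(crop_img, sub,
                                             height_tag = limg$height_tag,
                                             stage_tag = limg$stage_tag)
  }
  out
}

#' Balance a manifest by random replication (oversampling)
#'
#' Pads each flying-height x growth-stage cell with uniformly re-sampled
#' duplicate rows until its count reaches the target; cells already at
#' target are returned unchanged.
#'
#' @param manifest data frame with `height_tag` and `stage_tag` columns
#' @param targets matrix like [default_cell_counts()] (rows = stages,
#'   cols = heights as character) giving the per-cell target counts
#' @param seed integer RNG seed
#' @return manifest with duplicated rows appended (`replica` column marks them)
#' @export
balance_by_replication <- function(manifest, targets = default_cell_counts(TRUE),
                                   seed = 1L) {
  stopifnot(is.data.frame(manifest),
            all(c("height_tag", "stage_tag") %in% names(manifest)))
  set.seed(as.integer(seed))
  if (!"replica" %in% names(manifest)) manifest$replica <- FALSE
  extra <- list()
  for (st in rownames(targets)) for (ht in colnames(targets)) {
    idx <- which(manifest$stage_tag == st &
                 as.character(manifest$height_tag) == ht)
    cur <- length(idx); tgt <- targets[st, ht]
    if (cur == 0L && tgt == 0L) next
    if (tgt < cur)
      stop(sprintf("target %d below current count %d for cell %s/%s m",
                   tgt, cur, st, ht))
    if (tgt > cur) {
      if (cur == 0L) stop(sprintf("cannot oversample empty cell %s/%s m", st, ht))
      pick <- idx[sample.int(cur, tgt - cur, replace = TRUE)]
      dup <- manifest[pick, , drop = FALSE]
      dup$replica <- TRUE
      extra[[length(extra) + 1L]] <- dup
    }
  }
  out <- rbind(manifest, do.call(rbind, extra))
  rownames(out) <- NULL
  out
}

#' Fuse a labeled image with a background via Beta-mixup
#'
#' Pixelwise convex blend in which the labeled (ground-truth) image always
#' receives the larger coefficient: with blending draw `mu ~ Beta(0.2, 0.2)`,
#' the fused image is `mu*bg + (1-mu)*gt` when `mu < 0.5` and
#' `(1-mu)*bg + mu*gt` otherwise, so the ground-truth weight is
#' `max(mu, 1-mu) >= 0.5`. Annotations are carried over unchanged.
#'
#' @param gt a `labeled_image`
#' @param bg background raster `[H, W, 3]` of the same shape
#' @param mu optional fixed blend coefficient in (0, 1); when `NULL` a draw
#'   from `Beta(alpha, beta)` is used
#' @param alpha,beta Beta distribution parameters (default 0.2, 0.2: mass
#'   near 0 and 1, so most fusions keep the scene close to one source)
#' @param seed optional RNG seed used when `mu` is drawn
#' @return fused `labeled_image`
#' @export
mixup_fuse <- function(gt, bg, mu = NULL, alpha = 0.2, beta = 0.2, seed = NULL) {
  stopifnot(inherits(gt, "labeled_image"))
  .check_image(bg)
  if (!identical(dim(gt$image), dim(bg)))
    stop("gt and bg shapes differ: ", paste(dim(gt$image), collapse = "x"),
         " vs ", paste(dim(bg), collapse = "x"))
  if (is.null(mu)) {
    if (!is.null(seed)) set.seed(as.integer(seed))
    mu <- stats::rbeta(1, alpha, beta)
    # rbeta can return exactly 0 or 1 for very small shape parameters
    mu <- min(max(mu, 1e-6), 1 - 1e-6)
  }
  if (mu <= 0 || mu >= 1) stop("mu must be strictly inside (0, 1)")
  w_bg <- if (mu < 0.5) mu else 1 - mu
  fused <- w_bg * bg + (1 - w_bg) * gt$image
  labeled_image(fused, gt$annotations,
                height_tag = gt$height_tag, stage_tag = gt$stage_tag)
}

# ---- augmentation transforms ------------------------------------------------

.tf_hflip <- function(limg, ...) {
  d <- dim(limg$image)
  ann <- limg$annotations
  if (nrow(ann)) {
    x0 <- ann$x_min; ann$x_min <- d[2] - ann$x_max; ann$x_max <- d[2] - x0
  }
  labeled_image(flip_image(limg$image, "horizontal"), ann,
                limg$height_tag, limg$stage_tag)
}

.tf_vflip <- function(limg, ...) {
  d <- dim(limg$image)
  ann <- limg$annotations
  if (nrow(ann)) {
    y0 <- ann$y_min; ann$y_min <- d[1] - ann$y_max; ann$y_max <- d[1] - y0
  }
  labeled_image(flip_image(limg$image, "vertical"), ann,
                limg$height_tag, limg$stage_tag)
}

.tf_rot90 <- function(limg, ...) {
  k <- sample(1:3, 1L)
  img <- limg$image
  ann <- limg$annotations
  for (i in seq_len(k)) {
    d <- dim(img)
    img <- rot90_image(img, 1L)
    if (nrow(ann)) {
      # CCW: (x, y) -> (y, W - x)
      x0 <- ann$x_min; x1 <- ann$x_max
      ann$x_min <- ann$y_min; ann$x_max <- ann$y_max
      ann$y_min <- d[2] - x1; ann$y_max <- d[2] - x0
    }
  }
  labeled_image(img, ann, limg$height_tag, limg$stage_tag)
}

.tf_crop <- function(limg, ...) {
  d <- dim(limg$image)
  fh <- stats::runif(1, 0.7, 1); fw <- stats::runif(1, 0.7, 1)
  nh <- max(2L, floor(d[1] * fh)); nw <- max(2L, floor(d[2] * fw))
  y0 <- sample(0:(d[1] - nh), 1L); x0 <- sample(0:(d[2] - nw), 1L)
  ann <- limg$annotations
  if (nrow(ann)) {
    crop_box <- c(x0, y0, x0 + nw, y0 + nh)
    keep <- vapply(seq_len(nrow(ann)), function(j) {
      ob <- as.numeric(ann[j, c("x_min", "y_min", "x_max", "y_max")])
      .obj_coverage(ob, crop_box) >= 0.5
    }, TRUE)
    ann <- ann[keep, , drop = FALSE]
    ann$x_min <- pmax(ann$x_min - x0, 0); ann$x_max <- pmin(ann$x_max - x0, nw)
    ann$y_min <- pmax(ann$y_min - y0, 0); ann$y_max <- pmin(ann$y_max - y0, nh)
  }
  labeled_image(limg$image[(y0 + 1):(y0 + nh), (x0 + 1):(x0 + nw), , drop = FALSE],
                ann, limg$height_tag, limg$stage_tag)
}

.tf_resize <- function(limg, ...) {
  d <- dim(limg$image)
  f <- stats::runif(1, 0.5, 1.5)
  method <- sample(c("bilinear", "nearest"), 1L)
  nh <- max(8L, round(d[1] * f)); nw <- max(8L, round(d[2] * f))
  ann <- limg$annotations
  if (nrow(ann)) {
    sx <- nw / d[2]; sy <- nh / d[1]
    ann$x_min <- ann$x_min * sx; ann$x_max <- ann$x_max * sx
    ann$y_min <- ann$y_min * sy; ann$y_max <- ann$y_max * sy
  }
  labeled_image(resize_image(limg$image, nh, nw, method), ann,
                limg$height_tag, limg$stage_tag)
}

.tf_brightness <- function(limg, ...) {
  labeled_image(clamp01(limg$image + stats::runif(1, -0.2, 0.2)),
                limg$annotations, limg$height_tag, limg$stage_tag)
}

.tf_contrast <- function(limg, ...) {
  f <- stats::runif(1, 0.7, 1.3)
  labeled_image(clamp01((limg$image - 0.5) * f + 0.5),
                limg$annotations, limg$height_tag, limg$stage_tag)
}

.box_blur3 <- function(img) {
  d <- dim(img)
  out <- img
  for (c in 1:3) {
    ch <- img[, , c]
    padr <- ch[c(1, 1:d[1], d[1]), ]
    v <- padr[1:d[1], ] + padr[2:(d[1] + 1), ] + padr[3:(d[1] + 2), ]
    padc <- v[, c(1, 1:d[2], d[2])]
    out[, , c] <- (padc[, 1:d[2]] + padc[, 2:(d[2] + 1)] + padc[, 3:(d[2] + 2)]) / 9
  }
  out
}

.tf_sharpen <- function(limg, ...) {
  amt <- stats::runif(1, 0.5, 1.5)
  img <- clamp01(limg$image + amt * (limg$image - .box_blur3(limg$image)))
  labeled_image(img, limg$annotations, limg$height_tag, limg$stage_tag)
}

.tf_salt_pepper <- function(limg, ...) {
  img <- limg$image
  d <- dim(img)
  n <- d[1] * d[2]
  k <- max(1L, round(0.01 * n))
  idx <- sample.int(n, k)
  val <- sample(c(0, 1), k, replace = TRUE)
  for (c in 1:3) {
    ch <- img[, , c]; ch[idx] <- val; img[, , c] <- ch
  }
  labeled_image(img, limg$annotations, limg$height_tag, limg$stage_tag)
}

.tf_gauss_noise <- function(limg, ...) {
  img <- clamp01(limg$image + stats::rnorm(length(limg$image), 0, 0.03))
  labeled_image(img, limg$annotations, limg$height_tag, limg$stage_tag)
}

.augment_transforms <- function() {
  list(crop = .tf_crop, hflip = .tf_hflip, vflip = .tf_vflip,
       rotate = .tf_rot90, resize = .tf_resize, brightness = .tf_brightness,
       contrast = .tf_contrast, sharpen = .tf_sharpen,
       salt_pepper = .tf_salt_pepper, gauss_noise = .tf_gauss_noise)
}

.resize_labeled <- function(limg, size) {
  d <- dim(limg$image)
  ann <- limg$annotations
  if (nrow(ann)) {
    sx <- size / d[2]; sy <- size / d[1]
    ann$x_min <- ann$x_min * sx; ann$x_max <- ann$x_max * sx
    ann$y_min <- ann$y_min * sy; ann$y_max <- ann$y_max * sy
  }
  labeled_image(resize_image(limg$image, size, size), ann,
                limg$height_tag, limg$stage_tag)
}

#' Randomized dataset augmentation
#'
#' For each source image, draws `aug_num` in \{2, 3, 4\} and produces that
#' many derivatives, each the composition of exactly two randomly chosen
#' transforms (position: limited random crop, horizontal/vertical flip,
#' 90-degree rotation, random-interpolation resize; color: brightness,
#' contrast, sharpening, salt-and-pepper noise, Gaussian noise) followed by
#' a resize to `size` x `size`. The originals (also resized) are kept, so
#' the output holds between `3N` and `5N` images for `N` sources. A
#' geometric transform that removes every box is retried up to
#' `max_retries` times and the derivative is dropped (with a message) if
#' boxes still vanish.
#'
#' @param imgs list of `labeled_image`
#' @param seed integer RNG seed
#' @param size output side in pixels (default 416)
#' @param aug_range inclusive range of `aug_num` (default `c(2L, 4L)`);
#'   set e.g. `c(3L, 3L)` for an always-inclusive reading of the loop bound
#' @param max_retries redraw attempts when all boxes are lost (default 5)
#' @return list of `labeled_image`, each `size` x `size`
#' @export
augment_dataset <- function(imgs, seed = 1L, size = 416L,
                            aug_range = c(2L, 4L), max_retries = 5L) {
  set.seed(as.integer(seed))
  tfs <- .augment_transforms()
  out <- lapply(imgs, .resize_labeled, size = size)
  for (src in imgs) {
    aug_num <- sample(aug_range[1]:aug_range[2], 1L)
    for (i in seq_len(aug_num)) {
      ok <- FALSE
      for (try in seq_len(max_retries)) {
        b <- src
        for (t in 1:2) {
          f <- tfs[[sample(length(tfs), 1L)]]
          b <- f(b)
        }
        if (nrow(src$annotations) == 0L || nrow(b$annotations) > 0L) {
          ok <- TRUE; break
        }
      }
      if (!ok) {
        message("augment: derivative dropped (all boxes removed after ",
                max_retries, " retries)")
        next
      }
      out[[length(out) + 1L]] <- .resize_labeled(b, size)
    }
  }
  out
}

#' Split a manifest into train/validation/test
#'
#' Random disjoint assignment at the stated proportions using
#' largest-remainder rounding, so a 4250-row manifest at the default
#' 70/10/20 yields exactly 2975/425/850.
#'
#' @param manifest data frame (one row per image)
#' @param fractions length-3 proportions summing to 1 (train, val, test)
#' @param seed integer RNG seed
#' @return manifest with a `split` factor column
#' @export
split_dataset <- function(manifest, fractions = c(0.7, 0.1, 0.2), seed = 1L) {
  stopifnot(is.data.frame(manifest))
  if (nrow(manifest) == 0L) stop("cannot split an empty manifest")
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  n <- nrow(manifest)
  base <- floor(fractions * n)
  rem <- n - sum(base)
  if (rem > 0) {
    frac_part <- fractions * n - base
    ord <- order(frac_part, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1L
  }
  set.seed(as.integer(seed))
  lab <- rep(c("train", "val", "test"), times = base)
  manifest$split <- factor(sample(lab), levels = c("train", "val", "test"))
  manifest
}

#' Read/write a dataset manifest as a tab-separated table
#' @param manifest data frame
#' @param path file path
#' @export
write_manifest <- function(manifest, path) {
  utils::write.table(manifest, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
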