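#' Synthetic UAV scenes
#'
#' Stand-in fixture generator for field imagery (the surveyed UAV corpus
#' is not publicly deposited): procedurally textured frames with sparse
#' disk-shaped "poppy plot" objects whose pixel diameter follows
#' `30 cm / GSD` (about 37 px for the 1-inch-sensor preset at 30 m), over
#' a cluttered vegetated background with building-like rectangles and
#' shrub-like blobs. Objects are drawn by growth stage: seedlings are
#' grey-green speckled disks; flowering plots carry red/white dots on
#' green. The textures are deliberately schematic — sufficient to exercise
#' the dataset pipeline, the loss, evaluation and CPU smoke training, not
#' to emulate radiometry.
#'
#' @name synthetic_scenes
NULL

#' Scene specification
#'
#' @param frame_w,frame_h frame size in pixels (default full-frame
#'   5472 x 3648)
#' @param camera camera preset name or a `camera_spec`
#' @param height_m flying height (m), sets the GSD and with it the object
#'   pixel diameter
#' @param n_objects fixed count or inclusive range `c(lo, hi)`
#' @param stage `"flowering"` or `"seedling"` object texture
#' @param clutter background clutter level in \[0, 1\]
#' @param size_jitter multiplicative diameter jitter (default 0.2:
#'   diameters drawn uniformly within +/-20% of 30 cm / GSD)
#' @param object_cm ground diameter of one object (default 30 cm)
#' @param label class label written to annotations
#' @return object of class `scene_spec`
#' @export
scene_spec <- function(frame_w = 5472L, frame_h = 3648L, camera = "dji",
                       height_m = 30, n_objects = c(1L, 3L),
                       stage = c("flowering", "seedling"), clutter = 0.5,
                       size_jitter = 0.2, object_cm = 30, label = "poppy") {
  stage <- match.arg(stage)
  cam <- if (inherits(camera, "camera_spec")) camera else camera_preset(camera)
  g <- gsd(cam, height_m)
  diam <- object_pixel_diameter(g, object_cm)
  if (diam * (1 + size_jitter) >= min(frame_w, frame_h))
    stop(sprintf("object diameter %.0f px exceeds the %d x %d frame",
                 diam, frame_w, frame_h))
  structure(list(frame_w = as.integer(frame_w), frame_h = as.integer(frame_h),
                 camera = cam, height_m = height_m,
                 n_objects = as.integer(n_objects), stage = stage,
                 clutter = clutter, size_jitter = size_jitter,
                 object_cm = object_cm, label = label,
                 gsd_cm = g, diameter_px = diam),
            class = "scene_spec")
}

#' @export
print.scene_spec <- function(x, ...) {
  cat(sprintf("<scene_spec> %d x %d px, %s @ %g m (GSD %.2f cm, object ~%.0f px), %s\n",
              x$frame_w, x$frame_h, x$camera$name, x$height_m, x$gsd_cm,
              x$diameter_px, x$stage))
  invisible(x)
}

# blend a soft-edged disk into img; returns modified img
.draw_disk <- function(img, cx, cy, r, color, soft = 1.5) {
  d <- dim(img)
  y0 <- max(1L, floor(cy - r - soft)); y1 <- min(d[1], ceiling(cy + r + soft))
  x0 <- max(1L, floor(cx - r - soft)); x1 <- min(d[2], ceiling(cx + r + soft))
  if (y1 < y0 || x1 < x0) return(img)
  ys <- y0:y1; xs <- x0:x1
  dist <- sqrt(outer((ys - cy)^2, (xs - cx)^2, "+"))
  alpha <- clamp01((r - dist) / soft + 0.5)
  for (c in 1:3) {
    patch <- img[ys, xs, c]
    img[ys, xs, c] <- patch * (1 - alpha) + color[c] * alpha
  }
  img
}

.draw_rect <- function(img, x0, y0, w, h, color) {
  d <- dim(img)
  xs <- max(1L, x0):min(d[2], x0 + w)
  ys <- max(1L, y0):min(d[1], y0 + h)
  for (c in 1:3) img[ys, xs, c] <- color[c]
  img
}

# low-resolution random field upsampled over the frame (cheap large-scale
# vegetation mottling)
.smooth_field <- function(h, w, cells = 16L, sd = 1) {
  low <- array(stats::rnorm(cells * cells * 3, 0, sd), c(cells, cells, 3L))
  resize_image(low, h, w, "bilinear")
}

.poppy_texture <- function(img, cx, cy, r, stage) {
  if (stage == "seedling") {
    img <- .draw_disk(img, cx, cy, r, c(0.52, 0.58, 0.44))
    img <- .draw_disk(img, cx, cy, r * 0.55, c(0.47, 0.55, 0.40))
    n_sp <- max(3L, round(r))
    for (k in seq_len(n_sp)) {
      a <- stats::runif(1, 0, 2 * pi); rr <- stats::runif(1, 0, r * 0.85)
      img <- .draw_disk(img, cx + rr * cos(a), cy + rr * sin(a),
                        max(1, r / 8), c(0.58, 0.62, 0.50), soft = 1)
    }
  } else {
    img <- .draw_disk(img, cx, cy, r, c(0.30, 0.46, 0.20))
    n_fl <- max(4L, round(r * 1.2))
    for (k in seq_len(n_fl)) {
      a <- stats::runif(1, 0, 2 * pi); rr <- stats::runif(1, 0, r * 0.8)
      col <- if (stats::runif(1) < 0.7) c(0.85, 0.15, 0.22) else c(0.92, 0.90, 0.88)
      img <- .draw_disk(img, cx + rr * cos(a), cy + rr * sin(a),
                        max(1, r / 7), col, soft = 1)
    }
  }
  img
}

#' Generate one synthetic labeled scene
#'
#' Bit-reproducible under a fixed seed. Overlapping objects are permitted
#' and reported with a message.
#'
#' @param spec a `scene_spec`
#' @param seed integer RNG seed
#' @return a `labeled_image` with exact bounding boxes
#' @export
generate_scene <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "scene_spec"))
  set.seed(as.integer(seed))
  H <- spec$frame_h; W <- spec$frame_w
  base <- c(0.31, 0.42, 0.23)
  img <- new_image(H, W, base)
  img <- clamp01(img + 0.05 * .smooth_field(H, W))
  if (H * W <= 1024L * 1024L)  # fine grain only on small frames (cost)
    img <- clamp01(img + array(stats::rnorm(H * W * 3, 0, 0.015), dim(img)))

  # clutter: building-like rectangles, shrub-like blobs
  n_bld <- round(spec$clutter * 6)
  n_shr <- round(spec$clutter * 10)
  cap <- round(0.4 * min(H, W))
  bld_px <- min(cap, max(8L, round(500 / spec$gsd_cm)))  # ~5 m footprint
  for (k in seq_len(n_bld)) {
    w <- round(stats::runif(1, 0.4, 1) * bld_px)
    h <- round(stats::runif(1, 0.4, 1) * bld_px)
    col <- if (stats::runif(1) < 0.5) stats::runif(1, 0.45, 0.7) * c(1, 1, 1)
           else c(0.55, 0.32, 0.22) * stats::runif(1, 0.8, 1.2)
    img <- .draw_rect(img, sample.int(max(W - w, 1L), 1L),
                      sample.int(max(H - h, 1L), 1L), w, h, clamp01(col))
  }
  shr_px <- min(cap, max(4L, round(150 / spec$gsd_cm)))  # ~1.5 m shrubs
  for (k in seq_len(n_shr)) {
    r <- stats::runif(1, 0.3, 1) * shr_px / 2
    img <- .draw_disk(img, stats::runif(1, 1, W), stats::runif(1, 1, H), r,
                      c(0.16, 0.30, 0.13) * stats::runif(1, 0.8, 1.2))
  }

  # objects
  n <- if (length(spec$n_objects) == 2L)
    sample(spec$n_objects[1]:spec$n_objects[2], 1L) else spec$n_objects[1]
  ann <- .empty_annotations()
  centers <- matrix(numeric(0), 0, 2)
  overlaps <- 0L
  for (k in seq_len(n)) {
    dfac <- stats::runif(1, 1 - spec$size_jitter, 1 + spec$size_jitter)
    diam <- spec$diameter_px * dfac
    r <- diam / 2
    margin <- r + 3
    cx <- stats::runif(1, margin, W - margin)
    cy <- stats::runif(1, margin, H - margin)
    if (nrow(centers) &&
        any(sqrt((centers[, 1] - cx)^2 + (centers[, 2] - cy)^2) < 2 * r))
      overlaps <- overlaps + 1L
    centers <- rbind(centers, c(cx, cy))
    img <- .poppy_texture(img, cx, cy, r, spec$stage)
    ann <- rbind(ann, data.frame(
      x_min = floor(cx - r), y_min = floor(cy - r),
      x_max = ceiling(cx + r), y_max = ceiling(cy + r),
      label = spec$label, stringsAsFactors = FALSE))
  }
  if (overlaps > 0L) message("generate_scene: ", overlaps, " overlapping object(s)")
  labeled_image(img, ann, height_tag = spec$height_m, stage_tag = spec$stage)
}

#' Generate a corpus of scenes with annotations on disk
#'
#' Writes `frame_%04d.ppm` / `.xml` pairs plus a `manifest.tsv`. When
#' `cell_counts` (a stage x height matrix such as [default_cell_counts()])
#' is given, `n_frames` is distributed across the cells proportionally
#' (largest-remainder rounding) and each frame is generated with its
#' cell's flying height and growth stage.
#'
#' @param spec a `scene_spec` (frame size, camera, clutter are shared)
#' @param n_frames number of frames
#' @param out_dir output directory (created)
#' @param seed integer RNG seed; frame `i` uses `seed + i`
#' @param cell_counts optional stage x height weight matrix
#' @return the manifest data frame (invisibly written to
#'   `out_dir/manifest.tsv`)
#' @export
generate_corpus <- function(spec, n_frames, out_dir, seed = 1L,
                            cell_counts = NULL) {
  stopifnot(inherits(spec, "scene_spec"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  cells <- if (is.null(cell_counts)) {
    data.frame(stage = spec$stage, height = spec$height_m, n = n_frames)
  } else {
    w <- as.numeric(t(cell_counts)) # row-major: stage by stage
    grid <- expand.grid(height = as.numeric(colnames(cell_counts)),
                        stage = rownames(cell_counts),
                        stringsAsFactors = FALSE)
    q <- n_frames * w / sum(w)
    base <- floor(q); rem <- n_frames - sum(base)
    if (rem > 0) {
      ord <- order(q - base, decreasing = TRUE)
      base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
    }
    data.frame(stage = grid$stage, height = grid$height, n = base)
  }
  manifest <- list()
  i <- 0L
  for (r in seq_len(nrow(cells))) {
    if (cells$n[r] == 0) next
    sp <- scene_spec(frame_w = spec$frame_w, frame_h = spec$frame_h,
                     camera = spec$camera, height_m = cells$height[r],
                     n_objects = spec$n_objects, stage = cells$stage[r],
                     clutter = spec$clutter, size_jitter = spec$size_jitter,
                     object_cm = spec$object_cm, label = spec$label)
    for (k in seq_len(cells$n[r])) {
      i <- i + 1L
      limg <- generate_scene(sp, seed = as.integer(seed) + i)
      img_path <- file.path(out_dir, sprintf("frame_%04d.ppm", i))
      xml_path <- file.path(out_dir, sprintf("frame_%04d.xml", i))
      ok <- tryCatch({
        write_ppm(limg$image, img_path)
        write_voc_xml(limg, xml_path, image_filename = basename(img_path))
        TRUE
      }, error = function(e) stop("I/O failure writing ", img_path, ": ",
                                  conditionMessage(e)))
      manifest[[i]] <- data.frame(image = basename(img_path),
                                  height_tag = cells$height[r],
                                  stage_tag = cells$stage[r],
                                  n_objects = nrow(limg$annotations),
                                  stringsAsFactors = FALSE)
    }
  }
  manifest <- if (length(manifest)) do.call(rbind, manifest) else
    data.frame(image = character(0), height_tag = numeric(0),
               stage_tag = character(0), n_objects = integer(0))
  write_manifest(manifest, file.path(out_dir, "manifest.tsv"))
  manifest
}

#' Load `image.ppm` / `image.xml` pairs from a directory
#'
#' @param dir directory containing PPM images with sibling VOC XML files
#' @param height_tag,stage_tag defaults when the manifest is absent
#' @return named list of `labeled_image`
#' @export
load_labeled_dir <- function(dir, height_tag = NA_real_,
                             stage_tag = NA_character_) {
  ppms <- sort(list.files(dir, pattern = "\\.ppm$", full.names = TRUE))
  man_path <- file.path(dir, "manifest.tsv")
  man <- if (file.exists(man_path)) read_manifest(man_path) else NULL
  out <- list()
  for (p in ppms) {
    xml <- sub("\\.ppm$", ".xml", p)
    img <- read_ppm(p)
    ann <- if (file.exists(xml)) read_voc_xml(xml)$annotations else NULL
    ht <- height_tag; st <- stage_tag
    if (!is.null(man)) {
      row <- match(basename(p), man$image)
      if (!is.na(row)) { ht <- man$height_tag[row]; st <- man$stage_tag[row] }
    }
    out[[basename(p)]] <- labeled_image(img, ann, height_tag = ht,
                                        stage_tag = st)
  }
  out
}
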