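#' The detector graph
#'
#' A YOLOv3-style three-scale single-stage detector with a pluggable
#' backbone (a MobileNetv2-style inverted-residual network by default) and
#' an optional padded stride-1 spatial-pyramid-pooling (SPP) unit. For a
#' 416 x 416 input the three prediction grids are 13 x 13, 26 x 26 and
#' 52 x 52 (strides 32/16/8), fused coarse-to-fine by upsample-and-concat.
#' The SPP unit max-pools a feature map at `levels` filter sizes
#' `ceiling(S/n)` (stride 1, shape-preserving padding) and concatenates the
#' input with all pooled maps, widening channels by `(levels + 1)`; it can
#' be placed in the first (coarsest) prediction stage only, in all three
#' stages, or omitted.
#'
#' @name network_model
NULL

#' SPP pooling filter size
#'
#' `ceiling(map_size / n)`: for the 13/26/52 grids and `n` in 1..3 this
#' yields filter sizes \{13, 7, 5\}, \{26, 13, 9\} and \{52, 26, 18\}.
#'
#' @param map_size square feature-map side (>= 1)
#' @param n pyramid level (>= 1)
#' @return integer filter side
#' @export
spp_filter_size <- function(map_size, n) {
  stopifnot(all(map_size >= 1), all(n >= 1))
  as.integer(ceiling(map_size / n))
}

#' Apply a padded stride-1 SPP unit to a feature map
#'
#' @param feature_map square `[S, S, C]` array
#' @param levels number of pyramid levels (1..3 typical)
#' @return `[S, S, (levels + 1) * C]` array: the input followed by its
#'   max-pooled versions at filter sizes `ceiling(S / n)`, `n = 1..levels`
#' @export
spp_unit <- function(feature_map, levels = 3L) {
  d <- dim(feature_map)
  if (is.null(d) || length(d) != 3L) stop("feature map must be [S, S, C]")
  if (d[1] != d[2]) stop("SPP expects a square feature map, got ",
                         d[1], " x ", d[2])
  pools <- lapply(seq_len(levels), function(n) {
    k <- spp_filter_size(d[1], n)
    array(maxpool_s1_cpp(feature_map, d[1], d[2], d[3], k)$y, d)
  })
  out <- array(unlist(c(list(feature_map), pools), use.names = FALSE),
               c(d[1], d[2], (levels + 1L) * d[3]))
  out
}

#' Standard YOLOv3 anchor preset scaled to the unit square
#' @return 9 x 2 matrix of (w, h), ascending area
#' @export
yolo_anchor_preset <- function() {
  px <- matrix(c(10, 13, 16, 30, 33, 23, 30, 61, 62, 45, 59, 119,
                 116, 90, 156, 198, 373, 326), ncol = 2, byrow = TRUE)
  px / 416
}

#' K-means (IoU distance) anchors from training boxes
#'
#' Lloyd iterations with distance `1 - IoU` between centred box shapes;
#' returns the `k` cluster shapes sorted by ascending area.
#'
#' @param wh n x 2 matrix of normalized box widths/heights
#' @param k number of anchors (default 9)
#' @param seed RNG seed
#' @param iters maximum iterations
#' @return k x 2 matrix of (w, h)
#' @export
kmeans_anchors <- function(wh, k = 9L, seed = 1L, iters = 100L) {
  wh <- as.matrix(wh)
  stopifnot(ncol(wh) == 2L)
  if (nrow(wh) < k) {
    # too few shapes to cluster: jitter replicates
    set.seed(as.integer(seed))
    wh <- wh[sample.int(nrow(wh), k, replace = TRUE), , drop = FALSE] *
      matrix(stats::runif(2 * k, 0.9, 1.1), k, 2)
  }
  set.seed(as.integer(seed))
  centers <- wh[sample.int(nrow(wh), k), , drop = FALSE]
  shape_iou <- function(a, b) {
    # IoU of co-centred boxes: overlap is the min along each axis
    iw <- outer(a[, 1], b[, 1], pmin); ih <- outer(a[, 2], b[, 2], pmin)
    inter <- iw * ih
    un <- outer(a[, 1] * a[, 2], b[, 1] * b[, 2], "+") - inter
    inter / un
  }
  assign <- rep(0L, nrow(wh))
  for (it in seq_len(iters)) {
    iou <- shape_iou(wh, centers)
    new_assign <- max.col(iou, ties.method = "first")
    if (identical(new_assign, assign)) break
    assign <- new_assign
    for (j in seq_len(k)) {
      idx <- assign == j
      if (any(idx)) centers[j, ] <- colMeans(wh[idx, , drop = FALSE])
    }
  }
  centers[order(centers[, 1] * centers[, 2]), , drop = FALSE]
}

#' Detector configuration
#'
#' @param input_size square input side, divisible by 32 (default 416)
#' @param backbone registered backbone id (default `"mobilenetv2"`)
#' @param width_mult channel width multiplier; small values give desk-scale
#'   models trainable on a CPU in minutes
#' @param classes number of object classes (default 1)
#' @param labels class labels
#' @param anchors 9 x 2 matrix of normalized (w, h) priors, ascending area;
#'   rows 7-9 serve the coarse 13 x 13 grid, 4-6 the 26 x 26, 1-3 the 52 x 52
#' @param spp SPP placement: `"first"` (coarsest stage only, the default
#'   single-unit variant), `"all"` (three-unit variant) or `"none"`
#' @param spp_levels pyramid levels in each SPP unit (default 3)
#' @param expand inverted-residual expansion ratio (default 2; kept small
#'   for CPU-scale training)
#' @return object of class `detector_config`
#' @export
detector_config <- function(input_size = 416L, backbone = "mobilenetv2",
                            width_mult = 1, classes = 1L, labels = "poppy",
                            anchors = yolo_anchor_preset(),
                            spp = c("first", "none", "all"),
                            spp_levels = 3L, expand = 2L) {
  spp <- match.arg(spp)
  input_size <- as.integer(input_size)
  if (input_size %% 32L != 0L) stop("input_size must be divisible by 32")
  anchors <- as.matrix(anchors)
  if (!identical(dim(anchors), c(9L, 2L)) && !identical(dim(anchors), as.integer(c(9, 2))))
    stop("anchors must be a 9 x 2 matrix")
  if (any(anchors <= 0)) stop("anchors must be positive")
  if (length(labels) != classes) labels <- paste0("class", seq_len(classes))
  structure(list(input_size = input_size, backbone = backbone,
                 width_mult = width_mult, classes = as.integer(classes),
                 labels = labels, anchors = anchors, spp = spp,
                 spp_levels = as.integer(spp_levels),
                 expand = expand, n_anchors = 3L),
            class = "detector_config")
}

#' Grid sizes of the three prediction scales
#' @param cfg a `detector_config`
#' @return integer vector (input/32, input/16, input/8)
#' @export
grid_sizes <- function(cfg) as.integer(cfg$input_size / c(32L, 16L, 8L))

#' Anchors serving one prediction scale
#' @param cfg a `detector_config`
#' @param scale 1 (coarse, 13 x 13) to 3 (fine, 52 x 52)
#' @return 3 x 2 matrix of normalized (w, h)
#' @export
scale_anchors <- function(cfg, scale) {
  rows <- switch(scale, `1` = 7:9, `2` = 4:6, `3` = 1:3)
  cfg$anchors[rows, , drop = FALSE]
}

# ---- parameter init --------------------------------------------------------

.he_conv <- function(KH, KW, Cin, Cout) {
  fan_in <- KH * KW * Cin
  list(w = array(stats::rnorm(KH * KW * Cin * Cout, 0, sqrt(2 / fan_in)),
                 c(KH, KW, Cin, Cout)),
       b = rep(0, Cout))
}

.he_dw <- function(KH, KW, C) {
  fan_in <- KH * KW
  list(w = array(stats::rnorm(KH * KW * C, 0, sqrt(2 / fan_in)), c(KH, KW, C)),
       b = rep(0, C))
}

.width <- function(base, mult) max(4L, as.integer(round(base * mult)))

# ---- backbone registry -----------------------------------------------------

.backbone_registry <- new.env(parent = emptyenv())

#' Register a backbone
#'
#' A backbone is a pair of functions: `init(cfg, rng)` returning a named
#' parameter list plus the channel counts of its stride-8/16/32 taps, and
#' `forward(tape, xid, params, cfg)` returning the tap node ids.
#'
#' @param name backbone id
#' @param init,forward functions (see Details)
#' @export
register_backbone <- function(name, init, forward) {
  assign(name, list(init = init, forward = forward), envir = .backbone_registry)
  invisible(name)
}

#' @rdname register_backbone
#' @export
list_backbones <- function() ls(.backbone_registry)

.get_backbone <- function(name) {
  if (!exists(name, envir = .backbone_registry))
    stop("unknown backbone '", name, "'; registered: ",
         paste(list_backbones(), collapse = ", "))
  get(name, envir = .backbone_registry)
}

# MobileNetv2-style backbone: stem conv then one inverted-residual
# downsampling block per stage with a stride-1 residual block at the three
# tapped stages. Taps at strides 8/16/32.
.mnv2_widths <- function(mult) {
  c(stem = .width(16, mult), s4 = .width(24, mult), s8 = .width(32, mult),
    s16 = .width(64, mult), s32 = .width(96, mult))
}

.mnv2_init <- function(cfg) {
  wd <- .mnv2_widths(cfg$width_mult)
  ex <- cfg$expand
  P <- list()
  P[["bb.stem"]] <- .he_conv(3, 3, 3, wd["stem"])
  blocks <- list(c("s4", wd["stem"], wd["s4"]), c("s8", wd["s4"], wd["s8"]),
                 c("s16", wd["s8"], wd["s16"]), c("s32", wd["s16"], wd["s32"]))
  for (b in blocks) {
    nm <- b[1]; cin <- as.integer(b[2]); cout <- as.integer(b[3])
    P[[paste0("bb.", nm, ".exp")]] <- .he_conv(1, 1, cin, cin * ex)
    P[[paste0("bb.", nm, ".dw")]] <- .he_dw(3, 3, cin * ex)
    P[[paste0("bb.", nm, ".proj")]] <- .he_conv(1, 1, cin * ex, cout)
    if (nm %in% c("s8", "s16", "s32")) {
      P[[paste0("bb.", nm, ".r.exp")]] <- .he_conv(1, 1, cout, cout * ex)
      P[[paste0("bb.", nm, ".r.dw")]] <- .he_dw(3, 3, cout * ex)
      P[[paste0("bb.", nm, ".r.proj")]] <- .he_conv(1, 1, cout * ex, cout)
    }
  }
  list(params = P,
       taps = c(s8 = unname(wd["s8"]), s16 = unname(wd["s16"]),
                s32 = unname(wd["s32"])))
}

.invres <- function(t, xid, P, prefix, stride, residual) {
  h <- ad_conv(t, xid, P[[paste0(prefix, ".exp")]], paste0(prefix, ".exp"))
  h <- ad_leaky(t, h)
  h <- ad_dwconv(t, h, P[[paste0(prefix, ".dw")]], paste0(prefix, ".dw"),
                 stride = stride)
  h <- ad_leaky(t, h)
  h <- ad_conv(t, h, P[[paste0(prefix, ".proj")]], paste0(prefix, ".proj"))
  if (residual) h <- ad_add(t, h, xid)
  h
}

.mnv2_forward <- function(t, xid, P, cfg) {
  h <- ad_conv(t, xid, P[["bb.stem"]], "bb.stem", stride = 2L)
  h <- ad_leaky(t, h)
  h <- .invres(t, h, P, "bb.s4", 2L, FALSE)
  h <- .invres(t, h, P, "bb.s8", 2L, FALSE)
  h <- .invres(t, h, P, "bb.s8.r", 1L, TRUE)
  tap8 <- h
  h <- .invres(t, h, P, "bb.s16", 2L, FALSE)
  h <- .invres(t, h, P, "bb.s16.r", 1L, TRUE)
  tap16 <- h
  h <- .invres(t, h, P, "bb.s32", 2L, FALSE)
  h <- .invres(t, h, P, "bb.s32.r", 1L, TRUE)
  list(s8 = tap8, s16 = tap16, s32 = h)
}

# ---- detector --------------------------------------------------------------

#' Build a detector
#'
#' Initializes all parameters (He-normal weights, zero biases; the
#' objectness bias starts at -2 so a fresh model predicts mostly
#' background) and returns a trainable detector object.
#'
#' @param cfg a `detector_config`
#' @param seed RNG seed for initialization
#' @return object of class `poppy_detector`
#' @export
build_detector <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "detector_config"))
  bb <- .get_backbone(cfg$backbone)
  set.seed(as.integer(seed))
  init <- bb$init(cfg)
  P <- init$params
  taps <- init$taps
  nout <- cfg$n_anchors * (5L + cfg$classes)
  h1 <- .width(96, cfg$width_mult)
  h2 <- .width(48, cfg$width_mult)
  h3 <- .width(24, cfg$width_mult)
  sppk <- cfg$spp_levels + 1L
  P[["hd.1.pre"]] <- .he_conv(1, 1, taps[["s32"]], h1)
  if (cfg$spp %in% c("first", "all"))
    P[["hd.1.sppred"]] <- .he_conv(1, 1, sppk * h1, h1)
  P[["hd.1.out"]] <- .he_conv(1, 1, h1, nout)
  P[["hd.1.route"]] <- .he_conv(1, 1, h1, h2)
  P[["hd.2.pre"]] <- .he_conv(1, 1, h2 + taps[["s16"]], h2)
  if (cfg$spp == "all")
    P[["hd.2.sppred"]] <- .he_conv(1, 1, sppk * h2, h2)
  P[["hd.2.out"]] <- .he_conv(1, 1, h2, nout)
  P[["hd.2.route"]] <- .he_conv(1, 1, h2, h3)
  P[["hd.3.pre"]] <- .he_conv(1, 1, h3 + taps[["s8"]], h3)
  if (cfg$spp == "all")
    P[["hd.3.sppred"]] <- .he_conv(1, 1, sppk * h3, h3)
  P[["hd.3.out"]] <- .he_conv(1, 1, h3, nout)
  # objectness bias: index 5 within each anchor block
  for (s in 1:3) {
    b <- P[[paste0("hd.", s, ".out")]]$b
    b[5L + (0:(cfg$n_anchors - 1L)) * (5L + cfg$classes)] <- -2
    P[[paste0("hd.", s, ".out")]]$b <- b
  }
  structure(list(cfg = cfg, params = P, head_widths = c(h1, h2, h3)),
            class = "poppy_detector")
}

#' @export
print.poppy_detector <- function(x, ...) {
  cat(sprintf(paste0("<poppy_detector> backbone %s (width x%.2f), input %d,",
                     " SPP '%s', %d parameters\n"),
              x$cfg$backbone, x$cfg$width_mult, x$cfg$input_size, x$cfg$spp,
              n_parameters(x)))
  invisible(x)
}

#' Total number of trainable scalars in a detector
#' @param detector a `poppy_detector`
#' @export
n_parameters <- function(detector) {
  sum(vapply(detector$params,
             function(p) length(p$w) + length(p$b), 0))
}

.head_stage <- function(t, xid, P, cfg, stage) {
  pre <- paste0("hd.", stage, ".pre")
  h <- ad_conv(t, xid, P[[pre]], pre)
  h <- ad_leaky(t, h)
  use_spp <- (stage == 1L && cfg$spp %in% c("first", "all")) ||
             (stage > 1L && cfg$spp == "all")
  if (use_spp) {
    S <- dim(t$val[[h]])[1]
    ids <- list(h)
    for (n in seq_len(cfg$spp_levels))
      ids[[n + 1L]] <- ad_maxpool_s1(t, h, spp_filter_size(S, n))
    h <- ad_concat(t, ids)
    red <- paste0("hd.", stage, ".sppred")
    h <- ad_conv(t, h, P[[red]], red)
    h <- ad_leaky(t, h)
  }
  outp <- paste0("hd.", stage, ".out")
  out <- ad_conv(t, h, P[[outp]], outp)
  list(feat = h, out = out)
}

#' Forward pass of the detector
#'
#' @param detector a `poppy_detector`
#' @param img `[S, S, 3]` array matching `cfg$input_size`
#' @param tape optional tape (created when `NULL`); pass one to retain the
#'   graph for a backward pass during training
#' @return list with `grids` (raw `[S, S, B, 5 + C]` arrays, coarse to
#'   fine), `out_ids` (tape node ids) and `tape`
#' @export
forward_detector <- function(detector, img, tape = NULL) {
  cfg <- detector$cfg
  d <- dim(img)
  if (d[1] != cfg$input_size || d[2] != cfg$input_size)
    stop("input must be ", cfg$input_size, " x ", cfg$input_size)
  t <- if (is.null(tape)) tape_new() else tape
  x <- tp_input(t, img)
  P <- detector$params
  taps <- .get_backbone(cfg$backbone)$forward(t, x, P, cfg)
  s1 <- .head_stage(t, taps$s32, P, cfg, 1L)
  r1 <- ad_conv(t, s1$feat, P[["hd.1.route"]], "hd.1.route")
  r1 <- ad_leaky(t, r1)
  u1 <- ad_upsample2(t, r1)
  c2 <- ad_concat(t, list(u1, taps$s16))
  s2 <- .head_stage(t, c2, P, cfg, 2L)
  r2 <- ad_conv(t, s2$feat, P[["hd.2.route"]], "hd.2.route")
  r2 <- ad_leaky(t, r2)
  u2 <- ad_upsample2(t, r2)
  c3 <- ad_concat(t, list(u2, taps$s8))
  s3 <- .head_stage(t, c3, P, cfg, 3L)
  out_ids <- c(s1$out, s2$out, s3$out)
  grids <- lapply(out_ids, function(id) raw_to_grid(t$val[[id]], cfg))
  list(grids = grids, out_ids = out_ids, tape = t)
}

#' Reshape a raw head output `[S, S, B*(5+C)]` to `[S, S, B, 5+C]`
#' @param raw head output array
#' @param cfg a `detector_config`
#' @export
raw_to_grid <- function(raw, cfg) {
  d <- dim(raw)
  B <- cfg$n_anchors; K <- 5L + cfg$classes
  # channels are laid out as B blocks of K (k fastest), so reshape splits
  # K then B; aperm moves the anchor axis before the component axis
  aperm(array(raw, c(d[1], d[2], K, B)), c(1, 2, 4, 3))
}

sigmoid <- function(x) 1 / (1 + exp(-x))
logit <- function(p) log(p / (1 - p))

#' Decode a raw prediction grid to normalized boxes
#'
#' YOLOv3 convention: sigmoid cell-offset centers, exponential
#' anchor-scaled sizes, sigmoid objectness and class scores. All boxes are
#' in normalized image coordinates (x right, y down).
#'
#' @param grid raw `[S, S, B, 5 + C]` array
#' @param anchors `B x 2` matrix of normalized anchor (w, h)
#' @return list with `boxes` (n x 4 corner matrix), `confidence`,
#'   `class_probs` (n x C), `cell` (n x 3: row, col, anchor)
#' @export
decode_grid <- function(grid, anchors) {
  d <- dim(grid)
  S <- d[1]; B <- d[3]; C <- d[4] - 5L
  rows <- array(rep(seq_len(S) - 1L, times = S * B), c(S, S, B))
  cols <- array(rep(rep(seq_len(S) - 1L, each = S), times = B), c(S, S, B))
  anc_w <- array(rep(anchors[, 1], each = S * S), c(S, S, B))
  anc_h <- array(rep(anchors[, 2], each = S * S), c(S, S, B))
  bx <- (sigmoid(grid[, , , 1]) + cols) / S
  by <- (sigmoid(grid[, , , 2]) + rows) / S
  bw <- anc_w * exp(grid[, , , 3])
  bh <- anc_h * exp(grid[, , , 4])
  conf <- sigmoid(grid[, , , 5])
  boxes <- box_from_cwh(as.numeric(bx), as.numeric(by),
                        as.numeric(bw), as.numeric(bh))
  cp <- matrix(sigmoid(grid[, , , 5 + seq_len(C)]), ncol = C)
  list(boxes = .box_mat(boxes), confidence = as.numeric(conf),
       class_probs = cp,
       cell = cbind(row = as.numeric(rows) + 1, col = as.numeric(cols) + 1,
                    anchor = as.numeric(array(rep(seq_len(B), each = S * S),
                                              c(S, S, B)))))
}

#' Encode a normalized box into raw grid activations (decode inverse)
#'
#' @param b normalized corner box
#' @param S grid side
#' @param anchor length-2 normalized anchor (w, h)
#' @return list with `row`, `col` (1-based cell) and `raw` (tx, ty, tw, th)
#' @export
encode_box <- function(b, S, anchor) {
  cwh <- box_to_cwh(b)
  col <- min(floor(cwh[1] * S), S - 1); row <- min(floor(cwh[2] * S), S - 1)
  ox <- cwh[1] * S - col; oy <- cwh[2] * S - row
  ox <- min(max(ox, 1e-6), 1 - 1e-6); oy <- min(max(oy, 1e-6), 1 - 1e-6)
  list(row = row + 1, col = col + 1,
       raw = c(logit(ox), logit(oy), log(cwh[3] / anchor[1]),
               log(cwh[4] / anchor[2])))
}

#' Save / load detector weights
#'
#' Weights are stored with an architecture fingerprint; loading into a
#' mismatched architecture is an error.
#'
#' @param detector a `poppy_detector`
#' @param path file path (`.rds`)
#' @export
save_weights <- function(detector, path) {
  saveRDS(list(fingerprint = arch_fingerprint(detector$cfg),
               cfg = unclass(detector$cfg), params = detector$params,
               head_widths = detector$head_widths),
          path)
  invisible(path)
}

#' @rdname save_weights
#' @export
load_weights <- function(path) {
  obj <- readRDS(path)
  cfg <- structure(obj$cfg, class = "detector_config")
  if (!identical(obj$fingerprint, arch_fingerprint(cfg)))
    stop("weight file fingerprint does not match its configuration")
  structure(list(cfg = cfg, params = obj$params,
                 head_widths = obj$head_widths),
            class = "poppy_detector")
}

#' Architecture fingerprint string
#' @param cfg a `detector_config`
#' @export
arch_fingerprint <- function(cfg) {
  paste(cfg$backbone, cfg$input_size, cfg$width_mult, cfg$classes,
        cfg$spp, cfg$spp_levels, cfg$expand,
        paste(signif(cfg$anchors, 6), collapse = ","), sep = "|")
}
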