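#' Image rasters
#'
#' Images are numeric arrays `[H, W, 3]` with values in \[0, 1\]. On disk the
#' package uses the portable pixmap family (PPM, binary `P6` or plain-text
#' `P3`): a self-describing, dependency-free raster container that every
#' common image tool (ImageMagick, GIMP, Pillow, OpenCV) reads and writes.
#'
#' @name image_io
NULL

#' Create a blank image
#' @param h,w dimensions in pixels
#' @param fill scalar or length-3 RGB fill in \[0,1\]
#' @return `[h, w, 3]` numeric array
#' @export
new_image <- function(h, w, fill = 0) {
  if (length(fill) == 1L) fill <- rep(fill, 3L)
  array(rep(fill, each = h * w), dim = c(h, w, 3L))
}

.check_image <- function(img) {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L)
    stop("image must be an [H, W, 3] array")
  invisible(img)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

#' Write an image as PPM
#'
#' @param img `[H, W, 3]` array in \[0,1\]
#' @param path output path
#' @param ascii write plain-text `P3` instead of binary `P6`
#' @export
write_ppm <- function(img, path, ascii = FALSE) {
  .check_image(img)
  d <- dim(img)
  v <- as.integer(round(clamp01(img) * 255))
  # interleave to R,G,B per pixel, row-major
  px <- aperm(array(v, d), c(3L, 2L, 1L))  # [C, W, H]
  if (ascii) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("P3", paste(d[2], d[1]), "255"), con)
    writeLines(paste(as.vector(px), collapse = " "), con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(c("P6", paste(d[2], d[1]), "255"), con, sep = "\n")
    writeBin(as.raw(as.vector(px)), con)
  }
  invisible(path)
}

#' Read a PPM image (binary `P6` or plain `P3`)
#' @param path file path
#' @return `[H, W, 3]` numeric array in \[0,1\]
#' @export
read_ppm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  read_token <- function() {
    tok <- character(0)
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0L) break
      if (ch == "#") { # comment to end of line
        repeat {
          ch <- readChar(con, 1L, useBytes = TRUE)
          if (length(ch) == 0L || ch == "\n") break
        }
        next
      }
      if (grepl("^[[:space:]]$", ch)) {
        if (length(tok)) break else next
      }
      tok <- c(tok, ch)
    }
    paste(tok, collapse = "")
  }
  magic <- read_token()
  if (!magic %in% c("P3", "P6")) stop("not a PPM file: ", path)
  w <- as.integer(read_token()); h <- as.integer(read_token())
  maxv <- as.integer(read_token())
  n <- 3L * w * h
  if (magic == "P6") {
    v <- as.integer(readBin(con, "raw", n = n))
  } else {
    v <- scan(con, what = integer(), n = n, quiet = TRUE)
  }
  px <- array(v, dim = c(3L, w, h))          # [C, W, H], row-major pixels
  img <- aperm(px, c(3L, 2L, 1L)) / maxv
  img
}

#' Resize an image
#'
#' @param img `[H, W, 3]` array
#' @param h,w target size
#' @param method `"bilinear"` or `"nearest"`
#' @return resized `[h, w, 3]` array
#' @export
resize_image <- function(img, h, w, method = c("bilinear", "nearest")) {
  .check_image(img)
  method <- match.arg(method)
  d <- dim(img)
  if (d[1] == h && d[2] == w) return(img)
  if (method == "nearest") {
    ri <- pmin(pmax(floor((seq_len(h) - 0.5) * d[1] / h) + 1, 1), d[1])
    ci <- pmin(pmax(floor((seq_len(w) - 0.5) * d[2] / w) + 1, 1), d[2])
    return(img[ri, ci, , drop = FALSE])
  }
  # separable bilinear via interpolation matrices
  interp_mat <- function(n_out, n_in) {
    x <- (seq_len(n_out) - 0.5) * n_in / n_out - 0.5
    i0 <- floor(x); f <- x - i0
    i0 <- pmin(pmax(i0, 0), n_in - 1); i1 <- pmin(i0 + 1, n_in - 1)
    m <- matrix(0, n_out, n_in)
    m[cbind(seq_len(n_out), i0 + 1)] <- m[cbind(seq_len(n_out), i0 + 1)] + (1 - f)
    m[cbind(seq_len(n_out), i1 + 1)] <- m[cbind(seq_len(n_out), i1 + 1)] + f
    m
  }
  A <- interp_mat(h, d[1]); B <- t(interp_mat(w, d[2]))
  out <- array(0, dim = c(h, w, 3L))
  for (c in 1:3) out[, , c] <- A %*% img[, , c] %*% B
  out
}

#' Flip an image left-right or up-down
#' @param img `[H, W, 3]` array
#' @param axis `"horizontal"` (mirror columns) or `"vertical"` (mirror rows)
#' @export
flip_image <- function(img, axis = c("horizontal", "vertical")) {
  .check_image(img)
  axis <- match.arg(axis)
  d <- dim(img)
  if (axis == "horizontal") img[, d[2]:1, , drop = FALSE]
  else img[d[1]:1, , , drop = FALSE]
}

#' Rotate an image by a multiple of 90 degrees (counter-clockwise)
#' @param img `[H, W, 3]` array
#' @param k number of quarter turns (integer, may be negative)
#' @export
rot90_image <- function(img, k = 1L) {
  .check_image(img)
  k <- ((as.integer(k) %% 4L) + 4L) %% 4L
  if (k == 0L) return(img)
  for (i in seq_len(k)) {
    d <- dim(img)
    # CCW: out[i, j] = in[j, W - i + 1] ; out is [W, H, 3]
    img <- aperm(img, c(2L, 1L, 3L))[d[2]:1, , , drop = FALSE]
  }
  img
}
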