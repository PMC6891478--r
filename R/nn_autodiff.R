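#' @useDynLib poppydetect, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# A minimal reverse-mode tape for the detector graph. Values are whole
# feature-map arrays, so the tape holds a few dozen coarse nodes per forward
# pass; each op pushes a backward closure that scatters its output gradient
# to its inputs and to the named parameter gradient store.

tape_new <- function() {
  t <- new.env(parent = emptyenv())
  t$n <- 0L
  t$val <- list()
  t$bw <- list()
  t$grad <- list()
  t$pgrad <- list()
  t
}

tp_push <- function(t, val, bw = NULL) {
  t$n <- t$n + 1L
  t$val[[t$n]] <- val
  t$bw[t$n] <- list(bw)
  t$n
}

tp_acc <- function(t, id, g) {
  cur <- if (id <= length(t$grad)) t$grad[[id]] else NULL
  t$grad[[id]] <- if (is.null(cur)) g else cur + g
}

tp_accp <- function(t, pname, comp, g) {
  cur <- t$pgrad[[pname]][[comp]]
  if (is.null(cur)) {
    slot <- t$pgrad[[pname]]
    if (is.null(slot)) slot <- list()
    slot[[comp]] <- g
    t$pgrad[[pname]] <- slot
  } else {
    t$pgrad[[pname]][[comp]] <- cur + g
  }
}

# seeds: named list, names are node ids (as integers) -> gradient arrays
tape_backward <- function(t, seed_ids, seed_grads) {
  for (k in seq_along(seed_ids)) tp_acc(t, seed_ids[[k]], seed_grads[[k]])
  for (id in rev(seq_len(t$n))) {
    g <- if (id <= length(t$grad)) t$grad[[id]] else NULL
    if (is.null(g)) next
    fn <- t$bw[[id]]
    if (!is.null(fn)) fn(g)
  }
  invisible(t)
}

tp_input <- function(t, x) tp_push(t, x)

.conv_pads <- function(n, k, s) {
  nout <- ceiling(n / s)
  total <- max((nout - 1L) * s + k - n, 0L)
  c(total %/% 2L, nout)  # pad top/left; extra padding lands bottom/right
}

# Standard convolution: params list(w = [KH,KW,Cin,Cout], b = Cout)
ad_conv <- function(t, xid, params, pname, stride = 1L) {
  x <- t$val[[xid]]
  d <- dim(x)
  w <- params$w
  kd <- dim(w)
  KH <- kd[1]; KW <- kd[2]; Cin <- kd[3]; Cout <- kd[4]
  stopifnot(d[3] == Cin)
  ph <- .conv_pads(d[1], KH, stride); pw <- .conv_pads(d[2], KW, stride)
  pt <- ph[1]; Hout <- ph[2]; pl <- pw[1]; Wout <- pw[2]
  cols <- im2col_cpp(x, d[1], d[2], d[3], KH, KW, stride, stride,
                     pt, pl, Hout, Wout)
  Wmat <- matrix(w, KH * KW * Cin, Cout)
  ymat <- cols %*% Wmat
  ymat <- sweep(ymat, 2L, params$b, "+")
  y <- array(ymat, c(Hout, Wout, Cout))
  tp_push(t, y, bw = function(g) {
    gmat <- matrix(g, Hout * Wout, Cout)
    tp_accp(t, pname, "w", array(crossprod(cols, gmat), kd))
    tp_accp(t, pname, "b", colSums(gmat))
    dcols <- gmat %*% t(Wmat)
    dx <- col2im_cpp(dcols, d[1], d[2], d[3], KH, KW, stride, stride,
                     pt, pl, Hout, Wout)
    tp_acc(t, xid, array(dx, d))
  })
}

# Depthwise convolution: params list(w = [KH,KW,C], b = C)
ad_dwconv <- function(t, xid, params, pname, stride = 1L) {
  x <- t$val[[xid]]
  d <- dim(x)
  w <- params$w
  kd <- dim(w)
  KH <- kd[1]; KW <- kd[2]
  stopifnot(kd[3] == d[3])
  ph <- .conv_pads(d[1], KH, stride); pw <- .conv_pads(d[2], KW, stride)
  pt <- ph[1]; Hout <- ph[2]; pl <- pw[1]; Wout <- pw[2]
  y <- dwconv_fwd_cpp(x, d[1], d[2], d[3], w, params$b, KH, KW,
                      stride, stride, pt, pl, Hout, Wout)
  y <- array(y, c(Hout, Wout, d[3]))
  tp_push(t, y, bw = function(g) {
    r <- dwconv_bwd_cpp(x, g, d[1], d[2], d[3], w, KH, KW,
                        stride, stride, pt, pl, Hout, Wout)
    tp_accp(t, pname, "w", array(r$dw, kd))
    tp_accp(t, pname, "b", as.numeric(r$db))
    tp_acc(t, xid, array(r$dx, d))
  })
}

ad_leaky <- function(t, xid, alpha = 0.1) {
  x <- t$val[[xid]]
  pos <- x > 0
  y <- x * ifelse(pos, 1, alpha)
  tp_push(t, y, bw = function(g) {
    tp_acc(t, xid, g * ifelse(pos, 1, alpha))
  })
}

ad_add <- function(t, aid, bid) {
  y <- t$val[[aid]] + t$val[[bid]]
  tp_push(t, y, bw = function(g) {
    tp_acc(t, aid, g)
    tp_acc(t, bid, g)
  })
}

ad_concat <- function(t, ids) {
  vals <- lapply(ids, function(i) t$val[[i]])
  chans <- vapply(vals, function(v) dim(v)[3], 0L)
  d1 <- dim(vals[[1]])
  y <- array(unlist(vals, use.names = FALSE), c(d1[1], d1[2], sum(chans)))
  tp_push(t, y, bw = function(g) {
    off <- 0L
    for (k in seq_along(ids)) {
      tp_acc(t, ids[[k]], g[, , (off + 1L):(off + chans[k]), drop = FALSE])
      off <- off + chans[k]
    }
  })
}

ad_upsample2 <- function(t, xid) {
  x <- t$val[[xid]]
  d <- dim(x)
  y <- x[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L), ,
         drop = FALSE]
  tp_push(t, y, bw = function(g) {
    oi <- seq(1L, 2L * d[1], by = 2L); oj <- seq(1L, 2L * d[2], by = 2L)
    dx <- g[oi, oj, , drop = FALSE] + g[oi + 1L, oj, , drop = FALSE] +
          g[oi, oj + 1L, , drop = FALSE] + g[oi + 1L, oj + 1L, , drop = FALSE]
    tp_acc(t, xid, dx)
  })
}

ad_maxpool_s1 <- function(t, xid, k) {
  x <- t$val[[xid]]
  d <- dim(x)
  r <- maxpool_s1_cpp(x, d[1], d[2], d[3], as.integer(k))
  y <- array(r$y, d)
  tp_push(t, y, bw = function(g) {
    dx <- maxpool_s1_bwd_cpp(g, r$argmax, length(x))
    tp_acc(t, xid, array(dx, d))
  })
}
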