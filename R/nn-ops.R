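# Compact CPU tensor core used by the backbone, CAM head and PCM.
#
# Conventions: an image tensor is a numeric array [H, W, C, B] (batch last);
# single images/maps may be [H, W] or [H, W, C].  Vectorized pixel index is
# column-major, i.e. r + (c - 1) * H, matching as.vector() on a matrix.
# Convolution weights are arrays [k, k, C_in, C_out]; all layers carry biases.

as_nchw <- function(x) {
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L, 1L)
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  x
}

# im2col convolution. Returns output and (optionally) the cache needed for
# the backward pass. Column order of the patch matrix matches as.vector(w).
conv2d_forward <- function(x, w, b, stride = 1L, pad = 0L, keep_cache = FALSE) {
  x <- as_nchw(x)
  k <- dim(w)[1L]; cin <- dim(w)[3L]; cout <- dim(w)[4L]
  stopifnot(dim(w)[2L] == k, dim(x)[3L] == cin)
  h <- dim(x)[1L]; wd <- dim(x)[2L]; bsz <- dim(x)[4L]
  if (pad > 0L) {
    xp <- array(0, c(h + 2L * pad, wd + 2L * pad, cin, bsz))
    xp[pad + seq_len(h), pad + seq_len(wd), , ] <- x
    x <- xp
    h <- h + 2L * pad; wd <- wd + 2L * pad
  }
  ho <- (h - k) %/% stride + 1L
  wo <- (wd - k) %/% stride + 1L
  n <- ho * wo * bsz
  xc <- matrix(0, n, k * k * cin)
  ri <- seq.int(1L, by = stride, length.out = ho)
  ci <- seq.int(1L, by = stride, length.out = wo)
  for (kj in seq_len(k)) {
    for (ki in seq_len(k)) {
      sl <- x[ri + (ki - 1L), ci + (kj - 1L), , , drop = FALSE]   # [ho,wo,cin,b]
      sl <- aperm(sl, c(1L, 2L, 4L, 3L))                          # [ho,wo,b,cin]
      cols <- ki + (kj - 1L) * k + (seq_len(cin) - 1L) * k * k
      xc[, cols] <- matrix(sl, n, cin)
    }
  }
  wm <- matrix(w, k * k * cin, cout)
  y <- xc %*% wm
  y <- sweep(y, 2L, b, "+")
  y <- array(y, c(ho, wo, bsz, cout))
  y <- aperm(y, c(1L, 2L, 4L, 3L))
  if (!keep_cache) return(y)
  list(out = y,
       cache = list(xc = xc, w = w, stride = stride, pad = pad,
                    in_dim = dim(x), ho = ho, wo = wo, bsz = bsz))
}

conv2d_backward <- function(cache, dy, need_dx = TRUE) {
  w <- cache$w
  k <- dim(w)[1L]; cin <- dim(w)[3L]; cout <- dim(w)[4L]
  ho <- cache$ho; wo <- cache$wo; bsz <- cache$bsz
  dym <- matrix(aperm(as_nchw(dy), c(1L, 2L, 4L, 3L)), ho * wo * bsz, cout)
  dw <- array(crossprod(cache$xc, dym), dim(w))
  db <- colSums(dym)
  dx <- NULL
  if (need_dx) {
    dxc <- tcrossprod(dym, matrix(w, k * k * cin, cout))
    hp <- cache$in_dim[1L]; wp <- cache$in_dim[2L]
    dxp <- array(0, cache$in_dim)
    ri <- seq.int(1L, by = cache$stride, length.out = ho)
    ci <- seq.int(1L, by = cache$stride, length.out = wo)
    for (kj in seq_len(k)) {
      for (ki in seq_len(k)) {
        cols <- ki + (kj - 1L) * k + (seq_len(cin) - 1L) * k * k
        sl <- array(dxc[, cols], c(ho, wo, bsz, cin))
        sl <- aperm(sl, c(1L, 2L, 4L, 3L))
        dxp[ri + (ki - 1L), ci + (kj - 1L), , ] <-
          dxp[ri + (ki - 1L), ci + (kj - 1L), , , drop = FALSE] + sl
      }
    }
    p <- cache$pad
    dx <- if (p > 0L)
      dxp[p + seq_len(hp - 2L * p), p + seq_len(wp - 2L * p), , , drop = FALSE]
    else dxp
  }
  list(dw = dw, db = db, dx = dx)
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

# --- bilinear resize as a sparse linear operator ----------------------------

.resize_cache <- new.env(parent = emptyenv())

# Half-pixel-center sampling (no corner alignment), borders clamped.
resize_matrix <- function(h_in, w_in, h_out, w_out) {
  key <- paste(h_in, w_in, h_out, w_out, sep = "x")
  if (!is.null(.resize_cache[[key]])) return(.resize_cache[[key]])
  ro <- rep(seq_len(h_out) - 1, times = w_out)
  co <- rep(seq_len(w_out) - 1, each = h_out)
  ry <- pmin(pmax((ro + 0.5) * h_in / h_out - 0.5, 0), h_in - 1)
  cx <- pmin(pmax((co + 0.5) * w_in / w_out - 0.5, 0), w_in - 1)
  r0 <- floor(ry); c0 <- floor(cx)
  fr <- ry - r0; fc <- cx - c0
  r1 <- pmin(r0 + 1, h_in - 1); c1 <- pmin(c0 + 1, w_in - 1)
  idx <- function(r, c) r + c * h_in + 1
  i <- rep(seq_len(h_out * w_out), 4L)
  j <- c(idx(r0, c0), idx(r1, c0), idx(r0, c1), idx(r1, c1))
  v <- c((1 - fr) * (1 - fc), fr * (1 - fc), (1 - fr) * fc, fr * fc)
  m <- Matrix::sparseMatrix(i = i, j = j, x = v,
                            dims = c(h_out * w_out, h_in * w_in))
  .resize_cache[[key]] <- m
  m
}

apply_pixel_op <- function(m, x, h_out, w_out) {
  x <- as_nchw(x)
  h <- dim(x)[1L]; w <- dim(x)[2L]; cb <- prod(dim(x)[3:4])
  y <- as.matrix(m %*% matrix(x, h * w, cb))
  array(y, c(h_out, w_out, dim(x)[3L], dim(x)[4L]))
}

#' Bilinear resize of an image or feature map
#'
#' Resamples with half-pixel-center bilinear interpolation (no corner
#' alignment); border samples are clamped. The operation is linear in the
#' input, which is what allows the same operator to serve as the upsampling
#' step of a merge block and (via its transpose) as that step's gradient.
#'
#' @param x numeric matrix `[h, w]` or array `[h, w, C]` / `[h, w, C, B]`.
#' @param h_out,w_out output spatial size; `w_out` defaults to `h_out`.
#' @return array of the same rank as `x` with spatial size `h_out x w_out`.
#' @export
resize_bilinear <- function(x, h_out, w_out = h_out) {
  d <- dim(x)
  m <- resize_matrix(d[1L], d[2L], h_out, w_out)
  y <- apply_pixel_op(m, x, h_out, w_out)
  if (length(d) == 2L) dim(y) <- c(h_out, w_out)
  if (length(d) == 3L) dim(y) <- c(h_out, w_out, d[3L])
  y
}

resize_adjoint <- function(g, h_in, w_in) {
  d <- dim(as_nchw(g))
  m <- resize_matrix(h_in, w_in, d[1L], d[2L])
  y <- as.matrix(Matrix::crossprod(m, matrix(g, d[1L] * d[2L], d[3L] * d[4L])))
  array(y, c(h_in, w_in, d[3L], d[4L]))
}

# --- affine (rotation) warp -------------------------------------------------

#' Rotation warp operator on a pixel grid
#'
#' Builds the sparse linear operator that rotates an `h x w` image by
#' `angle_deg` (counter-clockwise, about the image center) with bilinear
#' interpolation and zero fill. Output pixels whose source sample falls
#' outside the input grid are marked invalid in `$valid`; equivariance
#' losses mask them out. The transpose of the operator is the exact adjoint,
#' used to backpropagate through a warp.
#'
#' @param h,w grid size in pixels.
#' @param angle_deg rotation angle in degrees.
#' @return an object of class `camloc_warp` with fields `m` (sparse
#'   `(h*w) x (h*w)` matrix), `valid` (logical `h*w`), `h`, `w`, `angle_deg`.
#' @seealso [apply_warp()]
#' @export
make_warp <- function(h, w, angle_deg) {
  a <- angle_deg * pi / 180
  cy <- (h - 1) / 2; cx <- (w - 1) / 2
  ro <- rep(seq_len(h) - 1, times = w)
  co <- rep(seq_len(w) - 1, each = h)
  # inverse mapping: rotate output coords by -angle around the center
  dy <- ro - cy; dx <- co - cx
  sy <- cy + sin(-a) * dx + cos(-a) * dy
  sx <- cx + cos(-a) * dx - sin(-a) * dy
  valid <- sy >= 0 & sy <= h - 1 & sx >= 0 & sx <= w - 1
  r0 <- floor(sy); c0 <- floor(sx)
  fr <- sy - r0; fc <- sx - c0
  out_i <- seq_len(h * w)
  pieces <- list(
    list(r = r0,     c = c0,     v = (1 - fr) * (1 - fc)),
    list(r = r0 + 1, c = c0,     v = fr * (1 - fc)),
    list(r = r0,     c = c0 + 1, v = (1 - fr) * fc),
    list(r = r0 + 1, c = c0 + 1, v = fr * fc))
  ii <- integer(0); jj <- integer(0); vv <- numeric(0)
  for (p in pieces) {
    ok <- valid & p$r >= 0 & p$r <= h - 1 & p$c >= 0 & p$c <= w - 1 & p$v > 0
    ii <- c(ii, out_i[ok])
    jj <- c(jj, p$r[ok] + p$c[ok] * h + 1)
    vv <- c(vv, p$v[ok])
  }
  m <- Matrix::sparseMatrix(i = ii, j = jj, x = vv, dims = c(h * w, h * w))
  structure(list(m = m, valid = valid, h = h, w = w, angle_deg = angle_deg),
            class = "camloc_warp")
}

#' Apply a warp operator to an image, feature map or CAM stack
#'
#' @param warp a [make_warp()] object.
#' @param x array `[h, w]`, `[h, w, C]` or `[h, w, C, B]` matching the warp grid.
#' @return warped array, same shape; invalid pixels are zero-filled.
#' @export
apply_warp <- function(warp, x) {
  d <- dim(x)
  y <- apply_pixel_op(warp$m, x, warp$h, warp$w)
  dim(y) <- d
  y
}

warp_adjoint <- function(warp, g) {
  d <- dim(as_nchw(g))
  y <- as.matrix(Matrix::crossprod(warp$m, matrix(g, d[1L] * d[2L], d[3L] * d[4L])))
  array(y, d)
}

#' @export
print.camloc_warp <- function(x, ...) {
  cat(sprintf("<camloc_warp %dx%d, %.2f deg, %.1f%% valid>\n",
              x$h, x$w, x$angle_deg, 100 * mean(x$valid)))
  invisible(x)
}

# --- Adam -------------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, betas = c(0.9, 0.9), eps = 1e-8) {
  state$t <- state$t + 1L
  b1 <- betas[1L]; b2 <- betas[2L]
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g * g
    mhat <- state$m[[nm]] / (1 - b1^state$t)
    vhat <- state$v[[nm]] / (1 - b2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ImageNet channel statistics used for input normalization.
IMAGENET_MEAN <- c(0.485, 0.456, 0.406)
IMAGENET_SD <- c(0.229, 0.224, 0.225)
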