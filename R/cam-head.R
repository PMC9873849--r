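# Classification head: per-pixel application of the classifier produces the
# class activation maps (CAMs); log-sum-exp pooling of each CAM produces the
# class score, so the CAM and the prediction vector share one set of weights.

#' Log-sum-exp (LSE) pooling
#'
#' Smooth interpolation between global mean pooling (`gamma -> 0`) and global
#' max pooling (`gamma -> Inf`): per channel,
#' `s = (1/gamma) * log( mean_ij exp(gamma * x_ij) )`,
#' computed with a max shift for overflow safety. The full-scale pipeline
#' uses `gamma = 10`.
#'
#' @param x numeric matrix `[h, w]`, or array `[h, w, C]` / `[h, w, C, B]`.
#' @param gamma positive sharpness parameter.
#' @return a numeric vector of length `C` (or a `C x B` matrix for batched
#'   input; a scalar for matrix input).
#' @export
lse_pool <- function(x, gamma = 10) {
  stopifnot(gamma > 0)
  if (!all(is.finite(x))) stop("lse_pool: non-finite values in input")
  single <- length(dim(x) %||% NULL) < 3L && is.matrix(x)
  x <- as_nchw(x)
  d <- dim(x)
  xm <- matrix(x, d[1L] * d[2L], d[3L] * d[4L])
  mx <- apply(xm, 2L, max)
  s <- mx + log(colMeans(exp(sweep(xm, 2L, mx, "-") * gamma))) / gamma
  out <- matrix(s, d[3L], d[4L])
  if (single) return(out[1L, 1L])
  if (d[4L] == 1L) drop(out[, 1L]) else out
}

# gradient of lse_pool wrt the map: softmax(gamma * x) / 1, per channel
lse_pool_backward <- function(x, gamma, ds) {
  x <- as_nchw(x)
  d <- dim(x)
  xm <- matrix(x, d[1L] * d[2L], d[3L] * d[4L])
  mx <- apply(xm, 2L, max)
  e <- exp(sweep(xm, 2L, mx, "-") * gamma)
  wgt <- sweep(e, 2L, colSums(e), "/")
  g <- sweep(wgt, 2L, as.vector(ds), "*")
  array(g, d)
}

#' Classify a feature map and emit its CAM stack
#'
#' A single affine classifier (weights `W`, bias `b`) shared across pixels is
#' applied at every location of the output feature map, producing one class
#' activation map per class: `CAM_c(i,j) = W[, c] . F(i, j, ) + b_c`. The
#' class score is the LSE pool of that same map, `z_c = lse_pool(CAM_c)`, so
#' pooling the CAM of class `c` reproduces `z_c` exactly.
#'
#' @param fmap feature array `[h, w, C]` or `[h, w, C, B]`.
#' @param weights `C x n_classes` matrix.
#' @param bias length-`n_classes` vector.
#' @param gamma LSE sharpness.
#' @return list with `z` (scores, `n_classes` vector or `n_classes x B`),
#'   `prob` (logistic transform of `z`) and `cams` (`[h, w, n_classes, B]`).
#' @export
forward_classify <- function(fmap, weights, bias, gamma = 10) {
  fmap <- as_nchw(fmap)
  d <- dim(fmap)
  if (d[3L] != nrow(weights))
    stop(sprintf("forward_classify: feature channels (%d) != classifier rows (%d)",
                 d[3L], nrow(weights)))
  ncls <- ncol(weights)
  fm <- matrix(aperm(fmap, c(1L, 2L, 4L, 3L)), d[1L] * d[2L] * d[4L], d[3L])
  cam <- sweep(fm %*% weights, 2L, bias, "+")
  cam <- aperm(array(cam, c(d[1L], d[2L], d[4L], ncls)), c(1L, 2L, 4L, 3L))
  z <- lse_pool(cam, gamma)
  z <- matrix(z, ncls, d[4L])
  list(z = z, prob = 1 / (1 + exp(-z)), cams = cam)
}

#' Per-pixel non-maximum suppression across classes
#'
#' At each pixel only the class with the maximal activation keeps its value;
#' all other classes are set to zero, and a kept value that is negative is
#' clamped to zero (a pixel whose best class is negative carries no
#' foreground). Ties keep the lowest class index. This is the foreground
#' selection applied to raw CAMs before PCM refinement; the negative clamp
#' is what makes the operation idempotent (without it, a pixel whose kept
#' value is negative would flip to an introduced zero on re-application).
#'
#' @param cams array `[h, w, n_classes]` or `[h, w, n_classes, B]`.
#' @return array of the same shape.
#' @export
suppress_non_maximum <- function(cams) {
  d0 <- dim(cams)
  x <- as_nchw(cams)
  d <- dim(x)
  xm <- matrix(aperm(x, c(3L, 1L, 2L, 4L)), d[3L], d[1L] * d[2L] * d[4L])
  keep <- max.col(t(xm), ties.method = "first")
  out <- matrix(0, d[3L], ncol(xm))
  sel <- cbind(keep, seq_along(keep))
  out[sel] <- pmax(xm[sel], 0)
  out <- aperm(array(out, c(d[3L], d[1L], d[2L], d[4L])), c(2L, 3L, 1L, 4L))
  dim(out) <- d0
  out
}

#' Rescale a single-class CAM to an 8-bit heatmap
#'
#' Bilinear upsampling to `out_side` squared, then per-map min-max
#' normalization to `[0, 1]` and quantization to `0..255` (`round()`, i.e.
#' half-to-even at the midpoint). A constant map carries no localization
#' signal and maps to all zeros. Thresholding for box extraction happens on
#' this normalized scale, which is what makes a constant threshold `Q`
#' meaningful across images.
#'
#' @param cam numeric matrix (one class map).
#' @param out_side output side length, at least the map side.
#' @return integer matrix `out_side x out_side` with values in `0..255`.
#' @export
rescale_heatmap <- function(cam, out_side) {
  stopifnot(is.matrix(cam), out_side >= max(dim(cam)))
  up <- if (all(dim(cam) == out_side)) cam else resize_bilinear(cam, out_side, out_side)
  rng <- range(up)
  if (rng[2L] - rng[1L] < .Machine$double.eps * max(1, abs(rng[2L])))
    return(matrix(0L, out_side, out_side))
  norm <- (up - rng[1L]) / (rng[2L] - rng[1L])
  matrix(as.integer(round(norm * 255)), out_side, out_side)
}
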