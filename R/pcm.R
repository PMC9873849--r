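# Pixel correlation module (PCM): each CAM pixel is rewritten as a weighted
# average of all CAM pixels, with weights from the ReLU'd cosine similarity
# of linearly embedded backbone features, row-normalized so that refinement
# is an exact convex combination per pixel.

PCM_EPS <- 1e-8

#' Create PCM parameters
#'
#' The only trainable part of the PCM is a 1x1 linear embedding (no
#' non-linearity) from feature channels to a lower-dimensional embedding
#' space in which pixel affinity is measured.
#'
#' @param c_in feature channels fed to the module.
#' @param c_embed embedding channels; default `max(2, c_in / 4)`.
#' @param seed integer seed for the Gaussian initialization.
#' @return object of class `camloc_pcm` with field `theta` (`c_in x c_embed`).
#' @export
pcm_params <- function(c_in, c_embed = NULL, seed = 1L) {
  c_embed <- as.integer(c_embed %||% max(2L, c_in %/% 4L))
  set.seed(seed)
  theta <- matrix(rnorm(c_in * c_embed, sd = sqrt(2 / c_in)), c_in, c_embed)
  structure(list(theta = theta, c_in = c_in, c_embed = c_embed),
            class = "camloc_pcm")
}

# features -> N x C_in pixel matrix (N = h*w, column-major pixel order)
features_to_pixels <- function(features) {
  d <- dim(features)
  if (length(d) == 2L) d <- c(d, 1L)
  matrix(features, d[1L] * d[2L], d[3L])
}

#' Pixel affinity matrix from embedded features
#'
#' Embeds every pixel's feature vector with the PCM's linear map, computes
#' pairwise cosine similarity, clips negatives with ReLU and normalizes each
#' row to sum to one, so the matrix is row-stochastic and refinement is a
#' convex combination. Pixels whose embedded vector has (near-)zero norm get
#' an identity row: they keep their own CAM value.
#'
#' @param features array `[h, w, C_in]` (or an `N x C_in` matrix of pixels).
#' @param params a [pcm_params()] object.
#' @return dense `N x N` row-stochastic matrix, `N = h * w`.
#' @export
embed_and_affinity <- function(features, params) {
  x <- if (is.matrix(features)) features else features_to_pixels(features)
  if (ncol(x) != params$c_in)
    stop(sprintf("embed_and_affinity: features have %d channels, embedding expects %d",
                 ncol(x), params$c_in))
  e <- x %*% params$theta
  n <- sqrt(rowSums(e * e))
  zero <- n < PCM_EPS
  u <- e / pmax(n, PCM_EPS)
  s <- tcrossprod(u)
  s[s < 0] <- 0
  r <- rowSums(s)
  bad <- zero | r < PCM_EPS
  r[bad] <- 1
  w <- s / r
  if (any(bad)) {
    w[bad, ] <- 0
    w[cbind(which(bad), which(bad))] <- 1
  }
  w
}

#' Refine a CAM stack with the pixel correlation module
#'
#' Every refined pixel is the affinity-weighted average of all pixels of the
#' original (suppressed) CAM, per class: `y_i = sum_j W[i, j] * yhat_j`.
#' Features are bilinearly interpolated to the CAM resolution if the two
#' disagree. Refinement feeds only the localization path; the class-score
#' path is untouched.
#'
#' @param cams array `[h, w, n_classes]` — typically [suppress_non_maximum()]
#'   output.
#' @param features array `[hf, wf, C_in]` of backbone features.
#' @param params a [pcm_params()] object.
#' @return refined CAM array, same shape as `cams`.
#' @export
refine_cams <- function(cams, features, params) {
  d <- dim(cams)
  fd <- dim(features)
  if (!(fd[1L] == d[1L] && fd[2L] == d[2L]))
    features <- resize_bilinear(features, d[1L], d[2L])
  w <- embed_and_affinity(features, params)
  ym <- matrix(cams, d[1L] * d[2L], d[3L])
  out <- w %*% ym
  array(out, d)
}

# Analytic gradient of a scalar loss wrt theta, given d(loss)/d(refined CAM).
# Chain: theta -> embeddings E -> unit rows U -> cosine C -> ReLU S ->
# row-normalized W -> Y = W %*% Yhat. Verified against finite differences
# in the test suite.
pcm_backward_theta <- function(features, params, cams, d_refined) {
  x <- features_to_pixels(features)
  d <- dim(cams)
  yhat <- matrix(cams, d[1L] * d[2L], d[3L])
  g <- matrix(d_refined, d[1L] * d[2L], d[3L])

  e <- x %*% params$theta
  n <- sqrt(rowSums(e * e))
  zero <- n < PCM_EPS
  u <- e / pmax(n, PCM_EPS)
  cs <- tcrossprod(u)
  s <- cs; s[s < 0] <- 0
  r <- rowSums(s)
  bad <- zero | r < PCM_EPS
  rr <- ifelse(bad, 1, r)
  w <- s / rr

  dw <- tcrossprod(g, yhat)             # N x N: dL/dW_ij = sum_c g_ic yhat_jc
  q <- rowSums(dw * w)
  ds <- (dw - q) / rr
  ds[bad, ] <- 0
  dc <- ds * (cs > 0)
  du <- (dc + t(dc)) %*% u
  # back through row normalization u = e / ||e||
  proj <- rowSums(du * u)
  de <- (du - u * proj) / pmax(n, PCM_EPS)
  de[zero, ] <- 0
  crossprod(x, de)
}
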