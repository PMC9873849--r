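# Loss algebra: dynamically class-balanced BCE for phase-1 classification
# training, and the Siamese PCM objective (multi-label soft-margin loss plus
# equivariant cross regularization with online hard example mining).

BCE_EPS <- 1e-7

#' Per-batch class balance weights for the weighted BCE
#'
#' For each class `c`, with `|P_c|` positive and `|N_c|` negative samples in
#' the batch, `beta_P = (|P_c| + |N_c|) / |P_c|` and
#' `beta_N = (|P_c| + |N_c|) / |N_c|`, recomputed for every batch. When a
#' class has no positives its positive loss term vanishes, so `beta_P` is
#' set to 0 (symmetrically for no negatives). Whenever both counts are
#' positive the weights satisfy `1/beta_P + 1/beta_N = 1`.
#'
#' @param labels_batch `B x n_classes` multi-hot matrix.
#' @return object of class `camloc_weights`: list with numeric vectors
#'   `beta_p`, `beta_n` and the counts `n_pos`, `n_neg`.
#' @export
class_balance_weights <- function(labels_batch) {
  labels_batch <- as.matrix(labels_batch)
  stopifnot(nrow(labels_batch) >= 1)
  if (!all(labels_batch %in% c(0, 1)))
    stop("class_balance_weights: labels must be 0/1")
  np <- colSums(labels_batch)
  nn <- nrow(labels_batch) - np
  tot <- np + nn
  beta_p <- ifelse(np > 0, tot / np, 0)
  beta_n <- ifelse(nn > 0, tot / nn, 0)
  structure(list(beta_p = beta_p, beta_n = beta_n, n_pos = np, n_neg = nn),
            class = "camloc_weights")
}

#' Dynamically class-balanced binary cross-entropy
#'
#' Per element: `-beta_P^c * y * log f - beta_N^c * (1 - y) * log(1 - f)`,
#' summed over classes and averaged over the samples of the batch (the
#' per-sample class sum is the published form; the batch mean keeps the
#' learning rate batch-size invariant). Probabilities are clamped to
#' `[eps, 1 - eps]` before the logs.
#'
#' @param probs `B x n_classes` predicted probabilities in (0, 1).
#' @param labels `B x n_classes` multi-hot matrix.
#' @param weights a [class_balance_weights()] object (recomputed from
#'   `labels` when omitted).
#' @return scalar loss.
#' @export
weighted_bce <- function(probs, labels, weights = class_balance_weights(labels)) {
  probs <- as.matrix(probs); labels <- as.matrix(labels)
  stopifnot(all(dim(probs) == dim(labels)))
  if (!all(labels %in% c(0, 1))) stop("weighted_bce: labels must be 0/1")
  f <- pmin(pmax(probs, BCE_EPS), 1 - BCE_EPS)
  el <- -sweep(labels * log(f), 2L, weights$beta_p, "*") -
    sweep((1 - labels) * log(1 - f), 2L, weights$beta_n, "*")
  mean(rowSums(el))
}

# gradient wrt the pre-sigmoid scores z (f = sigmoid(z)), same reduction
weighted_bce_backward_z <- function(probs, labels, weights) {
  f <- pmin(pmax(probs, BCE_EPS), 1 - BCE_EPS)
  g <- -sweep(labels * (1 - f), 2L, weights$beta_p, "*") +
    sweep((1 - labels) * f, 2L, weights$beta_n, "*")
  g / nrow(labels)
}

#' Multi-label soft-margin loss
#'
#' Mean over samples and classes of
#' `y * log(1 + exp(-z)) + (1 - y) * log(1 + exp(z))`, evaluated with the
#' numerically stable `log1p` form. Applied in phase-2 PCM training to the
#' global-average-pooled refined CAM scores of both Siamese branches.
#'
#' @param scores `B x n_classes` raw scores.
#' @param labels `B x n_classes` multi-hot matrix.
#' @return scalar loss.
#' @export
multilabel_soft_margin <- function(scores, labels) {
  scores <- as.matrix(scores); labels <- as.matrix(labels)
  stopifnot(all(dim(scores) == dim(labels)))
  softplus <- function(a) pmax(a, 0) + log1p(exp(-abs(a)))
  mean(labels * softplus(-scores) + (1 - labels) * softplus(scores))
}

msml_backward <- function(scores, labels) {
  sig <- 1 / (1 + exp(-scores))
  (sig - labels) / length(labels)
}

#' Equivariant cross regularization with online hard example mining
#'
#' The two Siamese consistency terms `|A(y^o) - yhat^t|` and
#' `|A(yhat^o) - y^t|` (refined CAMs `y`, raw CAMs `yhat`; `A` the affine
#' transform used on the images) are formed per pixel and class, pixels
#' invalidated by the transform (rotated-in border) are masked out, each
#' term keeps only its largest `keep_fraction` of elements (OHEM,
#' `ceiling(fraction * N)` elements, averaged), and the two reductions are
#' added.
#'
#' @param y_o,y_t refined CAM stacks `[h, w, n_classes]` for the original and
#'   transformed branch.
#' @param yhat_o,yhat_t raw (suppressed) CAM stacks, same shape.
#' @param A a [make_warp()] object acting on the CAM grid, or `NULL` for the
#'   identity.
#' @param keep_fraction fraction of elements kept by OHEM, in (0, 1].
#' @return scalar loss (attributes carry the per-term values).
#' @export
ecr_with_ohem <- function(y_o, y_t, yhat_o, yhat_t, A = NULL, keep_fraction = 0.2) {
  if (keep_fraction <= 0 || keep_fraction > 1)
    stop("ecr_with_ohem: keep_fraction must be in (0, 1]")
  stopifnot(all(dim(y_o) == dim(y_t)), all(dim(y_o) == dim(yhat_o)),
            all(dim(y_o) == dim(yhat_t)))
  d <- dim(y_o)
  if (is.null(A)) {
    ay_o <- y_o; ayhat_o <- yhat_o
    valid <- rep(TRUE, prod(d))
  } else {
    ay_o <- apply_warp(A, y_o)
    ayhat_o <- apply_warp(A, yhat_o)
    valid <- rep(A$valid, times = d[3L])
  }
  ohem_mean <- function(res) {
    v <- abs(res)[valid]
    k <- ceiling(keep_fraction * length(v))
    mean(sort(v, decreasing = TRUE)[seq_len(k)])
  }
  t1 <- ohem_mean(ay_o - yhat_t)
  t2 <- ohem_mean(ayhat_o - y_t)
  structure(t1 + t2, term_transformed_raw = t1, term_raw_transformed = t2)
}

# Gradients of ecr_with_ohem wrt the two refined stacks (raw stacks are
# constants during phase-2 training). Returns arrays matching y_o / y_t.
ecr_backward <- function(y_o, y_t, yhat_o, yhat_t, A = NULL, keep_fraction = 0.2) {
  d <- dim(y_o)
  n <- prod(d)
  if (is.null(A)) {
    ay_o <- y_o
    valid <- rep(TRUE, n)
  } else {
    ay_o <- apply_warp(A, y_o)
    valid <- rep(A$valid, times = d[3L])
  }
  top_grad <- function(res) {
    v <- abs(as.vector(res))
    v[!valid] <- -Inf
    k <- ceiling(keep_fraction * sum(valid))
    thr <- sort(v, decreasing = TRUE)[k]
    keep <- v >= thr & valid
    # guard against ties inflating the kept set
    if (sum(keep) > k) keep[which(keep)[-seq_len(k)]] <- FALSE
    g <- array(0, d)
    g[keep] <- sign(res[keep]) / k
    g
  }
  g1 <- top_grad(ay_o - yhat_t)              # wrt A(y_o)
  d_y_o <- if (is.null(A)) g1 else array(warp_adjoint(A, g1), d)
  ayhat_o <- if (is.null(A)) yhat_o else apply_warp(A, yhat_o)
  g2 <- top_grad(ayhat_o - y_t)              # wrt (A(yhat_o) - y_t)
  list(d_y_o = d_y_o, d_y_t = -g2)
}

#' Configuration of the combined Siamese PCM objective
#'
#' @param lambda_msml weight of the multi-label soft-margin term (default 1.5).
#' @param lambda_ecr weight of the equivariant cross regularization term
#'   (default 1.0).
#' @param ohem_keep_fraction OHEM keep fraction (default 0.20).
#' @return list of class `camloc_seam_config`.
#' @export
seam_loss_config <- function(lambda_msml = 1.5, lambda_ecr = 1.0,
                             ohem_keep_fraction = 0.2) {
  stopifnot(lambda_msml >= 0, lambda_ecr >= 0,
            ohem_keep_fraction > 0, ohem_keep_fraction <= 1)
  structure(list(lambda_msml = lambda_msml, lambda_ecr = lambda_ecr,
                 ohem_keep_fraction = ohem_keep_fraction),
            class = "camloc_seam_config")
}

#' Combined phase-2 objective
#'
#' `lambda_msml * msml + lambda_ecr * ecr` with the defaults (1.5, 1.0).
#'
#' @param msml,ecr finite component values.
#' @param cfg a [seam_loss_config()].
#' @return scalar.
#' @export
seam_total <- function(msml, ecr, cfg = seam_loss_config()) {
  stopifnot(is.finite(msml), is.finite(ecr))
  cfg$lambda_msml * msml + cfg$lambda_ecr * ecr
}
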