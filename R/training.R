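# Two-phase training. Phase 1 fine-tunes backbone + classifier with the
# dynamically class-balanced BCE; phase 2 trains the PCM embedding alone
# with the weight-shared Siamese objective (MSML + ECR with OHEM) while all
# other weights stay frozen.

#' Training configuration
#'
#' Defaults are the full-scale schedule: phase 1 Adam(lr 3e-4, betas
#' (0.9, 0.9)), 35 epochs, micro-batch 32 with 3 gradient-accumulation
#' steps (effective batch 96); phase 2 Adam(lr 1e-6), 3 epochs, per-image
#' random rotation in (-30, 30) degrees. See [tiny_train_config()] for the
#' desk-scale preset.
#'
#' @param phase1,phase2 lists overriding individual fields.
#' @param seed integer seed governing every random draw during training.
#' @return list of class `camloc_train_config`.
#' @export
train_config <- function(phase1 = list(), phase2 = list(), seed = 1L) {
  p1 <- utils::modifyList(
    list(lr = 3e-4, betas = c(0.9, 0.9), epochs = 35L, micro_batch = 32L,
         accumulation_steps = 3L), phase1)
  p2 <- utils::modifyList(
    list(lr = 1e-6, betas = c(0.9, 0.9), epochs = 3L, micro_batch = 32L,
         accumulation_steps = 1L, rotation_range_deg = c(-30, 30)), phase2)
  structure(list(phase1 = p1, phase2 = p2, seed = as.integer(seed)),
            class = "camloc_train_config")
}

#' Desk-scale training preset for the tiny base
#'
#' A 200-image 64-pixel problem needs a denser update schedule than the
#' full-scale run: micro-batch 8 without accumulation and a larger learning
#' rate give roughly 25 updates per epoch. The phase-2 rate is likewise
#' scaled up so the equivariance loss moves within 3 epochs (the PCM
#' embedding has to reorganize an initially near-uniform affinity; see the
#' methods vignette). The rotation range matches the full-scale schedule.
#'
#' @param seed integer seed.
#' @return a [train_config()] object.
#' @export
tiny_train_config <- function(seed = 1L) {
  train_config(
    phase1 = list(lr = 3e-3, epochs = 5L, micro_batch = 8L,
                  accumulation_steps = 1L),
    phase2 = list(lr = 1e-2, epochs = 3L, micro_batch = 8L),
    seed = seed)
}

# Normalize a list of grayscale images without augmentation (eval pipeline
# at native resolution).
normalize_images <- function(images, side = NULL) {
  side <- side %||% nrow(if (is.list(images[[1L]])) images[[1L]]$image else images[[1L]])
  augment_batch(images, augment_policy(resize_to = side), training = FALSE)
}

snapshot_params <- function(model) {
  list(params = model$params, theta = model$pcm$theta)
}

#' Phase 1: train backbone and classifier with weighted BCE
#'
#' Optimizes the class-balanced BCE with Adam and gradient accumulation
#' (parameters update every `accumulation_steps` micro-batches, gradients
#' averaged across the accumulated micro-batches). Records per-epoch
#' training and validation loss. Deterministic given `cfg$seed`.
#'
#' @param model a trainable `camloc_model` (base `"tiny"`).
#' @param images list of grayscale matrices.
#' @param labels multi-hot matrix, one row per image.
#' @param cfg a [train_config()].
#' @param policy optional [augment_policy()] applied in training mode each
#'   epoch; when `NULL` images are only normalized (deterministic).
#' @param val_images,val_labels optional held-out set for the loss history.
#' @return object of class `camloc_fit`: list with the trained `model` and a
#'   `history` tibble (epoch, train_loss, val_loss).
#' @export
train_phase1 <- function(model, images, labels, cfg = train_config(),
                         policy = NULL, val_images = NULL, val_labels = NULL) {
  if (length(images) == 0) stop("train_phase1: empty dataset")
  stopifnot(length(images) == nrow(labels))
  p1 <- cfg$phase1
  trainable <- trainable_param_names(model)
  state <- adam_init(model$params[trainable])
  xb_fixed <- if (is.null(policy)) normalize_images(images) else NULL
  val_x <- if (!is.null(val_images)) normalize_images(val_images) else NULL
  history <- vector("list", p1$epochs)

  with_local_seed(cfg$seed, {
    for (ep in seq_len(p1$epochs)) {
      idx <- sample(length(images))
      if (!is.null(policy))
        xb_all <- augment_batch(images, policy, training = TRUE)
      losses <- c()
      acc <- NULL; n_acc <- 0L
      starts <- seq(1L, length(idx), by = p1$micro_batch)
      for (bi in seq_along(starts)) {
        take <- idx[starts[bi]:min(starts[bi] + p1$micro_batch - 1L, length(idx))]
        xb <- if (is.null(policy)) xb_fixed[, , , take, drop = FALSE]
          else xb_all[, , , take, drop = FALSE]
        yb <- labels[take, , drop = FALSE]
        fwd <- model_forward(model, xb, keep_cache = TRUE)
        wts <- class_balance_weights(yb)
        probs <- t(fwd$prob)
        losses <- c(losses, weighted_bce(probs, yb, wts))
        dz <- t(weighted_bce_backward_z(probs, yb, wts))
        grads <- model_backward(model, fwd, dz)
        acc <- if (is.null(acc)) grads else
          Map(function(a, g) a + g, acc, grads[names(acc)])
        n_acc <- n_acc + 1L
        if (n_acc == p1$accumulation_steps || bi == length(starts)) {
          acc <- lapply(acc, function(g) g / n_acc)
          upd <- adam_step(model$params[trainable], acc[trainable], state,
                           lr = p1$lr, betas = p1$betas)
          model$params[trainable] <- upd$params
          state <- upd$state
          acc <- NULL; n_acc <- 0L
        }
      }
      val_loss <- NA_real_
      if (!is.null(val_x) && dim(val_x)[4L] > 0) {
        vfwd <- model_forward(model, val_x)
        val_loss <- weighted_bce(t(vfwd$prob), val_labels,
                                 class_balance_weights(val_labels))
      }
      history[[ep]] <- tibble::tibble(epoch = ep,
                                      train_loss = mean(losses),
                                      val_loss = val_loss)
    }
  })
  structure(list(model = model, history = dplyr::bind_rows(history),
                 phase = "classifier", config = cfg),
            class = "camloc_fit")
}

trainable_param_names <- function(model) {
  nm <- names(model$params)
  keep <- !grepl("^stage", nm)
  for (si in model$trainable_stages)
    keep <- keep | grepl(sprintf("^stage%d\\.", si), nm)
  nm[keep]
}

#' Weight-shared Siamese forward pass
#'
#' Branch one feeds the affine-transformed image through the network; branch
#' two applies the same transform to the network's output instead (done
#' inside the equivariance loss). Both branches share every weight. Raw CAMs
#' are non-maximum suppressed before PCM refinement.
#'
#' @param batch array `[S, S, 3, B]` (already normalized).
#' @param model a trainable `camloc_model`.
#' @param A a [make_warp()] on the image grid (`NULL` for identity).
#' @return list with per-image lists `yhat_o`, `y_o`, `yhat_t`, `y_t`
#'   (`[h, w, n_classes]` stacks), feature maps `fmap_o`, `fmap_t`, the
#'   transform `A` and its CAM-grid counterpart `A_cam`.
#' @export
siamese_forward <- function(batch, model, A = NULL) {
  batch <- as_nchw(batch)
  xb_t <- if (is.null(A)) batch else apply_warp(A, batch)
  fo <- model_forward(model, batch)
  ft <- model_forward(model, xb_t)
  bsz <- dim(batch)[4L]
  hc <- dim(fo$cams)[1L]; wc <- dim(fo$cams)[2L]
  a_cam <- if (is.null(A)) NULL else make_warp(hc, wc, A$angle_deg)
  per_image <- function(fwd, i) {
    s <- fwd$cams[, , , i, drop = FALSE]
    dim(s) <- dim(s)[1:3]
    s <- suppress_non_maximum(s)
    fm <- fwd$fmap[, , , i, drop = FALSE]
    dim(fm) <- dim(fm)[1:3]
    list(yhat = s, y = refine_cams(s, fm, model$pcm), fmap = fm)
  }
  out <- list(yhat_o = list(), y_o = list(), yhat_t = list(), y_t = list(),
              fmap_o = list(), fmap_t = list())
  for (i in seq_len(bsz)) {
    po <- per_image(fo, i); pt <- per_image(ft, i)
    out$yhat_o[[i]] <- po$yhat; out$y_o[[i]] <- po$y; out$fmap_o[[i]] <- po$fmap
    out$yhat_t[[i]] <- pt$yhat; out$y_t[[i]] <- pt$y; out$fmap_t[[i]] <- pt$fmap
  }
  out$A <- A; out$A_cam <- a_cam
  out$z_o <- fo$z; out$z_t <- ft$z
  out
}

#' Phase 2: train the PCM with the Siamese SEAM objective
#'
#' Per image a rotation angle is drawn uniformly from the configured range
#' (flip transforms are never sampled), the Siamese pass is run, and the
#' combined objective `lambda_msml * MSML + lambda_ecr * ECR(OHEM)` is
#' minimized with Adam over the PCM embedding only; the gradient is the
#' analytic cosine-affinity backward pass. MSML is averaged over the two
#' branches; ECR masks rotated-in border pixels. Every non-PCM parameter is
#' bit-identical before and after, so classification probabilities are
#' unchanged by phase 2.
#'
#' @param model a trainable `camloc_model` (typically a phase-1 result).
#' @param images,labels training images and multi-hot labels.
#' @param cfg a [train_config()].
#' @param loss_cfg a [seam_loss_config()].
#' @param pcm_enabled guard; an explicit `FALSE` raises an error.
#' @return object of class `camloc_fit` with the trained model and a
#'   `history` tibble (epoch, seam_loss, msml, ecr).
#' @export
train_phase2_pcm <- function(model, images, labels, cfg = train_config(),
                             loss_cfg = seam_loss_config(),
                             pcm_enabled = TRUE) {
  if (!pcm_enabled) stop("train_phase2_pcm: PCM is disabled")
  if (length(images) == 0) stop("train_phase2_pcm: empty dataset")
  p2 <- cfg$phase2
  xb_all <- normalize_images(images)
  side <- dim(xb_all)[1L]
  theta_state <- adam_init(list(theta = model$pcm$theta))
  history <- vector("list", p2$epochs)

  with_local_seed(cfg$seed + 7L, {
    for (ep in seq_len(p2$epochs)) {
      idx <- sample(length(images))
      ep_seam <- c(); ep_msml <- c(); ep_ecr <- c()
      starts <- seq(1L, length(idx), by = p2$micro_batch)
      for (bi in seq_along(starts)) {
        take <- idx[starts[bi]:min(starts[bi] + p2$micro_batch - 1L, length(idx))]
        dtheta <- array(0, dim(model$pcm$theta))
        for (i in take) {
          ang <- runif(1, p2$rotation_range_deg[1L], p2$rotation_range_deg[2L])
          A <- make_warp(side, side, ang)
          sf <- siamese_forward(xb_all[, , , i, drop = FALSE], model, A)
          y_o <- sf$y_o[[1L]]; y_t <- sf$y_t[[1L]]
          yhat_o <- sf$yhat_o[[1L]]; yhat_t <- sf$yhat_t[[1L]]
          hw <- prod(dim(y_o)[1:2])
          z_o <- apply(y_o, 3L, mean); z_t <- apply(y_t, 3L, mean)
          yb <- labels[i, , drop = FALSE]
          msml <- (multilabel_soft_margin(matrix(z_o, 1L), yb) +
                     multilabel_soft_margin(matrix(z_t, 1L), yb)) / 2
          ecr <- ecr_with_ohem(y_o, y_t, yhat_o, yhat_t, sf$A_cam,
                               loss_cfg$ohem_keep_fraction)
          ep_msml <- c(ep_msml, msml); ep_ecr <- c(ep_ecr, as.numeric(ecr))
          ep_seam <- c(ep_seam, seam_total(msml, as.numeric(ecr), loss_cfg))
          # gradients wrt refined stacks
          dz_o <- msml_backward(matrix(z_o, 1L), yb) / 2
          dz_t <- msml_backward(matrix(z_t, 1L), yb) / 2
          spread <- function(dz, d) array(rep(as.vector(dz) / hw, each = hw), d)
          eg <- ecr_backward(y_o, y_t, yhat_o, yhat_t, sf$A_cam,
                             loss_cfg$ohem_keep_fraction)
          d_y_o <- loss_cfg$lambda_msml * spread(dz_o, dim(y_o)) +
            loss_cfg$lambda_ecr * eg$d_y_o
          d_y_t <- loss_cfg$lambda_msml * spread(dz_t, dim(y_t)) +
            loss_cfg$lambda_ecr * eg$d_y_t
          dtheta <- dtheta +
            pcm_backward_theta(sf$fmap_o[[1L]], model$pcm, yhat_o, d_y_o) +
            pcm_backward_theta(sf$fmap_t[[1L]], model$pcm, yhat_t, d_y_t)
        }
        upd <- adam_step(list(theta = model$pcm$theta),
                         list(theta = dtheta / length(take)), theta_state,
                         lr = p2$lr, betas = p2$betas)
        model$pcm$theta <- upd$params$theta
        theta_state <- upd$state
      }
      history[[ep]] <- tibble::tibble(epoch = ep, seam_loss = mean(ep_seam),
                                      msml = mean(ep_msml), ecr = mean(ep_ecr))
    }
  })
  structure(list(model = model, history = dplyr::bind_rows(history),
                 phase = "pcm", config = cfg),
            class = "camloc_fit")
}

#' Predict class probabilities and CAMs for a set of images
#'
#' Deterministic evaluation pipeline: normalize at native (or policy)
#' resolution, forward pass, optionally PCM-refine the suppressed CAMs.
#'
#' @param model a trainable `camloc_model`.
#' @param images list of grayscale matrices.
#' @param use_pcm refine CAMs with the model's PCM.
#' @param batch_size forward micro-batch size.
#' @return list with `prob` (`n_images x n_classes`), `z`, and `cams` (list
#'   of `[h, w, n_classes]` stacks — refined when `use_pcm`).
#' @export
model_predict <- function(model, images, use_pcm = FALSE, batch_size = 16L) {
  xb <- normalize_images(images)
  n <- dim(xb)[4L]
  probs <- matrix(NA_real_, n, model$n_classes)
  zs <- matrix(NA_real_, n, model$n_classes)
  cams <- vector("list", n)
  for (s in seq(1L, n, by = batch_size)) {
    take <- s:min(s + batch_size - 1L, n)
    fwd <- model_forward(model, xb[, , , take, drop = FALSE])
    probs[take, ] <- t(fwd$prob)
    zs[take, ] <- t(fwd$z)
    for (k in seq_along(take)) {
      cam <- fwd$cams[, , , k, drop = FALSE]
      dim(cam) <- dim(cam)[1:3]
      if (use_pcm) {
        fm <- fwd$fmap[, , , k, drop = FALSE]
        dim(fm) <- dim(fm)[1:3]
        cam <- refine_cams(suppress_non_maximum(cam), fm, model$pcm)
      }
      cams[[take[k]]] <- cam
    }
  }
  colnames(probs) <- colnames(zs) <- NULL
  list(prob = probs, z = zs, cams = cams)
}

#' @export
print.camloc_fit <- function(x, ...) {
  cat(sprintf("<camloc_fit phase=%s epochs=%d final_loss=%.4f>\n",
              x$phase, nrow(x$history),
              x$history[[nrow(x$history), 2L]]))
  invisible(x)
}
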