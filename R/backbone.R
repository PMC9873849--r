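# Multi-resolution backbone. A staged CNN yields raw stage features
# F^l (stride 2^l, l = 2..5); merge blocks re-fuse them coarse-to-fine into
# resolution-preserving features F_o^l:
#   F_o^5 = F^5,   F_o^l = g(F_o^{l+1}, F^l)
# where g reduces both inputs' channels by 4 (1x1 conv + ReLU), bilinearly
# upsamples the coarse input x2, concatenates, and projects back to the fine
# input's channel count (1x1 conv + ReLU).
#
# Three bases are supported: "tiny" (a width-reduced 4-stage CNN with 8-64
# channels, fully trainable on a desktop CPU), and "resnet50" /
# "efficientnet_b4", which are constructed as parameter-shape descriptors:
# their layer inventory is exact (so parameter counts are exact) but weights
# are not instantiated.

TINY_CHANNELS <- c(8L, 16L, 32L, 64L)     # levels 2..5
RESNET50_CHANNELS <- c(256L, 512L, 1024L, 2048L)
EFFB4_CHANNELS <- c(32L, 56L, 160L, 448L)

conv_shape <- function(k, cin, cout) list(w = c(k, k, cin, cout), b = cout)

tiny_stage_defs <- function() {
  list(
    stage1 = list(conv1 = list(k = 3L, cin = 3L, cout = 8L, stride = 2L, pad = 1L),
                  conv2 = list(k = 3L, cin = 8L, cout = 8L, stride = 2L, pad = 1L)),
    stage2 = list(conv1 = list(k = 3L, cin = 8L, cout = 16L, stride = 2L, pad = 1L)),
    stage3 = list(conv1 = list(k = 3L, cin = 16L, cout = 32L, stride = 2L, pad = 1L)),
    stage4 = list(conv1 = list(k = 3L, cin = 32L, cout = 64L, stride = 2L, pad = 1L)))
}

# --- exact layer inventories for the reference bases ------------------------

resnet50_shapes <- function() {
  sh <- list()
  add <- function(name, dims) sh[[name]] <<- dims
  add("stem.conv.w", c(7, 7, 3, 64)); add("stem.bn.g", 64); add("stem.bn.b", 64)
  layers <- list(c(3, 64), c(4, 128), c(6, 256), c(3, 512))
  cin <- 64L
  for (li in seq_along(layers)) {
    n <- layers[[li]][1L]; wd <- layers[[li]][2L]
    for (b in seq_len(n)) {
      p <- sprintf("layer%d.block%d", li, b)
      add(paste0(p, ".conv1.w"), c(1, 1, cin, wd))
      add(paste0(p, ".bn1.g"), wd); add(paste0(p, ".bn1.b"), wd)
      add(paste0(p, ".conv2.w"), c(3, 3, wd, wd))
      add(paste0(p, ".bn2.g"), wd); add(paste0(p, ".bn2.b"), wd)
      add(paste0(p, ".conv3.w"), c(1, 1, wd, 4 * wd))
      add(paste0(p, ".bn3.g"), 4 * wd); add(paste0(p, ".bn3.b"), 4 * wd)
      if (b == 1L) {
        add(paste0(p, ".downsample.conv.w"), c(1, 1, cin, 4 * wd))
        add(paste0(p, ".downsample.bn.g"), 4 * wd)
        add(paste0(p, ".downsample.bn.b"), 4 * wd)
      }
      cin <- 4L * wd
    }
  }
  sh
}

make_divisible <- function(v, divisor = 8L) {
  nv <- max(divisor, (as.integer(v + divisor / 2) %/% divisor) * divisor)
  if (nv < 0.9 * v) nv <- nv + divisor
  as.integer(nv)
}

efficientnet_b4_shapes <- function() {
  wm <- 1.4; dm <- 1.8
  adj <- function(c) make_divisible(c * wm)
  cfg <- list(c(1, 3, 1, 32, 16, 1), c(6, 3, 2, 16, 24, 2),
              c(6, 5, 2, 24, 40, 2), c(6, 3, 2, 40, 80, 3),
              c(6, 5, 1, 80, 112, 3), c(6, 5, 2, 112, 192, 4),
              c(6, 3, 1, 192, 320, 1))
  sh <- list()
  add <- function(name, dims) sh[[name]] <<- dims
  stem <- adj(32)
  add("stem.conv.w", c(3, 3, 3, stem)); add("stem.bn.g", stem); add("stem.bn.b", stem)
  for (bi in seq_along(cfg)) {
    e <- cfg[[bi]][1L]; k <- cfg[[bi]][2L]
    cin <- adj(cfg[[bi]][4L]); cout <- adj(cfg[[bi]][5L])
    nlay <- as.integer(ceiling(cfg[[bi]][6L] * dm))
    for (i in seq_len(nlay)) {
      bin <- if (i == 1L) cin else cout
      exp_ch <- make_divisible(bin * e)
      p <- sprintf("block%d.layer%d", bi, i)
      if (exp_ch != bin) {
        add(paste0(p, ".expand.w"), c(1, 1, bin, exp_ch))
        add(paste0(p, ".expand_bn.g"), exp_ch); add(paste0(p, ".expand_bn.b"), exp_ch)
      }
      add(paste0(p, ".dwise.w"), c(k, k, 1, exp_ch))
      add(paste0(p, ".dwise_bn.g"), exp_ch); add(paste0(p, ".dwise_bn.b"), exp_ch)
      sq <- max(1L, bin %/% 4L)
      add(paste0(p, ".se.fc1.w"), c(1, 1, exp_ch, sq)); add(paste0(p, ".se.fc1.b"), sq)
      add(paste0(p, ".se.fc2.w"), c(1, 1, sq, exp_ch)); add(paste0(p, ".se.fc2.b"), exp_ch)
      add(paste0(p, ".project.w"), c(1, 1, exp_ch, cout))
      add(paste0(p, ".project_bn.g"), cout); add(paste0(p, ".project_bn.b"), cout)
    }
  }
  last_in <- adj(320); last_out <- 4L * last_in
  add("head.conv.w", c(1, 1, last_in, last_out))
  add("head.bn.g", last_out); add("head.bn.b", last_out)
  sh
}

merge_block_shapes <- function(c_coarse, c_fine) {
  if (c_coarse %% 4L != 0L || c_fine %% 4L != 0L)
    stop(sprintf(
      "merge block: channel counts (%d, %d) must be divisible by 4",
      c_coarse, c_fine))
  rc <- c_coarse %/% 4L; rf <- c_fine %/% 4L
  list(reduce_coarse = conv_shape(1L, c_coarse, rc),
       reduce_fine = conv_shape(1L, c_fine, rf),
       project = conv_shape(1L, rc + rf, c_fine))
}

init_array <- function(dims) {
  if (length(dims) == 1L) return(numeric(dims))
  fan_in <- prod(dims[-length(dims)])
  array(rnorm(prod(dims), sd = sqrt(2 / fan_in)), dims)
}

#' Assemble a (multi-resolution) classification + CAM model
#'
#' Builds the staged backbone, the optional merge blocks implementing the
#' coarse-to-fine recursion `F_o^l = g(F_o^{l+1}, F^l)` down to
#' `finest_level`, the shared per-pixel classifier, and a PCM embedding
#' sized to the output feature map. The `"tiny"` base (4 stages, 8-64
#' channels) carries instantiated weights and is trainable on a CPU; the
#' `"resnet50"` and `"efficientnet_b4"` bases are exact layer inventories
#' used for parameter accounting (batch-norm running statistics are buffers,
#' not parameters, and are not counted).
#'
#' @param base one of `"tiny"`, `"resnet50"`, `"efficientnet_b4"`.
#' @param n_classes number of output classes.
#' @param finest_level finest merged resolution level, in `{2, 3, 4}`
#'   (level `l` has stride `2^l`); ignored when `multires = FALSE`.
#' @param multires if `FALSE`, the model reduces to the base network plus
#'   classifier head (standard stride-32 CAM).
#' @param trainable_stages integer stages (1-4) whose parameters receive
#'   gradient updates.
#' @param gamma LSE pooling sharpness.
#' @param pcm_embed PCM embedding width; default `max(2, C_out / 4)`.
#' @param seed seed for weight initialization of the tiny base.
#' @return object of class `camloc_model`.
#' @export
assemble_multires_model <- function(base = c("tiny", "resnet50", "efficientnet_b4"),
                                    n_classes = 14L, finest_level = 2L,
                                    multires = TRUE, trainable_stages = 1:4,
                                    gamma = 10, pcm_embed = NULL, seed = 1L) {
  if (is.character(base) && !base[1L] %in% c("tiny", "resnet50", "efficientnet_b4"))
    stop("assemble_multires_model: unsupported base '", base[1L],
         "'; supported bases: tiny, resnet50, efficientnet_b4")
  base <- match.arg(base)
  if (multires && !finest_level %in% 2:4)
    stop("assemble_multires_model: finest_level must be in {2, 3, 4}")

  level_channels <- switch(base, tiny = TINY_CHANNELS,
                           resnet50 = RESNET50_CHANNELS,
                           efficientnet_b4 = EFFB4_CHANNELS)
  backbone_shapes <- switch(base,
    tiny = {
      sh <- list()
      for (sn in names(tiny_stage_defs()))
        for (cn in names(tiny_stage_defs()[[sn]])) {
          d <- tiny_stage_defs()[[sn]][[cn]]
          sh[[paste(sn, cn, "w", sep = ".")]] <- c(d$k, d$k, d$cin, d$cout)
          sh[[paste(sn, cn, "b", sep = ".")]] <- d$cout
        }
      sh
    },
    resnet50 = resnet50_shapes(),
    efficientnet_b4 = efficientnet_b4_shapes())

  out_channels <- if (base == "efficientnet_b4" && !multires) 1792L
    else if (multires) level_channels[finest_level - 1L]
    else level_channels[4L]

  shapes <- backbone_shapes
  if (multires) {
    for (l in 4:2) {
      if (l < finest_level) break
      mb <- merge_block_shapes(level_channels[l], level_channels[l - 1L])
      for (part in names(mb)) {
        shapes[[sprintf("merge%d.%s.w", l, part)]] <- mb[[part]]$w
        shapes[[sprintf("merge%d.%s.b", l, part)]] <- mb[[part]]$b
      }
    }
  }
  shapes[["classifier.w"]] <- c(out_channels, n_classes)
  shapes[["classifier.b"]] <- n_classes

  params <- NULL
  if (base == "tiny") {
    params <- with_local_seed(seed, {
      p <- lapply(shapes, init_array)
      p[["classifier.w"]] <- matrix(p[["classifier.w"]], out_channels, n_classes)
      p
    })
  }
  structure(list(base = base, n_classes = as.integer(n_classes),
                 multires = multires,
                 finest_level = if (multires) as.integer(finest_level) else 5L,
                 trainable_stages = as.integer(trainable_stages),
                 gamma = gamma, level_channels = level_channels,
                 out_channels = as.integer(out_channels),
                 param_shapes = shapes, params = params,
                 pcm = pcm_params(out_channels, pcm_embed, seed = seed + 1L)),
            class = "camloc_model")
}

#' @export
print.camloc_model <- function(x, ...) {
  cat(sprintf("<camloc_model base=%s%s classes=%d params=%s pcm=%dx%d>\n",
              x$base,
              if (x$multires) sprintf(" multires(finest=%d)", x$finest_level) else "",
              x$n_classes, format(count_parameters(x), big.mark = ","),
              x$pcm$c_in, x$pcm$c_embed))
  invisible(x)
}

#' Count model parameters
#'
#' Counts every parameter tensor element of the backbone, merge blocks and
#' classifier head, trainable or frozen (batch-norm scale/shift count;
#' running statistics do not). The PCM embedding is a separately trained
#' module and is included only when `include_pcm = TRUE`. Also accepts a
#' plain named list of numeric arrays.
#'
#' @param model a `camloc_model`, or a list of numeric arrays/vectors.
#' @param include_pcm include the PCM embedding parameters.
#' @return integer count.
#' @export
count_parameters <- function(model, include_pcm = FALSE) {
  if (inherits(model, "camloc_model")) {
    n <- sum(vapply(model$param_shapes, prod, numeric(1)))
    if (include_pcm) n <- n + length(model$pcm$theta)
    return(as.integer(n))
  }
  if (is.list(model))
    return(as.integer(sum(vapply(model, length, numeric(1)))))
  stop("count_parameters: unsupported object")
}

model_params_for <- function(model, prefix) {
  nm <- grep(paste0("^", prefix), names(model$params), value = TRUE)
  model$params[nm]
}

stage_forward <- function(model, sn, x, keep_cache = FALSE) {
  defs <- tiny_stage_defs()[[sn]]
  caches <- list()
  for (cn in names(defs)) {
    d <- defs[[cn]]
    r <- conv2d_forward(x, model$params[[paste(sn, cn, "w", sep = ".")]],
                        model$params[[paste(sn, cn, "b", sep = ".")]],
                        stride = d$stride, pad = d$pad, keep_cache = keep_cache)
    if (keep_cache) {
      caches[[cn]] <- r$cache
      x <- r$out
    } else x <- r
    caches[[paste0(cn, ".pre")]] <- if (keep_cache) x else NULL
    x <- relu(x)
  }
  list(out = x, caches = caches)
}

stage_backward <- function(model, sn, caches, dy, need_dx = TRUE) {
  defs <- tiny_stage_defs()[[sn]]
  grads <- list()
  for (cn in rev(names(defs))) {
    pre <- caches[[paste0(cn, ".pre")]]
    dy <- dy * (pre > 0)
    g <- conv2d_backward(caches[[cn]], dy,
                         need_dx = need_dx || cn != names(defs)[1L])
    grads[[paste(sn, cn, "w", sep = ".")]] <- g$dw
    grads[[paste(sn, cn, "b", sep = ".")]] <- g$db
    dy <- g$dx
  }
  list(grads = grads, dx = dy)
}

#' Extract raw stage features F^2..F^5
#'
#' Runs the staged base forward and returns the raw per-level activations
#' (level `l` at stride `2^l`). Only the `"tiny"` base carries weights; the
#' descriptor bases raise an error.
#'
#' @param batch array `[H, W, 3, B]`, `H = W` divisible by 32.
#' @param model a `camloc_model` with instantiated weights.
#' @return list with elements `F2`..`F5` (arrays `[H/2^l, W/2^l, C_l, B]`).
#' @export
extract_stage_features <- function(batch, model) {
  if (is.null(model$params))
    stop("extract_stage_features: base '", model$base,
         "' is a parameter descriptor without instantiated weights")
  batch <- as_nchw(batch)
  if (dim(batch)[1L] %% 32L != 0L || dim(batch)[2L] %% 32L != 0L)
    stop("extract_stage_features: input side must be divisible by 32")
  x <- batch
  feats <- list()
  for (si in 1:4) {
    r <- stage_forward(model, paste0("stage", si), x)
    x <- r$out
    feats[[paste0("F", si + 1L)]] <- x
  }
  feats
}

merge_params <- function(model, l) {
  list(rc_w = model$params[[sprintf("merge%d.reduce_coarse.w", l)]],
       rc_b = model$params[[sprintf("merge%d.reduce_coarse.b", l)]],
       rf_w = model$params[[sprintf("merge%d.reduce_fine.w", l)]],
       rf_b = model$params[[sprintf("merge%d.reduce_fine.b", l)]],
       pj_w = model$params[[sprintf("merge%d.project.w", l)]],
       pj_b = model$params[[sprintf("merge%d.project.b", l)]])
}

#' Merge block: fuse a coarse resolution-preserving map into a finer one
#'
#' Order of operations: reduce the channels of both inputs by a factor of 4
#' with 1x1 convolutions (ReLU), bilinearly upsample the coarse input x2,
#' concatenate along channels, then a final 1x1 convolution (ReLU) restores
#' the fine input's channel count. The output has exactly the fine input's
#' shape, which is what allows the coarse-to-fine recursion.
#'
#' @param f_o_coarse array `[h/2, w/2, C_coarse, B]`.
#' @param f_fine array `[h, w, C_fine, B]`.
#' @param params named list of the six weight/bias arrays (`rc_w`, `rc_b`,
#'   `rf_w`, `rf_b`, `pj_w`, `pj_b`), e.g. drawn from a model's parameters.
#' @param keep_cache keep intermediates for the backward pass.
#' @return array shaped like `f_fine` (or a list with `out` and `cache`).
#' @export
merge_block_forward <- function(f_o_coarse, f_fine, params, keep_cache = FALSE) {
  f_o_coarse <- as_nchw(f_o_coarse); f_fine <- as_nchw(f_fine)
  if (!all(dim(f_o_coarse)[1:2] * 2L == dim(f_fine)[1:2]))
    stop("merge_block_forward: coarse input must be half the fine input's size")
  if (dim(f_o_coarse)[3L] %% 4L != 0L || dim(f_fine)[3L] %% 4L != 0L)
    stop("merge_block_forward: channel counts must be divisible by 4")
  rc <- conv2d_forward(f_o_coarse, params$rc_w, params$rc_b, keep_cache = keep_cache)
  rc_pre <- if (keep_cache) rc$out else rc
  rc_act <- relu(rc_pre)
  rf <- conv2d_forward(f_fine, params$rf_w, params$rf_b, keep_cache = keep_cache)
  rf_pre <- if (keep_cache) rf$out else rf
  rf_act <- relu(rf_pre)
  h <- dim(f_fine)[1L]; w <- dim(f_fine)[2L]
  up <- apply_pixel_op(resize_matrix(h %/% 2L, w %/% 2L, h, w), rc_act, h, w)
  cat_in <- array(0, c(h, w, dim(up)[3L] + dim(rf_act)[3L], dim(f_fine)[4L]))
  cat_in[, , seq_len(dim(up)[3L]), ] <- up
  cat_in[, , dim(up)[3L] + seq_len(dim(rf_act)[3L]), ] <- rf_act
  pj <- conv2d_forward(cat_in, params$pj_w, params$pj_b, keep_cache = keep_cache)
  pj_pre <- if (keep_cache) pj$out else pj
  out <- relu(pj_pre)
  if (!keep_cache) return(out)
  list(out = out,
       cache = list(rc = rc$cache, rc_pre = rc_pre, rf = rf$cache,
                    rf_pre = rf_pre, pj = pj$cache, pj_pre = pj_pre,
                    c_up = dim(up)[3L], hw = c(h, w)))
}

merge_block_backward <- function(cache, dy) {
  dy <- dy * (cache$pj_pre > 0)
  gpj <- conv2d_backward(cache$pj, dy)
  c_up <- cache$c_up
  d_up <- gpj$dx[, , seq_len(c_up), , drop = FALSE]
  d_rf_act <- gpj$dx[, , c_up + seq_len(dim(gpj$dx)[3L] - c_up), , drop = FALSE]
  h <- cache$hw[1L]; w <- cache$hw[2L]
  d_rc_act <- resize_adjoint(d_up, h %/% 2L, w %/% 2L)
  d_rc <- d_rc_act * (cache$rc_pre > 0)
  grc <- conv2d_backward(cache$rc, d_rc)
  d_rf <- d_rf_act * (cache$rf_pre > 0)
  grf <- conv2d_backward(cache$rf, d_rf)
  list(d_coarse = grc$dx, d_fine = grf$dx,
       grads = list(rc_w = grc$dw, rc_b = grc$db,
                    rf_w = grf$dw, rf_b = grf$db,
                    pj_w = gpj$dw, pj_b = gpj$db))
}

# Full forward pass of a trainable model: stage features, merge recursion,
# CAMs and LSE-pooled class scores.
model_forward <- function(model, batch, keep_cache = FALSE) {
  if (is.null(model$params))
    stop("model_forward: base '", model$base, "' has no instantiated weights")
  batch <- as_nchw(batch)
  x <- batch
  feats <- list(); stage_caches <- list()
  for (si in 1:4) {
    r <- stage_forward(model, paste0("stage", si), x, keep_cache = keep_cache)
    x <- r$out
    feats[[paste0("F", si + 1L)]] <- x
    stage_caches[[paste0("stage", si)]] <- r$caches
  }
  merge_caches <- list()
  fo <- feats$F5
  if (model$multires) {
    for (l in 4:2) {
      if (l < model$finest_level) break
      r <- merge_block_forward(fo, feats[[paste0("F", l + 1L - 1L)]],
                               merge_params(model, l), keep_cache = keep_cache)
      if (keep_cache) {
        merge_caches[[paste0("merge", l)]] <- r$cache
        fo <- r$out
      } else fo <- r
    }
  }
  cls <- forward_classify(fo, model$params[["classifier.w"]],
                          model$params[["classifier.b"]], model$gamma)
  list(feats = feats, fmap = fo, cams = cls$cams, z = cls$z, prob = cls$prob,
       stage_caches = stage_caches, merge_caches = merge_caches)
}

# Backward pass from d(loss)/dz. Returns gradients for trainable parameters.
model_backward <- function(model, fwd, dz) {
  d <- dim(fwd$cams)
  dcam <- lse_pool_backward(fwd$cams, model$gamma, dz)
  # classifier: cam = fm %*% W + b per pixel
  fm <- matrix(aperm(as_nchw(fwd$fmap), c(1L, 2L, 4L, 3L)),
               prod(d[c(1L, 2L, 4L)]), model$out_channels)
  dcm <- matrix(aperm(as_nchw(dcam), c(1L, 2L, 4L, 3L)),
                prod(d[c(1L, 2L, 4L)]), model$n_classes)
  grads <- list()
  grads[["classifier.w"]] <- crossprod(fm, dcm)
  grads[["classifier.b"]] <- colSums(dcm)
  dfm <- tcrossprod(dcm, model$params[["classifier.w"]])
  dfo <- aperm(array(dfm, c(d[1L], d[2L], d[4L], model$out_channels)),
               c(1L, 2L, 4L, 3L))
  # merge chain (reverse: finest first)
  dF <- setNames(vector("list", 4L), paste0("F", 2:5))
  if (model$multires) {
    for (l in model$finest_level:4) {
      g <- merge_block_backward(fwd$merge_caches[[paste0("merge", l)]], dfo)
      for (part in names(g$grads))
        grads[[sprintf("merge%d.%s", l,
                       c(rc_w = "reduce_coarse.w", rc_b = "reduce_coarse.b",
                         rf_w = "reduce_fine.w", rf_b = "reduce_fine.b",
                         pj_w = "project.w", pj_b = "project.b")[part])]] <-
          g$grads[[part]]
      dF[[paste0("F", l)]] <- g$d_fine
      dfo <- g$d_coarse
    }
    dF[["F5"]] <- dfo
  } else {
    dF[["F5"]] <- dfo
  }
  lowest <- min(model$trainable_stages)
  dnext <- NULL
  for (si in 4:1) {
    dy <- dF[[paste0("F", si + 1L)]]
    if (is.null(dy)) dy <- dnext else if (!is.null(dnext)) dy <- dy + dnext
    if (is.null(dy)) { dnext <- NULL; next }
    if (si < lowest) break
    sb <- stage_backward(model, paste0("stage", si),
                         fwd$stage_caches[[paste0("stage", si)]], dy,
                         need_dx = si > lowest)
    if (si %in% model$trainable_stages)
      grads <- c(grads, sb$grads)
    dnext <- sb$dx
  }
  grads
}
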