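small_ds <- generate_dataset(24, 64, seed = 41)

test_that("phase-1 training reduces the loss and is seed-deterministic", {
  m <- make_tiny_model(seed = 2)
  cfg <- tiny_train_config(seed = 5)
  cfg$phase1$epochs <- 3L
  fit1 <- train_phase1(m, small_ds$images, small_ds$labels, cfg)
  expect_lt(fit1$history$train_loss[3], fit1$history$train_loss[1])
  fit2 <- train_phase1(m, small_ds$images, small_ds$labels, cfg)
  expect_identical(fit1$history, fit2$history)
  expect_identical(fit1$model$params, fit2$model$params)
  expect_error(train_phase1(m, list(), small_ds$labels[0, , drop = FALSE], cfg),
               "empty")
})

test_that("gradient accumulation equals one large-batch step on identical micro-batches", {
  img <- small_ds$images[[1]]
  imgs <- rep(list(img), 6)
  labs <- matrix(rep(small_ds$labels[1, ], each = 6), 6)
  m <- make_tiny_model(seed = 3)
  cfg_acc <- tiny_train_config(seed = 1)
  cfg_acc$phase1 <- utils::modifyList(cfg_acc$phase1,
                                      list(epochs = 1L, micro_batch = 2L,
                                           accumulation_steps = 3L))
  cfg_big <- tiny_train_config(seed = 1)
  cfg_big$phase1 <- utils::modifyList(cfg_big$phase1,
                                      list(epochs = 1L, micro_batch = 6L,
                                           accumulation_steps = 1L))
  fa <- train_phase1(m, imgs, labs, cfg_acc)
  fb <- train_phase1(m, imgs, labs, cfg_big)
  for (nm in names(fa$model$params))
    expect_equal(fa$model$params[[nm]], fb$model$params[[nm]],
                 tolerance = 1e-10)
})

test_that("Siamese branches agree under the identity transform", {
  m <- make_tiny_model(seed = 4)
  xb <- camloc:::normalize_images(small_ds$images[1:2])
  sf <- siamese_forward(xb, m, A = NULL)
  expect_equal(sf$yhat_o, sf$yhat_t, tolerance = 1e-12)
  expect_equal(sf$y_o, sf$y_t, tolerance = 1e-12)
})

test_that("rotating a CAM there and back restores interior pixels", {
  g <- outer(1:32, 1:32, function(r, c) sin(r / 6) + cos(c / 5))
  fwdw <- make_warp(32, 32, 20); bwdw <- make_warp(32, 32, -20)
  rt <- matrix(apply_warp(bwdw, apply_warp(fwdw, g)), 32, 32)
  interior <- 12:21
  expect_lt(max(abs(rt[interior, interior] - g[interior, interior])), 0.02)
})

test_that("a pointwise model is exactly equivariant up to interpolation error", {
  # single 1x1 conv: rotation and network commute, so the Siamese branches
  # must agree wherever the warp is valid
  set.seed(12)
  x <- array(abs(rnorm(16 * 16 * 2)), c(16, 16, 2, 1))
  w1 <- array(rnorm(2 * 3), c(1, 1, 2, 3)); b1 <- rnorm(3)
  net <- function(z) camloc:::conv2d_forward(z, w1, b1)
  A <- make_warp(16, 16, 90)   # exact rotation: no interpolation error
  out_then_warp <- apply_warp(A, net(x))
  warp_then_out <- net(apply_warp(A, x))
  v <- array(A$valid, c(16, 16))
  for (ci in 1:3) {
    d <- abs(out_then_warp[, , ci, 1] - warp_then_out[, , ci, 1])
    expect_lt(max(d[v]), 1e-9)
  }
})

test_that("phase 2 trains only the PCM embedding and never samples flips", {
  m <- make_tiny_model(seed = 6)
  cfg <- tiny_train_config(seed = 9)
  cfg$phase1$epochs <- 2L
  fit1 <- train_phase1(m, small_ds$images, small_ds$labels, cfg)
  cfg$phase2$epochs <- 1L
  fit2 <- train_phase2_pcm(fit1$model, small_ds$images, small_ds$labels, cfg)
  # freeze contract: backbone/classifier bit-identical, theta moved
  expect_identical(fit2$model$params, fit1$model$params)
  expect_false(identical(fit2$model$pcm$theta, fit1$model$pcm$theta))
  # classification path invariance
  p1 <- model_predict(fit1$model, small_ds$images[1:4])
  p2 <- model_predict(fit2$model, small_ds$images[1:4])
  expect_identical(p1$prob, p2$prob)
  expect_error(train_phase2_pcm(fit1$model, small_ds$images, small_ds$labels,
                                cfg, pcm_enabled = FALSE), "disabled")
  # sampled transforms are pure rotations within +/-30 degrees
  angles <- camloc:::with_local_seed(9 + 7, {
    replicate(500, runif(1, cfg$phase2$rotation_range_deg[1],
                         cfg$phase2$rotation_range_deg[2]))
  })
  expect_true(all(angles >= -30 & angles <= 30))
})

test_that("fit objects expose tidy, glance and autoplot surfaces", {
  m <- make_tiny_model(seed = 7)
  cfg <- tiny_train_config(seed = 2)
  cfg$phase1$epochs <- 2L
  fit <- train_phase1(m, small_ds$images[1:10],
                      small_ds$labels[1:10, , drop = FALSE], cfg,
                      val_images = small_ds$images[11:14],
                      val_labels = small_ds$labels[11:14, , drop = FALSE])
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("epoch", "train_loss", "val_loss"))
  expect_true(all(is.finite(td$val_loss)))
  gl <- glance(fit)
  expect_identical(gl$epochs, 2L)
  expect_s3_class(autoplot(fit), "ggplot")
})
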