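test_that("class balance weights follow the batch counts with zero guards", {
  lab <- matrix(c(1, 0, 0, 0,   # class 1: 1 pos, 3 neg
                  1, 1, 0, 0,   # class 2: balanced
                  0, 0, 0, 0),  # class 3: all negative
                nrow = 4)
  w <- class_balance_weights(lab)
  expect_equal(w$beta_p, c(4, 2, 0))
  expect_equal(w$beta_n, c(4 / 3, 2, 1))
  # identity 1/beta_P + 1/beta_N = 1 whenever both counts positive
  set.seed(2)
  for (i in 1:20) {
    lb <- matrix(rbinom(40, 1, 0.4), 8, 5)
    ww <- class_balance_weights(lb)
    both <- ww$n_pos > 0 & ww$n_neg > 0
    expect_equal(1 / ww$beta_p[both] + 1 / ww$beta_n[both],
                 rep(1, sum(both)), tolerance = 1e-12)
  }
  expect_error(class_balance_weights(matrix(c(0, 2), 1)), "0/1")
})

test_that("weighted BCE matches hand values and the elementwise oracle", {
  # single sample, one class, y=1, f=0.8, beta_P=2
  w <- structure(list(beta_p = 2, beta_n = 2, n_pos = 1, n_neg = 1),
                 class = "camloc_weights")
  expect_equal(weighted_bce(matrix(0.8), matrix(1), w), 2 * -log(0.8),
               tolerance = 1e-9)
  expect_equal(2 * -log(0.8), 0.4463, tolerance = 1e-4)

  # perfect predictions drive the loss to ~0
  lab <- matrix(c(1, 0, 0, 1), 2, 2)
  expect_lt(weighted_bce(abs(lab - 1e-9), lab), 1e-6)

  # balanced batch: exactly 2x the unweighted BCE class-sum
  labs <- rbind(c(1, 1), c(0, 0))
  pr <- matrix(runif(4, 0.2, 0.8), 2, 2)
  plain <- -mean(rowSums(labs * log(pr) + (1 - labs) * log(1 - pr)))
  expect_equal(weighted_bce(pr, labs), 2 * plain, tolerance = 1e-9)

  set.seed(3)
  for (i in 1:20) {
    lb <- matrix(rbinom(24, 1, 0.35), 6, 4)
    pp <- matrix(runif(24, 0.01, 0.99), 6, 4)
    ww <- class_balance_weights(lb)
    expect_equal(weighted_bce(pp, lb, ww),
                 oracle_weighted_bce(pp, lb, ww$beta_p, ww$beta_n),
                 tolerance = 1e-6)
  }
  expect_error(weighted_bce(matrix(0.5), matrix(2)), "0/1")
})

test_that("multi-label soft margin matches its sigmoid identity", {
  z0 <- matrix(0, 2, 3)
  expect_equal(multilabel_soft_margin(z0, matrix(1, 2, 3)), log(2),
               tolerance = 1e-12)
  expect_lt(multilabel_soft_margin(matrix(40, 1, 1), matrix(1)), 1e-12)
  set.seed(4)
  for (i in 1:20) {
    z <- matrix(rnorm(12, sd = 3), 3, 4)
    y <- matrix(rbinom(12, 1, 0.5), 3, 4)
    sig <- 1 / (1 + exp(-z))
    expect_equal(multilabel_soft_margin(z, y),
                 -mean(y * log(sig) + (1 - y) * log(1 - sig)),
                 tolerance = 1e-9)
  }
})

test_that("equivariant cross regularization with OHEM follows the counting rule", {
  d <- c(2, 2, 1)
  y <- array(rnorm(4), d)
  expect_equal(as.numeric(ecr_with_ohem(y, y, y, y, NULL, 0.2)), 0)

  # per-term pixel losses (1,0,0,1); ceil(0.2 * 4) = 1 kept per term
  y_o <- array(c(1, 0, 0, 1), d); yhat_t <- array(0, d)
  yhat_o <- array(c(1, 0, 0, 1), d); y_t <- array(0, d)
  expect_equal(as.numeric(ecr_with_ohem(y_o, y_t, yhat_o, yhat_t, NULL, 0.2)),
               2.0)

  set.seed(5)
  a <- array(rnorm(32), c(4, 4, 2)); b <- array(rnorm(32), c(4, 4, 2))
  cc <- array(rnorm(32), c(4, 4, 2)); dd <- array(rnorm(32), c(4, 4, 2))
  expect_gte(as.numeric(ecr_with_ohem(a, b, cc, dd, NULL, 0.2)), 0)

  # joint permutation invariance of pixels and classes (identity transform)
  perm <- sample(32)
  pm <- function(x) array(as.vector(x)[perm], dim(x))
  expect_equal(as.numeric(ecr_with_ohem(pm(a), pm(b), pm(cc), pm(dd), NULL, 0.25)),
               as.numeric(ecr_with_ohem(a, b, cc, dd, NULL, 0.25)),
               tolerance = 1e-12)

  expect_error(ecr_with_ohem(a, b, cc, dd, NULL, 0), "keep_fraction")
})

test_that("rotated-in border pixels are masked out of the OHEM pool", {
  A <- make_warp(8, 8, 45)
  expect_true(any(!A$valid))
  ones <- array(1, c(8, 8, 1))
  # identical, rotation-invariant content: only border effects could differ,
  # and those are masked, so the loss is exactly zero on valid pixels
  y_o <- ones; yhat_t <- apply_warp(A, ones); yhat_o <- ones
  y_t <- apply_warp(A, ones)
  v <- as.numeric(ecr_with_ohem(y_o, y_t, yhat_o, yhat_t, A, 0.2))
  expect_lt(v, 1e-9)
})

test_that("the combined objective weights its terms 1.5 and 1.0", {
  expect_equal(seam_total(2, 4), 7.0)
  expect_equal(seam_total(0, 0), 0)
  cfg <- seam_loss_config()
  expect_equal(cfg$lambda_msml, 1.5)
  expect_equal(cfg$lambda_ecr, 1.0)
  expect_equal(cfg$ohem_keep_fraction, 0.2)
  # linearity: gradient splits as (1.5, 1.0)
  eps <- 1e-6
  expect_equal((seam_total(2 + eps, 4) - seam_total(2, 4)) / eps, 1.5,
               tolerance = 1e-4)
  expect_equal((seam_total(2, 4 + eps) - seam_total(2, 4)) / eps, 1.0,
               tolerance = 1e-4)
})
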