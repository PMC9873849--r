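test_that("thresholded heatmaps yield the tight boxes of their components", {
  hm <- matrix(0L, 16, 16)
  hm[5:8, 6:10] <- 255L            # rows 4-7, cols 5-9 (0-based)
  b <- cam_to_boxes(hm, 0.7)
  expect_identical(nrow(b), 1L)
  expect_equal(unlist(b[1, ]), c(x = 5, y = 4, h = 4, w = 5))

  expect_identical(nrow(cam_to_boxes(matrix(0L, 16, 16), 0.7)), 0L)

  two <- matrix(0L, 16, 16)
  two[2:4, 2:4] <- 255L; two[10:13, 11:15] <- 200L
  b2 <- cam_to_boxes(two, 0.7)
  expect_identical(nrow(b2), 2L)
  expect_setequal(paste(b2$x, b2$y, b2$h, b2$w),
                  c("1 1 3 3", "10 9 4 5"))
})

test_that("component labelling agrees with a flood-fill oracle on random masks", {
  set.seed(19)
  for (i in 1:200) {
    side <- sample(8:20, 1)
    mask <- matrix(runif(side * side) < runif(1, 0.15, 0.5), side, side)
    hm <- matrix(0L, side, side); hm[mask] <- 255L
    got <- as.data.frame(cam_to_boxes(hm, 0.7))
    want <- oracle_boxes(mask)
    rownames(got) <- rownames(want) <- NULL
    expect_identical(nrow(got), nrow(want))
    expect_setequal(do.call(paste, got), do.call(paste, want))
  }
})

test_that("IoBB implements intersection over predicted area", {
  p <- c(x = 0, y = 0, h = 10, w = 10)
  expect_equal(iobb(p, p), 1.0)
  expect_equal(iobb(p, c(x = 5, y = 5, h = 10, w = 10)), 0.25)
  expect_equal(iobb(p, c(x = 20, y = 20, h = 4, w = 4)), 0.0)
  # containment characterization: ratio 1 iff pred inside gt
  set.seed(6)
  for (i in 1:50) {
    g <- random_box(64); q <- random_box(64)
    inside <- q["x"] >= g["x"] && q["y"] >= g["y"] &&
      q["x"] + q["w"] <= g["x"] + g["w"] && q["y"] + q["h"] <= g["y"] + g["h"]
    expect_identical(isTRUE(all.equal(iobb(q, g), 1.0)), inside)
    # integer rescaling leaves IoBB unchanged
    expect_equal(iobb(q * 4, g * 4), iobb(q, g), tolerance = 1e-12)
  }
  expect_error(iobb(c(x = 0, y = 0, h = 0, w = 3), p), "zero-area")
})

box_tbl <- function(...) {
  rows <- list(...)
  dplyr::bind_rows(lapply(rows, function(r)
    tibble::tibble(image = r[[1]], class = r[[2]], x = r[[3]], y = r[[4]],
                   h = r[[5]], w = r[[6]])))
}

test_that("Lacc and FPN follow their counting definitions", {
  gt <- box_tbl(list("a", "Disk", 10, 10, 10, 10),
                list("b", "Disk", 20, 20, 10, 10),
                list("c", "Disk", 30, 30, 10, 10))
  # perfect predictor
  la <- localization_accuracy(gt, gt)
  expect_equal(la$lacc, 1.0)
  fp <- false_positive_number(gt, gt)
  expect_equal(fp$fpn, 0.0)
  # no predictions at all
  empty <- gt[0, ]
  expect_equal(localization_accuracy(empty, gt)$lacc, 0.0)
  # hits on 2 of 3 images -> 0.6667
  pred <- box_tbl(list("a", "Disk", 10, 10, 10, 10),
                  list("b", "Disk", 21, 21, 10, 10),
                  list("c", "Disk", 50, 50, 5, 5))
  expect_equal(localization_accuracy(pred, gt)$lacc, 2 / 3, tolerance = 1e-6)
  # 3 non-overlapping predictions over 2 evaluated images -> FPN 1.5
  pred2 <- box_tbl(list("a", "Disk", 50, 50, 5, 5),
                   list("a", "Disk", 40, 40, 5, 5),
                   list("b", "Disk", 50, 50, 5, 5))
  gt2 <- gt[1:2, ]
  expect_equal(false_positive_number(pred2, gt2)$fpn, 1.5)
  # predictions on images without GT of the class are out of scope
  pred3 <- dplyr::bind_rows(pred2, box_tbl(list("zzz", "Disk", 0, 0, 5, 5)))
  expect_equal(false_positive_number(pred3, gt2)$fpn, 1.5)
  # a class with no GT images is absent, not zero
  expect_false("Ring" %in% localization_accuracy(pred, gt)$class)
})

test_that("Lacc is monotone non-increasing in the IoBB threshold", {
  set.seed(8)
  gt <- dplyr::bind_rows(lapply(1:12, function(i) {
    b <- random_box(64)
    tibble::tibble(image = paste0("im", i), class = "Disk",
                   x = b["x"], y = b["y"], h = b["h"], w = b["w"])
  }))
  pred <- dplyr::bind_rows(lapply(1:12, function(i) {
    b <- random_box(64)
    tibble::tibble(image = paste0("im", i), class = "Disk",
                   x = b["x"], y = b["y"], h = b["h"], w = b["w"])
  }))
  laccs <- vapply(c(0.05, 0.1, 0.3, 0.5, 0.9), function(t)
    localization_accuracy(pred, gt, t)$lacc, numeric(1))
  expect_true(all(diff(laccs) <= 1e-12))
})

test_that("strict inequality is used at the IoBB threshold", {
  gt <- box_tbl(list("a", "Disk", 0, 0, 10, 10))
  # exactly 10% overlap: 10x10 pred, 10 px^2 intersection
  pred <- box_tbl(list("a", "Disk", 9, 0, 10, 10))
  expect_equal(iobb(pred[1, ], gt[1, ]), 0.1)
  expect_equal(localization_accuracy(pred, gt, 0.1)$lacc, 0.0)
  expect_equal(localization_accuracy(pred, gt, 0.0999)$lacc, 1.0)
})

test_that("ROC-AUC matches the midrank Mann-Whitney statistic", {
  y <- c(1, 1, 1, 0, 0, 0)
  s <- c(0.9, 0.8, 0.7, 0.3, 0.2, 0.1)
  expect_equal(roc_auc(matrix(s), matrix(y))$auc, 1.0)
  set.seed(9)
  big <- rbinom(4000, 1, 0.5)
  noise <- runif(4000)
  expect_equal(roc_auc(matrix(noise), matrix(big))$auc, 0.5, tolerance = 0.05)
  for (i in 1:20) {
    yy <- rbinom(40, 1, 0.5)
    if (length(unique(yy)) < 2) next
    ss <- rnorm(40) + yy
    ss[sample(40, 5)] <- ss[1]    # inject ties
    expect_equal(roc_auc(matrix(ss), matrix(yy))$auc, auc_midrank(ss, yy),
                 tolerance = 1e-9)
  }
  # single-class labels are reported as absent
  expect_identical(nrow(roc_auc(matrix(rnorm(5)), matrix(rep(1, 5)))), 0L)
})

test_that("box scaling maps between resolution frames", {
  b <- tibble::tibble(x = 3, y = 4, h = 5, w = 6)
  s <- scale_boxes(b, 4)
  expect_equal(unlist(s), c(x = 12, y = 16, h = 20, w = 24))
})
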