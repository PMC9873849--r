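fixture_dir <- function(ds) {
  root <- withr::local_tempdir(.local_envir = parent.frame())
  write_fixture_tree(ds, root, overwrite = TRUE)
  root
}

test_that("fixture tree round-trips labels, boxes and images", {
  ds <- generate_dataset(30, 64, seed = 21)
  root <- fixture_dir(ds)
  back <- read_fixture(root, classes = ds$classes)
  expect_identical(unname(back$labels), unname(ds$labels))
  # boxes recovered exactly
  for (i in seq_along(ds$boxes)) {
    a <- dplyr::arrange(ds$boxes[[i]], class, x, y)
    b <- dplyr::arrange(back$boxes[[i]], class, x, y)
    expect_equal(as.data.frame(b), as.data.frame(a), ignore_attr = TRUE)
  }
  # 8-bit PNG quantization: within half a grey level
  expect_lt(max(abs(back$images[[1]] - ds$images[[1]])), 0.5 / 255 + 1e-9)
  # column sums match the generator's per-class positive counts
  parsed <- parse_label_table(file.path(root, "labels.csv"), ds$classes)
  expect_identical(unname(colSums(label_matrix(parsed, ds$classes))),
                   unname(colSums(ds$labels)))
})

test_that("bbox table of a boxless dataset has a header only", {
  ds <- generate_dataset(8, 64, no_finding_fraction = 1, seed = 2)
  root <- fixture_dir(ds)
  lines <- readLines(file.path(root, "bbox.csv"))
  expect_length(lines, 1L)
  expect_match(lines, "Image Index")
})

test_that("fixture split lists are disjoint at the patient level", {
  ds <- generate_dataset(40, 64, seed = 17)
  root <- fixture_dir(ds)
  back <- read_fixture(root, classes = ds$classes)
  pid <- setNames(ds$patient_ids, ds$names)
  expect_length(intersect(pid[back$splits$train_val], pid[back$splits$test]), 0)
  expect_setequal(c(back$splits$train_val, back$splits$test), ds$names)
})

test_that("write refuses a non-empty directory unless overwrite", {
  ds <- generate_dataset(4, 64, seed = 1)
  root <- withr::local_tempdir()
  write_fixture_tree(ds, root, overwrite = TRUE)
  expect_error(write_fixture_tree(ds, root), "not empty")
  expect_silent(write_fixture_tree(ds, root, overwrite = TRUE))
})

test_that("label parsing maps findings to the documented slots", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("Image Index,Finding Labels,Patient ID",
               "img1.png,Cardiomegaly|Effusion,1",
               "img2.png,No Finding,2"), f)
  tbl <- parse_label_table(f)
  m <- label_matrix(tbl, chestxray14_classes())
  expect_identical(unname(m["img1.png", c("Cardiomegaly", "Effusion")]),
                   c(1L, 1L))
  expect_identical(sum(m["img1.png", ]), 2L)
  expect_identical(sum(m["img2.png", ]), 0L)

  writeLines(c("Image Index,Finding Labels", "img.png,Dragonpox"), f)
  expect_error(parse_label_table(f), "Dragonpox")
  writeLines(c("Image Index,Patient ID", "img.png,1"), f)
  expect_error(parse_label_table(f), "Finding Labels")
})

test_that("bbox parsing validates geometry and resolves NIH-style headers", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("Image Index,Finding Label,x,y,h,w",
               "img1.png,Mass,100,50,30,40"), f)
  b <- parse_bbox_table(f, image_size = c(1024, 1024))
  expect_equal(unlist(b[1, c("x", "y", "h", "w")]),
               c(x = 100, y = 50, h = 30, w = 40))

  writeLines(c("Image Index,Finding Label,Bbox [x,y],h],w]",
               "img1.png,Mass,10,20,30,40"), f)
  b2 <- parse_bbox_table(f)
  expect_equal(unname(unlist(b2[1, c("x", "y", "h", "w")])), c(10, 20, 30, 40))

  writeLines(c("Image Index,Finding Label,x,y,h,w",
               "img1.png,Mass,100,50,0,40"), f)
  expect_error(parse_bbox_table(f), "row\\(s\\) 1")
  writeLines(c("Image Index,Finding Label,x,y,h,w",
               "img1.png,Mass,1000,50,30,40"), f)
  expect_error(parse_bbox_table(f, image_size = c(1024, 1024)), "out of bounds")
})

test_that("training subsets respect the official test list and patient split", {
  ds <- generate_dataset(200, 64, no_finding_fraction = 0.75, seed = 31)
  root <- fixture_dir(ds)
  parsed <- parse_label_table(file.path(root, "labels.csv"), ds$classes)
  splits <- list(train_val = readLines(file.path(root, "train_val_list.txt")),
                 test = readLines(file.path(root, "test_list.txt")))
  lab <- label_matrix(parsed, ds$classes)
  pool_dis <- sum(rowSums(lab[splits$train_val, ]) > 0)
  sub <- build_training_subsets(parsed, splits, ds$classes,
                                n_no_finding = 10L, val_fraction = 0.2,
                                seed = 4)
  # pool size arithmetic: all diseased + sampled no-finding
  expect_identical(sum(sub$split %in% c("train", "val")), pool_dis + 10L)
  # official test untouched
  expect_setequal(sub$image[sub$split == "test"], splits$test)
  expect_length(intersect(sub$image[sub$split != "test"], splits$test), 0)
  # patient-disjoint train/val
  expect_length(intersect(sub$patient_id[sub$split == "train"],
                          sub$patient_id[sub$split == "val"]), 0)

  sub0 <- build_training_subsets(parsed, splits, ds$classes,
                                 n_no_finding = 10L, val_fraction = 0,
                                 seed = 4)
  expect_identical(sum(sub0$split == "val"), 0L)
  expect_warning(
    build_training_subsets(parsed, splits, ds$classes,
                           n_no_finding = 100000L, seed = 4),
    "available")
})

test_that("evaluation preprocessing is a pure function with closed-form normalization", {
  img <- matrix(0.6, 48, 48)
  pol <- augment_policy(resize_to = 64)
  a <- augment_batch(list(img), pol, training = FALSE)
  b <- augment_batch(list(img), pol, training = FALSE)
  expect_identical(a, b)
  for (ch in 1:3)
    expect_equal(as.vector(a[, , ch, 1]),
                 rep((0.6 - pol$normalize_mean[ch]) / pol$normalize_sd[ch],
                     64 * 64),
                 tolerance = 1e-9)
})

test_that("sampled crop geometry stays within the policy's area and aspect ranges", {
  pol <- augment_policy(resize_to = 64)
  set.seed(99)
  for (i in 1:1000) {
    cp <- camloc:::sample_crop_params(64, 64, pol)
    frac <- (cp$hc * cp$wc) / (64 * 64)
    expect_gte(frac, 0.80)
    expect_lte(frac, 1.00)
    expect_gte(cp$r0, 1); expect_lte(cp$r0 + cp$hc - 1, 64)
    expect_gte(cp$c0, 1); expect_lte(cp$c0 + cp$wc - 1, 64)
  }
  set.seed(5)
  out <- augment_batch(list(matrix(runif(64^2), 64, 64)), pol, training = TRUE)
  expect_identical(dim(out), c(64L, 64L, 3L, 1L))
})
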