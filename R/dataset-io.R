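# Readers for the ChestX-ray14-style layout (real or fixture), training
# subset construction, and the preprocessing / augmentation policy.

#' The fourteen thoracic finding classes, in canonical order
#'
#' The fixed ordering used for every 14-slot multi-hot label vector.
#'
#' @return character vector of length 14.
#' @export
chestxray14_classes <- function() {
  c("Atelectasis", "Cardiomegaly", "Effusion", "Infiltration", "Mass",
    "Nodule", "Pneumonia", "Pneumothorax", "Consolidation", "Edema",
    "Emphysema", "Fibrosis", "Pleural_Thickening", "Hernia")
}

require_columns <- function(tbl, cols, what) {
  miss <- setdiff(cols, names(tbl))
  if (length(miss) > 0)
    stop(sprintf("%s: missing required column(s): %s", what,
                 paste(miss, collapse = ", ")))
}

#' Parse a finding-label table into multi-hot vectors
#'
#' Reads a CSV with columns `Image Index` and `Finding Labels`
#' (pipe-separated findings; the sentinel `No Finding` maps to the all-zero
#' vector) and an optional `Patient ID`. Unknown finding strings are
#' rejected by name.
#'
#' @param path CSV file path.
#' @param classes class vocabulary fixing the multi-hot slot order;
#'   default [chestxray14_classes()].
#' @return tibble with columns `image`, `patient_id`, then one 0/1 integer
#'   column per class (in `classes` order).
#' @export
parse_label_table <- function(path, classes = chestxray14_classes()) {
  tbl <- readr::read_csv(path, show_col_types = FALSE)
  require_columns(tbl, c("Image Index", "Finding Labels"), "parse_label_table")
  findings <- strsplit(tbl[["Finding Labels"]], "|", fixed = TRUE)
  lab <- matrix(0L, nrow(tbl), length(classes),
                dimnames = list(NULL, classes))
  for (i in seq_along(findings)) {
    f <- setdiff(trimws(findings[[i]]), c("No Finding", ""))
    unknown <- setdiff(f, classes)
    if (length(unknown) > 0)
      stop(sprintf("parse_label_table: unknown finding label(s) in row %d: %s",
                   i, paste(unknown, collapse = ", ")))
    lab[i, f] <- 1L
  }
  out <- tibble::tibble(
    image = tbl[["Image Index"]],
    patient_id = if ("Patient ID" %in% names(tbl))
      as.integer(tbl[["Patient ID"]]) else NA_integer_)
  dplyr::bind_cols(out, tibble::as_tibble(lab))
}

#' Extract the multi-hot label matrix from a parsed label table
#'
#' @param label_tbl a [parse_label_table()] tibble.
#' @param classes the class vocabulary (column names to pull).
#' @return integer matrix with image names as row names.
#' @export
label_matrix <- function(label_tbl, classes) {
  m <- as.matrix(label_tbl[, classes])
  rownames(m) <- label_tbl$image
  storage.mode(m) <- "integer"
  m
}

#' Parse a bounding-box table
#'
#' Columns are resolved by header name: `Image Index`, `Finding Label` and
#' coordinates `x`, `y`, `h`, `w` (the NIH dialect headers `Bbox [x`, `y`,
#' `h`, `w]` are recognized and mapped to the same `(x, y, h, w)` order:
#' `x`/`y` the top-left corner, `h`/`w` height and width, 0-based, pixel
#' units of the original image resolution).
#'
#' @param path CSV file path.
#' @param image_size optional `c(width, height)`; when given, boxes are
#'   validated to lie inside the image.
#' @return tibble with columns `image`, `class`, `x`, `y`, `h`, `w`.
#' @export
parse_bbox_table <- function(path, image_size = NULL) {
  tbl <- readr::read_csv(path, show_col_types = FALSE)
  nm <- names(tbl)
  ren <- c("Bbox [x" = "x", "y]" = "y", "h]" = "h", "w]" = "w")
  for (old in names(ren)) if (old %in% nm) names(tbl)[nm == old] <- ren[[old]]
  require_columns(tbl, c("Image Index", "Finding Label", "x", "y", "h", "w"),
                  "parse_bbox_table")
  out <- tibble::tibble(image = tbl[["Image Index"]],
                        class = tbl[["Finding Label"]],
                        x = as.numeric(tbl$x), y = as.numeric(tbl$y),
                        h = as.numeric(tbl$h), w = as.numeric(tbl$w))
  bad <- which(!(out$h > 0 & out$w > 0))
  if (length(bad) > 0)
    stop(sprintf("parse_bbox_table: non-positive box height/width in row(s) %s",
                 paste(bad, collapse = ", ")))
  if (!is.null(image_size)) {
    oob <- which(out$x < 0 | out$y < 0 |
                   out$x + out$w > image_size[1L] |
                   out$y + out$h > image_size[2L])
    if (length(oob) > 0)
      stop(sprintf("parse_bbox_table: box out of bounds in row(s) %s",
                   paste(oob, collapse = ", ")))
  }
  out
}

read_split_lists <- function(root) {
  list(train_val = readLines(file.path(root, "train_val_list.txt")),
       test = readLines(file.path(root, "test_list.txt")))
}

#' Read a fixture tree back into a dataset object
#'
#' Inverse of [write_fixture_tree()]: loads the PNG images, the label and
#' box tables and the split lists.
#'
#' @param root fixture directory.
#' @param classes class vocabulary; default: the classes observed in the
#'   label table, in first-appearance order.
#' @return a `camloc_dataset` with an extra `splits` field.
#' @export
read_fixture <- function(root, classes = NULL) {
  lab_tbl <- readr::read_csv(file.path(root, "labels.csv"),
                             show_col_types = FALSE)
  if (is.null(classes)) {
    f <- unlist(strsplit(lab_tbl[["Finding Labels"]], "|", fixed = TRUE))
    classes <- setdiff(unique(f), "No Finding")
  }
  parsed <- parse_label_table(file.path(root, "labels.csv"), classes)
  imgs <- lapply(parsed$image, function(nm) {
    m <- png::readPNG(file.path(root, "images", nm))
    if (length(dim(m)) == 3L) m <- m[, , 1L]
    m
  })
  side <- nrow(imgs[[1L]])
  bb <- parse_bbox_table(file.path(root, "bbox.csv"),
                         image_size = c(side, side))
  boxes <- lapply(parsed$image, function(nm) {
    b <- bb[bb$image == nm, c("class", "x", "y", "h", "w")]
    tibble::as_tibble(b)
  })
  structure(list(images = imgs, labels = label_matrix(parsed, classes),
                 boxes = boxes, patient_ids = parsed$patient_id,
                 names = parsed$image, classes = classes,
                 image_side = as.integer(side), seed = NA_integer_,
                 splits = read_split_lists(root)),
            class = "camloc_dataset")
}

#' Build train / validation / test subsets
#'
#' The official test list is kept unchanged. From the train/val pool, all
#' diseased images are kept plus `n_no_finding` sampled disease-free images
#' (clamped with a warning when fewer are available); that pool is split
#' 80:20 (by default) into train and validation at the patient level, so no
#' patient contributes images to both.
#'
#' @param label_tbl a [parse_label_table()] tibble covering every image.
#' @param splits list with character vectors `train_val` and `test`.
#' @param classes class vocabulary used in `label_tbl`.
#' @param n_no_finding number of disease-free images to keep in the pool.
#' @param val_fraction fraction of pool images routed to validation.
#' @param seed RNG seed; the result is deterministic given it.
#' @return tibble with columns `image`, `patient_id`, `split` (one of
#'   `"train"`, `"val"`, `"test"`).
#' @export
build_training_subsets <- function(label_tbl, splits,
                                   classes = chestxray14_classes(),
                                   n_no_finding = 5000L, val_fraction = 0.2,
                                   seed = 1L) {
  lab <- label_matrix(label_tbl, classes)
  stopifnot(all(c(splits$train_val, splits$test) %in% label_tbl$image))
  pool_tbl <- label_tbl[label_tbl$image %in% splits$train_val, ]
  pool_lab <- lab[pool_tbl$image, , drop = FALSE]
  diseased <- pool_tbl$image[rowSums(pool_lab) > 0]
  healthy <- pool_tbl$image[rowSums(pool_lab) == 0]
  with_local_seed(seed, {
    if (n_no_finding > length(healthy)) {
      warning(sprintf(
        "build_training_subsets: requested %d no-finding images, only %d available",
        n_no_finding, length(healthy)))
      n_no_finding <- length(healthy)
    }
    keep <- c(diseased, sample(healthy, n_no_finding))
    keep_tbl <- pool_tbl[pool_tbl$image %in% keep, ]
    val_pats <- if (val_fraction > 0)
      patient_split(keep_tbl$patient_id, val_fraction, seed) else integer(0)
    split <- ifelse(keep_tbl$patient_id %in% val_pats, "val", "train")
    dplyr::bind_rows(
      tibble::tibble(image = keep_tbl$image, patient_id = keep_tbl$patient_id,
                     split = split),
      tibble::tibble(image = splits$test,
                     patient_id = label_tbl$patient_id[
                       match(splits$test, label_tbl$image)],
                     split = "test"))
  })
}

#' Preprocessing / augmentation policy
#'
#' Training-time policy: random crop with area in `crop_area_range` of the
#' image and aspect ratio (w/h) in `crop_aspect_range`, resized to
#' `resize_to` squared, random horizontal flip, random rotation in
#' `rotation_range_deg`; at evaluation time only the deterministic resize.
#' All outputs are replicated to 3 channels and normalized by the ImageNet
#' channel statistics.
#'
#' @param resize_to output side in pixels.
#' @param crop_area_range,crop_aspect_range crop sampling ranges.
#' @param hflip_prob probability of a horizontal flip.
#' @param rotation_range_deg rotation range in degrees.
#' @param normalize_mean,normalize_sd per-channel statistics.
#' @return list of class `camloc_augment_policy`.
#' @export
augment_policy <- function(resize_to = 256L, crop_area_range = c(0.80, 1.00),
                           crop_aspect_range = c(0.75, 1.733),
                           hflip_prob = 0.5, rotation_range_deg = c(-15, 15),
                           normalize_mean = IMAGENET_MEAN,
                           normalize_sd = IMAGENET_SD) {
  stopifnot(crop_area_range[1L] > 0, crop_area_range[2L] <= 1,
            all(crop_aspect_range > 0))
  structure(list(resize_to = as.integer(resize_to),
                 crop_area_range = crop_area_range,
                 crop_aspect_range = crop_aspect_range,
                 hflip_prob = hflip_prob,
                 rotation_range_deg = rotation_range_deg,
                 normalize_mean = normalize_mean, normalize_sd = normalize_sd),
            class = "camloc_augment_policy")
}

# Rejection-sample crop geometry whose realized (rounded) area stays inside
# the policy's area range. Returns 1-based row/col offsets and sizes.
sample_crop_params <- function(h, w, policy) {
  repeat {
    frac <- runif(1, policy$crop_area_range[1L], policy$crop_area_range[2L])
    aspect <- runif(1, policy$crop_aspect_range[1L], policy$crop_aspect_range[2L])
    ta <- frac * h * w
    wc <- round(sqrt(ta * aspect))
    hc <- round(sqrt(ta / aspect))
    if (hc < 1 || wc < 1 || hc > h || wc > w) next
    realized <- (hc * wc) / (h * w)
    if (realized < policy$crop_area_range[1L] ||
        realized > policy$crop_area_range[2L]) next
    return(list(r0 = sample.int(h - hc + 1L, 1L),
                c0 = sample.int(w - wc + 1L, 1L), hc = hc, wc = wc))
  }
}

#' Preprocess (and optionally augment) a batch of images
#'
#' @param images list of grayscale matrices in `[0, 1]`, or of lists with an
#'   `$image` field (e.g. dataset records).
#' @param policy an [augment_policy()].
#' @param training if `TRUE`, apply the stochastic crop / flip / rotation
#'   pipeline; if `FALSE`, only the deterministic resize (a pure function of
#'   the input).
#' @param seed optional seed making the stochastic pipeline reproducible.
#' @return numeric array `[S, S, 3, B]`, `S = policy$resize_to`, normalized
#'   per channel by the policy's statistics.
#' @export
augment_batch <- function(images, policy = augment_policy(), training = FALSE,
                          seed = NULL) {
  get_img <- function(e) if (is.list(e)) e$image else e
  run <- function() {
    s <- policy$resize_to
    out <- array(0, c(s, s, 3L, length(images)))
    for (i in seq_along(images)) {
      img <- get_img(images[[i]])
      if (training) {
        cp <- sample_crop_params(nrow(img), ncol(img), policy)
        img <- img[cp$r0:(cp$r0 + cp$hc - 1L), cp$c0:(cp$c0 + cp$wc - 1L)]
        img <- resize_bilinear(img, s, s)
        if (runif(1) < policy$hflip_prob) img <- img[, rev(seq_len(s))]
        ang <- runif(1, policy$rotation_range_deg[1L],
                     policy$rotation_range_deg[2L])
        img <- matrix(apply_warp(make_warp(s, s, ang), img), s, s)
      } else if (!all(dim(img) == s)) {
        img <- resize_bilinear(img, s, s)
      }
      for (ch in 1:3)
        out[, , ch, i] <- (img - policy$normalize_mean[ch]) /
          policy$normalize_sd[ch]
    }
    out
  }
  if (!is.null(seed)) with_local_seed(seed, run()) else run()
}
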