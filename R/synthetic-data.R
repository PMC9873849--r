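# Synthetic radiograph generator. Renders grayscale images containing
# class-discriminative geometric lesions (disk / ring / bar) over a smooth
# low-frequency background with Gaussian noise, together with multi-hot
# image-level labels and ground-truth boxes, and writes them in the NIH
# ChestX-ray14 directory dialect so every downstream stage runs offline.

with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(list = ".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Describe one synthetic lesion class
#'
#' @param class_name label string used in the fixture tables.
#' @param shape_kind one of `"disk"`, `"ring"`, `"bar"`.
#' @param intensity additive brightness of the lesion, in (0, 1].
#' @param size_range integer `(min_px, max_px)` bounding-box side range.
#' @param count_range integer `(min, max)` lesions per positive image.
#' @return a `camloc_lesion_spec` list.
#' @export
lesion_spec <- function(class_name, shape_kind = c("disk", "ring", "bar"),
                        intensity = 0.5, size_range = c(10L, 16L),
                        count_range = c(1L, 2L)) {
  shape_kind <- match.arg(shape_kind)
  stopifnot(intensity > 0, intensity <= 1,
            size_range[1L] >= 3L, size_range[2L] >= size_range[1L],
            count_range[1L] >= 1L, count_range[2L] >= count_range[1L])
  structure(list(class_name = class_name, shape_kind = shape_kind,
                 intensity = intensity,
                 size_range = as.integer(size_range),
                 count_range = as.integer(count_range)),
            class = "camloc_lesion_spec")
}

#' Default three-class lesion panel (disk / ring / bar)
#'
#' @param size_range shared bounding-box side range in pixels.
#' @return list of three [lesion_spec()] objects.
#' @export
default_lesion_specs <- function(size_range = c(10L, 16L)) {
  list(lesion_spec("Disk", "disk", intensity = 0.45, size_range = size_range),
       lesion_spec("Ring", "ring", intensity = 0.50, size_range = size_range),
       lesion_spec("Bar",  "bar",  intensity = 0.45, size_range = size_range))
}

render_lesion <- function(img, spec, x0, y0, h, w) {
  side <- nrow(img)
  rr <- matrix(seq_len(side) - 1, side, side)            # row (y) coordinate
  cc <- matrix(seq_len(side) - 1, side, side, byrow = TRUE)
  cy <- y0 + (h - 1) / 2; cx <- x0 + (w - 1) / 2
  mask <- switch(spec$shape_kind,
    disk = ((rr - cy) / (h / 2))^2 + ((cc - cx) / (w / 2))^2 <= 1,
    ring = {
      d2 <- ((rr - cy) / (h / 2))^2 + ((cc - cx) / (w / 2))^2
      d2 <= 1 & d2 >= 0.45
    },
    bar = rr >= y0 & rr <= y0 + h - 1 & cc >= x0 & cc <= x0 + w - 1)
  img + mask * spec$intensity
}

smooth_background <- function(side, coarse = 6L) {
  base <- matrix(runif(coarse * coarse, 0.15, 0.45), coarse, coarse)
  resize_bilinear(base, side, side)
}

#' Generate a synthetic multi-label lesion dataset
#'
#' Deterministic given `seed`. Roughly `no_finding_fraction` of the images
#' carry an all-zero label row; each remaining image carries 1-3 positive
#' classes, every lesion rendered as its class's geometric shape at its
#' intensity over a smooth low-frequency background plus Gaussian noise.
#' Every rendered lesion is recorded as a tight axis-aligned box in `(x, y,
#' h, w)` form (0-based, origin top-left) unless the image is drawn as
#' "label-only" (fraction `1 - box_fraction`), emulating datasets in which
#' only a small subset of images has box annotations.
#'
#' @param n_images number of images (>= 1).
#' @param image_side square image side in pixels (>= 32).
#' @param specs list of [lesion_spec()]; shape kinds must be distinct.
#' @param background_noise_sd standard deviation of the additive Gaussian
#'   pixel noise.
#' @param no_finding_fraction probability that an image is disease-free.
#' @param box_fraction fraction of positive images whose boxes are recorded.
#' @param seed integer RNG seed.
#' @return object of class `camloc_dataset`: list with `images` (list of
#'   `side x side` matrices in `[0, 1]`), `labels` (`n x n_classes` multi-hot
#'   matrix, class names as columns), `boxes` (per image a tibble with
#'   columns class, x, y, h, w), `patient_ids`, `names`, `classes`, `seed`.
#' @export
generate_dataset <- function(n_images, image_side = 64L,
                             specs = default_lesion_specs(),
                             background_noise_sd = 0.05,
                             no_finding_fraction = 0.2,
                             box_fraction = 1.0, seed = 1L) {
  if (n_images < 1) stop("generate_dataset: n_images must be >= 1")
  if (image_side < 32) stop("generate_dataset: image_side must be >= 32")
  if (no_finding_fraction < 0 || no_finding_fraction > 1)
    stop("generate_dataset: no_finding_fraction must be in [0, 1]")
  kinds <- vapply(specs, function(s) s$shape_kind, character(1))
  if (anyDuplicated(kinds))
    stop("generate_dataset: overlapping identical specs (duplicate shape_kind); ",
         "distinct classes must use distinct shapes")
  classes <- vapply(specs, function(s) s$class_name, character(1))
  for (s in specs)
    if (s$size_range[2L] > image_side / 2)
      stop("generate_dataset: lesion max size exceeds image_side / 2")

  with_local_seed(seed, {
    # 1-3 images per synthetic patient
    pid <- integer(0); p <- 0L
    while (length(pid) < n_images) {
      p <- p + 1L
      pid <- c(pid, rep(p, sample(1:3, 1L)))
    }
    pid <- pid[seq_len(n_images)]

    images <- vector("list", n_images)
    boxes <- vector("list", n_images)
    labels <- matrix(0L, n_images, length(specs),
                     dimnames = list(NULL, classes))
    for (i in seq_len(n_images)) {
      img <- smooth_background(image_side) +
        matrix(rnorm(image_side^2, sd = background_noise_sd),
               image_side, image_side)
      bx <- list()
      if (runif(1) >= no_finding_fraction) {
        k <- sample(seq_len(min(3L, length(specs))), 1L)
        cls <- sample(seq_along(specs), k)
        for (ci in cls) {
          s <- specs[[ci]]
          labels[i, ci] <- 1L
          n_les <- sample(s$count_range[1L]:s$count_range[2L], 1L)
          for (j in seq_len(n_les)) {
            sz <- sample(s$size_range[1L]:s$size_range[2L], 1L)
            if (s$shape_kind == "bar") {
              h <- max(3L, round(sz / 3)); w <- sz
              if (runif(1) < 0.5) { tmp <- h; h <- w; w <- tmp }
            } else {
              h <- sz; w <- sz
            }
            x0 <- sample(0:(image_side - w), 1L)
            y0 <- sample(0:(image_side - h), 1L)
            img <- render_lesion(img, s, x0, y0, h, w)
            bx[[length(bx) + 1L]] <-
              tibble::tibble(class = s$class_name, x = x0, y = y0, h = h, w = w)
          }
        }
      }
      keep_boxes <- length(bx) > 0 && runif(1) <= box_fraction
      boxes[[i]] <- if (keep_boxes) dplyr::bind_rows(bx) else
        tibble::tibble(class = character(0), x = integer(0), y = integer(0),
                       h = integer(0), w = integer(0))
      images[[i]] <- pmin(pmax(img, 0), 1)
    }
    structure(list(images = images, labels = labels, boxes = boxes,
                   patient_ids = pid,
                   names = sprintf("%08d_000.png", seq_len(n_images)),
                   classes = classes, image_side = as.integer(image_side),
                   seed = as.integer(seed)),
              class = "camloc_dataset")
  })
}

#' @export
print.camloc_dataset <- function(x, ...) {
  cat(sprintf("<camloc_dataset: %d images %dx%d, %d classes (%s), %d boxed images>\n",
              length(x$images), x$image_side, x$image_side,
              length(x$classes), paste(x$classes, collapse = ", "),
              sum(vapply(x$boxes, nrow, integer(1)) > 0)))
  invisible(x)
}

#' Draw a patient-level holdout
#'
#' Samples whole patients until roughly `test_fraction` of the images are
#' covered, so no patient contributes images to both sides of a split.
#' Deterministic given `seed`.
#'
#' @param patient_ids integer patient id per image.
#' @param test_fraction target image fraction of the holdout.
#' @param seed integer seed.
#' @return integer vector of held-out patient ids.
#' @export
patient_split <- function(patient_ids, test_fraction = 0.2, seed = 1L) {
  with_local_seed(seed + 1000L, {
    pats <- unique(patient_ids)
    pats <- sample(pats)
    n_target <- test_fraction * length(patient_ids)
    test_pats <- integer(0); n_test <- 0L
    for (p in pats) {
      if (n_test >= n_target) break
      test_pats <- c(test_pats, p)
      n_test <- n_test + sum(patient_ids == p)
    }
    test_pats
  })
}

#' Write a dataset as a ChestX-ray14-style fixture tree
#'
#' Writes `images/*.png` (8-bit grayscale), `labels.csv` with columns
#' `Image Index`, `Finding Labels` (pipe-separated, `No Finding` sentinel)
#' and `Patient ID`, `bbox.csv` with columns `Image Index`, `Finding Label`,
#' `x`, `y`, `h`, `w`, and patient-level split lists `train_val_list.txt` /
#' `test_list.txt` (80:20 by image count, whole patients).
#'
#' @param ds a `camloc_dataset`.
#' @param root_dir output directory.
#' @param overwrite if `FALSE` (default), refuse to write into a non-empty
#'   existing directory.
#' @param test_fraction image fraction routed to `test_list.txt`.
#' @return `root_dir`, invisibly.
#' @export
write_fixture_tree <- function(ds, root_dir, overwrite = FALSE,
                               test_fraction = 0.2) {
  if (dir.exists(root_dir) && length(list.files(root_dir)) > 0 && !overwrite)
    stop("write_fixture_tree: ", root_dir,
         " exists and is not empty (use overwrite = TRUE)")
  dir.create(file.path(root_dir, "images"), recursive = TRUE,
             showWarnings = FALSE)
  for (i in seq_along(ds$images))
    png::writePNG(ds$images[[i]], file.path(root_dir, "images", ds$names[i]))

  findings <- apply(ds$labels, 1L, function(r) {
    pos <- ds$classes[r == 1]
    if (length(pos) == 0) "No Finding" else paste(pos, collapse = "|")
  })
  readr::write_csv(
    tibble::tibble(`Image Index` = ds$names, `Finding Labels` = findings,
                   `Patient ID` = ds$patient_ids),
    file.path(root_dir, "labels.csv"))

  bb <- dplyr::bind_rows(lapply(seq_along(ds$boxes), function(i) {
    b <- ds$boxes[[i]]
    if (nrow(b) == 0) return(NULL)
    tibble::tibble(`Image Index` = ds$names[i], `Finding Label` = b$class,
                   x = b$x, y = b$y, h = b$h, w = b$w)
  }))
  if (is.null(bb) || nrow(bb) == 0)
    bb <- tibble::tibble(`Image Index` = character(0),
                         `Finding Label` = character(0),
                         x = numeric(0), y = numeric(0),
                         h = numeric(0), w = numeric(0))
  readr::write_csv(bb, file.path(root_dir, "bbox.csv"))

  test_pats <- patient_split(ds$patient_ids, test_fraction, ds$seed)
  is_test <- ds$patient_ids %in% test_pats
  writeLines(ds$names[!is_test], file.path(root_dir, "train_val_list.txt"))
  writeLines(ds$names[is_test], file.path(root_dir, "test_list.txt"))
  invisible(root_dir)
}
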