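# Localization protocol: binary-threshold each normalized heatmap at Q,
# extract the tight boxes of its 8-connected components, and score them
# against ground truth with IoBB (intersection over predicted-box area),
# per-class localization accuracy (Lacc) and average false-positive number
# (FPN). Classification quality is scored with per-class ROC-AUC.

#' Extract predicted boxes from an 8-bit heatmap
#'
#' Binarizes at `Q * 255` (strictly greater), labels 8-connected foreground
#' components with a two-pass union-find sweep, and returns each component's
#' tight axis-aligned box in `(x, y, h, w)` form (0-based, origin top-left).
#'
#' @param heatmap integer matrix in `0..255` (a [rescale_heatmap()] output).
#' @param Q threshold on the normalized scale, in (0, 1); default 0.7.
#' @return tibble with columns `x`, `y`, `h`, `w` (zero rows for an empty
#'   mask).
#' @export
cam_to_boxes <- function(heatmap, Q = 0.7) {
  stopifnot(Q > 0, Q < 1)
  mask <- heatmap > Q * 255
  lab <- label_components(mask)
  ids <- setdiff(unique(as.vector(lab)), 0L)
  if (length(ids) == 0)
    return(tibble::tibble(x = numeric(0), y = numeric(0),
                          h = numeric(0), w = numeric(0)))
  out <- lapply(ids, function(id) {
    pos <- which(lab == id, arr.ind = TRUE)
    tibble::tibble(x = min(pos[, 2L]) - 1, y = min(pos[, 1L]) - 1,
                   h = diff(range(pos[, 1L])) + 1,
                   w = diff(range(pos[, 2L])) + 1)
  })
  dplyr::arrange(dplyr::bind_rows(out), x, y)
}

# Two-pass 8-connectivity connected-component labelling with union-find.
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  parent <- integer(0)
  find <- function(a) { while (parent[a] != a) a <- parent[a]; a }
  nxt <- 0L
  for (cc in seq_len(nc)) {
    for (rr in seq_len(nr)) {
      if (!mask[rr, cc]) next
      nb <- integer(0)
      if (rr > 1L && mask[rr - 1L, cc]) nb <- c(nb, lab[rr - 1L, cc])
      if (cc > 1L) {
        if (mask[rr, cc - 1L]) nb <- c(nb, lab[rr, cc - 1L])
        if (rr > 1L && mask[rr - 1L, cc - 1L]) nb <- c(nb, lab[rr - 1L, cc - 1L])
        if (rr < nr && mask[rr + 1L, cc - 1L]) nb <- c(nb, lab[rr + 1L, cc - 1L])
      }
      if (length(nb) == 0) {
        nxt <- nxt + 1L
        parent[nxt] <- nxt
        lab[rr, cc] <- nxt
      } else {
        roots <- vapply(nb, find, integer(1))
        r0 <- min(roots)
        lab[rr, cc] <- r0
        for (r in roots) parent[r] <- r0
      }
    }
  }
  if (nxt > 0L) {
    remap <- vapply(seq_len(nxt), find, integer(1))
    remap <- match(remap, sort(unique(remap)))
    lab[lab > 0L] <- remap[lab[lab > 0L]]
  }
  lab
}

as_box <- function(b) {
  if (is.data.frame(b))
    return(setNames(as.numeric(b[1L, c("x", "y", "h", "w")]),
                    c("x", "y", "h", "w")))
  b[c("x", "y", "h", "w")]
}

#' Intersection over predicted-box area (IoBB)
#'
#' `area(pred intersect gt) / area(pred)`; equals 1 exactly when the
#' predicted box is contained in the ground-truth box.
#'
#' @param pred,gt boxes as named vectors `c(x, y, h, w)` or single-row data
#'   frames with those columns (0-based, top-left origin; boxes are closed
#'   on the left/top and exclusive on the right/bottom edge).
#' @return overlap ratio in `[0, 1]`.
#' @export
iobb <- function(pred, gt) {
  p <- as_box(pred); g <- as_box(gt)
  if (p["h"] <= 0 || p["w"] <= 0) stop("iobb: zero-area predicted box")
  ix <- max(0, min(p["x"] + p["w"], g["x"] + g["w"]) - max(p["x"], g["x"]))
  iy <- max(0, min(p["y"] + p["h"], g["y"] + g["h"]) - max(p["y"], g["y"]))
  unname((ix * iy) / (p["w"] * p["h"]))
}

check_pred_gt <- function(predictions, ground_truths) {
  for (nm in c("image", "class", "x", "y", "h", "w")) {
    if (!nm %in% names(predictions) || !nm %in% names(ground_truths))
      stop("localization scoring: prediction/ground-truth tables need columns ",
           "image, class, x, y, h, w")
  }
}

# per (image, class): does any predicted box clear the IoBB threshold
# against any ground-truth box of that class?
hits_by_image <- function(predictions, ground_truths, t_iobb) {
  gt_keys <- unique(ground_truths[, c("image", "class")])
  res <- vector("list", nrow(gt_keys))
  for (i in seq_len(nrow(gt_keys))) {
    im <- gt_keys$image[i]; cl <- gt_keys$class[i]
    gts <- ground_truths[ground_truths$image == im & ground_truths$class == cl, ]
    prs <- predictions[predictions$image == im & predictions$class == cl, ]
    hit <- FALSE; n_fp <- nrow(prs)
    if (nrow(prs) > 0) {
      fp_flags <- rep(TRUE, nrow(prs))
      for (pi in seq_len(nrow(prs))) {
        ratios <- vapply(seq_len(nrow(gts)), function(gi)
          iobb(prs[pi, ], gts[gi, ]), numeric(1))
        if (any(ratios > t_iobb)) fp_flags[pi] <- FALSE
      }
      hit <- any(!fp_flags)
      n_fp <- sum(fp_flags)
    }
    res[[i]] <- tibble::tibble(image = im, class = cl, hit = hit, n_fp = n_fp)
  }
  dplyr::bind_rows(res)
}

#' Per-class localization accuracy (Lacc)
#'
#' For each class, the fraction of ground-truth-annotated images on which at
#' least one predicted box of that class overlaps some ground-truth box with
#' `IoBB > t_iobb` (strict inequality). Only images that carry ground truth
#' for the class are evaluated; classes without any such image are absent
#' from the result.
#'
#' @param predictions tibble of predicted boxes: columns `image`, `class`,
#'   `x`, `y`, `h`, `w`.
#' @param ground_truths tibble of ground-truth boxes, same columns.
#' @param t_iobb IoBB threshold (default 0.1).
#' @return tibble with columns `class`, `n_images`, `lacc`.
#' @export
localization_accuracy <- function(predictions, ground_truths, t_iobb = 0.1) {
  check_pred_gt(predictions, ground_truths)
  if (nrow(ground_truths) == 0)
    return(tibble::tibble(class = character(0), n_images = integer(0),
                          lacc = numeric(0)))
  hits <- hits_by_image(predictions, ground_truths, t_iobb)
  dplyr::summarise(dplyr::group_by(hits, class),
                   n_images = dplyr::n(), lacc = mean(hit), .groups = "drop")
}

#' Per-class average false positive number (FPN)
#'
#' Total number of predicted boxes failing the IoBB threshold against every
#' ground-truth box of their class, divided by the number of evaluated
#' (ground-truth-bearing) images for that class. Predictions on images
#' without ground truth for the class are out of scope.
#'
#' @inheritParams localization_accuracy
#' @return tibble with columns `class`, `n_images`, `fpn`.
#' @export
false_positive_number <- function(predictions, ground_truths, t_iobb = 0.1) {
  check_pred_gt(predictions, ground_truths)
  if (nrow(ground_truths) == 0)
    return(tibble::tibble(class = character(0), n_images = integer(0),
                          fpn = numeric(0)))
  hits <- hits_by_image(predictions, ground_truths, t_iobb)
  dplyr::summarise(dplyr::group_by(hits, class),
                   n_images = dplyr::n(), fpn = sum(n_fp) / dplyr::n(),
                   .groups = "drop")
}

#' Per-class ROC-AUC
#'
#' Trapezoidal area under the ROC curve (midrank tie handling), per class.
#' Classes whose labels are single-valued are reported as absent.
#'
#' @param scores `n_images x n_classes` score or probability matrix.
#' @param labels matching multi-hot matrix.
#' @param classes optional class names.
#' @return tibble with columns `class`, `auc`.
#' @export
roc_auc <- function(scores, labels, classes = colnames(labels)) {
  scores <- as.matrix(scores); labels <- as.matrix(labels)
  stopifnot(all(dim(scores) == dim(labels)))
  if (is.null(classes)) classes <- paste0("class", seq_len(ncol(labels)))
  out <- lapply(seq_len(ncol(labels)), function(ci) {
    y <- labels[, ci]
    if (length(unique(y)) < 2) return(NULL)
    a <- as.numeric(pROC::auc(pROC::roc(
      response = y, predictor = scores[, ci], levels = c(0, 1),
      direction = "<", quiet = TRUE)))
    tibble::tibble(class = classes[ci], auc = a)
  })
  dplyr::bind_rows(out)
}

#' Predict boxes and score the localization protocol on a dataset
#'
#' For each selected image and each class, the class CAM is upsampled to the
#' image resolution, rescaled to 8-bit ([rescale_heatmap()]), thresholded at
#' `Q`, and converted to boxes; boxes are scored against the dataset's
#' ground truth with [localization_accuracy()] and
#' [false_positive_number()]. Heatmaps are produced at the model input
#' frame; when ground truth lives at a different resolution, scale
#' predicted boxes first (see `scale_boxes`).
#'
#' @param model a trainable `camloc_model`.
#' @param ds a `camloc_dataset`.
#' @param indices image indices to evaluate (default: all with boxes).
#' @param q heatmap threshold (default 0.7).
#' @param t_iobb IoBB threshold (default 0.1).
#' @param use_pcm refine CAMs with the model's PCM before thresholding.
#' @return object of class `camloc_loc_eval`: list with tibbles `lacc`,
#'   `fpn`, `predictions`, `ground_truths` and the thresholds used.
#' @export
evaluate_localization <- function(model, ds, indices = NULL, q = 0.7,
                                  t_iobb = 0.1, use_pcm = FALSE) {
  if (is.null(indices))
    indices <- which(vapply(ds$boxes, nrow, integer(1)) > 0)
  preds <- model_predict(model, ds$images[indices], use_pcm = use_pcm)
  side <- ds$image_side
  pred_rows <- list()
  gt_rows <- list()
  for (k in seq_along(indices)) {
    i <- indices[k]
    b <- ds$boxes[[i]]
    if (nrow(b) > 0)
      gt_rows[[length(gt_rows) + 1L]] <-
        tibble::tibble(image = ds$names[i], class = b$class,
                       x = b$x, y = b$y, h = b$h, w = b$w)
    for (ci in seq_along(ds$classes)) {
      hm <- rescale_heatmap(preds$cams[[k]][, , ci], side)
      bx <- cam_to_boxes(hm, q)
      if (nrow(bx) > 0)
        pred_rows[[length(pred_rows) + 1L]] <-
          tibble::tibble(image = ds$names[i], class = ds$classes[ci],
                         x = bx$x, y = bx$y, h = bx$h, w = bx$w)
    }
  }
  empty <- tibble::tibble(image = character(0), class = character(0),
                          x = numeric(0), y = numeric(0),
                          h = numeric(0), w = numeric(0))
  predictions <- if (length(pred_rows)) dplyr::bind_rows(pred_rows) else empty
  ground_truths <- if (length(gt_rows)) dplyr::bind_rows(gt_rows) else empty
  structure(list(lacc = localization_accuracy(predictions, ground_truths, t_iobb),
                 fpn = false_positive_number(predictions, ground_truths, t_iobb),
                 predictions = predictions, ground_truths = ground_truths,
                 q = q, t_iobb = t_iobb, use_pcm = use_pcm,
                 n_images = length(indices)),
            class = "camloc_loc_eval")
}

#' Scale boxes between resolution frames
#'
#' Multiplies all coordinates by `factor` (e.g. 4 to map boxes predicted in
#' a 256-pixel input frame to 1024-pixel annotations).
#'
#' @param boxes tibble with columns `x`, `y`, `h`, `w`.
#' @param factor per-axis scale factor.
#' @return rescaled tibble.
#' @export
scale_boxes <- function(boxes, factor) {
  dplyr::mutate(boxes, x = x * factor, y = y * factor,
                h = h * factor, w = w * factor)
}

#' @export
print.camloc_loc_eval <- function(x, ...) {
  cat(sprintf("<camloc_loc_eval: %d images, Q=%.2f, T_IoBB=%.2f, pcm=%s>\n",
              x$n_images, x$q, x$t_iobb, x$use_pcm))
  print(x$lacc)
  invisible(x)
}
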