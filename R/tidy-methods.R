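# broom-style accessors and plotting for fitted objects and evaluations.

#' @describeIn train_phase1 tidy loss history of a fit (one row per epoch).
#' @param x a `camloc_fit`.
#' @param ... unused.
#' @export
tidy.camloc_fit <- function(x, ...) x$history

#' @describeIn train_phase1 one-row summary of a fit.
#' @export
glance.camloc_fit <- function(x, ...) {
  h <- x$history
  tibble::tibble(phase = x$phase, epochs = nrow(h),
                 final_loss = h[[nrow(h), 2L]],
                 n_parameters = count_parameters(x$model, include_pcm = TRUE))
}

#' @describeIn evaluate_localization per-class metric table (Lacc and FPN).
#' @param x a `camloc_loc_eval`.
#' @param ... unused.
#' @export
tidy.camloc_loc_eval <- function(x, ...) {
  dplyr::full_join(x$lacc, x$fpn[, c("class", "fpn")], by = "class")
}

#' @describeIn evaluate_localization one-row summary over classes.
#' @export
glance.camloc_loc_eval <- function(x, ...) {
  tibble::tibble(n_images = x$n_images, q = x$q, t_iobb = x$t_iobb,
                 use_pcm = x$use_pcm,
                 mean_lacc = mean(x$lacc$lacc),
                 mean_fpn = mean(x$fpn$fpn))
}

#' @describeIn train_phase1 loss-curve plot of a fit.
#' @param object a `camloc_fit`.
#' @export
autoplot.camloc_fit <- function(object, ...) {
  h <- object$history
  value_cols <- setdiff(names(h), "epoch")
  long <- do.call(rbind, lapply(value_cols, function(cn)
    data.frame(epoch = h$epoch, curve = cn, loss = h[[cn]])))
  long <- long[is.finite(long$loss), ]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                     colour = .data$curve)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "epoch", y = "loss", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn evaluate_localization per-class bar chart of Lacc and FPN.
#' @param object a `camloc_loc_eval`.
#' @export
autoplot.camloc_loc_eval <- function(object, ...) {
  tb <- tidy(object)
  long <- rbind(data.frame(class = tb$class, metric = "Lacc", value = tb$lacc),
                data.frame(class = tb$class, metric = "FPN", value = tb$fpn))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$class, y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a CAM heatmap with predicted and ground-truth boxes
#'
#' @param heatmap integer matrix from [rescale_heatmap()].
#' @param pred_boxes,gt_boxes optional tibbles with `x`, `y`, `h`, `w`.
#' @return a ggplot object.
#' @export
plot_heatmap <- function(heatmap, pred_boxes = NULL, gt_boxes = NULL) {
  df <- data.frame(x = rep(seq_len(ncol(heatmap)) - 1, each = nrow(heatmap)),
                   y = rep(seq_len(nrow(heatmap)) - 1, times = ncol(heatmap)),
                   v = as.vector(heatmap))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                        fill = .data$v)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "activation") +
    ggplot2::coord_fixed() + ggplot2::theme_minimal()
  add_boxes <- function(p, b, colour) {
    if (is.null(b) || nrow(b) == 0) return(p)
    p + ggplot2::geom_rect(
      data = as.data.frame(b),
      ggplot2::aes(xmin = .data$x, xmax = .data$x + .data$w,
                   ymin = .data$y, ymax = .data$y + .data$h),
      inherit.aes = FALSE, colour = colour, fill = NA, linewidth = 0.6)
  }
  p <- add_boxes(p, pred_boxes, "red")
  add_boxes(p, gt_boxes, "green")
}
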