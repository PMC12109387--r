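#' Plot a labelled cloud in occlusal projection
#'
#' Projects the cloud onto the x-y plane (the view onto the biting surfaces)
#' and colors points by class label; a quick visual check of arches,
#' scenarios and predictions.
#'
#' @param cloud a [labeled_cloud()].
#' @param labels optional label vector overriding the cloud's own (e.g. a
#'   prediction).
#' @param point_size passed to `ggplot2::geom_point()`.
#' @return a ggplot object.
#' @export
plot_cloud <- function(cloud, labels = NULL, point_size = 0.3) {
  stopifnot(inherits(cloud, "labeled_cloud"))
  lab <- if (!is.null(labels)) labels else cloud$labels
  df <- data.frame(x = cloud$points[, 1], y = cloud$points[, 2],
                   label = if (is.null(lab)) "point" else factor(lab))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   colour = .data$label)) +
    ggplot2::geom_point(size = point_size) +
    ggplot2::coord_equal() +
    ggplot2::guides(colour = ggplot2::guide_legend(
      override.aes = list(size = 2))) +
    ggplot2::labs(x = "x", y = "y", colour = "class") +
    ggplot2::theme_minimal()
}

#' Plot a training history
#'
#' Losses (train/validation) and validation mIoU against the epoch.
#'
#' @param history the `history` data.frame of a [train_model()] fit (or the
#'   fit itself).
#' @return a ggplot object.
#' @export
plot_history <- function(history) {
  if (inherits(history, "toothseg_fit")) history <- history$history
  long <- rbind(
    data.frame(epoch = history$epoch, value = history$train_loss,
               series = "train loss"),
    data.frame(epoch = history$epoch, value = history$val_loss,
               series = "val loss"),
    data.frame(epoch = history$epoch, value = history$val_miou,
               series = "val mIoU"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value,
                                     colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}
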