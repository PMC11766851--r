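# ggplot2 views of metric reports and training histories.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot per-region metric distributions
#'
#' Boxplots of the per-case values per subregion for one metric.
#'
#' @param object A `metric_report`.
#' @param metric One of `"dsc"`, `"iou"`, `"hausdorff"`.
#' @param ... Unused.
#' @export
autoplot.metric_report <- function(object, metric = c("dsc", "iou", "hausdorff"),
                                   ...) {
  metric <- match.arg(metric)
  df <- object$per_case
  df$region <- factor(df$region, levels = region_order())
  lab <- c(dsc = "Dice similarity coefficient", iou = "Jaccard index",
           hausdorff = "Hausdorff distance (mm)")[[metric]]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$region, y = .data[[metric]])) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey85") +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6, size = 1) +
    ggplot2::labs(x = "Subregion", y = lab) +
    ggplot2::theme_minimal()
}

#' Plot a training history
#'
#' Loss and validation mean DSC per epoch, with the learning-rate schedule.
#'
#' @param object A `catseg_train`.
#' @param ... Unused.
#' @export
autoplot.catseg_train <- function(object, ...) {
  h <- object$history
  df <- rbind(
    data.frame(epoch = h$epoch, value = h$loss, what = "Dice loss"),
    data.frame(epoch = h$epoch, value = h$val_dsc, what = "validation mean DSC"),
    data.frame(epoch = h$epoch, value = h$lr / max(h$lr), what = "lr (scaled)")
  )
  df <- df[is.finite(df$value), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value,
                                   colour = .data$what)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Epoch", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}
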