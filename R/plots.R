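#' Plot a model-comparison table
#'
#' Dot plot of within- and out-of-sample R-squared per tier, ordered by
#' AIC (best at the top).
#'
#' @param object A `psd_comparison` from [compare_models()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.psd_comparison <- function(object, ...) {
  df <- tidyr::pivot_longer(as_tibble(object), c("r2_in", "r2_out"),
                            names_to = "sample", values_to = "r2")
  df$sample <- ifelse(df$sample == "r2_in", "within-sample", "out-of-sample")
  df$model <- factor(df$model, levels = rev(object$model))
  ggplot2::ggplot(df, ggplot2::aes(x = 100 * .data$r2, y = .data$model,
                                   colour = .data$sample)) +
    ggplot2::geom_point(size = 2.5, na.rm = TRUE) +
    ggplot2::labs(x = expression(R^2 ~ "(%)"), y = NULL, colour = NULL,
                  title = "Model tiers ordered by AIC") +
    ggplot2::theme_minimal()
}

#' Plot the NBS permutation null
#'
#' Histogram of the permutation null of the maximal component statistic,
#' with the observed component statistics overlaid.
#'
#' @param object A `psd_nbs` from [nbs_test()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.psd_nbs <- function(object, ...) {
  p <- ggplot2::ggplot(tibble(null_max = object$null_max),
                       ggplot2::aes(x = .data$null_max)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70") +
    ggplot2::labs(x = sprintf("max component %s under permutation",
                              object$statistic),
                  y = "permutations") +
    ggplot2::theme_minimal()
  if (nrow(object$components) > 0) {
    p <- p + ggplot2::geom_vline(xintercept = object$components$stat,
                                 colour = "firebrick", linetype = 2)
  }
  p
}

#' Plot the forward stacking trace
#'
#' Deviance of the growing meta-model at each forward step; filled points
#' are accepted additions, the open point the first rejected candidate.
#'
#' @param object A `psd_stack` from [hierarchical_stack()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.psd_stack <- function(object, ...) {
  tr <- object$trace
  if (nrow(tr) == 0) abort("empty stacking trace")
  tr$label <- tr$model
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$step, y = .data$rss_after)) +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(shape = .data$accepted), size = 3) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1)) +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), vjust = -1,
                       size = 3) +
    ggplot2::labs(x = "forward step", y = "residual sum of squares",
                  shape = "accepted") +
    ggplot2::theme_minimal()
}
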