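#' Plot training history
#'
#' Loss curves (classification, reconstruction, total) and validation
#' accuracy across epochs. Requires ggplot2.
#'
#' @param fit a [train_heteronet()] fit.
#' @return A ggplot object.
#' @export
plot_training_history <- function(fit) {
  require_ggplot()
  h <- fit$history
  long <- rbind(
    data.frame(epoch = h$epoch, value = h$l_cls, what = "cross-entropy"),
    data.frame(epoch = h$epoch, value = h$l_total, what = "total"),
    data.frame(epoch = h$epoch, value = h$val_acc, what = "validation accuracy")
  )
  long <- long[!is.na(long$value), ]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~what, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot novelty-score distributions
#'
#' Score histograms for known vs novel cells with the calibrated threshold;
#' low scores indicate novel cells.
#'
#' @param novelty a [detect_novel()] result.
#' @param is_novel_truth optional logical ground truth to color the groups.
#' @return A ggplot object.
#' @export
plot_novelty_scores <- function(novelty, is_novel_truth = NULL) {
  require_ggplot()
  df <- data.frame(score = novelty$score)
  df$group <- if (!is.null(is_novel_truth))
    ifelse(is_novel_truth, "novel", "known") else "all"
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$score,
                                        fill = .data$group)) +
    ggplot2::geom_histogram(alpha = 0.6, position = "identity", bins = 40) +
    ggplot2::labs(x = "novelty score (low = novel)", y = "cells") +
    ggplot2::theme_minimal()
  if (!is.na(novelty$threshold)) {
    p <- p + ggplot2::geom_vline(xintercept = novelty$threshold,
                                 linetype = "dashed")
  }
  p
}

require_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
}
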