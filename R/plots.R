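#' Plot a confusion matrix as a heatmap
#'
#' @param object A [confusion_matrix()].
#' @param ... Unused.
#' @return A ggplot object: true class by predicted class, tile fill and
#'   label giving the trial counts.
#' @export
autoplot.confusion_eeg <- function(object, ...) {
  df <- as.data.frame(as.table(object$counts))
  names(df) <- c("truth", "estimate", "n")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate, y = .data$truth,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), colour = "white") +
    ggplot2::scale_y_discrete(limits = rev(object$levels)) +
    ggplot2::scale_fill_viridis_c(guide = "none") +
    ggplot2::labs(x = "predicted verb", y = "true verb",
                  title = sprintf("accuracy %.1f%%", 100 * accuracy(object)))
}

#' Plot a dual-LSTM training trace
#'
#' @param object A [fit_dual_lstm()] object.
#' @param ... Unused.
#' @return A ggplot object with loss and accuracy panels over epochs.
#' @export
autoplot.dual_lstm <- function(object, ...) {
  tr <- tidyr::pivot_longer(object$trace, -"epoch",
                            names_to = "metric", values_to = "value")
  tr <- tr[!is.na(tr$value), ]
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, title = "dual-LSTM training trace")
}

#' Plot an evaluation curve
#'
#' Dispatches on the curve kind produced by [repetitions_curve()],
#' [proportion_curve()] or [lr_curve()].
#'
#' @param object A `decode_curve` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.decode_curve <- function(object, ...) {
  kind <- attr(object, "kind")
  if (kind == "learning_rate") {
    ggplot2::ggplot(object, ggplot2::aes(x = .data$learning_rate,
                                         y = .data$wer)) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::scale_x_log10() +
      ggplot2::labs(x = "learning rate", y = "word error rate")
  } else {
    xvar <- if (kind == "repetitions") "reps" else "proportion"
    ggplot2::ggplot(object, ggplot2::aes(x = .data[[xvar]],
                                         y = .data$mean_accuracy)) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::geom_errorbar(ggplot2::aes(
        ymin = .data$mean_accuracy - .data$sd_accuracy,
        ymax = .data$mean_accuracy + .data$sd_accuracy), width = 0) +
      ggplot2::labs(x = if (kind == "repetitions")
        "training repetitions per verb" else "training proportion",
        y = "mean accuracy")
  }
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
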