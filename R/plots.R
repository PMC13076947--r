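#' Plot training loss history
#'
#' @param object A `synergy_model`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.synergy_model <- function(object, ...) {
  ggplot2::ggplot(object$loss_history, ggplot2::aes(x = .data$epoch, y = .data$mse)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "epoch", y = "training MSE (score units²)",
                  title = "Training loss") +
    ggplot2::theme_minimal()
}

#' Plot cross-validated predictions against observations
#'
#' Scatter of held-out predictions versus observed scores, one panel per
#' fold summary statistic in the subtitle, with the identity line.
#'
#' @param object A `synergy_cv`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.synergy_cv <- function(object, ...) {
  g <- glance(object)
  ggplot2::ggplot(object$predictions,
                  ggplot2::aes(x = .data$y, y = .data$y_hat)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8, colour = "steelblue") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::labs(
      x = sprintf("observed %s score", object$metric),
      y = "predicted score",
      title = sprintf("%d-fold cross-validation", object$k),
      subtitle = sprintf("RMSE %.3g | PCC %.3f", g$rmse_mean, g$pcc_mean)
    ) +
    ggplot2::theme_minimal()
}

#' Plot an ablation report
#'
#' @param object An `ablation_report` from [run_ablation()].
#' @param ... Unused.
#' @return A ggplot with MSE (and its fold-CI) per configuration.
#' @export
autoplot.ablation_report <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$configuration <- factor(df$configuration, levels = rev(df$configuration))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mse, y = .data$configuration)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_lo, xmax = .data$ci_hi),
                            height = 0.2) +
    ggplot2::labs(x = "cross-validated MSE (95% CI over folds)", y = NULL,
                  title = "Component ablation") +
    ggplot2::theme_minimal()
}
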