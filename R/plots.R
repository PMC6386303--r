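# ggplot2 figures for the result objects.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an ROC curve
#'
#' @param object An `eus_roc` from [roc_scores()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.eus_roc <- function(object, ...) {
  df <- object$points[order(object$points$fpr, object$points$sensitivity), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$sensitivity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity",
                  title = sprintf("AUC %.2f (%.0f%% CI %.2f-%.2f)", object$auc,
                                  100 * object$level, object$auc_ci[1], object$auc_ci[2])) +
    ggplot2::theme_minimal()
}

#' Compare the ROC curves of the two criteria
#'
#' @param roc_new,roc_old `eus_roc` objects for the 3-item and 4-item criteria.
#' @return A ggplot overlaying both stepwise curves.
#' @export
plot_roc_comparison <- function(roc_new, roc_old) {
  df <- dplyr::bind_rows(
    dplyr::mutate(roc_new$points, criteria = sprintf("new (AUC %.2f)", roc_new$auc)),
    dplyr::mutate(roc_old$points, criteria = sprintf("old (AUC %.2f)", roc_old$auc))
  )
  df <- df[order(df$criteria, df$fpr, df$sensitivity), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$sensitivity,
                                   colour = .data$criteria)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the per-feature agreement screen
#'
#' Kappa point estimates with bootstrap intervals and the selection
#' threshold.
#'
#' @param object An `eus_agreement` from [rate_agreement()].
#' @param threshold Kappa threshold drawn as a reference line (default 0.4).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.eus_agreement <- function(object, threshold = 0.4, ...) {
  df <- tibble::as_tibble(unclass(object))
  df$feature <- factor(df$feature, levels = rev(df$feature))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$kappa, y = .data$feature)) +
    ggplot2::geom_vline(xintercept = threshold, linetype = "dashed", colour = "grey40") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high),
                            height = 0.2, na.rm = TRUE) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "Fleiss kappa", y = NULL) +
    ggplot2::theme_minimal()
}
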