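# broom-style tidiers for the fitted result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an ROC result into its operating points
#'
#' @param x An `eus_roc` from [roc_scores()].
#' @param ... Unused.
#' @return A tibble with one row per operating point: `threshold`,
#'   `sensitivity`, `specificity`, `fpr`.
#' @export
tidy.eus_roc <- function(x, ...) x$points

#' One-row summary of an ROC result
#'
#' @param x An `eus_roc` from [roc_scores()].
#' @param ... Unused.
#' @return A tibble: `auc`, `auc_low`, `auc_high`, `n_pos`, `n_neg`.
#' @export
glance.eus_roc <- function(x, ...) {
  tibble::tibble(auc = x$auc, auc_low = x$auc_ci[1], auc_high = x$auc_ci[2],
                 n_pos = x$n_pos, n_neg = x$n_neg)
}

#' One-row summary of a DeLong paired AUC comparison
#'
#' @param x An `eus_delong` from [delong_test()].
#' @param ... Unused.
#' @return A tibble: `auc_a`, `auc_b`, `delta`, `se`, `statistic` (z),
#'   `p_value`, `degenerate`.
#' @export
glance.eus_delong <- function(x, ...) {
  tibble::tibble(auc_a = x$auc_a, auc_b = x$auc_b, delta = x$delta, se = x$se,
                 statistic = x$z, p_value = x$p_value, degenerate = x$degenerate)
}

#' @rdname glance.eus_delong
#' @export
tidy.eus_delong <- function(x, ...) glance.eus_delong(x, ...)

#' Tidy a per-feature agreement table into long metric form
#'
#' @param x An `eus_agreement` from [rate_agreement()].
#' @param ... Unused.
#' @return The agreement tibble (already tidy: one row per feature).
#' @export
tidy.eus_agreement <- function(x, ...) tibble::as_tibble(unclass(x))

#' Tidy a diagnostic performance row into one row per metric
#'
#' @param x An `eus_performance` from [diagnostic_metrics()].
#' @param ... Unused.
#' @return A tibble: `metric`, `estimate`, `conf_low`, `conf_high`.
#' @export
tidy.eus_performance <- function(x, ...) {
  metrics <- c("sensitivity", "specificity", "accuracy", "ppv", "npv")
  purrr::map_dfr(metrics, function(m) {
    tibble::tibble(metric = m, estimate = x[[m]][1],
                   conf_low = x[[paste0(m, "_low")]][1],
                   conf_high = x[[paste0(m, "_high")]][1])
  })
}
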