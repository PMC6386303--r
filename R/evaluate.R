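# Diagnostic evaluation: ROC over criteria scores, DeLong paired AUC
# comparison, and the accuracy table with Wilson confidence intervals.

# Placement values: for each diseased observation, the fraction of
# non-diseased observations it exceeds (ties get half credit), and vice
# versa. The mean placement is the Mann-Whitney AUC; their empirical
# covariances drive the DeLong variance.
.placements <- function(scores, pos) {
  x <- scores[pos]
  y <- scores[!pos]
  v10 <- vapply(x, function(xi) mean((xi > y) + 0.5 * (xi == y)), numeric(1))
  v01 <- vapply(y, function(yj) mean((x > yj) + 0.5 * (x == yj)), numeric(1))
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' ROC curve and AUC for an ordinal malignancy score
#'
#' Builds one operating point per distinct score threshold (positive =
#' score at least the threshold) plus the trivial endpoints, and computes the
#' AUC two ways: as the trapezoidal area of the stepwise curve and as the
#' tie-corrected Mann-Whitney statistic (half credit for ties). The two are
#' mathematically identical and asserted equal to within 1e-12. The AUC
#' confidence interval is a Wald interval on the DeLong variance.
#'
#' @param scores Numeric (typically ordinal) scores, higher = more malignant.
#' @param labels Diagnoses, same length.
#' @param positive Diseased-class label (default `"malignant"`).
#' @param level Confidence level for the AUC interval (default 0.95).
#' @return An object of class `eus_roc`: list with `points` (tibble
#'   `threshold`, `sensitivity`, `specificity`, `fpr`), `auc`, `auc_ci`,
#'   `n_pos`, `n_neg`, `level`.
#' @examples
#' roc_scores(c(2, 1, 1, 0), c("malignant", "malignant", "benign", "benign"))
#' @export
roc_scores <- function(scores, labels, positive = "malignant", level = 0.95) {
  stopifnot(length(scores) == length(labels), !anyNA(scores))
  pos <- labels == positive
  if (!any(pos) || all(pos)) stop("both classes must be present", call. = FALSE)
  thr <- sort(unique(scores))
  points <- tibble::tibble(
    threshold = c(-Inf, thr, Inf),
    sensitivity = vapply(c(-Inf, thr, Inf), function(t) mean(scores[pos] >= t), numeric(1)),
    specificity = vapply(c(-Inf, thr, Inf), function(t) mean(scores[!pos] < t), numeric(1))
  )
  points$fpr <- 1 - points$specificity
  # trapezoid over the curve ordered by increasing fpr
  ord <- order(points$fpr, points$sensitivity)
  fpr <- points$fpr[ord]
  tpr <- points$sensitivity[ord]
  auc_trap <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  pl <- .placements(scores, pos)
  stopifnot(abs(auc_trap - pl$auc) < 1e-12)
  var_auc <- stats::var(pl$v10) / length(pl$v10) + stats::var(pl$v01) / length(pl$v01)
  z <- stats::qnorm(1 - (1 - level) / 2)
  ci <- pmin(1, pmax(0, pl$auc + c(-1, 1) * z * sqrt(var_auc)))
  structure(list(points = points, auc = pl$auc, auc_ci = ci,
                 n_pos = sum(pos), n_neg = sum(!pos), level = level),
            class = "eus_roc")
}

#' @export
print.eus_roc <- function(x, ...) {
  cat(sprintf("ROC: AUC %.3f (%d%% CI %.3f-%.3f), %d malignant / %d benign\n",
              x$auc, round(100 * x$level), x$auc_ci[1], x$auc_ci[2], x$n_pos, x$n_neg))
  invisible(x)
}

#' DeLong paired comparison of two correlated AUCs
#'
#' Compares two scores measured on the same lesions via DeLong's
#' nonparametric method: AUCs are Mann-Whitney statistics from placement
#' values, the variance of their difference uses the paired placement
#' covariances, and the p-value is a two-sided normal tail on
#' z = (AUC_a - AUC_b) / se. Identical scores give zero variance; the
#' comparison is then reported as delta 0, p 1, flagged degenerate.
#'
#' @param scores_a,scores_b Paired per-lesion scores (same lesions, same order).
#' @param labels Diagnoses, same length.
#' @param positive Diseased-class label (default `"malignant"`).
#' @return An object of class `eus_delong`: `auc_a`, `auc_b`, `delta`, `se`,
#'   `z`, `p_value`, `degenerate`.
#' @export
delong_test <- function(scores_a, scores_b, labels, positive = "malignant") {
  stopifnot(length(scores_a) == length(scores_b), length(scores_a) == length(labels))
  pos <- labels == positive
  if (!any(pos) || all(pos)) stop("both classes must be present", call. = FALSE)
  pa <- .placements(scores_a, pos)
  pb <- .placements(scores_b, pos)
  m <- sum(pos)
  n <- sum(!pos)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  var_delta <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  delta <- pa$auc - pb$auc
  if (var_delta <= .Machine$double.eps) {
    res <- list(auc_a = pa$auc, auc_b = pb$auc, delta = 0, se = 0, z = 0,
                p_value = 1, degenerate = TRUE)
  } else {
    z <- delta / sqrt(var_delta)
    res <- list(auc_a = pa$auc, auc_b = pb$auc, delta = delta, se = sqrt(var_delta),
                z = z, p_value = 2 * stats::pnorm(-abs(z)), degenerate = FALSE)
  }
  structure(res, class = "eus_delong")
}

#' @export
print.eus_delong <- function(x, ...) {
  cat(sprintf("DeLong paired AUC test: %.3f vs %.3f (delta %.3f, z %.2f, p %.3g)%s\n",
              x$auc_a, x$auc_b, x$delta, x$z, x$p_value,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

# Wilson score interval (prop.test without continuity correction).
.wilson_ci <- function(x, n, level) {
  if (is.na(x) || n == 0) return(c(NA_real_, NA_real_))
  # only the confidence interval is used, which is the closed-form Wilson
  # score interval; the test's small-count approximation warning is moot
  ci <- suppressWarnings(stats::prop.test(x, n, conf.level = level, correct = FALSE))
  unname(ci$conf.int)
}

#' Diagnostic performance of a score at a threshold
#'
#' Dichotomises at positive = score >= `threshold` and reports the confusion
#' counts with sensitivity, specificity, accuracy, PPV and NPV, each with a
#' Wilson score confidence interval. Metrics whose denominator is empty
#' (e.g. PPV with no test-positives) are `NA` and flagged in `undefined`.
#'
#' @param scores Numeric per-lesion scores.
#' @param labels Diagnoses, same length.
#' @param threshold Positivity threshold on the score.
#' @param level Confidence level (default 0.95).
#' @param positive Diseased-class label (default `"malignant"`).
#' @return A one-row tibble of class `eus_performance`: `threshold`, `tp`,
#'   `fp`, `tn`, `fn`, and for each metric the estimate and `_low`/`_high`
#'   bounds, plus `undefined` (comma-separated names of undefined metrics,
#'   `NA` if none).
#' @export
diagnostic_metrics <- function(scores, labels, threshold, level = 0.95,
                               positive = "malignant") {
  stopifnot(length(scores) == length(labels))
  pos <- labels == positive
  test_pos <- scores >= threshold
  tp <- sum(test_pos & pos); fp <- sum(test_pos & !pos)
  tn <- sum(!test_pos & !pos); fn <- sum(!test_pos & pos)
  ratio_or_na <- function(num, den) if (den > 0) num / den else NA_real_
  est <- c(sensitivity = ratio_or_na(tp, tp + fn),
           specificity = ratio_or_na(tn, tn + fp),
           accuracy = ratio_or_na(tp + tn, tp + fp + tn + fn),
           ppv = ratio_or_na(tp, tp + fp),
           npv = ratio_or_na(tn, tn + fn))
  dens <- c(tp + fn, tn + fp, tp + fp + tn + fn, tp + fp, tn + fn)
  nums <- c(tp, tn, tp + tn, tp, tn)
  out <- tibble::tibble(threshold = threshold, tp = tp, fp = fp, tn = tn, fn = fn)
  for (i in seq_along(est)) {
    nm <- names(est)[i]
    ci <- if (dens[i] > 0) .wilson_ci(nums[i], dens[i], level) else c(NA_real_, NA_real_)
    out[[nm]] <- unname(est[i])
    out[[paste0(nm, "_low")]] <- ci[1]
    out[[paste0(nm, "_high")]] <- ci[2]
  }
  undef <- names(est)[is.na(est)]
  out$undefined <- if (length(undef) > 0) paste(undef, collapse = ",") else NA_character_
  class(out) <- c("eus_performance", class(out))
  out
}

#' Reconstruct confusion counts and predictive values from printed
#' sensitivity and specificity
#'
#' Given a published sensitivity/specificity pair and the cohort composition,
#' reconstructs the integer confusion counts (round half up) and the implied
#' accuracy, PPV and NPV -- the audit identity linking the columns of a
#' diagnostic accuracy table.
#'
#' @param sens,spec Proportions in \[0, 1\] (vectorised).
#' @param n_pos,n_neg Class sizes (diseased, non-diseased).
#' @return A tibble: `tp`, `fp`, `tn`, `fn`, `sensitivity`, `specificity`,
#'   `accuracy`, `ppv`, `npv` (recomputed from the integer counts; `NA`
#'   where a denominator is zero).
#' @examples
#' ppv_npv_from_sens_spec(0.267, 0.974, 30, 38)  # tp 8, fp 1 -> ppv 8/9
#' @export
ppv_npv_from_sens_spec <- function(sens, spec, n_pos, n_neg) {
  stopifnot(all(sens >= 0 & sens <= 1), all(spec >= 0 & spec <= 1),
            n_pos > 0, n_neg > 0)
  half_up <- function(x) floor(x + 0.5)
  tp <- half_up(sens * n_pos)
  tn <- half_up(spec * n_neg)
  fp <- n_neg - tn
  fn <- n_pos - tp
  safe <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  tibble::tibble(
    tp = tp, fp = fp, tn = tn, fn = fn,
    sensitivity = tp / n_pos, specificity = tn / n_neg,
    accuracy = (tp + tn) / (n_pos + n_neg),
    ppv = safe(tp, tp + fp), npv = safe(tn, tn + fn)
  )
}

#' Accuracy table for the two criteria at their reporting thresholds
#'
#' The head-to-head diagnostic accuracy table: performance of the historical
#' 4-item criteria and of the 3-item criteria at "at least 2 items" and "all
#' items" positivity thresholds.
#'
#' @param scores_new,scores_old Paired per-lesion scores under the two criteria.
#' @param labels Diagnoses.
#' @param level Confidence level (default 0.95).
#' @return A tibble with one row per (criteria, threshold) pair, columns as
#'   in [diagnostic_metrics()] plus `criteria` and `rule`.
#' @export
performance_table <- function(scores_new, scores_old, labels, level = 0.95) {
  rows <- list(
    list(criteria = "old", threshold = 2, rule = "at least 2 of 4", scores = scores_old),
    list(criteria = "old", threshold = 3, rule = "at least 3 of 4", scores = scores_old),
    list(criteria = "new", threshold = 2, rule = "at least 2 of 3", scores = scores_new),
    list(criteria = "new", threshold = 3, rule = "all 3", scores = scores_new)
  )
  purrr::map_dfr(rows, function(r) {
    dm <- diagnostic_metrics(r$scores, labels, r$threshold, level = level)
    dplyr::bind_cols(tibble::tibble(criteria = r$criteria, rule = r$rule), dm)
  })
}
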