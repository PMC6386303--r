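# Criteria construction: ROC-derived size cutoffs with clinical rounding,
# agreement-threshold feature selection, the 3-item and historical 4-item
# criteria, per-lesion scoring, and the group-comparison statistics.

#' Youden-index optimal cutoff for a continuous marker
#'
#' Searches every midpoint between consecutive distinct observed values and
#' returns the cutoff maximising the Youden index J = sensitivity +
#' specificity - 1, with "positive" defined as value strictly greater than
#' the cutoff. Ties in J are broken toward the higher cutoff (higher
#' specificity). By construction this equals an exhaustive search over all
#' achievable operating points.
#'
#' @param values Numeric marker values, one per lesion.
#' @param labels Diagnoses, same length; values equal to `positive` are the
#'   diseased class.
#' @param positive Label of the diseased class (default `"malignant"`).
#' @return A one-row tibble: `youden_cutoff`, `sensitivity`, `specificity`,
#'   `youden_j`, `n_pos`, `n_neg`.
#' @examples
#' youden_cutoff(c(30, 25, 10, 12), c("malignant", "malignant", "benign", "benign"))
#' @export
youden_cutoff <- function(values, labels, positive = "malignant") {
  stopifnot(length(values) == length(labels), !anyNA(values))
  pos <- labels == positive
  if (!any(pos) || all(pos)) stop("both classes must be present", call. = FALSE)
  v <- sort(unique(values))
  if (length(v) < 2) stop("no discriminating threshold: all values identical", call. = FALSE)
  cand <- (v[-1] + v[-length(v)]) / 2
  sens <- vapply(cand, function(ct) mean(values[pos] > ct), numeric(1))
  spec <- vapply(cand, function(ct) mean(values[!pos] <= ct), numeric(1))
  j <- sens + spec - 1
  best <- max(which(j == max(j)))  # tie -> higher cutoff
  tibble::tibble(
    youden_cutoff = cand[best],
    sensitivity = sens[best],
    specificity = spec[best],
    youden_j = j[best],
    n_pos = sum(pos),
    n_neg = sum(!pos)
  )
}

#' Round a cutoff to a clinically usable grid
#'
#' Nearest multiple of `grid` (default 5 mm), halves rounding up: 19.7 -> 20,
#' 10.7 -> 10, 12.5 -> 15. A 5 mm grid reproduces the clinically used
#' 20 mm / 10 mm pair from ROC-derived 19.7 / 10.7 mm cutoffs, where
#' nearest-integer rounding would give 11 mm.
#'
#' @param cutoff_mm Positive numeric cutoff(s).
#' @param grid_mm Positive grid step (default 5).
#' @return The rounded cutoff(s).
#' @export
clinical_round <- function(cutoff_mm, grid_mm = 5) {
  if (grid_mm <= 0) stop("grid_mm must be positive", call. = FALSE)
  stopifnot(all(cutoff_mm > 0))
  floor(cutoff_mm / grid_mm + 0.5) * grid_mm
}

#' Derive ROC size cutoffs for both axes of a lesion cohort
#'
#' Applies [youden_cutoff()] to the long and short axes and rounds each to
#' the clinical grid, reporting sensitivity/specificity at both the exact and
#' the rounded cutoff.
#'
#' @param lesions A lesion tibble (see [read_lesions()]).
#' @param grid_mm Rounding grid in mm (default 5).
#' @param positive Diseased-class label (default `"malignant"`).
#' @return A tibble with one row per axis: `axis`, `youden_cutoff_mm`,
#'   `rounded_cutoff_mm`, `sens_youden`, `spec_youden`, `sens_rounded`,
#'   `spec_rounded`.
#' @export
derive_cutoffs <- function(lesions, grid_mm = 5, positive = "malignant") {
  purrr::map_dfr(c(long = "long_axis_mm", short = "short_axis_mm"), function(col) {
    yc <- youden_cutoff(lesions[[col]], lesions$diagnosis, positive)
    rc <- clinical_round(yc$youden_cutoff, grid_mm)
    pos <- lesions$diagnosis == positive
    tibble::tibble(
      youden_cutoff_mm = yc$youden_cutoff,
      rounded_cutoff_mm = rc,
      sens_youden = yc$sensitivity,
      spec_youden = yc$specificity,
      sens_rounded = mean(lesions[[col]][pos] > rc),
      spec_rounded = mean(lesions[[col]][!pos] <= rc)
    )
  }, .id = "axis")
}

#' Select features passing the agreement threshold
#'
#' Keeps features whose Fleiss kappa is strictly greater than `threshold`
#' (default 0.4, the lower edge of the Landis-Koch "moderate" band) -- the
#' rule under which shape is the only categorical feature retained for the
#' criteria.
#'
#' @param agreement An agreement tibble from [rate_agreement()].
#' @param threshold Kappa threshold (default 0.4), strict inequality.
#' @return Character vector of selected feature names (possibly empty).
#' @export
select_features <- function(agreement, threshold = 0.4) {
  stopifnot(all(c("feature", "kappa") %in% names(agreement)))
  agreement$feature[!is.na(agreement$kappa) & agreement$kappa > threshold]
}

#' The agreement-based 3-item malignancy criteria
#'
#' Items: long axis above `long_cutoff_mm` (default 20 mm); short axis above
#' `short_cutoff_mm` (default 10 mm); consensus round-or-oval shape with a
#' long-short ratio above `ratio_cutoff` (default 0.5). All comparisons are
#' strict by default (`strict = FALSE` uses `>=`).
#'
#' @param long_cutoff_mm,short_cutoff_mm Size cutoffs in mm.
#' @param ratio_cutoff Long-short ratio cutoff for the shape item.
#' @param strict Use strict `>` comparisons (default `TRUE`).
#' @return An object of class `eus_criteria`.
#' @examples
#' new_criteria()
#' @export
new_criteria <- function(long_cutoff_mm = 20, short_cutoff_mm = 10,
                         ratio_cutoff = 0.5, strict = TRUE) {
  gt <- if (strict) `>` else `>=`
  items <- list(
    long_axis = list(
      label = sprintf("long axis %s %g mm", if (strict) ">" else ">=", long_cutoff_mm),
      fn = function(d) gt(d$long_axis_mm, long_cutoff_mm)
    ),
    short_axis = list(
      label = sprintf("short axis %s %g mm", if (strict) ">" else ">=", short_cutoff_mm),
      fn = function(d) gt(d$short_axis_mm, short_cutoff_mm)
    ),
    shape = list(
      label = sprintf("round or oval shape with ratio %s %g",
                      if (strict) ">" else ">=", ratio_cutoff),
      fn = function(d) d$shape_round_or_oval & gt(d$ratio, ratio_cutoff)
    )
  )
  structure(list(name = "new", items = items), class = "eus_criteria")
}

#' The historical 4-item malignancy criteria
#'
#' Items: long axis above 10 mm, consensus round shape, sharp (clear) border,
#' and hypoechoic (dark) pattern -- the conventional EUS signs of malignant
#' lymphadenopathy against which the 3-item criteria are evaluated.
#'
#' @param long_cutoff_mm Long-axis cutoff in mm (default 10).
#' @param strict Use strict `>` for the size item (default `TRUE`).
#' @return An object of class `eus_criteria`.
#' @export
old_criteria <- function(long_cutoff_mm = 10, strict = TRUE) {
  gt <- if (strict) `>` else `>=`
  items <- list(
    long_axis = list(
      label = sprintf("long axis %s %g mm", if (strict) ">" else ">=", long_cutoff_mm),
      fn = function(d) gt(d$long_axis_mm, long_cutoff_mm)
    ),
    # a finding is present only when agreed by >= min_votes raters, so an
    # indeterminate consensus (NA) means the finding is absent, not missing
    round = list(label = "round shape", fn = function(d) d$shape %in% "round"),
    border = list(label = "clear border", fn = function(d) d$border %in% "clear"),
    echogenicity = list(label = "dark (hypoechoic) pattern",
                        fn = function(d) d$echogenicity %in% "dark")
  )
  structure(list(name = "old", items = items), class = "eus_criteria")
}

#' @export
print.eus_criteria <- function(x, ...) {
  cat("EUS malignancy criteria '", x$name, "' (", length(x$items), " items):\n", sep = "")
  for (it in x$items) cat("  - ", it$label, "\n", sep = "")
  invisible(x)
}

#' Score lesions against a criteria definition
#'
#' Joins measurements with consensus features, evaluates each binary item,
#' and counts satisfied items. Items referencing an indeterminate consensus
#' category are `NA` and propagate to the score.
#'
#' @param lesions A lesion tibble.
#' @param consensus A consensus tibble from [consensus_features()].
#' @param criteria An [new_criteria()] / [old_criteria()] object.
#' @return A tibble: `lesion_id`, `criteria`, one logical column per item,
#'   and the integer `score` (count of `TRUE` items).
#' @examples
#' sim <- simulate_cohort(cohort_config(n_lesions = 12), seed = 1)
#' ratings <- simulate_ratings(sim$truth, rater_noise_config(0), seed = 2)
#' score_lesions(sim$lesions, consensus_features(ratings), new_criteria())
#' @export
score_lesions <- function(lesions, consensus, criteria) {
  stopifnot(inherits(criteria, "eus_criteria"))
  d <- lesions |>
    long_short_ratio() |>
    dplyr::left_join(consensus, by = "lesion_id")
  item_vals <- purrr::map(criteria$items, function(it) it$fn(d))
  out <- tibble::tibble(lesion_id = d$lesion_id, criteria = criteria$name)
  for (nm in names(item_vals)) out[[paste0("item_", nm)]] <- item_vals[[nm]]
  out$score <- as.integer(rowSums(do.call(cbind, item_vals)))
  out
}

#' Wilcoxon rank-sum comparison of a continuous variable between classes
#'
#' Mid-ranks for ties; exact enumeration when both groups have at most 10
#' observations and no ties, otherwise the normal approximation with tie and
#' continuity correction (via [stats::wilcox.test()]).
#'
#' @param x,y Numeric samples for the two groups (both non-empty).
#' @return A tibble: `statistic` (rank-sum W), `p_value`, `method`.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  stopifnot(length(x) > 0, length(y) > 0)
  ties <- any(duplicated(c(x, y)))
  exact <- length(x) <= 10 && length(y) <= 10 && !ties
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact, correct = TRUE))
  tibble::tibble(
    statistic = unname(wt$statistic),
    p_value = wt$p.value,
    method = if (exact) "exact" else "normal approximation"
  )
}

#' Chi-square or Fisher association test for a 2x2 table
#'
#' Pearson's chi-square without continuity correction when every expected
#' count is at least 5, otherwise Fisher's exact test (two-sided, summing
#' hypergeometric tables no more probable than the observed). A table with a
#' zero margin carries no information and returns p = 1 flagged degenerate.
#'
#' @param tab 2x2 matrix of non-negative integer counts (rows: groups,
#'   columns: outcome present/absent).
#' @return A tibble: `p_value`, `test_used` (`"chi-square"`, `"fisher"` or
#'   `"degenerate"`), `degenerate`.
#' @examples
#' assoc_test_2x2(rbind(c(27, 3), c(32, 6)))   # Fisher, p ~ 0.72
#' assoc_test_2x2(rbind(c(19, 11), c(9, 29)))  # chi-square, p ~ 0.001
#' @export
assoc_test_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(identical(dim(tab), c(2L, 2L)), all(tab >= 0),
            all(abs(tab - round(tab)) < 1e-9))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(tibble::tibble(p_value = 1, test_used = "degenerate", degenerate = TRUE))
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5)) {
    p <- stats::fisher.test(tab)$p.value
    test <- "fisher"
  } else {
    p <- stats::chisq.test(tab, correct = FALSE)$p.value
    test <- "chi-square"
  }
  tibble::tibble(p_value = p, test_used = test, degenerate = FALSE)
}

#' Class comparison of sizes, shape and criteria items
#'
#' The descriptive comparison of malignant vs benign lesions: mean +/- SD and
#' rank-sum p for the continuous measurements (long axis, short axis,
#' long-short ratio), and counts/percentages with chi-square-or-Fisher p for
#' the binary indicators (ratio > 0.5, the size cutoffs, each consensus
#' shape, and round-or-oval with ratio > 0.5).
#'
#' @param lesions A lesion tibble.
#' @param consensus A consensus tibble from [consensus_features()].
#' @param long_cutoff_mm,short_cutoff_mm Size cutoffs used for the indicator
#'   rows (defaults 20 and 10).
#' @return A tibble with one row per variable: `variable`, `kind`, per-class
#'   `mean`/`sd` (continuous) or `n`/`pct` (binary), `p_value`, `test_used`.
#' @export
compare_groups <- function(lesions, consensus, long_cutoff_mm = 20, short_cutoff_mm = 10) {
  d <- lesions |>
    long_short_ratio() |>
    dplyr::left_join(consensus, by = "lesion_id")
  pos <- d$diagnosis == "malignant"
  cont_row <- function(name, v) {
    w <- wilcoxon_rank_sum(v[pos], v[!pos])
    tibble::tibble(variable = name, kind = "continuous",
                   malignant_mean = mean(v[pos]), malignant_sd = stats::sd(v[pos]),
                   benign_mean = mean(v[!pos]), benign_sd = stats::sd(v[!pos]),
                   malignant_n = NA_integer_, malignant_pct = NA_real_,
                   benign_n = NA_integer_, benign_pct = NA_real_,
                   p_value = w$p_value, test_used = paste("wilcoxon", w$method))
  }
  bin_row <- function(name, ind) {
    keep <- !is.na(ind)
    tab <- rbind(c(sum(ind[pos & keep]), sum(!ind[pos & keep])),
                 c(sum(ind[!pos & keep]), sum(!ind[!pos & keep])))
    at <- assoc_test_2x2(tab)
    tibble::tibble(variable = name, kind = "binary",
                   malignant_mean = NA_real_, malignant_sd = NA_real_,
                   benign_mean = NA_real_, benign_sd = NA_real_,
                   malignant_n = tab[1, 1], malignant_pct = 100 * tab[1, 1] / sum(tab[1, ]),
                   benign_n = tab[2, 1], benign_pct = 100 * tab[2, 1] / sum(tab[2, ]),
                   p_value = at$p_value, test_used = at$test_used)
  }
  dplyr::bind_rows(
    cont_row("long_axis_mm", d$long_axis_mm),
    cont_row("short_axis_mm", d$short_axis_mm),
    cont_row("long_short_ratio", d$ratio),
    bin_row("ratio_gt_0.5", d$ratio > 0.5),
    bin_row("long_axis_gt_10mm", d$long_axis_mm > 10),
    bin_row(sprintf("long_axis_gt_%gmm", long_cutoff_mm), d$long_axis_mm > long_cutoff_mm),
    bin_row(sprintf("short_axis_gt_%gmm", short_cutoff_mm), d$short_axis_mm > short_cutoff_mm),
    purrr::map_dfr(.vocab$shape, function(s) bin_row(paste0("shape_", s), d$shape == s)),
    bin_row("round_or_oval_ratio_gt_0.5", d$shape_round_or_oval & d$ratio > 0.5)
  )
}
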