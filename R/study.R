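# Published summary statistics of the 68-lesion development cohort
# (30 malignant / 38 benign lymph nodes assessed by 5 expert raters).
# These printed values are reference inputs: the class-conditional feature
# counts, the reported kappas with their verbal assessments, the ROC-derived
# size cutoffs, and the accuracy table of both criteria. They let the
# package's audit identities (count reconstruction, Landis-Koch labelling,
# single-item sensitivities) be recomputed without patient-level data.

#' Reference summary statistics of the 68-lesion development cohort
#'
#' Printed summary statistics of the retrospective EUS-FNA cohort on which
#' the 3-item criteria were developed: 30 malignant and 38 benign lymph
#' nodes, five expert raters.
#'
#' @return A list:
#' \describe{
#'   \item{n_malignant, n_benign}{Cohort composition (30, 38).}
#'   \item{feature_counts}{Tibble of class-conditional 2x2 counts for the
#'     reported binary indicators (`variable`, `malignant_yes`,
#'     `malignant_no`, `benign_yes`, `benign_no`, `p_reported`).}
#'   \item{size_summary}{Tibble of reported mean/SD per class for the long
#'     axis, short axis and long-short ratio.}
#'   \item{kappas}{Tibble of the reported per-feature kappas with their
#'     confidence intervals and verbal assessments.}
#'   \item{cutoffs}{Reported ROC-derived cutoffs (long 19.7 mm, short
#'     10.7 mm) and their clinically used roundings (20, 10).}
#'   \item{accuracy}{Tibble of the reported accuracy table: per
#'     (criteria, rule) the printed sensitivity, specificity, accuracy, PPV
#'     and NPV as percentages.}
#'   \item{auc}{Reported AUCs of the new (0.82) and old (0.52) criteria.}
#' }
#' @examples
#' study_reference()$cutoffs
#' @export
study_reference <- function() {
  list(
    n_malignant = 30L,
    n_benign = 38L,
    feature_counts = tibble::tribble(
      ~variable,                    ~malignant_yes, ~malignant_no, ~benign_yes, ~benign_no, ~p_reported,
      "ratio_gt_0.5",               22L,            8L,            22L,         16L,        0.19,
      "long_axis_gt_10mm",          27L,            3L,            32L,         6L,         0.72,
      "long_axis_gt_20mm",          19L,            11L,           9L,          29L,        0.001,
      "short_axis_gt_10mm",         24L,            6L,            12L,         26L,        0.001,
      "shape_round",                8L,             22L,           4L,          34L,        0.11,
      "shape_oval",                 14L,            16L,           18L,         20L,        0.95,
      "shape_triangle",             0L,             30L,           5L,          33L,        0.06,
      "shape_polygonal",            8L,             22L,           11L,         27L,        0.84,
      "round_or_oval_ratio_gt_0.5", 18L,            12L,           13L,         25L,        0.03
    ),
    size_summary = tibble::tribble(
      ~variable,          ~malignant_mean, ~malignant_sd, ~benign_mean, ~benign_sd,
      "long_axis_mm",     25.3,            11.3,          16.8,         8.1,
      "short_axis_mm",    16.3,            9.6,           9.8,          5.2,
      "long_short_ratio", 0.66,            0.21,          0.59,         0.17
    ),
    kappas = tibble::tribble(
      ~feature,       ~kappa, ~ci_low, ~ci_high, ~assessment,
      "shape",        0.44,   0.34,    0.54,     "moderate",
      "border",       0.22,   0.21,    0.31,     "fair",
      "margin",       -0.02,  -0.07,   0.02,     "less than chance",
      "echogenicity", 0.33,   0.17,    0.38,     "fair",
      "homogeneity",  0.34,   0.26,    0.35,     "fair",
      "hilum",        0.22,   0.11,    0.26,     "fair"
    ),
    cutoffs = tibble::tribble(
      ~axis,   ~youden_cutoff_mm, ~rounded_cutoff_mm,
      "long",  19.7,              20,
      "short", 10.7,              10
    ),
    accuracy = tibble::tribble(
      ~criteria, ~rule,             ~sensitivity, ~specificity, ~accuracy, ~ppv, ~npv,
      "old",     "at least 2 of 4", 83.3,         15.8,         45.6,      43.9, 54.5,
      "old",     "at least 3 of 4", 46.7,         52.6,         50.0,      43.8, 55.6,
      "new",     "at least 2 of 3", 76.7,         71.1,         73.5,      67.6, 79.4,
      "new",     "all 3",           26.7,         97.4,         66.2,      88.9, 62.7
    ),
    auc = c(new = 0.82, old = 0.52)
  )
}

#' Class-conditional criteria-item rates of the development cohort
#'
#' The per-item positivity rates implied by the development cohort's
#' reported class-conditional counts: for the 3-item criteria, long axis
#' > 20 mm (19/30 vs 9/38), short axis > 10 mm (24/30 vs 12/38), and
#' round-or-oval shape with ratio > 0.5 (18/30 vs 13/38); for the 4-item
#' criteria, long axis > 10 mm (27/30 vs 32/38) and round shape (8/30 vs
#' 4/38). The cohort does not report class-conditional rates for clear
#' border or dark echogenicity; consistent with the near-chance AUC it
#' reports for the 4-item criteria, these default to 0.5 in both classes
#' (present but uninformative).
#'
#' @param border_rate,echogenicity_rate Class-shared positivity rates for
#'   the two unreported 4-item criteria items (defaults 0.5).
#' @return A list with matrices `new` (3 x 2) and `old` (4 x 2) of
#'   class-conditional item rates (columns `malignant`, `benign`).
#' @export
study_item_rates <- function(border_rate = 0.5, echogenicity_rate = 0.5) {
  new <- rbind(
    long_axis_gt_20 = c(19 / 30, 9 / 38),
    short_axis_gt_10 = c(24 / 30, 12 / 38),
    round_or_oval_ratio = c(18 / 30, 13 / 38)
  )
  old <- rbind(
    long_axis_gt_10 = c(27 / 30, 32 / 38),
    round = c(8 / 30, 4 / 38),
    clear_border = c(border_rate, border_rate),
    dark_echogenicity = c(echogenicity_rate, echogenicity_rate)
  )
  colnames(new) <- colnames(old) <- c("malignant", "benign")
  list(new = new, old = old)
}

#' Replicated head-to-head comparison of the two criteria
#'
#' Repeatedly simulates cohorts whose class-conditional criteria-item
#' marginals equal the development cohort's reported rates
#' ([study_item_rates()]; 30 malignant / 38 benign per replicate, item
#' indicators drawn as independent class-conditional Bernoullis), scores
#' both criteria as item counts, and compares their AUCs. This isolates the
#' direction of the criteria comparison under the published marginal
#' structure; the moment-based [simulate_cohort()] generator is the
#' complementary tool for full-pipeline experiments.
#'
#' @param n_rep Number of replicate cohorts (default 100).
#' @param seed Integer seed.
#' @param n_pos,n_neg Class sizes per replicate (defaults 30, 38).
#' @param rates Item-rate list as from [study_item_rates()].
#' @return A tibble with one row per replicate: `replicate`, `auc_new`,
#'   `auc_old`, `new_wins`.
#' @examples
#' res <- headtohead_experiment(n_rep = 20, seed = 1)
#' mean(res$new_wins)
#' @export
headtohead_experiment <- function(n_rep = 100, seed = 1, n_pos = 30, n_neg = 38,
                                  rates = study_item_rates()) {
  labels <- rep(c("malignant", "benign"), c(n_pos, n_neg))
  withr::with_seed(as.integer(seed), {
    purrr::map_dfr(seq_len(n_rep), function(i) {
      draw_scores <- function(m) {
        p <- t(m)[labels, , drop = FALSE]
        rowSums(matrix(stats::runif(length(p)), nrow(p)) < p)
      }
      s_new <- draw_scores(rates$new)
      s_old <- draw_scores(rates$old)
      auc_new <- roc_scores(s_new, labels)$auc
      auc_old <- roc_scores(s_old, labels)$auc
      tibble::tibble(replicate = i, auc_new = auc_new, auc_old = auc_old,
                     new_wins = auc_new > auc_old)
    })
  })
}
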