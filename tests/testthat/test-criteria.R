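test_that("Youden cutoff uses midpoints, breaks ties high, and rejects degenerates", {
  yc <- youden_cutoff(c(30, 25, 10, 12),
                      c("malignant", "malignant", "benign", "benign"))
  expect_equal(yc$youden_cutoff, 18.5)  # midpoint convention under perfect separation
  expect_equal(yc$youden_j, 1)

  expect_error(youden_cutoff(rep(7, 6), rep(c("malignant", "benign"), 3)),
               "identical")
  expect_error(youden_cutoff(c(1, 2), c("benign", "benign")), "both classes")
})

test_that("Youden cutoff equals brute-force maximization on random samples", {
  withr::with_seed(71, {
    for (i in 1:25) {
      n <- sample(6:30, 1)
      labels <- sample(c("malignant", "benign"), n, replace = TRUE)
      if (length(unique(labels)) < 2) next
      values <- round(rnorm(n, ifelse(labels == "malignant", 22, 15), 8), 1)
      if (length(unique(values)) < 2) next
      yc <- youden_cutoff(values, labels)
      expect_equal(yc$youden_j, oracle_youden_j(values, labels), tolerance = 1e-12)
    }
  })
})

test_that("population-level Youden cutoff is recovered on a large cohort", {
  # fine-grid oracle over the two truncated long-axis normals
  sim <- simulate_cohort(cohort_config(n_lesions = 10000), seed = 81)
  yc <- youden_cutoff(sim$lesions$long_axis_mm, sim$lesions$diagnosis)
  grid <- seq(5, 60, by = 0.01)
  trunc_cdf <- function(x, mu, sd, lo) {
    (pnorm(x, mu, sd) - pnorm(lo, mu, sd)) / (1 - pnorm(lo, mu, sd))
  }
  j_pop <- (1 - trunc_cdf(grid, 25.3, 11.3, 3)) + trunc_cdf(grid, 16.8, 8.1, 3) - 1
  expect_lt(abs(yc$youden_cutoff - grid[which.max(j_pop)]), 2)
})

test_that("clinical rounding reproduces the 20/10 mm pair and half-up rule", {
  expect_equal(clinical_round(19.7), 20)
  expect_equal(clinical_round(10.7), 10)
  expect_equal(clinical_round(12.5), 15)
  expect_equal(clinical_round(10.7, grid_mm = 1), 11)
  expect_error(clinical_round(10, grid_mm = 0), "positive")
})

test_that("feature selection keeps strictly super-threshold kappas only", {
  ag <- tibble::tibble(
    feature = c("shape", "border", "margin", "echogenicity", "homogeneity", "hilum"),
    kappa = c(0.44, 0.22, -0.02, 0.33, 0.34, 0.22)
  )
  expect_equal(select_features(ag), "shape")
  expect_equal(sort(select_features(ag, 0)),
               sort(setdiff(ag$feature, "margin")))
  expect_equal(select_features(ag[0, ]), character(0))
  expect_equal(select_features(dplyr::mutate(ag, kappa = 0.4)), character(0))
})

make_scored_lesion <- function(long, short, shape, criteria,
                               border = "clear", echogenicity = "dark") {
  les <- tibble::tibble(lesion_id = "L1", location = "abdominal",
                        long_axis_mm = long, short_axis_mm = short,
                        diagnosis = "malignant", subtype = NA_character_)
  cons <- tibble::tibble(lesion_id = "L1", shape = shape, border = border,
                         margin = "regular", echogenicity = echogenicity,
                         homogeneity = "homogeneous", hilum = "present",
                         shape_round_or_oval = shape %in% c("round", "oval"))
  score_lesions(les, cons, criteria)
}

test_that("criteria scoring applies the item rules with strict inequalities", {
  # size items true, shape item false: ratio 12/25 = 0.48 <= 0.5
  s1 <- make_scored_lesion(25, 12, "oval", new_criteria())
  expect_equal(s1$score, 2L)
  expect_false(s1$item_shape)

  s2 <- make_scored_lesion(9, 5, "triangle", new_criteria())
  expect_equal(s2$score, 0L)
  expect_equal(make_scored_lesion(9, 5, "triangle", old_criteria(),
                                  border = "fuzzy", echogenicity = "intermediate")$score, 0L)

  # ratio exactly 0.5 fails the strict shape item
  s3 <- make_scored_lesion(22, 11, "round", new_criteria())
  expect_equal(s3$score, 2L)
  expect_false(s3$item_shape)
  expect_equal(make_scored_lesion(22, 11, "round", new_criteria(strict = FALSE))$score, 3L)

  s4 <- make_scored_lesion(25, 14, "round", old_criteria())
  expect_equal(s4$score, 4L)
  # indeterminate consensus shape: the finding "round" is absent, not missing
  s5 <- make_scored_lesion(25, 14, NA_character_, old_criteria())
  expect_equal(s5$score, 3L)
})

test_that("new-criteria score is monotone where the item structure allows it", {
  # growing the short axis raises both the short-axis item and the ratio, so
  # the score is monotone; growing the long axis is monotone for the two size
  # items but can lower the ratio through 0.5 and drop the shape item, so
  # only the size sub-score is monotone in that direction
  withr::with_seed(83, {
    for (i in 1:30) {
      long <- runif(1, 5, 40)
      short <- runif(1, 0.2, 1) * long
      shape <- sample(c("round", "oval", "triangle", "polygonal"), 1)
      base <- make_scored_lesion(long, short, shape, new_criteria())
      grown_short <- make_scored_lesion(long, min(long, short + runif(1, 0, 10)),
                                        shape, new_criteria())
      expect_gte(grown_short$score, base$score)
      grown_long <- make_scored_lesion(long + runif(1, 0, 20), short, shape,
                                       new_criteria())
      expect_gte(grown_long$item_long_axis + grown_long$item_short_axis,
                 base$item_long_axis + base$item_short_axis)
    }
  })
  # the counterexample that rules out full monotonicity in the long axis
  before <- make_scored_lesion(22, 12, "round", new_criteria())$score
  after <- make_scored_lesion(30, 12, "round", new_criteria())$score
  expect_equal(c(before, after), c(3L, 2L))
})

test_that("Wilcoxon comparison is exact for small untied samples and consistent", {
  w <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(w$p_value, 0.1)  # exhaustive enumeration of C(6,3) rank splits
  expect_equal(w$method, "exact")

  same <- wilcoxon_rank_sum(c(1, 2, 2, 3, 5), c(1, 2, 2, 3, 5))
  expect_gte(same$p_value, 0.99)

  sim <- simulate_cohort(cohort_config(n_lesions = 10000), seed = 91)
  mal <- sim$lesions$long_axis_mm[sim$lesions$diagnosis == "malignant"]
  ben <- sim$lesions$long_axis_mm[sim$lesions$diagnosis == "benign"]
  expect_lt(wilcoxon_rank_sum(mal, ben)$p_value, 1e-10)
})

test_that("2x2 association test picks the reported test and p-values", {
  # long axis > 10 mm by class: expected count 3.97 < 5 -> Fisher, p ~ 0.72
  t1 <- assoc_test_2x2(rbind(c(27, 3), c(32, 6)))
  expect_equal(t1$test_used, "fisher")
  expect_equal(round(t1$p_value, 2), 0.72)

  # triangle shape by class -> Fisher, p ~ 0.06
  t2 <- assoc_test_2x2(rbind(c(0, 30), c(5, 33)))
  expect_equal(t2$test_used, "fisher")
  expect_equal(round(t2$p_value, 2), 0.06)

  # long axis > 20 mm: all expected counts >= 5 -> chi-square, p ~ 0.001
  t3 <- assoc_test_2x2(rbind(c(19, 11), c(9, 29)))
  expect_equal(t3$test_used, "chi-square")
  expect_equal(round(t3$p_value, 3), 0.001)

  z <- assoc_test_2x2(rbind(c(0, 0), c(5, 33)))
  expect_true(z$degenerate)
  expect_equal(z$p_value, 1)
})

test_that("Fisher branch matches hypergeometric enumeration for small tables", {
  withr::with_seed(97, {
    tried <- 0
    while (tried < 20) {
      tab <- matrix(rpois(4, 4), 2)
      if (sum(tab) > 40 || any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
      expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      if (all(expected >= 5)) next
      res <- assoc_test_2x2(tab)
      expect_equal(res$test_used, "fisher")
      expect_equal(res$p_value, oracle_fisher_p(tab), tolerance = 1e-10)
      tried <- tried + 1
    }
  })
})

test_that("group comparison reproduces the reported single-feature tests", {
  # rebuild per-lesion data from the reported class-conditional counts
  ref <- study_reference()
  counts <- ref$feature_counts
  row <- counts[counts$variable == "long_axis_gt_20mm", ]
  scores <- rep(c(1, 0, 1, 0),
                c(row$malignant_yes, row$malignant_no, row$benign_yes, row$benign_no))
  labels <- rep(c("malignant", "benign"),
                c(row$malignant_yes + row$malignant_no, row$benign_yes + row$benign_no))
  tab <- rbind(c(row$malignant_yes, row$malignant_no),
               c(row$benign_yes, row$benign_no))
  expect_equal(round(assoc_test_2x2(tab)$p_value, 3), row$p_reported)
  dm <- diagnostic_metrics(scores, labels, threshold = 1)
  expect_equal(round(100 * dm$sensitivity, 1), 63.3)
})
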