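test_that("ROC handles uninformative, perfect, and hand-counted score patterns", {
  labels4 <- c("malignant", "malignant", "benign", "benign")
  expect_equal(roc_scores(c(1, 1, 1, 1), labels4)$auc, 0.5)
  expect_equal(roc_scores(c(3, 2, 1, 0), labels4)$auc, 1)
  # scores {M:2, M:1, B:1, B:0}: pairwise credit (1 + 0.5 + 1 + 0)/4
  expect_equal(roc_scores(c(2, 1, 1, 0), labels4)$auc, 0.875)
  expect_error(roc_scores(c(1, 2), c("benign", "benign")), "both classes")
})

test_that("ROC curve is monotone and trapezoid AUC equals Mann-Whitney", {
  withr::with_seed(111, {
    for (i in 1:25) {
      n <- sample(6:50, 1)
      labels <- sample(c("malignant", "benign"), n, replace = TRUE)
      if (length(unique(labels)) < 2) next
      scores <- sample(0:4, n, replace = TRUE)
      roc <- roc_scores(scores, labels)
      expect_true(all(diff(roc$points$sensitivity) <= 1e-12))
      expect_true(all(diff(roc$points$specificity) >= -1e-12))
      expect_equal(roc$auc, oracle_auc(scores, labels), tolerance = 1e-12)
    }
  })
})

test_that("DeLong test is symmetric, exact under self-comparison", {
  labels <- rep(c("malignant", "benign"), c(8, 12))
  withr::with_seed(121, {
    a <- sample(0:3, 20, replace = TRUE)
    b <- sample(0:4, 20, replace = TRUE)
  })
  self <- delong_test(a, a, labels)
  expect_true(self$degenerate)
  expect_equal(self$p_value, 1)
  expect_equal(self$delta, 0)

  ab <- delong_test(a, b, labels)
  ba <- delong_test(b, a, labels)
  expect_equal(ab$z, -ba$z)
  expect_equal(ab$p_value, ba$p_value)
})

test_that("DeLong variance agrees with a stratified bootstrap", {
  labels <- rep(c("malignant", "benign"), c(8, 12))
  sa <- c(2, 3, 1, 2, 3, 2, 1, 3, 0, 1, 2, 0, 1, 1, 2, 0, 1, 2, 0, 1)
  sb <- c(1, 2, 2, 3, 1, 2, 0, 2, 1, 0, 2, 1, 1, 2, 1, 0, 2, 1, 1, 0)
  dl <- delong_test(sa, sb, labels)
  ipos <- which(labels == "malignant")
  ineg <- which(labels == "benign")
  deltas <- withr::with_seed(42, vapply(1:4000, function(b) {
    idx <- c(sample(ipos, replace = TRUE), sample(ineg, replace = TRUE))
    d <- delong_test(sa[idx], sb[idx], labels[idx])
    d$auc_a - d$auc_b
  }, numeric(1)))
  expect_lt(abs(var(deltas) - dl$se^2) / dl$se^2, 0.15)
})

test_that("AUC and DeLong agree with the independent pROC implementation", {
  labels <- rep(c("malignant", "benign"), c(10, 14))
  withr::with_seed(131, {
    a <- rnorm(24, ifelse(labels == "malignant", 1, 0))
    b <- rnorm(24, ifelse(labels == "malignant", 0.5, 0))
  })
  ra <- suppressMessages(pROC::roc(labels, a, levels = c("benign", "malignant"),
                                   direction = "<"))
  expect_equal(roc_scores(a, labels)$auc, as.numeric(pROC::auc(ra)))
  rb <- suppressMessages(pROC::roc(labels, b, levels = c("benign", "malignant"),
                                   direction = "<"))
  ref <- suppressMessages(pROC::roc.test(ra, rb, method = "delong", paired = TRUE))
  dl <- delong_test(a, b, labels)
  expect_equal(dl$p_value, as.numeric(ref$p.value), tolerance = 1e-10)
})

test_that("diagnostic metrics reproduce the reported accuracy-table rows", {
  # all 3 items positive: tp 8, fp 1, tn 37, fn 22
  scores <- rep(c(3, 0, 3, 0), c(8, 22, 1, 37))
  labels <- rep(c("malignant", "benign"), c(30, 38))
  dm <- diagnostic_metrics(scores, labels, threshold = 3)
  expect_equal(c(dm$tp, dm$fp, dm$tn, dm$fn), c(8, 1, 37, 22))
  expect_equal(round(c(dm$sensitivity, dm$specificity, dm$accuracy, dm$ppv, dm$npv), 3),
               c(0.267, 0.974, 0.662, 0.889, 0.627))

  # at least 2 of the 4-item criteria: tp 25, fp 32, tn 6, fn 5
  scores2 <- rep(c(2, 0, 2, 0), c(25, 5, 32, 6))
  dm2 <- diagnostic_metrics(scores2, labels, threshold = 2)
  expect_equal(dm2$ppv, 25 / 57)
  expect_equal(dm2$npv, 6 / 11)
})

test_that("metrics with empty denominators are flagged undefined", {
  labels <- rep(c("malignant", "benign"), c(3, 4))
  dm <- diagnostic_metrics(rep(0, 7), labels, threshold = 1)
  expect_true(is.na(dm$ppv))
  expect_match(dm$undefined, "ppv")
  expect_equal(dm$specificity, 1)
})

test_that("PPV and NPV satisfy the Bayes-consistency identity", {
  withr::with_seed(141, {
    for (i in 1:20) {
      n <- sample(20:80, 1)
      labels <- sample(c("malignant", "benign"), n, replace = TRUE)
      if (length(unique(labels)) < 2) next
      scores <- sample(0:3, n, replace = TRUE)
      dm <- diagnostic_metrics(scores, labels, threshold = 2)
      pi_hat <- mean(labels == "malignant")
      denom <- dm$sensitivity * pi_hat + (1 - dm$specificity) * (1 - pi_hat)
      if (!is.na(dm$ppv) && denom > 0) {
        expect_equal(dm$ppv, dm$sensitivity * pi_hat / denom, tolerance = 1e-12)
      }
      expect_equal(dm$tp + dm$fn, sum(labels == "malignant"))
      expect_equal(dm$tn + dm$fp, sum(labels == "benign"))
    }
  })
})

test_that("count reconstruction recovers predictive values from sens/spec", {
  r <- ppv_npv_from_sens_spec(0.267, 0.974, 30, 38)
  expect_equal(c(r$tp, r$fp, r$tn, r$fn), c(8, 1, 37, 22))
  expect_equal(round(c(r$ppv, r$npv), 3), c(0.889, 0.627))

  perfect <- ppv_npv_from_sens_spec(1, 1, 10, 10)
  expect_equal(c(perfect$ppv, perfect$npv), c(1, 1))

  r2 <- ppv_npv_from_sens_spec(0.767, 0.711, 30, 38)
  expect_equal(c(r2$tp, r2$fp, r2$tn, r2$fn), c(23, 11, 27, 7))
  expect_equal(r2$ppv, 23 / 34)
  expect_equal(r2$npv, 27 / 34)
})

test_that("tidiers expose ROC points, AUC summaries, and metric intervals", {
  labels <- rep(c("malignant", "benign"), c(6, 8))
  scores <- rep(c(2, 1, 1, 0), c(4, 2, 3, 5))
  roc <- roc_scores(scores, labels)
  expect_named(glance(roc), c("auc", "auc_low", "auc_high", "n_pos", "n_neg"))
  expect_equal(tidy(roc), roc$points)
  dm <- diagnostic_metrics(scores, labels, 2)
  td <- tidy(dm)
  expect_equal(td$metric, c("sensitivity", "specificity", "accuracy", "ppv", "npv"))
  expect_true(all(td$conf_low <= td$estimate & td$estimate <= td$conf_high))
  dl <- delong_test(scores, rev(scores), labels)
  expect_true(is.numeric(glance(dl)$p_value))
})
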