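# Independent oracles used across the suite. Each re-derives a quantity by a
# different route than the implementation: pairwise-agreement counting for
# kappa, all-pairs counting for the AUC, exhaustive threshold search for the
# Youden cutoff, and hypergeometric enumeration for Fisher's test.

# Kappa by direct pairwise counting over expanded rating vectors: observed
# agreement is the fraction of agreeing rater pairs per lesion; chance
# agreement from the pooled category frequencies.
oracle_kappa <- function(counts) {
  R <- sum(counts[1, ])
  agree <- apply(counts, 1, function(n) {
    pairs <- 0
    for (j in seq_along(n)) pairs <- pairs + choose(n[j], 2)
    pairs / choose(R, 2)
  })
  p <- colSums(counts) / sum(counts)
  pe <- sum(p^2)
  (mean(agree) - pe) / (1 - pe)
}

# AUC by brute force over all (diseased, non-diseased) pairs.
oracle_auc <- function(scores, labels, positive = "malignant") {
  x <- scores[labels == positive]
  y <- scores[labels != positive]
  mean(outer(x, y, `>`) + 0.5 * outer(x, y, `==`))
}

# Best Youden cutoff by exhaustive search over a fine grid spanning the data,
# reporting the maximal J achieved.
oracle_youden_j <- function(values, labels, positive = "malignant") {
  pos <- labels == positive
  cand <- sort(unique(c(values - 1e-9, values + 1e-9,
                        min(values) - 1, max(values) + 1)))
  max(vapply(cand, function(ct) {
    mean(values[pos] > ct) + mean(values[!pos] <= ct) - 1
  }, numeric(1)))
}

# Two-sided Fisher p by hypergeometric enumeration: sum the probabilities of
# all tables with the observed margins that are no more probable than the
# observed one.
oracle_fisher_p <- function(tab) {
  m <- sum(tab[1, ])
  n <- sum(tab[2, ])
  k <- sum(tab[, 1])
  x_obs <- tab[1, 1]
  xs <- max(0, k - n):min(k, m)
  probs <- dhyper(xs, m, n, k)
  p_obs <- dhyper(x_obs, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Small long-format rating table from a per-lesion list of vote vectors for
# one feature.
make_ratings <- function(votes, feature = "shape") {
  purrr::imap_dfr(votes, function(v, i) {
    tibble::tibble(
      lesion_id = sprintf("L%02d", as.integer(i)),
      rater_id = paste0("R", seq_along(v)),
      feature = feature,
      category = v
    )
  })
}

# Binary truth table for a single feature, for noise-model experiments.
make_truth <- function(n, q = 0.5, feature = "border", seed = 1) {
  cats <- euscrit::feature_vocabulary()
  vocab <- cats$category[cats$feature == feature]
  withr::with_seed(seed, tibble::tibble(
    lesion_id = sprintf("L%05d", seq_len(n)),
    feature = feature,
    category = ifelse(stats::runif(n) < q, vocab[1], vocab[2])
  ))
}

# All complete binary count tables with n_lesions rows and R raters.
enumerate_binary_tables <- function(n_lesions, R) {
  rows <- expand.grid(rep(list(0:R), n_lesions))
  lapply(seq_len(nrow(rows)), function(i) {
    n1 <- as.integer(rows[i, ])
    cbind(n1, R - n1)
  })
}
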