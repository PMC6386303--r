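# Multi-rater agreement: Fleiss kappa per feature, percentile-bootstrap
# confidence intervals, Landis-Koch interpretation, and the >=3-of-5
# majority consolidation of ratings into per-lesion consensus features.

#' Fleiss' multi-rater kappa from a lesion-by-category count matrix
#'
#' For N lesions each rated by the same number R of raters into k categories,
#' with `counts[i, j]` the number of raters assigning lesion i to category j:
#' the observed per-lesion agreement is
#' `P_i = (sum_j n_ij^2 - R) / (R (R - 1))` (the fraction of agreeing rater
#' pairs), chance agreement is `P_e = sum_j p_j^2` from the pooled marginals
#' `p_j`, and `kappa = (mean(P_i) - P_e) / (1 - P_e)`.
#'
#' A table in which every rating falls in a single category has `P_e = 1`;
#' kappa is then undefined and an error is raised (an explicit error state,
#' never silently 0, 1 or NaN).
#'
#' @param counts Integer matrix, one row per lesion, one column per category;
#'   all row sums equal and at least 2 rows.
#' @return The kappa value, a scalar in \[-1, 1\].
#' @examples
#' # 3 lesions x 3 raters, binary: counts (3,0), (0,3), (2,1) -> 0.55
#' fleiss_kappa(rbind(c(3, 0), c(0, 3), c(2, 1)))
#' @export
fleiss_kappa <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) >= 2, all(counts >= 0))
  R <- sum(counts[1, ])
  stopifnot(R >= 2, all(abs(rowSums(counts) - R) < 1e-9))
  p_j <- colSums(counts) / (nrow(counts) * R)
  p_e <- sum(p_j^2)
  if (1 - p_e < 1e-12) {
    stop("kappa is undefined: all ratings fall in a single category", call. = FALSE)
  }
  p_i <- (rowSums(counts^2) - R) / (R * (R - 1))
  (mean(p_i) - p_e) / (1 - p_e)
}

# Lesion-by-category count matrix for one feature, complete-case lesions only.
.feature_counts <- function(ratings, feat, raters = NULL) {
  if (is.null(raters)) raters <- unique(ratings$rater_id)
  sub <- ratings[ratings$feature == feat & ratings$rater_id %in% raters, ]
  cc <- complete_cells(sub, raters)
  keep <- cc$lesion_id[cc$complete]
  sub <- sub[sub$lesion_id %in% keep, ]
  if (nrow(sub) == 0) {
    return(matrix(0L, 0, length(.vocab[[feat]]), dimnames = list(NULL, .vocab[[feat]])))
  }
  tab <- table(factor(sub$lesion_id, levels = sort(unique(sub$lesion_id))),
               factor(sub$category, levels = .vocab[[feat]]))
  matrix(as.integer(tab), nrow = nrow(tab), dimnames = dimnames(tab))
}

#' Percentile-bootstrap confidence interval for Fleiss kappa
#'
#' Resamples lesions (rows of the count matrix) with replacement, keeping each
#' lesion's rater panel intact, and returns the percentile interval of kappa
#' over `B` replicates. Resamples for which kappa is undefined (all resampled
#' ratings in one category) are redrawn; if the retry budget is exhausted the
#' interval is returned with `flagged = TRUE`.
#'
#' @param counts Lesion-by-category count matrix (see [fleiss_kappa()]), at
#'   least 5 rows.
#' @param B Number of bootstrap replicates, at least 200 (default 2000).
#' @param level Coverage level (default 0.95).
#' @param seed Integer seed; the same inputs and seed give the same interval.
#' @param max_retries Redraw budget for degenerate resamples (default `10 * B`).
#' @return A list with `ci_low`, `ci_high`, `flagged`.
#' @export
kappa_bootstrap_ci <- function(counts, B = 2000, level = 0.95, seed = 1,
                               max_retries = 10 * B) {
  counts <- as.matrix(counts)
  stopifnot(B >= 200, level > 0, level < 1, nrow(counts) >= 5)
  n <- nrow(counts)
  withr::with_seed(as.integer(seed), {
    kap <- numeric(B)
    retries <- 0L
    b <- 1L
    while (b <= B) {
      idx <- sample.int(n, n, replace = TRUE)
      k <- tryCatch(fleiss_kappa(counts[idx, , drop = FALSE]), error = function(e) NA_real_)
      if (is.na(k)) {
        retries <- retries + 1L
        if (retries > max_retries) break
      } else {
        kap[b] <- k
        b <- b + 1L
      }
    }
    flagged <- b <= B
    kap <- kap[seq_len(b - 1L)]
    alpha <- (1 - level) / 2
    qs <- stats::quantile(kap, c(alpha, 1 - alpha), names = FALSE, na.rm = TRUE)
    list(ci_low = qs[1], ci_high = qs[2], flagged = flagged)
  })
}

#' Per-feature multi-rater agreement table
#'
#' Computes Fleiss kappa, a percentile-bootstrap confidence interval, and the
#' Landis-Koch verbal label for each feature of a rating table, using
#' complete-case lesions only (every rater rated the cell). This is the
#' agreement screen from which criteria items are selected
#' (see [select_features()]).
#'
#' @param ratings A rating tibble (see [read_ratings()]).
#' @param features Features to assess (default: all six).
#' @param B Bootstrap replicates (default 2000); `B = 0` skips the interval.
#' @param level Confidence level (default 0.95).
#' @param seed Integer seed for the bootstrap.
#' @param raters Rater ids defining completeness (default: all observed).
#' @return A tibble of class `eus_agreement` with columns `feature`, `kappa`,
#'   `ci_low`, `ci_high`, `label`, `n_lesions_used`, `undefined` (`TRUE`
#'   where kappa could not be computed).
#' @examples
#' sim <- simulate_cohort(cohort_config(n_lesions = 30), seed = 1)
#' ratings <- simulate_ratings(sim$truth, rater_noise_config(0.2), seed = 2)
#' rate_agreement(ratings, B = 200, seed = 3)
#' @export
rate_agreement <- function(ratings, features = NULL, B = 2000, level = 0.95,
                           seed = 1, raters = NULL) {
  validate_ratings(ratings)
  if (is.null(features)) features <- intersect(.features, unique(ratings$feature))
  if (is.null(raters)) raters <- unique(ratings$rater_id)
  res <- purrr::map_dfr(seq_along(features), function(i) {
    feat <- features[i]
    counts <- .feature_counts(ratings, feat, raters)
    kap <- tryCatch(fleiss_kappa(counts), error = function(e) NA_real_)
    ci <- c(NA_real_, NA_real_)
    if (!is.na(kap) && B > 0 && nrow(counts) >= 5) {
      bs <- kappa_bootstrap_ci(counts, B = B, level = level,
                               seed = as.integer(seed) + i - 1L)
      ci <- c(bs$ci_low, bs$ci_high)
    }
    tibble::tibble(
      feature = feat,
      kappa = kap,
      ci_low = ci[1],
      ci_high = ci[2],
      label = landis_koch(kap),
      n_lesions_used = nrow(counts),
      undefined = is.na(kap)
    )
  })
  class(res) <- c("eus_agreement", class(res))
  res
}

#' Consolidate multi-rater ratings into per-lesion consensus features
#'
#' For each complete-case (lesion, feature) cell, the category receiving at
#' least `min_votes` of the R votes becomes the consensus ("agreed upon by
#' three or more" with the 5-rater default); otherwise the cell is
#' indeterminate (`NA`). With 5 raters this can only happen for the
#' 4-category shape. Because the criteria consume shape only as
#' round-or-oval, shape is additionally binarised per rater (round or oval
#' vs other) and majority-voted, which with an odd rater count always yields
#' a decision, reported in `shape_round_or_oval`.
#'
#' @param ratings A rating tibble (see [read_ratings()]).
#' @param min_votes Minimum votes for consensus (default 3); must not exceed
#'   the rater count.
#' @param raters Rater ids defining completeness (default: all observed).
#' @return A wide tibble: `lesion_id`, one column per feature with the
#'   consensus category (`NA` = indeterminate or incomplete), and the logical
#'   `shape_round_or_oval`.
#' @export
consensus_features <- function(ratings, min_votes = 3, raters = NULL) {
  validate_ratings(ratings)
  if (is.null(raters)) raters <- unique(ratings$rater_id)
  R <- length(raters)
  if (min_votes > R) stop("min_votes (", min_votes, ") exceeds rater count (", R, ")",
                          call. = FALSE)
  sub <- ratings[ratings$rater_id %in% raters, ]
  cc <- complete_cells(sub, raters)
  sub <- dplyr::inner_join(sub, cc[cc$complete, c("lesion_id", "feature")],
                           by = c("lesion_id", "feature"))
  consensus <- sub |>
    dplyr::count(.data$lesion_id, .data$feature, .data$category) |>
    dplyr::group_by(.data$lesion_id, .data$feature) |>
    dplyr::summarise(
      consensus = {
        top <- .data$category[.data$n == max(.data$n)]
        if (max(.data$n) >= min_votes && length(top) == 1) top else NA_character_
      },
      .groups = "drop"
    ) |>
    tidyr::pivot_wider(names_from = "feature", values_from = "consensus")
  shape_bin <- sub |>
    dplyr::filter(.data$feature == "shape") |>
    dplyr::group_by(.data$lesion_id) |>
    dplyr::summarise(
      shape_round_or_oval = sum(.data$category %in% c("round", "oval")) > R / 2,
      .groups = "drop"
    )
  all_lesions <- tibble::tibble(lesion_id = sort(unique(ratings$lesion_id)))
  out <- all_lesions |>
    dplyr::left_join(consensus, by = "lesion_id") |>
    dplyr::left_join(shape_bin, by = "lesion_id")
  for (feat in .features) {
    if (!feat %in% names(out)) out[[feat]] <- NA_character_
  }
  dplyr::select(out, "lesion_id", dplyr::all_of(.features), "shape_round_or_oval") |>
    dplyr::arrange(.data$lesion_id)
}
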