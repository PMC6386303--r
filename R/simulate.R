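# Synthetic cohort and rater-noise generators. These emulate the statistical
# structure of the 68-lesion EUS-FNA study (class-conditional size
# distributions, shape prevalences, 5 expert raters), so that every
# downstream stage -- agreement, cutoff derivation, criteria scoring,
# head-to-head evaluation -- can be exercised without patient-level data.

#' Configuration for the synthetic lesion cohort
#'
#' Defaults reproduce the study conditions: 68 lesions with 30/68 malignant
#' prevalence; class-conditional long-axis normals (malignant 25.3 +/- 11.3 mm,
#' benign 16.8 +/- 8.1 mm) truncated below at 3 mm; long-short ratio normals
#' (malignant 0.66 +/- 0.21, benign 0.59 +/- 0.17) truncated to (0.05, 1];
#' shape prevalences from the study's class-conditional counts (malignant
#' 8/30 round, 14/30 oval, 0 triangle, 8/30 polygonal; benign 4/38, 18/38,
#' 5/38, 11/38). The short axis is derived as long axis times ratio, so axis
#' ordering holds by construction. The class-conditional prevalences of the
#' malignant-looking category for the five binary features are free
#' parameters (the study does not report them); the defaults 0.7 malignant /
#' 0.3 benign encode a generic malignancy signal.
#'
#' @param n_lesions Number of lesions (default 68).
#' @param prevalence_malignant Probability a lesion is malignant (default 30/68).
#' @param long_axis_params List with `malignant` and `benign`, each `c(mean, sd)`
#'   in mm.
#' @param ratio_params List with per-class `c(mean, sd)` of the long-short ratio.
#' @param shape_prevalence List with per-class probability vectors over
#'   (round, oval, triangle, polygonal); each must sum to 1.
#' @param binary_feature_prevalence List with per-class probability of the
#'   malignant-looking category, either a scalar recycled over the five binary
#'   features or a named vector over border/margin/echogenicity/homogeneity/hilum.
#' @param location_prevalence List with per-class probability of a mediastinal
#'   location (defaults 3/30 malignant, 5/38 benign).
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_lesions = 68,
                          prevalence_malignant = 30 / 68,
                          long_axis_params = list(malignant = c(25.3, 11.3),
                                                  benign = c(16.8, 8.1)),
                          ratio_params = list(malignant = c(0.66, 0.21),
                                              benign = c(0.59, 0.17)),
                          shape_prevalence = list(
                            malignant = c(round = 8, oval = 14, triangle = 0, polygonal = 8) / 30,
                            benign = c(round = 4, oval = 18, triangle = 5, polygonal = 11) / 38),
                          binary_feature_prevalence = list(malignant = 0.7, benign = 0.3),
                          location_prevalence = list(malignant = 3 / 30, benign = 5 / 38)) {
  stopifnot(n_lesions >= 1, prevalence_malignant >= 0, prevalence_malignant <= 1)
  bin_feats <- setdiff(.features, "shape")
  cfg <- list(
    n_lesions = as.integer(n_lesions),
    prevalence_malignant = prevalence_malignant,
    long_axis_params = long_axis_params,
    ratio_params = ratio_params,
    shape_prevalence = shape_prevalence,
    binary_feature_prevalence = lapply(binary_feature_prevalence, function(p) {
      if (length(p) == 1) p <- stats::setNames(rep(p, length(bin_feats)), bin_feats)
      stopifnot(setequal(names(p), bin_feats))
      p[bin_feats]
    }),
    location_prevalence = location_prevalence
  )
  for (cls in c("malignant", "benign")) {
    sp <- cfg$shape_prevalence[[cls]]
    stopifnot(length(sp) == 4, abs(sum(sp) - 1) < 1e-9, all(sp >= 0), all(sp <= 1))
    stopifnot(cfg$long_axis_params[[cls]][2] > 0, cfg$ratio_params[[cls]][2] > 0)
    bp <- cfg$binary_feature_prevalence[[cls]]
    stopifnot(all(bp >= 0), all(bp <= 1))
  }
  structure(cfg, class = "cohort_config")
}

#' Configuration for the rater-noise model
#'
#' Each of `n_raters` raters independently reports a lesion's true category
#' with probability `1 - epsilon`, and otherwise a uniformly random different
#' category from the feature's vocabulary (symmetric uniform confusion).
#' `epsilon = 0` forces unanimous, truthful panels. The default
#' `epsilon = 0.25` for every feature places downstream Fleiss kappas in the
#' fair-to-moderate band typical of expert EUS image reading.
#'
#' @param epsilon Per-feature mis-report probability in \[0, 1): a scalar
#'   recycled over the six features or a named vector.
#' @param n_raters Number of raters (default 5).
#' @return An object of class `rater_noise_config`.
#' @export
rater_noise_config <- function(epsilon = 0.25, n_raters = 5) {
  if (length(epsilon) == 1) epsilon <- stats::setNames(rep(epsilon, length(.features)), .features)
  stopifnot(setequal(names(epsilon), .features), all(epsilon >= 0), all(epsilon < 1),
            n_raters >= 1)
  structure(list(epsilon = epsilon[.features], n_raters = as.integer(n_raters)),
            class = "rater_noise_config")
}

# Truncated-normal draws by inverse-CDF; deterministic given the RNG state.
.rtruncnorm <- function(n, mean, sd, lower, upper) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

#' Simulate a lesion cohort with latent true features
#'
#' Draws each lesion's diagnosis, location, long axis (class-conditional
#' truncated normal, lower bound 3 mm), long-short ratio (class-conditional
#' normal truncated to (0.05, 1]), short axis (long axis times ratio), true
#' shape, and true binary-feature categories per [cohort_config()].
#' Reproducible: the same config and seed give identical output.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed for this draw.
#' @return A list with `lesions` (a lesion tibble as from [read_lesions()])
#'   and `truth` (long tibble `lesion_id`, `feature`, `category` of the
#'   latent true categories each rater perturbs).
#' @examples
#' sim <- simulate_cohort(cohort_config(n_lesions = 10), seed = 1)
#' sim$lesions
#' @export
simulate_cohort <- function(config = cohort_config(), seed = 1) {
  stopifnot(inherits(config, "cohort_config"))
  withr::with_seed(as.integer(seed), {
    n <- config$n_lesions
    cls <- ifelse(stats::runif(n) < config$prevalence_malignant, "malignant", "benign")
    draw_by_class <- function(params, lower, upper) {
      out <- numeric(n)
      for (cl in c("malignant", "benign")) {
        idx <- cls == cl
        out[idx] <- .rtruncnorm(sum(idx), params[[cl]][1], params[[cl]][2], lower, upper)
      }
      out
    }
    long_axis <- draw_by_class(config$long_axis_params, 3, Inf)
    ratio <- draw_by_class(config$ratio_params, 0.05, 1)
    loc_p <- unname(unlist(config$location_prevalence)[cls])
    location <- ifelse(stats::runif(n) < loc_p, "mediastinal", "abdominal")
    shapes <- character(n)
    for (cl in c("malignant", "benign")) {
      idx <- which(cls == cl)
      sp <- config$shape_prevalence[[cl]]
      shapes[idx] <- sample(names(sp), length(idx), replace = TRUE, prob = sp)
    }
    lesions <- tibble::tibble(
      lesion_id = sprintf("L%04d", seq_len(n)),
      location = location,
      long_axis_mm = long_axis,
      short_axis_mm = long_axis * ratio,
      diagnosis = cls,
      subtype = NA_character_
    )
    bin_feats <- setdiff(.features, "shape")
    truth_bin <- purrr::map_dfr(bin_feats, function(feat) {
      p <- unname(vapply(config$binary_feature_prevalence,
                         function(v) v[[feat]], numeric(1))[cls])
      mal_cat <- .malignant_like[[feat]]
      ben_cat <- setdiff(.vocab[[feat]], mal_cat)
      tibble::tibble(
        lesion_id = lesions$lesion_id,
        feature = feat,
        category = ifelse(stats::runif(n) < p, mal_cat, ben_cat)
      )
    })
    truth <- dplyr::bind_rows(
      tibble::tibble(lesion_id = lesions$lesion_id, feature = "shape", category = shapes),
      truth_bin
    ) |>
      dplyr::arrange(.data$lesion_id, factor(.data$feature, levels = .features))
    list(lesions = lesions, truth = truth)
  })
}

#' Simulate a multi-rater rating table from latent true features
#'
#' Applies the symmetric uniform-confusion noise model of
#' [rater_noise_config()] independently per rater and feature: with
#' probability `1 - epsilon` the rater reports the true category, otherwise a
#' uniformly random different category from that feature's vocabulary.
#'
#' @param truth Long tibble `lesion_id`, `feature`, `category` (from
#'   [simulate_cohort()]).
#' @param noise A [rater_noise_config()].
#' @param seed Integer seed, independent of the cohort seed so agreement
#'   experiments can vary noise on a fixed cohort.
#' @return A rating tibble (`lesion_id`, `rater_id`, `feature`, `category`)
#'   with one row per (lesion, rater, feature).
#' @export
simulate_ratings <- function(truth, noise = rater_noise_config(), seed = 1) {
  stopifnot(inherits(noise, "rater_noise_config"),
            all(c("lesion_id", "feature", "category") %in% names(truth)))
  withr::with_seed(as.integer(seed), {
    raters <- paste0("R", seq_len(noise$n_raters))
    out <- tidyr::expand_grid(truth, rater_id = raters)
    eps <- noise$epsilon[out$feature]
    flip <- stats::runif(nrow(out)) < eps
    reported <- out$category
    if (any(flip)) {
      reported[flip] <- vapply(which(flip), function(i) {
        others <- setdiff(.vocab[[out$feature[i]]], out$category[i])
        others[sample.int(length(others), 1)]
      }, character(1))
    }
    tibble::tibble(
      lesion_id = out$lesion_id,
      rater_id = out$rater_id,
      feature = out$feature,
      category = reported
    ) |>
      dplyr::arrange(.data$lesion_id, .data$rater_id,
                     factor(.data$feature, levels = .features))
  })
}

#' Expected Fleiss kappa under the uniform-confusion noise model
#'
#' Closed-form long-run kappa for a single feature with `k` categories, true
#' category mix `q`, and per-rater mis-report probability `epsilon`: two
#' raters agree with probability `(1-eps)^2 + eps^2/(k-1)` plus, for non-equal
#' true mixes, the between-category terms; the reported marginal for category
#' j is `q_j (1-eps) + (1-q_j) eps/(k-1)`. Used as the analytic oracle for
#' parameter-recovery checks of the agreement stage.
#'
#' @param q Probability vector of true categories (sums to 1).
#' @param epsilon Mis-report probability in \[0, 1).
#' @return The population Fleiss kappa implied by the model.
#' @export
kappa_uniform_confusion <- function(q, epsilon) {
  stopifnot(abs(sum(q) - 1) < 1e-9, epsilon >= 0, epsilon < 1)
  k <- length(q)
  stopifnot(k >= 2)
  # reported-category distribution for a lesion with true category t:
  # P(report j | t) = (1-eps) if j == t else eps/(k-1)
  p_cond <- function(t) {
    p <- rep(epsilon / (k - 1), k)
    p[t] <- 1 - epsilon
    p
  }
  p_agree <- sum(vapply(seq_len(k), function(t) q[t] * sum(p_cond(t)^2), numeric(1)))
  marg <- Reduce(`+`, lapply(seq_len(k), function(t) q[t] * p_cond(t)))
  p_e <- sum(marg^2)
  (p_agree - p_e) / (1 - p_e)
}
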