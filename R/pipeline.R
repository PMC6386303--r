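# End-to-end pipeline: simulate (or read) -> agreement screen -> consensus ->
# cutoff derivation -> criteria scoring -> head-to-head evaluation -> report.

#' Pipeline configuration
#'
#' Bundles the inputs and tuning parameters of a full criteria-development
#' run. Either supply paths to a lesion and a rating CSV, or leave them
#' `NULL` to simulate a cohort from `cohort` and `noise`. All randomness
#' (cohort, raters, bootstrap) is derived from `seed`.
#'
#' @param lesions_path,ratings_path Optional CSV paths (see [read_lesions()],
#'   [read_ratings()]); both or neither.
#' @param cohort A [cohort_config()] used when simulating.
#' @param noise A [rater_noise_config()] used when simulating.
#' @param bootstrap_B Bootstrap replicates for kappa intervals (default 2000).
#' @param kappa_threshold Agreement threshold for feature selection (default 0.4).
#' @param grid_mm Clinical rounding grid for size cutoffs (default 5).
#' @param strict Strict `>` comparisons in the criteria (default `TRUE`).
#' @param ci_level Confidence level for all intervals (default 0.95).
#' @param min_votes Votes required for consensus (default 3).
#' @param seed Master seed (integer).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(lesions_path = NULL, ratings_path = NULL,
                            cohort = cohort_config(), noise = rater_noise_config(),
                            bootstrap_B = 2000, kappa_threshold = 0.4, grid_mm = 5,
                            strict = TRUE, ci_level = 0.95, min_votes = 3, seed = 1) {
  if (xor(is.null(lesions_path), is.null(ratings_path))) {
    stop("supply both lesions_path and ratings_path, or neither", call. = FALSE)
  }
  structure(list(lesions_path = lesions_path, ratings_path = ratings_path,
                 cohort = cohort, noise = noise, bootstrap_B = bootstrap_B,
                 kappa_threshold = kappa_threshold, grid_mm = grid_mm,
                 strict = strict, ci_level = ci_level, min_votes = min_votes,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full criteria-development pipeline
#'
#' Executes the complete analysis: obtain lesions and ratings (from disk or
#' the synthetic generators), screen features by Fleiss kappa with bootstrap
#' intervals, consolidate ratings by majority vote, derive Youden size
#' cutoffs with clinical rounding, assemble the 3-item criteria from the
#' rounded cutoffs (the historical 4-item criteria are fixed), score every
#' lesion under both, run the class comparisons, and evaluate head-to-head
#' (ROC, DeLong paired AUC test, accuracy table). Deterministic given the
#' config seed.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory: if given, `lesions.csv`, `ratings.csv`
#'   and `report.json` are written there.
#' @return An object of class `eus_report`: a named list with elements
#'   `run` (config echo, seed, package version, schema version), `lesions`,
#'   `ratings`, `agreement`, `selected_features`, `consensus`, `cutoffs`,
#'   `group_comparison`, `scores`, `performance`, `roc_new`, `roc_old`,
#'   `delong`.
#' @examples
#' rep <- run_pipeline(pipeline_config(bootstrap_B = 200, seed = 7))
#' rep$delong
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed
  if (is.null(config$lesions_path)) {
    sim <- simulate_cohort(config$cohort, seed = seed)
    lesions <- sim$lesions
    ratings <- simulate_ratings(sim$truth, config$noise, seed = seed + 1L)
  } else {
    lesions <- read_lesions(config$lesions_path)
    ratings <- read_ratings(config$ratings_path)
  }
  agreement <- rate_agreement(ratings, B = config$bootstrap_B,
                              level = config$ci_level, seed = seed + 2L)
  selected <- select_features(agreement, config$kappa_threshold)
  consensus <- consensus_features(ratings, min_votes = config$min_votes)
  cutoffs <- derive_cutoffs(lesions, grid_mm = config$grid_mm)
  crit_new <- new_criteria(
    long_cutoff_mm = cutoffs$rounded_cutoff_mm[cutoffs$axis == "long"],
    short_cutoff_mm = cutoffs$rounded_cutoff_mm[cutoffs$axis == "short"],
    strict = config$strict
  )
  crit_old <- old_criteria(strict = config$strict)
  scores_new <- score_lesions(lesions, consensus, crit_new)
  scores_old <- score_lesions(lesions, consensus, crit_old)
  comparison <- compare_groups(lesions, consensus,
                               long_cutoff_mm = cutoffs$rounded_cutoff_mm[cutoffs$axis == "long"],
                               short_cutoff_mm = cutoffs$rounded_cutoff_mm[cutoffs$axis == "short"])
  labels <- lesions$diagnosis
  roc_new <- roc_scores(scores_new$score, labels, level = config$ci_level)
  roc_old <- roc_scores(scores_old$score, labels, level = config$ci_level)
  delong <- delong_test(scores_new$score, scores_old$score, labels)
  perf <- performance_table(scores_new$score, scores_old$score, labels,
                            level = config$ci_level)
  report <- structure(list(
    run = list(schema_version = "1.0",
               package_version = as.character(utils::packageVersion("euscrit")),
               seed = seed,
               simulated = is.null(config$lesions_path),
               bootstrap_B = config$bootstrap_B,
               kappa_threshold = config$kappa_threshold,
               grid_mm = config$grid_mm,
               strict = config$strict,
               ci_level = config$ci_level,
               min_votes = config$min_votes),
    lesions = lesions,
    ratings = ratings,
    agreement = agreement,
    selected_features = selected,
    consensus = consensus,
    cutoffs = cutoffs,
    group_comparison = comparison,
    scores = dplyr::bind_rows(scores_new, scores_old),
    performance = perf,
    roc_new = roc_new,
    roc_old = roc_old,
    delong = delong
  ), class = "eus_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.eus_report <- function(x, ...) {
  cat("EUS criteria-development report (seed ", x$run$seed, ")\n", sep = "")
  cat("Agreement screen:\n")
  print(tibble::as_tibble(x$agreement))
  cat("Selected features (kappa > threshold):",
      if (length(x$selected_features)) paste(x$selected_features, collapse = ", ") else "none", "\n")
  cat("Size cutoffs:\n")
  print(x$cutoffs)
  print(x$roc_new)
  print(x$roc_old)
  print(x$delong)
  invisible(x)
}

#' Write a report bundle to disk
#'
#' Writes `lesions.csv`, `ratings.csv` and a machine-readable `report.json`
#' (agreement table, selected features, cutoffs, group comparison,
#' performance table, ROC points, DeLong comparison, and the run record with
#' a schema version). Byte-identical for identical reports.
#'
#' @param report An `eus_report` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "eus_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_lesions(report$lesions, file.path(dir, "lesions.csv"))
  write_ratings(report$ratings, file.path(dir, "ratings.csv"))
  payload <- list(
    run = report$run,
    agreement = tibble::as_tibble(report$agreement),
    selected_features = report$selected_features,
    cutoffs = report$cutoffs,
    group_comparison = report$group_comparison,
    performance = tibble::as_tibble(report$performance),
    roc = list(
      # the infinite-threshold endpoints (0,0)/(1,1) are implicit in JSON
      new = list(points = report$roc_new$points[is.finite(report$roc_new$points$threshold), ],
                 auc = report$roc_new$auc, auc_ci = report$roc_new$auc_ci),
      old = list(points = report$roc_old$points[is.finite(report$roc_old$points$threshold), ],
                 auc = report$roc_old$auc, auc_ci = report$roc_old$auc_ci)
    ),
    delong = unclass(report$delong)
  )
  jsonlite::write_json(payload, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
  invisible(dir)
}
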