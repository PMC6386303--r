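# Readers and writers for the two input tables and basic per-lesion geometry.

.lesion_cols <- c("lesion_id", "location", "long_axis_mm", "short_axis_mm",
                  "diagnosis", "subtype")
.rating_cols <- c("lesion_id", "rater_id", "feature", "category")

#' Read a lesion table
#'
#' Reads a CSV with one row per lymph node: `lesion_id`, `location`
#' (mediastinal/abdominal), `long_axis_mm`, `short_axis_mm`, `diagnosis`
#' (malignant/benign), and an optional free-text `subtype`. Labels are
#' case-insensitive on input and canonicalised to lower case. Rows whose axes
#' arrive in the wrong order (short > long) are swapped with a warning rather
#' than rejected, because axis measurements are human-entered.
#'
#' @param path Path to a CSV file with a header row.
#' @return A tibble with the columns above, axes ordered so that
#'   `short_axis_mm <= long_axis_mm`.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("lesion_id,location,long_axis_mm,short_axis_mm,diagnosis,subtype",
#'              "L1,abdominal,25.0,12.0,malignant,"), f)
#' read_lesions(f)
#' @export
read_lesions <- function(path) {
  stopifnot(file.exists(path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  missing <- setdiff(setdiff(.lesion_cols, "subtype"), names(raw))
  if (length(missing) > 0) {
    stop("lesion table is missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!"subtype" %in% names(raw)) raw$subtype <- NA_character_
  if (nrow(raw) == 0) {
    return(tibble::tibble(lesion_id = character(), location = character(),
                          long_axis_mm = double(), short_axis_mm = double(),
                          diagnosis = character(), subtype = character()))
  }
  out <- raw |>
    dplyr::mutate(
      location = tolower(trimws(.data$location)),
      diagnosis = tolower(trimws(.data$diagnosis)),
      long_axis_mm = .parse_axis(.data$long_axis_mm, .data$lesion_id, "long_axis_mm"),
      short_axis_mm = .parse_axis(.data$short_axis_mm, .data$lesion_id, "short_axis_mm")
    ) |>
    dplyr::select(dplyr::all_of(.lesion_cols))
  bad_diag <- setdiff(unique(out$diagnosis), c("malignant", "benign"))
  if (length(bad_diag) > 0) {
    stop("unknown diagnosis label(s): ", paste(bad_diag, collapse = ", "), call. = FALSE)
  }
  bad_loc <- setdiff(unique(out$location), c("mediastinal", "abdominal"))
  if (length(bad_loc) > 0) {
    stop("unknown location label(s): ", paste(bad_loc, collapse = ", "), call. = FALSE)
  }
  if (any(out$long_axis_mm <= 0) || any(out$short_axis_mm <= 0)) {
    bad <- out$lesion_id[out$long_axis_mm <= 0 | out$short_axis_mm <= 0]
    stop("non-positive axis for lesion(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  swap <- out$short_axis_mm > out$long_axis_mm
  if (any(swap)) {
    warning(sum(swap), " lesion(s) had short axis > long axis; axes swapped: ",
            paste(out$lesion_id[swap], collapse = ", "), call. = FALSE)
    tmp <- out$long_axis_mm[swap]
    out$long_axis_mm[swap] <- out$short_axis_mm[swap]
    out$short_axis_mm[swap] <- tmp
  }
  tibble::as_tibble(out)
}

.parse_axis <- function(x, lesion_id, col) {
  val <- suppressWarnings(as.numeric(x))
  bad <- is.na(val) & !is.na(x) & trimws(x) != ""
  if (any(bad)) {
    stop("non-numeric ", col, " for lesion(s): ", paste(lesion_id[bad], collapse = ", "),
         call. = FALSE)
  }
  if (any(is.na(val))) {
    stop("missing ", col, " for lesion(s): ",
         paste(lesion_id[is.na(val)], collapse = ", "), call. = FALSE)
  }
  val
}

#' Read a long-format rating table
#'
#' Reads a CSV with one row per (lesion, rater, feature) categorical
#' assessment: `lesion_id`, `rater_id`, `feature`, `category`. Every category
#' is validated against [feature_vocabulary()]; duplicate
#' (lesion, rater, feature) keys are an error. Cells for which not every
#' rater supplied a rating are retained but treated as incomplete by the
#' agreement and consensus stages (see [complete_cells()]).
#'
#' @param path Path to a CSV file with a header row.
#' @return A tibble with the four columns above, labels lower-cased.
#' @export
read_ratings <- function(path) {
  stopifnot(file.exists(path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  missing <- setdiff(.rating_cols, names(raw))
  if (length(missing) > 0) {
    stop("rating table is missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  out <- raw |>
    dplyr::mutate(feature = tolower(trimws(.data$feature)),
                  category = tolower(trimws(.data$category))) |>
    dplyr::select(dplyr::all_of(.rating_cols)) |>
    tibble::as_tibble()
  validate_ratings(out)
  out
}

#' Validate a rating table against the feature vocabulary
#'
#' Checks uniqueness of (lesion, rater, feature) keys and membership of every
#' category in its feature's vocabulary. Called by [read_ratings()]; exported
#' so programmatically built tables can be checked too.
#'
#' @param ratings A tibble with columns `lesion_id`, `rater_id`, `feature`,
#'   `category`.
#' @return `ratings`, invisibly, if valid; otherwise an error.
#' @export
validate_ratings <- function(ratings) {
  stopifnot(all(.rating_cols %in% names(ratings)))
  dup <- ratings |>
    dplyr::count(.data$lesion_id, .data$rater_id, .data$feature) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    keys <- paste0("(", dup$lesion_id, ", ", dup$rater_id, ", ", dup$feature, ")")
    stop("duplicate rating key(s): ", paste(keys, collapse = "; "), call. = FALSE)
  }
  bad_feat <- setdiff(unique(ratings$feature), .features)
  if (length(bad_feat) > 0) {
    stop("unknown feature(s): ", paste(bad_feat, collapse = ", "), call. = FALSE)
  }
  for (feat in unique(ratings$feature)) {
    cats <- unique(ratings$category[ratings$feature == feat])
    bad <- setdiff(cats, .vocab[[feat]])
    if (length(bad) > 0) {
      stop("feature '", feat, "' has unknown category label(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  invisible(ratings)
}

#' Flag complete-case (lesion, feature) cells
#'
#' A (lesion, feature) cell is usable for agreement statistics and majority
#' consolidation only if all raters rated it. Raters default to every
#' `rater_id` present anywhere in the table.
#'
#' @param ratings A rating tibble (see [read_ratings()]).
#' @param raters Character vector of rater ids; defaults to all observed.
#' @return A tibble with `lesion_id`, `feature`, `n_raters`, `complete`.
#' @export
complete_cells <- function(ratings, raters = NULL) {
  if (is.null(raters)) raters <- unique(ratings$rater_id)
  ratings |>
    dplyr::filter(.data$rater_id %in% raters) |>
    dplyr::count(.data$lesion_id, .data$feature, name = "n_raters") |>
    dplyr::mutate(complete = .data$n_raters == length(raters))
}

#' Write lesion and rating tables
#'
#' Plain-CSV writers matching [read_lesions()] / [read_ratings()]; a
#' write-then-read round trip reproduces all fields.
#'
#' @param x A lesion or rating tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_lesions <- function(x, path) {
  readr::write_csv(x[.lesion_cols], path, progress = FALSE)
  invisible(path)
}

#' @rdname write_lesions
#' @export
write_ratings <- function(x, path) {
  readr::write_csv(x[.rating_cols], path, progress = FALSE)
  invisible(path)
}

#' Long-short ratio of a lymph node
#'
#' The ratio of the short to the long axis: 1 is perfectly round, values near
#' 0 are elongated. With axes ordered at read time the ratio lies in (0, 1].
#' Rounder nodes (ratio > 0.5) are a malignant sign when combined with a
#' round or oval consensus shape.
#'
#' @param lesions A lesion tibble (see [read_lesions()]).
#' @return The tibble with a `ratio` column appended.
#' @examples
#' tibble::tibble(lesion_id = "L1", long_axis_mm = 20, short_axis_mm = 10) |>
#'   long_short_ratio()
#' @export
long_short_ratio <- function(lesions) {
  stopifnot(all(c("long_axis_mm", "short_axis_mm") %in% names(lesions)),
            all(lesions$long_axis_mm > 0), all(lesions$short_axis_mm > 0))
  dplyr::mutate(lesions, ratio = .data$short_axis_mm / .data$long_axis_mm)
}
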