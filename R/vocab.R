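# Category vocabularies for the six EUS features of a lymph node.

.features <- c("shape", "border", "margin", "echogenicity", "homogeneity", "hilum")

.vocab <- list(
  shape        = c("round", "oval", "triangle", "polygonal"),
  border       = c("clear", "fuzzy"),
  margin       = c("regular", "irregular"),
  echogenicity = c("dark", "intermediate"),
  homogeneity  = c("homogeneous", "heterogeneous"),
  hilum        = c("present", "absent")
)

# For the binary features, the category conventionally read as a sign of
# malignancy: a sharply demarcated (clear) border, an irregular margin, dark
# (hypoechoic) internal echo, heterogeneous echotexture, and loss of the
# hyperechoic hilum. Shape is handled separately (round/oval vs other).
.malignant_like <- c(
  border       = "clear",
  margin       = "irregular",
  echogenicity = "dark",
  homogeneity  = "heterogeneous",
  hilum        = "absent"
)

#' Feature vocabulary for EUS lymph-node assessment
#'
#' The six categorical EUS features rated for each lymph node and their
#' admissible categories: shape (round, oval, triangle, polygonal), border
#' (clear, fuzzy), margin (regular, irregular), echogenicity (dark,
#' intermediate), homogeneity (homogeneous, heterogeneous), and hilum
#' (present, absent -- a linear or band-shaped hyperechoic internal
#' structure). All labels are canonical lower-case.
#'
#' @return A tibble with columns `feature`, `category`, and `malignant_like`
#'   (`TRUE` for the binary-feature category conventionally read as a
#'   malignant sign; `NA` for shape, which enters the criteria as
#'   round-or-oval combined with the long-short ratio).
#' @examples
#' feature_vocabulary()
#' @export
feature_vocabulary <- function() {
  purrr::imap_dfr(.vocab, function(cats, feat) {
    tibble::tibble(
      feature = feat,
      category = cats,
      malignant_like = if (feat == "shape") NA else cats == .malignant_like[[feat]]
    )
  })
}

#' Landis-Koch verbal interpretation of a kappa value
#'
#' Maps chance-corrected agreement coefficients onto the conventional verbal
#' bands: below 0 "less than chance", (0, 0.20] "slight", (0.20, 0.40]
#' "fair", (0.40, 0.60] "moderate", (0.60, 0.80] "substantial", and above
#' 0.80 "almost perfect". Exactly 0 is labelled "slight" (agreement no better
#' than chance but not below it).
#'
#' @param kappa Numeric vector of kappa values in \[-1, 1\].
#' @return Character vector of labels, same length as `kappa`.
#' @examples
#' landis_koch(c(0.44, 0.33, -0.02))
#' @export
landis_koch <- function(kappa) {
  stopifnot(is.numeric(kappa), all(is.na(kappa) | (kappa >= -1 & kappa <= 1)))
  dplyr::case_when(
    is.na(kappa) ~ NA_character_,
    kappa < 0 ~ "less than chance",
    kappa <= 0.20 ~ "slight",
    kappa <= 0.40 ~ "fair",
    kappa <= 0.60 ~ "moderate",
    kappa <= 0.80 ~ "substantial",
    TRUE ~ "almost perfect"
  )
}
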