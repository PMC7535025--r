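#' Asset-based wealth index with quintiles
#'
#' The classic survey wealth index: asset indicators are standardised to zero
#' mean and unit variance, the household score is the projection onto the
#' first principal component (sign-oriented so the indicator with the largest
#' absolute loading loads positively), and households are cut into five
#' quintiles at the 20/40/60/80 rank percentiles (ties broken by first
#' occurrence), so quintile sizes differ by at most one.
#'
#' @param data A data frame; asset columns are selected with `cols`.
#' @param cols Tidy-selection of asset indicator columns (default: columns
#'   starting with `"asset_"`).
#' @return The input with `wealth_score` and integer `wealth_quintile` (1 =
#'   poorest) appended; a `wealth_index` attribute carries the loadings and
#'   the fraction of variance explained by the first component.
#' @export
wealth_index <- function(data, cols = dplyr::starts_with("asset_")) {
  data <- as_tibble(data)
  X <- as.matrix(dplyr::select(data, {{ cols }}))
  if (ncol(X) < 2) abort("need at least two asset indicators")
  sds <- apply(X, 2, stats::sd)
  drop <- which(sds == 0)
  if (length(drop) == ncol(X)) abort("all asset indicators are constant")
  if (length(drop)) {
    warn(paste("dropping zero-variance indicator(s):",
               paste(colnames(X)[drop], collapse = ", ")))
    X <- X[, -drop, drop = FALSE]
  }
  if (ncol(X) < 2) abort("need at least two non-constant asset indicators")
  pca <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  loading <- pca$rotation[, 1L]
  if (loading[which.max(abs(loading))] < 0) loading <- -loading
  score <- scale(X) %*% loading
  score <- as.numeric(score)
  # first-occurrence tie-breaking keeps quintile sizes within one of each
  # other even when many households share an asset profile (and a score)
  rk <- rank(score, ties.method = "first")
  quintile <- as.integer(ceiling(5 * rk / length(rk)))
  out <- dplyr::mutate(data, wealth_score = score, wealth_quintile = quintile)
  attr(out, "wealth_index") <- list(
    loadings = loading,
    explained_variance_fraction = pca$sdev[1L]^2 / sum(pca$sdev^2)
  )
  out
}

#' Recode model covariates at the published cuts
#'
#' Binary indicators used in the anemia determinant models: MUAC below 22 cm,
#' maternal age at or below 21 years, gravidity 1-3 (reference 4-8),
#' illiteracy, plasma zinc below 10.7 umol/L, TfR below the 8.3 mg/L
#' functional-deficit cutoff (reference: at/above), and AGP at/below 1 g/L
#' (reference: above, i.e. chronic inflammation).
#'
#' @param data Cohort data frame with `muac`, `age`, `gravidity`, `education`,
#'   `zinc` columns; `tfr` (or `tfr_adj`) and `agp` are used when present.
#' @inheritParams classify_anemia
#' @return The input with integer indicator columns `muac_low`, `age_young`,
#'   `gravidity_low`, `illiterate`, `zinc_low`, and (when available)
#'   `tfr_low`, `agp_normal` appended.
#' @export
recode_covariates <- function(data, cutoffs = status_cutoffs()) {
  out <- dplyr::mutate(
    as_tibble(data),
    muac_low = as.integer(.data$muac < 22),
    age_young = as.integer(.data$age <= 21),
    gravidity_low = as.integer(.data$gravidity <= 3),
    illiterate = as.integer(.data$education == "illiterate"),
    zinc_low = as.integer(.data$zinc < cutoffs$zinc_inadequate)
  )
  tfr <- out[["tfr_adj"]] %||% out[["tfr"]]
  if (!is.null(tfr)) {
    out$tfr_low <- as.integer(tfr < cutoffs$tfr_functional_deficit)
  }
  if (!is.null(out[["agp"]])) {
    out$agp_normal <- as.integer(out$agp <= cutoffs$agp_chronic)
  }
  out
}
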