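#' Cohort specification
#'
#' Bundles everything [generate_cohort()] needs: the anchored biomarker
#' marginals, the copula correlation targets, categorical field probabilities,
#' anthropometry moments, the site altitude, asset-indicator probabilities and
#' an optional effects hook linking socio-demographic fields to hemoglobin.
#'
#' @param n Number of women to generate (>= 1).
#' @param seed Integer seed; the generator is fully deterministic given
#'   (spec, seed).
#' @param marginals Named list of [quantile_marginal()] objects.
#' @param copula A [copula_spec()] over (a subset of) the marginal names.
#' @param categorical_probs Named list of named probability vectors, each
#'   summing to 1 (education, hfias_category, age_band, household_size_band,
#'   children_band).
#' @param anthropometry Named list of `c(mean, sd)` pairs for `muac` (cm) and
#'   `bmi` (kg/m^2).
#' @param altitude_m Site altitude in metres (constant per cohort).
#' @param asset_probs Named vector of Bernoulli probabilities for the binary
#'   household asset indicators.
#' @param effects Optional [cohort_effects()] hook; `NULL` means
#'   socio-demographic fields are independent of the biomarkers.
#' @param hb_altitude_adjusted Generate hemoglobin on the altitude-adjusted
#'   scale (the scale published summaries are reported on)? If `FALSE` the
#'   altitude correction term is added back so records carry field-measured Hb.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n, seed = 1L,
                        marginals = default_marginals(),
                        copula = default_copula(),
                        categorical_probs = default_categorical_probs(),
                        anthropometry = list(muac = c(24.4, 2.4), bmi = c(20.7, 2.3)),
                        altitude_m = 1700,
                        asset_probs = default_asset_probs(),
                        effects = NULL,
                        hb_altitude_adjusted = TRUE) {
  if (!is.numeric(n) || length(n) != 1L || n < 1) abort("`n` must be >= 1")
  for (nm in names(categorical_probs)) {
    p <- categorical_probs[[nm]]
    if (abs(sum(p) - 1) > 1e-9) {
      abort(sprintf("categorical probabilities for '%s' sum to %.12f, not 1", nm, sum(p)))
    }
    if (any(p < 0)) abort(sprintf("negative probability in '%s'", nm))
  }
  missing <- setdiff(copula$variables, names(marginals))
  if (length(missing)) abort(paste("copula names variables without marginals:", paste(missing, collapse = ", ")))
  structure(
    list(
      n = as.integer(n), seed = as.integer(seed), marginals = marginals,
      copula = copula, categorical_probs = categorical_probs,
      anthropometry = anthropometry, altitude_m = altitude_m,
      asset_probs = asset_probs, effects = effects,
      hb_altitude_adjusted = isTRUE(hb_altitude_adjusted)
    ),
    class = "cohort_spec"
  )
}

#' Effects hook: socio-demographic shifts on hemoglobin
#'
#' By default the generator samples socio-demographic fields independently of
#' the biomarkers. Turning the hook on subtracts the given amounts (g/L) from
#' the hemoglobin of women with MUAC below 22 cm and of illiterate women, so
#' downstream logistic models have recoverable signal on those factors.
#'
#' @param muac_low_hb Shift (g/L, typically negative) applied when MUAC < 22 cm.
#' @param illiterate_hb Shift (g/L) applied to illiterate women.
#' @export
cohort_effects <- function(muac_low_hb = -6, illiterate_hb = -4) {
  structure(list(muac_low_hb = muac_low_hb, illiterate_hb = illiterate_hb),
            class = "cohort_effects")
}

#' Default biomarker marginals
#'
#' Anchors encode the published cohort summaries: medians and IQRs for each
#' biomarker plus every printed prevalence/threshold pair (anemia cutoffs on
#' hemoglobin, the transferrin-receptor functional-deficit cutoff, the CRP and
#' AGP inflammation cutoffs, the zinc inadequacy cutoff, the ferritin overload
#' cutoff). Prevalence anchors take precedence over summary anchors when the
#' two conflict (the published zinc upper quartile of 11 is inconsistent with
#' 78% of values below 10.7 and is dropped with a warning). Right-skewed
#' biomarkers interpolate on the log scale; hemoglobin, zinc and selenium on
#' the raw scale; selenium is truncated to the observed (2.0, 5.0) umol/L
#' range.
#'
#' @return Named list of [quantile_marginal()] objects.
#' @export
default_marginals <- function() {
  zn <- resolve_anchors(
    "zinc",
    p = c(0.25, 0.5, 0.75, 0.78),
    q = c(8, 9.5, 11, 10.7),
    priority = c(2, 2, 2, 1)
  )
  list(
    hb = quantile_marginal(
      "hb",
      p = c(0.066, 0.191, 0.25, 0.5, 0.75),
      q = c(110, 120, 123, 131.5, 139)
    ),
    ferritin = quantile_marginal(
      "ferritin",
      p = c(0.25, 0.5, 0.75, 0.98), q = c(12, 27.6, 56, 150), log_scale = TRUE
    ),
    tfr = quantile_marginal(
      "tfr",
      p = c(0.25, 0.5, 0.75, 0.92), q = c(2, 3.5, 5, 8.3), log_scale = TRUE
    ),
    plasma_iron = quantile_marginal(
      "plasma_iron",
      p = c(0.25, 0.5, 0.75), q = c(11, 14.7, 20), log_scale = TRUE
    ),
    hepcidin = quantile_marginal(
      "hepcidin",
      p = c(0.25, 0.5, 0.75), q = c(4, 7.2, 11), log_scale = TRUE
    ),
    crp = quantile_marginal(
      "crp",
      p = c(0.25, 0.5, 0.75, 0.94), q = c(0.4, 0.8, 1.9, 5), log_scale = TRUE
    ),
    agp = quantile_marginal(
      "agp",
      p = c(0.25, 0.5, 0.75, 0.87), q = c(0.5, 0.7, 0.8, 1.0), log_scale = TRUE
    ),
    zinc = quantile_marginal("zinc", p = zn$p, q = zn$q),
    selenium = quantile_marginal(
      "selenium",
      p = c(0.25, 0.5, 0.75), q = c(2.6, 3.0, 3.4), lower = 2.0, upper = 5.0
    )
  )
}

#' Default copula correlation targets
#'
#' The published pairwise Pearson correlations between hemoglobin, the iron
#' biomarkers, the inflammation markers and plasma zinc, on the analysis scale
#' (log for skewed biomarkers). Pairs not listed were not significant and
#' default to zero.
#'
#' @return A [copula_spec()].
#' @export
default_copula <- function() {
  copula_spec(
    variables = c("hb", "ferritin", "tfr", "plasma_iron", "hepcidin",
                  "crp", "agp", "zinc", "selenium"),
    pairs = tibble(
      var1 = c("hb", "hb", "hb", "hb",
               "ferritin", "ferritin", "ferritin",
               "crp", "crp", "agp"),
      var2 = c("plasma_iron", "zinc", "tfr", "agp",
               "plasma_iron", "hepcidin", "tfr",
               "agp", "plasma_iron", "plasma_iron"),
      r = c(0.33, 0.23, -0.19, -0.23,
            0.32, 0.48, -0.24,
            0.34, -0.17, -0.16)
    )
  )
}

#' Default categorical field probabilities
#'
#' Published socio-demographic category frequencies. The printed four-level
#' food-insecurity percentages (52.6/12.5/23.0/11.8) sum to 99.9 and are
#' renormalised to 1.
#'
#' @return Named list of named probability vectors.
#' @export
default_categorical_probs <- function() {
  hfias <- c(food_secure = 0.526, mild = 0.125, moderate = 0.230, severe = 0.118)
  list(
    education = c(illiterate = 0.618, literate = 0.382),
    hfias_category = hfias / sum(hfias),
    age_band = c(`18-25` = 0.757, `26-35` = 0.230, `36+` = 0.013),
    household_size_band = c(`1-4` = 0.385, `5-7` = 0.412, `8+` = 0.203),
    children_band = c(`1-2` = 0.441, `3-5` = 0.441, `6+` = 0.118)
  )
}

#' Default household asset indicator probabilities
#'
#' The source survey does not list its asset items; these eight synthetic
#' binary indicators stand in for a rural household asset questionnaire and
#' feed the PCA wealth index. Fully configurable.
#'
#' @return Named vector of Bernoulli probabilities.
#' @export
default_asset_probs <- function() {
  c(radio = 0.35, mobile_phone = 0.45, bed = 0.60, corrugated_roof = 0.50,
    cattle = 0.55, latrine = 0.40, bicycle = 0.15, electricity = 0.10)
}

#' Packaged default cohort specification
#'
#' @param n Cohort size.
#' @param seed Generator seed.
#' @param calibrate Run [calibrate_copula()] now (needed before generation;
#'   done lazily by [generate_cohort()] otherwise)?
#' @param n_cal Calibration Monte-Carlo size.
#' @param ... Passed to [cohort_spec()].
#' @return A `cohort_spec`.
#' @export
default_cohort_spec <- function(n = 150L, seed = 1L, calibrate = FALSE,
                                n_cal = 1e5, ...) {
  spec <- cohort_spec(n = n, seed = seed, ...)
  if (calibrate) {
    spec$copula <- calibrate_copula(spec$copula, spec$marginals, n_cal = n_cal)
  }
  spec
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(
    "<cohort_spec> n = %d, seed = %d, %d marginals, %d correlation targets, altitude %g m\n",
    x$n, x$seed, length(x$marginals), sum(x$copula$target_corr[upper.tri(x$copula$target_corr)] != 0),
    x$altitude_m
  ))
  invisible(x)
}
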