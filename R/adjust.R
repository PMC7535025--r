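#' Altitude correction term for hemoglobin
#'
#' Evaluates the UNICEF/UNU/WHO altitude adjustment polynomial
#' `coeff_linear * x + coeff_quad * x^2` with `x = altitude_m * altitude_factor`,
#' returning the correction in g/dL. Altitude-adjusted hemoglobin (g/L) is the
#' observed value minus ten times this term.
#'
#' The default coefficients (-0.32, 0.22) are the ones this pipeline's source
#' survey prints; they are tenfold the widely used CDC scale (-0.032, 0.022)
#' and give large corrections at highland altitudes, so both are supported and
#' the coefficients are fully configurable.
#'
#' @param altitude_m Altitude in metres (>= 0).
#' @param coeff_linear,coeff_quad Polynomial coefficients.
#' @param altitude_factor Scale from metres to the polynomial argument
#'   (per-metre, > 0).
#' @return Correction term in g/dL.
#' @export
#' @examples
#' altitude_correction_term(0)     # 0
#' altitude_correction_term(1000)  # -0.32*3.3 + 0.22*3.3^2
altitude_correction_term <- function(altitude_m, coeff_linear = -0.32,
                                     coeff_quad = 0.22, altitude_factor = 0.0033) {
  if (any(altitude_m < 0)) abort("altitude must be non-negative")
  if (altitude_factor <= 0) abort("altitude_factor must be positive")
  x <- altitude_m * altitude_factor
  coeff_linear * x + coeff_quad * x^2
}

#' Adjust hemoglobin for altitude
#'
#' @param data A data frame with `hb` (g/L) and `altitude` (m) columns. If
#'   hemoglobin is already on the altitude-adjusted scale (attribute
#'   `hb_altitude_adjusted`, as set by [generate_cohort()]), `hb_adj` is a
#'   copy of `hb`.
#' @inheritParams altitude_correction_term
#' @param force Apply the correction even when the data are flagged as already
#'   adjusted.
#' @return The input with an `hb_adj` column (g/L) appended.
#' @export
adjust_hemoglobin <- function(data, coeff_linear = -0.32, coeff_quad = 0.22,
                              altitude_factor = 0.0033, force = FALSE) {
  data <- as_tibble(data)
  already <- isTRUE(attr(data, "hb_altitude_adjusted"))
  if (already && !force) {
    return(dplyr::mutate(data, hb_adj = .data$hb))
  }
  term <- altitude_correction_term(data$altitude, coeff_linear, coeff_quad,
                                   altitude_factor)
  dplyr::mutate(data, hb_adj = .data$hb - 10 * term)
}

#' Fit an inflammation-adjustment model for an iron biomarker
#'
#' Regression-based (BRINDA-style) correction: ordinary least squares of
#' `ln(biomarker)` on `ln(CRP)` and `ln(AGP)` jointly, with the reference for
#' each inflammation marker taken as the maximum observed ln value among the
#' lowest decile of the sample ordered by that marker (ties at the decile
#' boundary are kept in the decile).
#'
#' @param biomarker,crp,agp Positive numeric vectors of equal length >= 20.
#' @param name Biomarker label carried in the result (e.g. "ferritin").
#' @return An object of class `adjustment_model` with elements `beta_crp`,
#'   `beta_agp`, `ref_ln_crp`, `ref_ln_agp`, `n_fit`, `name`.
#' @export
fit_adjustment_model <- function(biomarker, crp, agp, name = "biomarker") {
  n <- length(biomarker)
  if (length(crp) != n || length(agp) != n) abort("inputs must have equal length")
  if (n < 20) abort("refusing to fit an adjustment model on fewer than 20 records")
  assert_positive(biomarker, "biomarker")
  assert_positive(crp, "crp")
  assert_positive(agp, "agp")
  if (stats::sd(crp) == 0 || stats::sd(agp) == 0) {
    abort("degenerate design: an inflammation marker is constant")
  }
  fit <- stats::lm(log(biomarker) ~ log(crp) + log(agp))
  co <- stats::coef(fit)
  decile_max <- function(x) {
    k <- max(1L, ceiling(0.1 * length(x)))
    s <- sort(x)
    max(log(s[seq_len(k)]))
  }
  structure(
    list(
      name = name,
      beta_crp = unname(co["log(crp)"]),
      beta_agp = unname(co["log(agp)"]),
      ref_ln_crp = decile_max(crp),
      ref_ln_agp = decile_max(agp),
      n_fit = n
    ),
    class = "adjustment_model"
  )
}

#' @export
print.adjustment_model <- function(x, ...) {
  cat(sprintf(
    "<adjustment_model '%s'> beta_CRP = %.4f, beta_AGP = %.4f, ref ln(CRP) = %.4f, ref ln(AGP) = %.4f, n = %d\n",
    x$name, x$beta_crp, x$beta_agp, x$ref_ln_crp, x$ref_ln_agp, x$n_fit
  ))
  invisible(x)
}

#' Apply an inflammation adjustment to biomarker values
#'
#' Computes `exp(ln(value) - b1 * max(0, ln(crp) - ref_crp)
#' - b2 * max(0, ln(agp) - ref_agp))`: the biomarker is corrected downward
#' only for records whose inflammation markers exceed the reference decile
#' (the clamp), and by default only when the fitted slope is positive (a
#' negative slope would inflate the biomarker, which the correction is not
#' meant to do).
#'
#' @param value,crp,agp Positive numeric vectors (recycled to a common
#'   length).
#' @param model An [fit_adjustment_model()] result.
#' @param clamp Apply the `max(0, .)` clamp at the reference (default TRUE;
#'   turning it off adjusts every record, for sensitivity analysis).
#' @param positive_only Skip a term whose beta is <= 0 (default TRUE).
#' @return Adjusted values, same units as `value`.
#' @export
apply_adjustment <- function(value, crp, agp, model, clamp = TRUE,
                             positive_only = TRUE) {
  stopifnot(inherits(model, "adjustment_model"))
  assert_positive(value, "value")
  assert_positive(crp, "crp")
  assert_positive(agp, "agp")
  excess <- function(lnx, ref) if (clamp) pmax(0, lnx - ref) else lnx - ref
  t1 <- model$beta_crp * excess(log(crp), model$ref_ln_crp)
  t2 <- model$beta_agp * excess(log(agp), model$ref_ln_agp)
  if (positive_only) {
    if (model$beta_crp <= 0) t1 <- 0
    if (model$beta_agp <= 0) t2 <- 0
  }
  # multiplicative form keeps unadjusted records exactly equal to their input
  value * exp(-(t1 + t2))
}

#' Body iron index
#'
#' Cook's estimate of total body iron (mg/kg) from the ratio of soluble
#' transferrin receptor to ferritin:
#' `-(log10(ratio) - 2.8229) / 0.1207`, where the ratio is formed after
#' converting TfR from mg/L to ug/L (the Cook convention), i.e.
#' `ratio = 1000 * tfr / ferritin`. Negative body iron denotes tissue iron
#' deficiency; the sign flips exactly at ratio `10^2.8229` (~665).
#'
#' @param tfr Soluble transferrin receptor, mg/L (> 0).
#' @param ferritin (Inflammation-adjusted) ferritin, ug/L (> 0).
#' @return Body iron in mg/kg.
#' @export
#' @examples
#' body_iron(3.5, 27.6)  # about +5.96 mg/kg at the cohort medians
body_iron <- function(tfr, ferritin) {
  assert_positive(tfr, "tfr")
  assert_positive(ferritin, "ferritin")
  ratio <- 1000 * tfr / ferritin
  -(log10(ratio) - 2.8229) / 0.1207
}

#' Run all biomarker adjustments on a cohort
#'
#' Altitude-adjusts hemoglobin (a no-op when the cohort is flagged as already
#' adjusted), fits inflammation-adjustment models for ferritin and transferrin
#' receptor on the cohort itself, applies them, and computes body iron from
#' the adjusted values.
#'
#' @param data Cohort data frame with `hb`, `altitude`, `ferritin`, `tfr`,
#'   `crp`, `agp` columns.
#' @param clamp,positive_only Passed to [apply_adjustment()].
#' @param coeff_linear,coeff_quad,altitude_factor Passed to
#'   [adjust_hemoglobin()].
#' @return The input with `hb_adj`, `ferritin_adj`, `tfr_adj` and `body_iron`
#'   columns appended; the two fitted [fit_adjustment_model()] objects are
#'   attached as attribute `adjustment_models`.
#' @export
adjust_cohort <- function(data, clamp = TRUE, positive_only = TRUE,
                          coeff_linear = -0.32, coeff_quad = 0.22,
                          altitude_factor = 0.0033) {
  data <- adjust_hemoglobin(data, coeff_linear, coeff_quad, altitude_factor)
  m_fer <- fit_adjustment_model(data$ferritin, data$crp, data$agp, "ferritin")
  m_tfr <- fit_adjustment_model(data$tfr, data$crp, data$agp, "tfr")
  out <- dplyr::mutate(
    data,
    ferritin_adj = apply_adjustment(.data$ferritin, .data$crp, .data$agp,
                                    m_fer, clamp, positive_only),
    tfr_adj = apply_adjustment(.data$tfr, .data$crp, .data$agp,
                               m_tfr, clamp, positive_only),
    body_iron = body_iron(.data$tfr_adj, .data$ferritin_adj)
  )
  attr(out, "adjustment_models") <- list(ferritin = m_fer, tfr = m_tfr)
  attr(out, "hb_altitude_adjusted") <- attr(data, "hb_altitude_adjusted")
  out
}
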