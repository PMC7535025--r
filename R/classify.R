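#' Classification cutoffs
#'
#' All thresholds used by the status classifiers, centralised so that boundary
#' audits can enumerate them mechanically. CRP inclusivity is configurable
#' because survey reports commonly mix "> 5" and ">= 5" wordings; strict
#' `> 5` is the default.
#'
#' @param hb_anemia,hb_mild_lower,hb_moderate_lower Hemoglobin cutoffs, g/L:
#'   anemia is `hb < hb_anemia`; severity bands are
#'   mild `[hb_mild_lower, hb_anemia)`, moderate
#'   `[hb_moderate_lower, hb_mild_lower)`, severe `< hb_moderate_lower`.
#' @param ferritin_deficiency Adjusted ferritin below this (ug/L) is iron
#'   deficiency (strict `<`).
#' @param ferritin_overload Adjusted ferritin above this (ug/L) is iron
#'   overload (strict `>`).
#' @param tfr_functional_deficit TfR at or above this (mg/L) is a functional
#'   iron deficit (inclusive `>=`).
#' @param crp_acute CRP cutoff (mg/L) for acute inflammation.
#' @param crp_inclusive Treat CRP equal to the cutoff as acute?
#' @param agp_chronic AGP above this (g/L) is chronic inflammation (strict
#'   `>`).
#' @param zinc_inadequate Plasma zinc below this (umol/L) is inadequate
#'   (strict `<`).
#' @return A named list of cutoffs.
#' @export
status_cutoffs <- function(hb_anemia = 120, hb_mild_lower = 110,
                           hb_moderate_lower = 80,
                           ferritin_deficiency = 15, ferritin_overload = 150,
                           tfr_functional_deficit = 8.3,
                           crp_acute = 5, crp_inclusive = FALSE,
                           agp_chronic = 1, zinc_inadequate = 10.7) {
  as.list(environment())
}

anemia_levels <- c("none", "mild", "moderate", "severe")
inflammation_stages <- c("reference", "incubation", "early_convalescence",
                         "late_convalescence")

#' Classify anemia severity from altitude-adjusted hemoglobin
#'
#' WHO bands for non-pregnant women of reproductive age: none (>= 120 g/L),
#' mild (110-119), moderate (80-109), severe (< 80). On continuous values the
#' printed integer bands are read as half-open intervals (119.5 g/L is mild).
#'
#' @param hb_adj Altitude-adjusted hemoglobin, g/L.
#' @param cutoffs A [status_cutoffs()] list.
#' @return Ordered factor `none < mild < moderate < severe`.
#' @export
classify_anemia <- function(hb_adj, cutoffs = status_cutoffs()) {
  if (any(hb_adj <= 0, na.rm = TRUE)) abort("hemoglobin must be positive")
  out <- dplyr::case_when(
    hb_adj >= cutoffs$hb_anemia ~ "none",
    hb_adj >= cutoffs$hb_mild_lower ~ "mild",
    hb_adj >= cutoffs$hb_moderate_lower ~ "moderate",
    .default = "severe"
  )
  factor(out, levels = anemia_levels, ordered = TRUE)
}

#' Classify inflammation status and stage
#'
#' Acute inflammation is raised CRP (fast-rising acute-phase protein);
#' chronic inflammation is raised AGP (slow-rising). The four-stage reading:
#' neither raised = reference; CRP only = incubation; both = early
#' convalescence; AGP only = late convalescence.
#'
#' @param crp CRP, mg/L (> 0).
#' @param agp AGP, g/L (> 0).
#' @inheritParams classify_anemia
#' @return A tibble with logical `acute_inflammation`, `chronic_inflammation`
#'   and factor `inflammation_stage`.
#' @export
classify_inflammation <- function(crp, agp, cutoffs = status_cutoffs()) {
  assert_positive(crp, "crp")
  assert_positive(agp, "agp")
  acute <- if (cutoffs$crp_inclusive) crp >= cutoffs$crp_acute else crp > cutoffs$crp_acute
  chronic <- agp > cutoffs$agp_chronic
  stage <- dplyr::case_when(
    acute & chronic ~ "early_convalescence",
    acute ~ "incubation",
    chronic ~ "late_convalescence",
    .default = "reference"
  )
  tibble(
    acute_inflammation = acute,
    chronic_inflammation = chronic,
    inflammation_stage = factor(stage, levels = inflammation_stages)
  )
}

#' Classify zinc adequacy
#'
#' @param zinc Plasma zinc, umol/L (> 0).
#' @inheritParams classify_anemia
#' @return Logical: zinc inadequate (strictly below the cutoff)?
#' @export
classify_zinc <- function(zinc, cutoffs = status_cutoffs()) {
  assert_positive(zinc, "zinc")
  zinc < cutoffs$zinc_inadequate
}

#' Classify iron status flags
#'
#' Iron deficiency is adjusted ferritin strictly below 15 ug/L; iron
#' deficiency anemia is deficiency concurrent with anemia; iron overload is
#' adjusted ferritin above 150 ug/L; a functional iron deficit is TfR at or
#' above 8.3 mg/L; tissue iron deficiency is negative body iron.
#'
#' @param ferritin_adj Inflammation-adjusted ferritin, ug/L.
#' @param tfr Transferrin receptor, mg/L.
#' @param body_iron Body iron, mg/kg.
#' @param hb_adj Altitude-adjusted hemoglobin, g/L.
#' @inheritParams classify_anemia
#' @return A tibble of logical flags `iron_deficient`, `ida`, `iron_overload`,
#'   `functional_iron_deficit`, `tissue_iron_deficient`.
#' @export
classify_iron_status <- function(ferritin_adj, tfr, body_iron, hb_adj,
                                 cutoffs = status_cutoffs()) {
  anemic <- classify_anemia(hb_adj, cutoffs) != "none"
  deficient <- ferritin_adj < cutoffs$ferritin_deficiency
  tibble(
    iron_deficient = deficient,
    ida = deficient & anemic,
    iron_overload = ferritin_adj > cutoffs$ferritin_overload,
    functional_iron_deficit = tfr >= cutoffs$tfr_functional_deficit,
    tissue_iron_deficient = body_iron < 0
  )
}

#' Classify a full cohort
#'
#' Applies every status classifier and appends the complete status profile:
#' anemia severity and flag, iron-status flags, inflammation flags and stage,
#' and zinc adequacy.
#'
#' @param data A cohort data frame carrying `hb_adj`, `ferritin_adj`,
#'   `tfr_adj` (or `tfr`), `body_iron`, `crp`, `agp`, `zinc` (see
#'   [adjust_cohort()]).
#' @inheritParams classify_anemia
#' @return The input with status columns appended.
#' @export
classify_cohort <- function(data, cutoffs = status_cutoffs()) {
  data <- as_tibble(data)
  needed <- c("hb_adj", "ferritin_adj", "body_iron", "crp", "agp", "zinc")
  missing <- setdiff(needed, names(data))
  if (length(missing)) abort(paste("missing columns:", paste(missing, collapse = ", ")))
  tfr <- data[["tfr_adj"]] %||% data[["tfr"]]
  severity <- classify_anemia(data$hb_adj, cutoffs)
  dplyr::bind_cols(
    data,
    tibble(anemia_severity = severity, anemic = severity != "none"),
    classify_iron_status(data$ferritin_adj, tfr, data$body_iron,
                         data$hb_adj, cutoffs),
    classify_inflammation(data$crp, data$agp, cutoffs),
    tibble(zinc_inadequate = classify_zinc(data$zinc, cutoffs))
  )
}

#' Cohort prevalence summary
#'
#' Counts and percentages for every status flag and for the anemia severity
#' bands. The severity bands partition the cohort, so mild + moderate +
#' severe equals the anemic percentage.
#'
#' @param data A classified cohort from [classify_cohort()].
#' @return A tibble of class `prevalence_summary` with columns `status`,
#'   `count`, `denominator`, `percent`.
#' @export
summarize_prevalence <- function(data) {
  if (nrow(data) == 0) abort("cannot summarise an empty cohort")
  n <- nrow(data)
  flags <- c("anemic", "iron_deficient", "ida", "iron_overload",
             "functional_iron_deficit", "tissue_iron_deficient",
             "acute_inflammation", "chronic_inflammation", "zinc_inadequate")
  flags <- intersect(flags, names(data))
  rows <- purrr::map(flags, function(f) {
    k <- sum(data[[f]], na.rm = TRUE)
    tibble(status = f, count = k, denominator = n, percent = 100 * k / n)
  })
  sev <- purrr::map(c("mild", "moderate", "severe"), function(s) {
    k <- sum(data$anemia_severity == s, na.rm = TRUE)
    tibble(status = paste0("anemia_", s), count = k, denominator = n,
           percent = 100 * k / n)
  })
  out <- dplyr::bind_rows(c(rows, sev))
  class(out) <- c("prevalence_summary", class(out))
  out
}
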