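#' Generate a synthetic cohort of lactating women
#'
#' Draws `spec$n` records deterministically from `spec$seed`. Biomarkers come
#' from the Gaussian copula (latent multivariate normal pushed through the
#' anchored inverse quantile functions); socio-demographic fields are drawn
#' independently from the categorical probabilities; HFIAS item responses are
#' constructed to map back to their drawn four-level category under the FANTA
#' rules; anthropometry is truncated-normal. Each pipeline stage consumes a
#' named random substream derived from the single seed, so adding a stage
#' never perturbs earlier draws.
#'
#' @param spec A [cohort_spec()]. If its copula has not been calibrated yet,
#'   [calibrate_copula()] is run first (with its own fixed calibration
#'   stream, independent of `spec$seed`).
#' @return A tibble with one row per woman: `id`, socio-demographics, nine
#'   HFIAS item pairs, asset indicators, `altitude`, and the biomarker panel
#'   (`hb` g/L, `ferritin` ug/L, `tfr` mg/L, `plasma_iron` umol/L,
#'   `hepcidin` ug/L, `crp` mg/L, `agp` g/L, `zinc` umol/L,
#'   `selenium` umol/L). The attribute `hb_altitude_adjusted` records which
#'   scale hemoglobin is on.
#' @export
#' @examples
#' \donttest{
#' cohort <- generate_cohort(default_cohort_spec(n = 200, seed = 42))
#' dplyr::glimpse(cohort)
#' }
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n
  if (is.null(spec$copula$repaired_latent_corr)) {
    spec$copula <- calibrate_copula(spec$copula, spec$marginals)
  }

  vars <- spec$copula$variables
  L <- spec$copula$repaired_latent_corr
  Z <- with_substream(spec$seed, "biomarkers", {
    matrix(stats::rnorm(n * length(vars)), nrow = n) %*% chol(L)
  })
  U <- stats::pnorm(Z)
  biomarkers <- purrr::imap(
    stats::setNames(seq_along(vars), vars),
    function(j, v) sample_marginal(spec$marginals[[v]], U[, j])
  )

  cp <- spec$categorical_probs
  draw_cat <- function(p, n) {
    factor(sample(names(p), n, replace = TRUE, prob = p), levels = names(p))
  }
  socio <- with_substream(spec$seed, "socio", {
    education <- draw_cat(cp$education, n)
    age_band <- draw_cat(cp$age_band, n)
    hh_band <- draw_cat(cp$household_size_band, n)
    child_band <- draw_cat(cp$children_band, n)
    age <- dplyr::case_when(
      age_band == "18-25" ~ sample(18:25, n, replace = TRUE),
      age_band == "26-35" ~ sample(26:35, n, replace = TRUE),
      .default = 36L
    )
    household_size <- dplyr::case_when(
      hh_band == "1-4" ~ sample(1:4, n, replace = TRUE),
      hh_band == "5-7" ~ sample(5:7, n, replace = TRUE),
      .default = sample(8:12, n, replace = TRUE)
    )
    n_children <- dplyr::case_when(
      child_band == "1-2" ~ sample(1:2, n, replace = TRUE),
      child_band == "3-5" ~ sample(3:5, n, replace = TRUE),
      .default = sample(6:8, n, replace = TRUE)
    )
    list(education = education, age = age, household_size = household_size,
         n_children = n_children)
  })
  # six months post partum, gravidity is taken equal to parity (n_children),
  # kept within the modelled 1-8 band
  gravidity <- pmin(pmax(socio$n_children, 1L), 8L)

  hfias <- with_substream(spec$seed, "hfias", {
    cats <- sample(names(cp$hfias_category), n, replace = TRUE,
                   prob = cp$hfias_category)
    simulate_hfias_items(match(cats, names(cp$hfias_category)))
  })

  assets <- with_substream(spec$seed, "assets", {
    out <- purrr::imap(spec$asset_probs, function(p, nm) {
      as.integer(stats::runif(n) < p)
    })
    stats::setNames(out, paste0("asset_", names(spec$asset_probs)))
  })

  anthro <- with_substream(spec$seed, "anthropometry", {
    mu <- spec$anthropometry
    list(
      muac = pmax(stats::rnorm(n, mu$muac[1], mu$muac[2]), 15),
      bmi = pmax(stats::rnorm(n, mu$bmi[1], mu$bmi[2]), 12)
    )
  })

  hb <- biomarkers$hb
  if (!is.null(spec$effects)) {
    hb <- hb +
      spec$effects$muac_low_hb * (anthro$muac < 22) +
      spec$effects$illiterate_hb * (socio$education == "illiterate")
  }
  if (!spec$hb_altitude_adjusted) {
    # emit field-measured Hb by inverting the altitude correction
    hb <- hb + 10 * altitude_correction_term(spec$altitude_m)
  }
  biomarkers$hb <- hb

  cohort <- dplyr::bind_cols(
    tibble(
      id = seq_len(n),
      age = socio$age,
      household_size = socio$household_size,
      n_children = socio$n_children,
      gravidity = gravidity,
      education = socio$education,
      muac = anthro$muac,
      bmi = anthro$bmi,
      altitude = rep(spec$altitude_m, n)
    ),
    as_tibble(hfias),
    as_tibble(assets),
    as_tibble(biomarkers)
  )
  attr(cohort, "hb_altitude_adjusted") <- spec$hb_altitude_adjusted
  attr(cohort, "seed") <- spec$seed
  cohort
}

# Build HFIAS item responses whose FANTA category equals the drawn category
# code (1-4). One defining condition of exactly that severity is planted, then
# each other item independently takes a response of no greater severity, so
# the most-severe-condition rule recovers the target.
simulate_hfias_items <- function(cat_code) {
  hfias_table()
  tb <- the_hfias_env$table
  n <- length(cat_code)
  freq <- matrix(0L, nrow = n, ncol = 9)
  defining <- lapply(1:4, function(cc) tb[tb$category == cc & tb$frequency > 0, ])
  allowed <- lapply(1:4, function(cc) tb[tb$category <= cc, ])
  for (cc in 2:4) {
    rows <- which(cat_code == cc)
    if (!length(rows)) next
    def <- defining[[cc]]
    pick <- sample.int(nrow(def), length(rows), replace = TRUE)
    freq[cbind(rows, def$item[pick])] <- def$frequency[pick]
  }
  # benign extra responses (probability 0.3 per remaining item)
  for (cc in 1:4) {
    rows <- which(cat_code == cc)
    if (!length(rows)) next
    alw <- allowed[[cc]]
    for (item in 1:9) {
      cand <- alw$frequency[alw$item == item]
      sub <- rows[freq[rows, item] == 0 & stats::runif(length(rows)) < 0.3]
      if (length(sub) && length(cand)) {
        freq[sub, item] <- sample(cand, length(sub), replace = TRUE)
      }
    }
  }
  out <- list()
  for (item in 1:9) {
    out[[sprintf("hfias%d_occ", item)]] <- as.integer(freq[, item] > 0)
    out[[sprintf("hfias%d_freq", item)]] <- freq[, item]
  }
  out
}

#' Write a cohort to CSV with a sidecar schema
#'
#' Writes one row per woman with canonical column names; a JSON sidecar
#' (`<path>.schema.json`) records column units, the generator seed and whether
#' hemoglobin is on the altitude-adjusted scale. Missing values are encoded as
#' empty cells. The round trip through [read_cohort()] is lossless.
#'
#' @param cohort A cohort tibble from [generate_cohort()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_csv(cohort, path, na = "")
  schema <- list(
    columns = names(cohort),
    units = cohort_units()[intersect(names(cohort_units()), names(cohort))],
    hb_altitude_adjusted = attr(cohort, "hb_altitude_adjusted") %||% TRUE,
    seed = attr(cohort, "seed")
  )
  jsonlite::write_json(schema, paste0(path, ".schema.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a cohort CSV
#'
#' @param path CSV path written by [write_cohort()] (the sidecar schema is
#'   used when present).
#' @return A cohort tibble.
#' @export
read_cohort <- function(path) {
  cohort <- readr::read_csv(path, na = "", show_col_types = FALSE)
  if ("education" %in% names(cohort)) {
    cohort$education <- factor(cohort$education, levels = c("illiterate", "literate"))
  }
  schema_path <- paste0(path, ".schema.json")
  if (file.exists(schema_path)) {
    schema <- jsonlite::read_json(schema_path)
    attr(cohort, "hb_altitude_adjusted") <- isTRUE(schema$hb_altitude_adjusted)
    attr(cohort, "seed") <- schema$seed
  }
  cohort
}

cohort_units <- function() {
  c(age = "years", household_size = "count", n_children = "count",
    gravidity = "count", muac = "cm", bmi = "kg/m^2", altitude = "m",
    hb = "g/L", ferritin = "ug/L", tfr = "mg/L", plasma_iron = "umol/L",
    hepcidin = "ug/L", crp = "mg/L", agp = "g/L", zinc = "umol/L",
    selenium = "umol/L")
}
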