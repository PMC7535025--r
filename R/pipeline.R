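#' Pipeline run configuration
#'
#' Exactly one cohort source must be given: a [cohort_spec()] to generate
#' from, or a CSV path written by [write_cohort()].
#'
#' @param spec A [cohort_spec()], or `NULL` when reading a CSV.
#' @param csv Path to a cohort CSV, or `NULL` when generating.
#' @param out_dir Output directory (created if missing).
#' @param seed Top-level seed; each stage derives a named substream from it.
#' @param cutoffs A [status_cutoffs()] list.
#' @param alpha Bivariate screen retention threshold.
#' @param vif_threshold VIF retention threshold for the linear model.
#' @param adjustment Named list passed to [adjust_cohort()] (`clamp`,
#'   `positive_only`, `coeff_linear`, `coeff_quad`, `altitude_factor`).
#' @return An object of class `run_config`.
#' @export
run_config <- function(spec = NULL, csv = NULL, out_dir = tempfile("anemetrics_run_"),
                       seed = 1L, cutoffs = status_cutoffs(), alpha = 0.05,
                       vif_threshold = 2.5, adjustment = list()) {
  if (is.null(spec) == is.null(csv)) {
    abort("exactly one cohort source (`spec` or `csv`) must be given")
  }
  structure(
    list(spec = spec, csv = csv, out_dir = out_dir, seed = as.integer(seed),
         cutoffs = cutoffs, alpha = alpha, vif_threshold = vif_threshold,
         adjustment = adjustment),
    class = "run_config"
  )
}

required_cohort_cols <- function() {
  c("hb", "ferritin", "tfr", "plasma_iron", "hepcidin", "crp", "agp",
    "zinc", "selenium", "altitude", "muac", "age", "gravidity", "education")
}

#' Run the full pipeline: generate/read, adjust, classify, score, model
#'
#' Executes every stage in order and writes the derived cohort CSV, the
#' prevalence summary (JSON), the adjustment-model fit report (JSON), the
#' hemoglobin linear-model and anemia logistic-model tables (JSON) and a
#' human-readable report. All outputs embed the seed and a configuration
#' hash; identical config and seed give identical outputs.
#'
#' @param config A [run_config()].
#' @return A list of class `run_report`: output `paths`, the classified and
#'   scored `cohort`, the prevalence summary, model objects and the config
#'   hash. Stage failures abort with the stage name and a manifest of the
#'   outputs already written.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config[setdiff(names(config), "out_dir")])
  paths <- list()
  stage <- "setup"
  on_fail <- function(e) {
    abort(sprintf("pipeline failed in stage '%s': %s\npartial outputs: %s",
                  stage, conditionMessage(e),
                  paste(unlist(paths), collapse = ", ")))
  }
  tryCatch({
    stage <- "cohort"
    cohort <- if (!is.null(config$spec)) {
      spec <- config$spec
      spec$seed <- config$seed
      generate_cohort(spec)
    } else {
      read_cohort(config$csv)
    }
    missing <- setdiff(required_cohort_cols(), names(cohort))
    if (length(missing)) {
      abort(paste("cohort is missing column(s):", paste(missing, collapse = ", ")))
    }
    if (nrow(cohort) < 100) {
      warn(sprintf("small cohort (n = %d); model estimates will be unstable", nrow(cohort)))
    }

    stage <- "adjust"
    cohort <- do.call(adjust_cohort, c(list(cohort), config$adjustment))
    fits <- attr(cohort, "adjustment_models")

    stage <- "classify"
    cohort <- classify_cohort(cohort, config$cutoffs)
    prevalence <- summarize_prevalence(cohort)

    stage <- "score"
    cohort <- hfias_score(cohort)
    cohort <- hfias_category(cohort)
    wi <- NULL
    if (any(startsWith(names(cohort), "asset_"))) {
      cohort <- wealth_index(cohort)
      wi <- attr(cohort, "wealth_index")
    }
    cohort <- recode_covariates(cohort, config$cutoffs)

    stage <- "model"
    trans <- transform_predictors(cohort)
    screen <- vif_screen(trans, default_skewed, config$vif_threshold)
    hb_model <- fit_hb_model(trans, "hb_adj", screen$retained)
    factors <- intersect(
      c("tfr_low", "agp_normal", "muac_low", "illiterate", "age_young",
        "zinc_low", "gravidity_low"),
      names(cohort)
    )
    screen_tbl <- bivariate_screen(cohort, factors, "anemic", config$alpha)
    retained <- screen_tbl$factor[screen_tbl$retained]
    anemia_model <- if (length(retained)) {
      fit_anemia_model(cohort, retained)
    } else NULL

    stage <- "write"
    meta <- list(seed = config$seed, config_hash = hash)
    paths$cohort <- file.path(config$out_dir, "cohort.csv")
    write_cohort(cohort, paths$cohort)
    paths$prevalence <- file.path(config$out_dir, "prevalence.json")
    jsonlite::write_json(c(meta, list(prevalence = prevalence)),
                         paths$prevalence, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
    paths$adjustment <- file.path(config$out_dir, "adjustment_fit.json")
    jsonlite::write_json(c(meta, list(
      ferritin = unclass(fits$ferritin), tfr = unclass(fits$tfr)
    )), paths$adjustment, auto_unbox = TRUE, pretty = TRUE, digits = NA)
    paths$hb_model <- file.path(config$out_dir, "hb_model.json")
    jsonlite::write_json(c(meta, list(
      vif = screen$vif_table, coefficients = tidy(hb_model),
      summary = glance(hb_model)
    )), paths$hb_model, auto_unbox = TRUE, pretty = TRUE, digits = NA)
    paths$anemia_model <- file.path(config$out_dir, "anemia_model.json")
    jsonlite::write_json(c(meta, list(
      bivariate_screen = screen_tbl,
      multivariate = if (!is.null(anemia_model)) tidy(anemia_model)
    )), paths$anemia_model, auto_unbox = TRUE, pretty = TRUE, digits = NA)
    paths$report <- file.path(config$out_dir, "report.txt")
    writeLines(render_report(meta, cohort, prevalence, hb_model, anemia_model,
                             screen_tbl, wi), paths$report)

    structure(
      list(paths = paths, cohort = cohort, prevalence = prevalence,
           adjustment_models = fits, hb_model = hb_model,
           anemia_model = anemia_model, bivariate = screen_tbl,
           wealth = wi, seed = config$seed, config_hash = hash),
      class = "run_report"
    )
  }, error = on_fail)
}

render_report <- function(meta, cohort, prevalence, hb_model, anemia_model,
                          screen_tbl, wi) {
  fmt_pct <- function(x) sprintf("%.1f", x)
  lines <- c(
    "anemetrics pipeline report",
    sprintf("seed: %d  config: %s  n: %d", meta$seed, meta$config_hash,
            nrow(cohort)),
    "",
    "Prevalence (%):",
    sprintf("  %-26s %6s (%d/%d)", prevalence$status,
            fmt_pct(prevalence$percent), prevalence$count,
            prevalence$denominator),
    "",
    sprintf("Hemoglobin model: adjusted R^2 = %.1f%% (n = %d)",
            100 * hb_model$adj.r.squared, hb_model$n),
    sprintf("  %-14s %8.3f (%8.3f, %8.3f) p=%.3f sr2=%.3f",
            tidy(hb_model)$term, tidy(hb_model)$estimate,
            tidy(hb_model)$conf.low, tidy(hb_model)$conf.high,
            tidy(hb_model)$p.value, tidy(hb_model)$sr2),
    ""
  )
  if (!is.null(anemia_model)) {
    tt <- tidy(anemia_model)
    lines <- c(lines,
      sprintf("Anemia model (n = %d, events = %d):", anemia_model$n,
              anemia_model$n_events),
      sprintf("  %-14s OR %7.3f (%7.3f, %7.3f) p=%.3f", tt$term, tt$or,
              tt$conf.low, tt$conf.high, tt$p.value))
  } else {
    lines <- c(lines, "Anemia model: no factors passed the bivariate screen")
  }
  if (!is.null(wi)) {
    lines <- c(lines, "",
      sprintf("Wealth index: first PC explains %.1f%% of indicator variance",
              100 * wi$explained_variance_fraction))
  }
  lines
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> n = %d, seed = %d\noutputs:\n", nrow(x$cohort), x$seed))
  for (p in unlist(x$paths)) cat("  ", p, "\n")
  invisible(x)
}
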