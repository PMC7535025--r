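#' Serialise a cohort specification to JSON or YAML
#'
#' The full specification -- anchors, copula targets (and latent matrix if
#' calibrated), categorical probabilities, anthropometry, assets, altitude --
#' round-trips through [read_cohort_spec()]. A packaged copy encoding all the
#' default (published-summary) values ships at
#' `system.file("extdata", "default_cohort_spec.json", package = "anemetrics")`.
#'
#' @param spec A [cohort_spec()].
#' @param path Output path; format chosen by extension (`.json` or
#'   `.yaml`/`.yml`; YAML requires the yaml package).
#' @return `path`, invisibly.
#' @export
write_cohort_spec <- function(spec, path) {
  stopifnot(inherits(spec, "cohort_spec"))
  enc_num <- function(x) ifelse(is.finite(x), x, NA_real_)
  M <- spec$copula$target_corr
  idx <- which(upper.tri(M) & M != 0, arr.ind = TRUE)
  obj <- list(
    n = spec$n, seed = spec$seed, altitude_m = spec$altitude_m,
    hb_altitude_adjusted = spec$hb_altitude_adjusted,
    marginals = purrr::map(spec$marginals, function(m) {
      list(name = m$name, p = m$p, q = m$q, log_scale = m$log_scale,
           floor_value = m$floor_value, cap_factor = enc_num(m$cap_factor),
           lower = enc_num(m$lower), upper = enc_num(m$upper))
    }),
    copula = list(
      variables = spec$copula$variables,
      pairs = purrr::map(seq_len(nrow(idx)), function(r) {
        list(var1 = rownames(M)[idx[r, 1]], var2 = colnames(M)[idx[r, 2]],
             r = M[idx[r, 1], idx[r, 2]])
      }),
      repaired_latent_corr = if (!is.null(spec$copula$repaired_latent_corr))
        apply(unclass(spec$copula$repaired_latent_corr), 1, as.numeric,
              simplify = FALSE)
    ),
    categorical_probs = purrr::map(spec$categorical_probs, as.list),
    anthropometry = purrr::map(spec$anthropometry, as.numeric),
    asset_probs = as.list(spec$asset_probs),
    effects = if (!is.null(spec$effects)) unclass(spec$effects)
  )
  if (grepl("\\.ya?ml$", path)) {
    rlang::check_installed("yaml")
    yaml::write_yaml(obj, path)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA, null = "null", na = "null")
  }
  invisible(path)
}

#' Read a cohort specification
#'
#' @param path A JSON or YAML file written by [write_cohort_spec()], or the
#'   packaged default spec (the default).
#' @return A [cohort_spec()].
#' @export
read_cohort_spec <- function(path = system.file("extdata", "default_cohort_spec.json",
                                                package = "anemetrics")) {
  obj <- if (grepl("\\.ya?ml$", path)) {
    rlang::check_installed("yaml")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = FALSE,
                        simplifyDataFrame = FALSE)
  }
  dec_num <- function(x, inf) {
    if (is.null(x) || !is.numeric(x) || is.na(x)) inf else x
  }
  marginals <- purrr::map(obj$marginals, function(m) {
    quantile_marginal(
      m$name, p = unlist(m$p), q = unlist(m$q),
      log_scale = isTRUE(m$log_scale), floor_value = m$floor_value,
      cap_factor = dec_num(m$cap_factor, Inf),
      lower = dec_num(m$lower, -Inf), upper = dec_num(m$upper, Inf)
    )
  })
  pairs <- if (length(obj$copula$pairs)) {
    dplyr::bind_rows(purrr::map(obj$copula$pairs, as_tibble))
  }
  cop <- copula_spec(unlist(obj$copula$variables), pairs)
  if (!is.null(obj$copula$repaired_latent_corr)) {
    L <- do.call(rbind, purrr::map(obj$copula$repaired_latent_corr, unlist))
    dimnames(L) <- list(cop$variables, cop$variables)
    cop$repaired_latent_corr <- L
  }
  effects <- if (!is.null(obj$effects)) {
    cohort_effects(obj$effects$muac_low_hb, obj$effects$illiterate_hb)
  }
  cohort_spec(
    n = obj$n, seed = obj$seed, marginals = marginals, copula = cop,
    categorical_probs = purrr::map(obj$categorical_probs, function(p) {
      p <- unlist(p)
      # absorb serialisation round-off well below any meaningful probability
      if (abs(sum(p) - 1) < 1e-6) p <- p / sum(p)
      p
    }),
    anthropometry = purrr::map(obj$anthropometry, unlist),
    altitude_m = obj$altitude_m,
    asset_probs = unlist(obj$asset_probs),
    effects = effects,
    hb_altitude_adjusted = isTRUE(obj$hb_altitude_adjusted)
  )
}
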