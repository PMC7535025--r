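#' Gaussian copula specification
#'
#' Couples the anchored marginals through a latent multivariate normal so that
#' generated cohorts reproduce published pairwise Pearson correlations on the
#' analysis scale (natural log for right-skewed biomarkers, raw scale
#' otherwise). Correlations for pairs not listed default to zero.
#'
#' @param variables Ordered character vector of marginal names.
#' @param pairs A data frame with columns `var1`, `var2`, `r` giving target
#'   Pearson correlations on the analysis scale. May be `NULL` (independence).
#' @return An object of class `copula_spec` with fields `variables`,
#'   `target_corr` (symmetric, unit diagonal) and `repaired_latent_corr`
#'   (`NULL` until [calibrate_copula()] is run).
#' @export
copula_spec <- function(variables, pairs = NULL) {
  k <- length(variables)
  M <- diag(k)
  dimnames(M) <- list(variables, variables)
  if (!is.null(pairs)) {
    pairs <- as_tibble(pairs)
    stopifnot(all(c("var1", "var2", "r") %in% names(pairs)))
    for (i in seq_len(nrow(pairs))) {
      a <- pairs$var1[i]; b <- pairs$var2[i]; r <- pairs$r[i]
      if (!a %in% variables || !b %in% variables) {
        abort(sprintf("correlation pair (%s, %s) names an unknown variable", a, b))
      }
      if (abs(r) > 1) abort("target correlations must lie in [-1, 1]")
      M[a, b] <- r
      M[b, a] <- r
    }
  }
  structure(
    list(variables = variables, target_corr = M, repaired_latent_corr = NULL),
    class = "copula_spec"
  )
}

validate_target_corr <- function(M) {
  if (!isSymmetric(unname(M))) abort("target_corr must be symmetric")
  if (any(abs(diag(M) - 1) > 1e-12)) abort("target_corr must have unit diagonal")
  if (any(abs(M) > 1)) abort("target_corr entries must lie in [-1, 1]")
  invisible(M)
}

#' Repair a correlation matrix to positive definiteness
#'
#' Eigenvalue clipping followed by renormalisation to unit diagonal. The
#' maximum elementwise perturbation is attached as attribute
#' `max_perturbation`.
#'
#' @param M Symmetric matrix with unit diagonal.
#' @param eig_floor Smallest admissible eigenvalue before clipping.
#' @return Positive-definite correlation matrix.
#' @export
repair_correlation <- function(M, eig_floor = 1e-6) {
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  if (min(e$values) >= eig_floor) {
    attr(M, "max_perturbation") <- 0
    return(M)
  }
  vals <- pmax(e$values, eig_floor)
  R <- e$vectors %*% diag(vals) %*% t(e$vectors)
  d <- 1 / sqrt(diag(R))
  R <- R * tcrossprod(d)
  diag(R) <- 1
  dimnames(R) <- dimnames(M)
  attr(R, "max_perturbation") <- max(abs(R - M))
  R
}

#' Calibrate latent copula correlations against the anchored marginals
#'
#' The Pearson correlation of two copula-transformed variables on the analysis
#' scale differs from the latent Gaussian correlation whenever the analysis
#' scale is not exactly normal. For every non-zero target pair this routine
#' root-finds the latent correlation so that the empirical analysis-scale
#' correlation matches the target, using common random numbers (a fixed
#' calibration stream of `n_cal` deviates), then assembles the latent matrix
#' and repairs it to positive definiteness by eigenvalue clipping.
#'
#' @param spec A [copula_spec()].
#' @param marginals Named list of [quantile_marginal()] objects covering
#'   `spec$variables`.
#' @param n_cal Monte-Carlo size for calibration (default 1e5).
#' @param seed Seed for the calibration stream.
#' @param tol Root-finding tolerance on the achieved correlation.
#' @return The spec with `repaired_latent_corr` filled in and a
#'   `calibration` tibble (pair, target, latent rho, achieved r).
#' @export
calibrate_copula <- function(spec, marginals, n_cal = 1e5, seed = 761143, tol = 1e-4) {
  stopifnot(inherits(spec, "copula_spec"))
  validate_target_corr(spec$target_corr)
  vars <- spec$variables
  missing <- setdiff(vars, names(marginals))
  if (length(missing)) abort(paste("no marginal for:", paste(missing, collapse = ", ")))

  draws <- withr::with_seed(seed, list(z = stats::rnorm(n_cal), w = stats::rnorm(n_cal)))
  z <- draws$z; w <- draws$w
  # analysis-scale transform of the base stream, per variable
  analysis <- function(v, x) {
    m <- marginals[[v]]
    val <- quantile_fun(m)(stats::pnorm(x))
    if (m$log_scale) log(val) else val
  }
  base_vals <- lapply(vars, analysis, x = z)
  names(base_vals) <- vars

  M <- spec$target_corr
  L <- diag(length(vars))
  dimnames(L) <- dimnames(M)
  rows <- list()
  idx <- which(upper.tri(M) & M != 0, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1L]; j <- idx[r, 2L]
    a <- vars[i]; b <- vars[j]
    target <- M[i, j]
    f <- function(rho) {
      xb <- analysis(b, rho * z + sqrt(1 - rho^2) * w)
      stats::cor(base_vals[[a]], xb) - target
    }
    lohi <- c(-0.999, 0.999)
    flo <- f(lohi[1L]); fhi <- f(lohi[2L])
    if (sign(flo) == sign(fhi)) {
      abort(sprintf(
        "target correlation r(%s, %s) = %g is unattainable under the given marginals",
        a, b, target
      ), class = "anemetrics_calibration_error")
    }
    rho <- stats::uniroot(f, lohi, f.lower = flo, f.upper = fhi, tol = tol)$root
    L[i, j] <- L[j, i] <- rho
    rows[[length(rows) + 1L]] <- tibble(
      var1 = a, var2 = b, target = target, latent_rho = rho,
      achieved = f(rho) + target
    )
  }
  spec$repaired_latent_corr <- repair_correlation(L)
  spec$calibration <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble(var1 = character(), var2 = character(), target = numeric(),
           latent_rho = numeric(), achieved = numeric())
  spec
}
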