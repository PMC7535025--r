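#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

default_skewed <- c("ferritin", "tfr", "plasma_iron", "hepcidin",
                    "crp", "agp", "zinc", "selenium")

#' Log10-transform skewed predictors
#'
#' Applies `log10` to the listed columns (the convention for predictors
#' entering the hemoglobin regression); hemoglobin itself stays on the raw
#' scale. Values at or below `epsilon` are rejected -- silent flooring would
#' distort downstream fits.
#'
#' @param data A data frame.
#' @param skewed Character vector of columns to transform.
#' @param epsilon Positivity floor below which values are rejected.
#' @return The input tibble with the listed columns log10-transformed; the
#'   transformed names are recorded in attribute `log10_columns`.
#' @export
transform_predictors <- function(data, skewed = default_skewed, epsilon = 0.01) {
  data <- as_tibble(data)
  skewed <- intersect(skewed, names(data))
  for (col in skewed) {
    bad <- which(!is.finite(data[[col]]) | data[[col]] <= epsilon)
    if (length(bad)) {
      abort(sprintf("column '%s' has values <= %g at rows: %s", col, epsilon,
                    paste(utils::head(bad, 10L), collapse = ", ")))
    }
    data[[col]] <- log10(data[[col]])
  }
  attr(data, "log10_columns") <- skewed
  data
}

#' Variance-inflation-factor screen
#'
#' `VIF_j = 1 / (1 - R^2_j)` from regressing predictor `j` on the remaining
#' predictors. Predictors at or above the threshold are dropped iteratively,
#' highest VIF first, recomputing each round; a perfectly collinear predictor
#' reports an infinite VIF and is dropped.
#'
#' @param data A data frame holding the (already transformed) predictors.
#' @param predictors Character vector of predictor columns.
#' @param threshold Retention threshold (default 2.5: predictors with VIF
#'   below it are kept).
#' @return A list with `retained` (character vector) and `vif_table` (tibble
#'   with columns `predictor`, `vif`, `round`, `dropped`).
#' @export
vif_screen <- function(data, predictors, threshold = 2.5) {
  if (length(predictors) < 2) abort("need at least two predictors")
  if (nrow(data) <= length(predictors)) abort("need more rows than predictors")
  current <- predictors
  rows <- list()
  round <- 0L
  repeat {
    round <- round + 1L
    X <- as.matrix(data[current])
    vifs <- vapply(seq_along(current), function(j) {
      # a perfectly collinear predictor triggers lm's "perfect fit" warning;
      # the infinite VIF below is the meaningful report of that situation
      r2 <- suppressWarnings(
        summary(stats::lm(X[, j] ~ X[, -j, drop = FALSE]))$r.squared
      )
      if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
    }, numeric(1))
    worst <- which.max(vifs)
    drop_one <- vifs[worst] >= threshold && length(current) > 2
    rows[[round]] <- tibble(
      predictor = current, vif = vifs, round = round,
      dropped = drop_one & seq_along(current) == worst
    )
    if (!drop_one) break
    current <- current[-worst]
  }
  list(retained = current, vif_table = dplyr::bind_rows(rows))
}

#' Multiple linear regression for hemoglobin with squared semipartials
#'
#' Ordinary least squares of hemoglobin on the (log10-transformed) biomarker
#' predictors. The squared semipartial correlation of each predictor -- the
#' increment in model R^2 attributable to it beyond all other predictors -- is
#' computed by explicit nested refit (`R^2(full) - R^2(full minus j)`) with a
#' partial F-test p-value; the model's adjusted R^2 is also reported as a
#' percentage, the convention of survey reports.
#'
#' @param data A data frame (typically after [transform_predictors()]).
#' @param outcome Outcome column (altitude-adjusted hemoglobin, g/L).
#' @param predictors Character vector of predictor columns.
#' @return An object of class `hb_model`: the `lm` fit plus a tidy
#'   coefficient table with semipartials.
#' @export
fit_hb_model <- function(data, outcome = "hb_adj", predictors = default_skewed) {
  data <- as_tibble(data)
  predictors <- intersect(predictors, names(data))
  n <- nrow(data)
  p <- length(predictors)
  if (n <= p + 1) abort("need n > predictors + 1")
  form <- stats::reformulate(predictors, response = outcome)
  fit <- stats::lm(form, data = data)
  if (any(is.na(stats::coef(fit)))) abort("singular design; run vif_screen() first")
  sm <- summary(fit)
  r2_full <- sm$r.squared
  ci <- stats::confint(fit)
  sr <- purrr::map(predictors, function(v) {
    rest <- setdiff(predictors, v)
    sub_form <- if (length(rest)) stats::reformulate(rest, response = outcome)
                else stats::reformulate("1", response = outcome)
    sub <- stats::lm(sub_form, data = data)
    sr2 <- r2_full - summary(sub)$r.squared
    f <- sr2 / ((1 - r2_full) / (n - p - 1))
    tibble(term = v, sr2 = sr2,
           sr2.p.value = stats::pf(f, 1, n - p - 1, lower.tail = FALSE))
  })
  co <- sm$coefficients
  tidy_tbl <- tibble(
    term = rownames(co),
    estimate = unname(co[, 1]), std.error = unname(co[, 2]),
    statistic = unname(co[, 3]), p.value = unname(co[, 4]),
    conf.low = unname(ci[, 1]), conf.high = unname(ci[, 2])
  ) |>
    dplyr::left_join(dplyr::bind_rows(sr), by = "term")
  structure(
    list(
      fit = fit, tidy = tidy_tbl, n = n,
      r.squared = r2_full, adj.r.squared = sm$adj.r.squared,
      outcome = outcome, predictors = predictors
    ),
    class = "hb_model"
  )
}

#' @method tidy hb_model
#' @export
tidy.hb_model <- function(x, ...) x$tidy

#' @method glance hb_model
#' @export
glance.hb_model <- function(x, ...) {
  tibble(
    r.squared = x$r.squared,
    adj.r.squared = x$adj.r.squared,
    adj.r.squared.percent = 100 * x$adj.r.squared,
    n = x$n,
    n.predictors = length(x$predictors)
  )
}

#' @export
print.hb_model <- function(x, ...) {
  cat(sprintf("<hb_model> n = %d, adjusted R^2 = %.1f%%\n", x$n,
              100 * x$adj.r.squared))
  print(x$tidy)
  invisible(x)
}

#' Bivariate logistic screen of candidate anemia factors
#'
#' Fits a one-factor logistic regression per candidate and retains those with
#' Wald p below `alpha`. A separated 2x2 (a zero cell) gets a
#' continuity-corrected (Haldane, +0.5) odds ratio with a warning.
#'
#' @param data A data frame with binary (0/1) factor columns and the outcome.
#' @param factors Character vector of candidate factor columns.
#' @param outcome Binary outcome column (default `"anemic"`).
#' @param alpha Retention threshold on the Wald p-value.
#' @return A tibble with one row per factor: `or`, `conf.low`, `conf.high`,
#'   `p.value`, `separation`, `retained`.
#' @export
bivariate_screen <- function(data, factors, outcome = "anemic", alpha = 0.05) {
  y <- as.integer(as.logical(data[[outcome]]))
  if (length(unique(y)) < 2) abort("outcome has no variation")
  rows <- purrr::map(factors, function(f) {
    x <- data[[f]]
    xi <- as.integer(as.logical(x))
    tab <- table(factor(xi, levels = 0:1), factor(y, levels = 0:1))
    if (any(tab == 0)) {
      warn(sprintf("separation in 2x2 for factor '%s'; continuity-corrected estimate", f))
      tt <- tab + 0.5
      or <- (tt[2, 2] * tt[1, 1]) / (tt[2, 1] * tt[1, 2])
      se <- sqrt(sum(1 / tt))
      z <- log(or) / se
      return(tibble(
        factor = f, or = or,
        conf.low = exp(log(or) - 1.96 * se), conf.high = exp(log(or) + 1.96 * se),
        p.value = 2 * stats::pnorm(-abs(z)), separation = TRUE
      ))
    }
    fit <- stats::glm(y ~ xi, family = stats::binomial())
    co <- summary(fit)$coefficients
    tibble(
      factor = f, or = exp(co[2, 1]),
      conf.low = exp(co[2, 1] - 1.96 * co[2, 2]),
      conf.high = exp(co[2, 1] + 1.96 * co[2, 2]),
      p.value = co[2, 4], separation = FALSE
    )
  })
  dplyr::bind_rows(rows) |>
    dplyr::mutate(retained = .data$p.value < alpha)
}

#' Multivariate logistic regression for anemia
#'
#' Maximum-likelihood logistic regression of the anemia outcome on the
#' retained factors; reports odds ratios with Wald 95% confidence intervals
#' (`exp(coefficient +/- 1.96 SE)`). Warns when there are fewer than 10
#' events, and flags (quasi-)separation without silently altering the fit.
#'
#' @param data A data frame with binary factor columns and the outcome.
#' @param factors Character vector of factor columns to enter jointly.
#' @param outcome Binary outcome column.
#' @param conf_level Confidence level for the Wald intervals.
#' @return An object of class `anemia_model`.
#' @export
fit_anemia_model <- function(data, factors, outcome = "anemic",
                             conf_level = 0.95) {
  if (!length(factors)) abort("no factors to fit")
  y <- as.integer(as.logical(data[[outcome]]))
  if (length(unique(y)) < 2) abort("outcome has no variation")
  if (sum(y) < 10) warn(sprintf("only %d events; estimates may be unstable", sum(y)))
  df <- dplyr::bind_cols(tibble(.y = y), data[factors])
  fit <- withCallingHandlers(
    stats::glm(stats::reformulate(factors, response = ".y"), data = df,
               family = stats::binomial(), control = stats::glm.control(maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        warn("possible separation: fitted probabilities of 0 or 1 occurred")
        invokeRestart("muffleWarning")
      }
    }
  )
  if (!fit$converged) {
    abort(sprintf("logistic fit did not converge in %d iterations", fit$iter))
  }
  co <- summary(fit)$coefficients
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  separation <- any(abs(co[-1, 1]) > 10) || any(fit$fitted.values < 1e-10) ||
    any(fit$fitted.values > 1 - 1e-10)
  if (separation) warn("separation suspected; consider a penalized fit")
  est <- unname(co[-1, 1]); se <- unname(co[-1, 2])
  tidy_tbl <- tibble(
    term = rownames(co)[-1],
    estimate = est, std.error = se, p.value = unname(co[-1, 4]),
    or = exp(est),
    conf.low = exp(est - z * se),
    conf.high = exp(est + z * se)
  )
  structure(
    list(fit = fit, tidy = tidy_tbl, n = nrow(df), n_events = sum(y),
         converged = fit$converged, iterations = fit$iter,
         separation = separation, outcome = outcome, factors = factors),
    class = "anemia_model"
  )
}

#' @method tidy anemia_model
#' @export
tidy.anemia_model <- function(x, ...) x$tidy

#' @method glance anemia_model
#' @export
glance.anemia_model <- function(x, ...) {
  tibble(
    n = x$n, n.events = x$n_events, converged = x$converged,
    iterations = x$iterations, separation = x$separation,
    deviance = x$fit$deviance, aic = x$fit$aic
  )
}

#' @export
print.anemia_model <- function(x, ...) {
  cat(sprintf("<anemia_model> n = %d (%d events)\n", x$n, x$n_events))
  print(x$tidy)
  invisible(x)
}
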