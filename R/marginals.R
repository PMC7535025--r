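#' Quantile-anchored marginal distributions
#'
#' A marginal distribution is specified non-parametrically by monotone
#' (probability, value) anchor pairs -- typically the published median and
#' interquartile range of a biomarker, plus any printed prevalence/threshold
#' pairs (e.g. "19% of women had Hb < 120 g/L" places an anchor at
#' p = 0.19, q = 120). The quantile function is the monotone piecewise-linear
#' interpolation of the anchors, on the natural-log scale for right-skewed
#' biomarkers, with linear tail extrapolation continuing the slope of the
#' outermost segment.
#'
#' @param name Variable name (a single string).
#' @param p Anchor probabilities, strictly increasing, all in (0, 1).
#' @param q Anchor values in the variable's units, strictly increasing.
#' @param log_scale Interpolate on `log(q)`? Use for right-skewed biomarkers
#'   (ferritin, transferrin receptor, hepcidin, CRP, AGP, plasma iron).
#' @param floor_value Positive floor applied after low-tail extrapolation.
#' @param cap_factor Upper cap expressed as a multiple of the largest anchor
#'   value, guarding against absurd extrapolated extremes. `Inf` disables it.
#' @param lower,upper Optional hard truncation bounds on the value scale
#'   (e.g. the observed selenium range).
#'
#' @return An object of class `quantile_marginal`.
#' @export
#' @examples
#' hb <- quantile_marginal("hb", p = c(0.25, 0.5, 0.75), q = c(123, 131.5, 139))
#' sample_marginal(hb, c(0.25, 0.5, 0.75))
quantile_marginal <- function(name, p, q, log_scale = FALSE,
                              floor_value = 1e-3, cap_factor = 5,
                              lower = -Inf, upper = Inf) {
  stopifnot(is.character(name), length(name) == 1L, length(p) == length(q))
  if (length(p) < 2L) abort("need at least two anchors")
  if (any(p <= 0 | p >= 1)) abort("anchor probabilities must lie in (0, 1)")
  bad_p <- which(diff(p) <= 0)
  bad_q <- which(diff(q) <= 0)
  if (length(bad_p) || length(bad_q)) {
    i <- c(bad_p, bad_q)[1L]
    abort(sprintf(
      "anchors for '%s' must be strictly increasing in p and q; offending pair: (p=%g, q=%g) -> (p=%g, q=%g)",
      name, p[i], q[i], p[i + 1L], q[i + 1L]
    ), class = "anemetrics_calibration_error")
  }
  if (log_scale && any(q <= 0)) abort("log-scale anchors require all q > 0")
  structure(
    list(
      name = name, p = as.numeric(p), q = as.numeric(q),
      log_scale = isTRUE(log_scale), floor_value = floor_value,
      cap_factor = cap_factor, lower = lower, upper = upper
    ),
    class = "quantile_marginal"
  )
}

#' @export
print.quantile_marginal <- function(x, ...) {
  cat(sprintf(
    "<quantile_marginal '%s'> %d anchors%s\n", x$name, length(x$p),
    if (x$log_scale) " (log scale)" else ""
  ))
  print(tibble(p = x$p, q = x$q))
  invisible(x)
}

#' Quantile function of an anchored marginal
#'
#' Returns the quantile function Q(u): piecewise-linear in the anchors (on the
#' log scale when `log_scale`), with linear tail extrapolation beyond the
#' extreme anchors, floored at `floor_value` and capped at
#' `cap_factor * max(q)`.
#'
#' @param m A [quantile_marginal()].
#' @return A vectorised function of `u` in (0, 1).
#' @export
quantile_fun <- function(m) {
  stopifnot(inherits(m, "quantile_marginal"))
  yp <- if (m$log_scale) log(m$q) else m$q
  p <- m$p
  k <- length(p)
  slope_low <- (yp[2L] - yp[1L]) / (p[2L] - p[1L])
  slope_high <- (yp[k] - yp[k - 1L]) / (p[k] - p[k - 1L])
  cap <- if (is.finite(m$cap_factor)) m$cap_factor * max(m$q) else Inf
  function(u) {
    if (any(u <= 0 | u >= 1)) abort("u must lie strictly in (0, 1)")
    y <- stats::approx(p, yp, xout = u, rule = 2)$y
    lo <- u < p[1L]
    hi <- u > p[k]
    y[lo] <- yp[1L] + slope_low * (u[lo] - p[1L])
    y[hi] <- yp[k] + slope_high * (u[hi] - p[k])
    v <- if (m$log_scale) exp(y) else y
    v <- pmax(v, m$floor_value)
    v <- pmin(v, cap)
    pmin(pmax(v, m$lower), m$upper)
  }
}

#' Draw values from an anchored marginal by inverse-quantile sampling
#'
#' @param m A [quantile_marginal()].
#' @param u Uniform deviates in (0, 1).
#' @return Numeric vector of sampled values, same length as `u`.
#' @export
sample_marginal <- function(m, u) {
  quantile_fun(m)(u)
}

# Resolve anchors with priorities: prevalence-threshold anchors (priority 1)
# beat summary-statistic anchors (priority 2). A lower-priority anchor that
# breaks joint monotonicity against the kept set is dropped with a warning.
# This handles conflicts like a printed IQR upper quartile of 11 umol/L against
# a 78% prevalence below a 10.7 umol/L cutoff.
resolve_anchors <- function(name, p, q, priority) {
  ord <- order(priority, seq_along(p))
  keep_p <- numeric(0)
  keep_q <- numeric(0)
  dropped <- character(0)
  for (i in ord) {
    cand_p <- c(keep_p, p[i])
    cand_q <- c(keep_q, q[i])
    o <- order(cand_p)
    if (all(diff(cand_p[o]) > 0) && all(diff(cand_q[o]) > 0)) {
      keep_p <- cand_p
      keep_q <- cand_q
    } else {
      dropped <- c(dropped, sprintf("(p=%g, q=%g)", p[i], q[i]))
    }
  }
  if (length(dropped)) {
    warn(sprintf(
      "marginal '%s': dropped anchor(s) %s conflicting with higher-priority prevalence anchors",
      name, paste(dropped, collapse = ", ")
    ), class = "anemetrics_anchor_conflict")
  }
  o <- order(keep_p)
  list(p = keep_p[o], q = keep_q[o])
}
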