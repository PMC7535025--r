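#' Plot a prevalence summary
#'
#' Horizontal bar chart of per-status prevalences, mirroring the usual
#' survey-report prevalence figures.
#'
#' @param object A [summarize_prevalence()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot prevalence_summary
#' @export
autoplot.prevalence_summary <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$percent,
    y = stats::reorder(.data$status, .data$percent)
  )) +
    ggplot2::geom_col(fill = "#4477AA") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.1f%%", .data$percent)),
                       hjust = -0.1, size = 3) +
    ggplot2::labs(x = "Prevalence (%)", y = NULL) +
    ggplot2::expand_limits(x = max(object$percent) * 1.15) +
    ggplot2::theme_minimal()
}

#' Plot hemoglobin-model coefficients
#'
#' Point estimates with 95% confidence intervals for each (log10-scale)
#' predictor of hemoglobin.
#'
#' @param object An [fit_hb_model()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hb_model
#' @export
autoplot.hb_model <- function(object, ...) {
  tt <- dplyr::filter(tidy(object), .data$term != "(Intercept)")
  ggplot2::ggplot(tt, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high)) +
    ggplot2::labs(x = "Coefficient (g/L per log10 unit)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot anemia-model odds ratios
#'
#' Forest-style plot of odds ratios with Wald 95% confidence intervals on a
#' log scale.
#'
#' @param object An [fit_anemia_model()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot anemia_model
#' @export
autoplot.anemia_model <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$or, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Odds ratio (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}
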