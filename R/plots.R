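#' Forest-style plot of effect estimates
#'
#' Point estimates with 95% confidence intervals, one row per
#' exposure-outcome-analysis combination, faceted by outcome. Mirrors the
#' usual MVR-vs-MR comparison figure: for every exposure the MR estimate is
#' shown next to the multivariable-regression estimate on the common
#' risk-difference scale.
#'
#' @param effects Effects tibble from [run_study()] (or any tibble with
#'   `exposure`, `analysis`, `beta`, `ci_low`, `ci_high`, `outcome`).
#' @param pooled_only Drop per-split rows (default TRUE).
#' @return A ggplot object.
#' @export
plot_effects <- function(effects, pooled_only = TRUE) {
  if (pooled_only && "method" %in% names(effects)) {
    effects <- effects[effects$method %in% c("ols_robust", "2sls_meta"), ]
  }
  ggplot2::ggplot(effects,
                  ggplot2::aes(x = .data$beta, y = .data$exposure,
                               colour = .data$analysis)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_pointrange(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high),
      position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::facet_wrap(~outcome) +
    ggplot2::labs(x = "risk difference per scaled unit (95% CI)",
                  y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot per-variant ratios with estimator fits
#'
#' Scatter of variant-outcome against variant-exposure associations with
#' the IVW (through the origin) and MR-Egger (free intercept) fits overlaid;
#' the vertical gap of the Egger line at zero visualizes directional
#' pleiotropy.
#'
#' @param r Ratio set from [make_ratios()].
#' @return A ggplot object.
#' @export
plot_ratios <- function(r) {
  iv <- ivw(r)
  eg <- if (nrow(r) >= 3) mr_egger(r) else NULL
  p <- ggplot2::ggplot(r, ggplot2::aes(x = .data$beta_gx, y = .data$beta_gy)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$beta_gy - 1.96 * .data$se_gy,
                   ymax = .data$beta_gy + 1.96 * .data$se_gy),
      width = 0, colour = "grey70") +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = 0, slope = iv$beta, colour = "#2166ac") +
    ggplot2::labs(x = "variant-exposure beta", y = "variant-outcome beta") +
    ggplot2::theme_minimal()
  if (!is.null(eg)) {
    p <- p + ggplot2::geom_abline(
      intercept = eg$beta[eg$term == "egger_intercept"],
      slope = eg$beta[eg$term == "egger_slope"], colour = "#b2182b",
      linetype = "dotdash")
  }
  p
}

#' Plot a mediation decomposition
#'
#' Bars for the total and direct effects with the indirect effect annotated;
#' the proportion mediated is printed in the subtitle (or flagged when
#' mediation is inconsistent).
#'
#' @param object A `mediation_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mediation_result
#' @export
autoplot.mediation_result <- function(object, ...) {
  td <- tidy(object)
  td <- td[td$term != "proportion_mediated", ]
  sub <- if (object$inconsistent) {
    "proportion mediated suppressed: inconsistent mediation"
  } else {
    sprintf("proportion mediated %.1f%% (95%% CI %.1f, %.1f)",
            object$pm, object$pm_ci[1], object$pm_ci[2])
  }
  ggplot2::ggplot(td, ggplot2::aes(x = .data$term, y = .data$estimate)) +
    ggplot2::geom_col(fill = "grey75") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high), width = 0.2) +
    ggplot2::labs(x = NULL, y = "risk difference",
                  title = sprintf("Mediation (%s) via %s",
                                  toupper(object$framework),
                                  paste(object$mediators, collapse = " + ")),
                  subtitle = sub) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
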