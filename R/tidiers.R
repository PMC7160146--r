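# broom-style tidiers and ggplot2 autoplot methods for fitted objects.

#' Tidy a burden fit
#'
#' @param x A `burden_fit` from [fit_logistic_burden()].
#' @param ... Unused.
#' @return One-row tibble in broom convention (`term`, `estimate` on the
#'   log-odds scale, `std.error`, `statistic`, `p.value`) plus the odds
#'   ratio and its 95% interval.
#' @export
#' @exportS3Method generics::tidy
tidy.burden_fit <- function(x, ...) {
  tibble::tibble(
    term = x$term,
    estimate = x$beta,
    std.error = x$se,
    statistic = x$z,
    p.value = x$p_one_sided,
    odds.ratio = x$odds_ratio,
    conf.low = x$ci_lower,
    conf.high = x$ci_upper
  )
}

#' Model-level summary of a burden fit
#'
#' @inheritParams tidy.burden_fit
#' @return One-row tibble with the odds ratio, one-sided and empirical
#'   p-values, case/control sizes and fit flags.
#' @export
#' @exportS3Method generics::glance
glance.burden_fit <- function(x, ...) {
  tibble::tibble(
    odds_ratio = x$odds_ratio,
    ci_lower = x$ci_lower, ci_upper = x$ci_upper,
    p_one_sided = x$p_one_sided, p_empirical = x$p_empirical,
    n_permutations = x$n_permutations,
    n_case = x$n_case, n_control = x$n_control,
    case_total = x$case_total, control_total = x$control_total,
    converged = x$converged, separation = x$separation
  )
}

#' Tidy a heritability fit
#'
#' @param x A `heritability_fit` from [reml_fit()].
#' @param ... Unused.
#' @return Tibble of variance components with standard errors.
#' @export
#' @exportS3Method generics::tidy
tidy.heritability_fit <- function(x, ...) {
  x$components
}

#' Model-level summary of a heritability fit
#'
#' @inheritParams tidy.heritability_fit
#' @return One-row tibble: observed- and liability-scale h2 (+ SEs),
#'   prevalence, case proportion, convergence.
#' @export
#' @exportS3Method generics::glance
glance.heritability_fit <- function(x, ...) {
  tibble::tibble(
    h2_observed = x$h2_observed, h2_observed_se = x$h2_observed_se,
    h2_liability = x$h2_liability, h2_liability_se = x$h2_liability_se,
    K = x$K %||% NA_real_, P = x$P,
    n = x$n, n_iter = x$n_iter, converged = x$converged
  )
}

#' Forest plot of burden-scan odds ratios
#'
#' @param object A tibble from [burden_scan()].
#' @param ... Unused.
#' @return A ggplot: per-annotation odds ratio with 95% CI on a log scale,
#'   significant tests (BH-adjusted p < 0.05) highlighted.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.burden_scan <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$annotation, y = .data$odds_ratio,
                               ymin = .data$ci_lower, ymax = .data$ci_upper,
                               colour = .data$significant)) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange() +
    ggplot2::scale_y_log10() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "odds ratio per unit burden",
                  colour = "BH-FDR < 0.05") +
    ggplot2::theme_minimal()
}

#' Variance-component plot of a heritability fit
#'
#' @param object A `heritability_fit`.
#' @param ... Unused.
#' @return A ggplot of per-component variance estimates with +-1 SE bars.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.heritability_fit <- function(object, ...) {
  d <- object$components
  ggplot2::ggplot(d, ggplot2::aes(x = .data$component, y = .data$variance)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$variance - .data$se,
                   ymax = .data$variance + .data$se), width = 0.2) +
    ggplot2::labs(x = NULL, y = "variance component") +
    ggplot2::theme_minimal()
}

#' Quantile-quantile plot of association p-values
#'
#' @param p_values Numeric vector of p-values.
#' @return A ggplot of observed vs expected -log10(p) with the identity
#'   line and the genomic inflation factor in the subtitle.
#' @export
plot_qq <- function(p_values) {
  p_values <- sort(p_values[!is.na(p_values)])
  d <- tibble::tibble(
    expected = -log10(stats::ppoints(length(p_values))),
    observed = -log10(p_values)
  )
  lambda <- if (length(p_values) >= 100) genomic_inflation(p_values) else NA
  ggplot2::ggplot(d, ggplot2::aes(.data$expected, .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey50") +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::labs(x = expression(Expected ~ -log[10](p)),
                  y = expression(Observed ~ -log[10](p)),
                  subtitle = if (!is.na(lambda)) {
                    paste0("lambda[GC] = ", signif(lambda, 4))
                  }) +
    ggplot2::theme_minimal()
}
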