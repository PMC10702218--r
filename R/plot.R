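#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_errorbarh
#'   geom_vline labs theme_minimal
#' @export
ggplot2::autoplot

#' Forest plot of MR estimates
#'
#' @param estimates Estimate tibble (rows from any estimator), optionally
#'   with OR columns from [or_transform()].
#' @param scale `"beta"` or `"or"` (log-spaced axis around 1).
#' @return A ggplot object.
#' @export
plot_forest <- function(estimates, scale = c("beta", "or")) {
  scale <- match.arg(scale)
  df <- estimates
  if (scale == "or") {
    if (!"or" %in% names(df)) df <- or_transform(df)
    df <- dplyr::mutate(df, est = .data$or, lo = .data$or_ci_low,
                        hi = .data$or_ci_high)
    ref <- 1
    xlab <- "Odds ratio (95% CI)"
  } else {
    df <- dplyr::mutate(df, est = .data$beta, lo = .data$ci_low, hi = .data$ci_high)
    ref <- 0
    xlab <- "Causal effect (95% CI)"
  }
  p <- ggplot(df, aes(x = .data$est, y = .data$method)) +
    geom_vline(xintercept = ref, linetype = "dashed", colour = "grey50") +
    geom_errorbarh(aes(xmin = .data$lo, xmax = .data$hi), height = 0.2) +
    geom_point(size = 2) +
    labs(x = xlab, y = NULL) +
    theme_minimal()
  if (scale == "or") p <- p + ggplot2::scale_x_log10()
  p
}

#' @rdname plot_forest
#' @param object An `mr_analysis` object.
#' @param ... Passed on to [plot_forest()].
#' @method autoplot mr_analysis
#' @export
autoplot.mr_analysis <- function(object, ...) {
  plot_forest(object$estimates, ...)
}

#' Forest plot of mediation effects and proportions
#'
#' @param object An `mr_mediation` object.
#' @param ... Unused.
#' @return A ggplot object showing each mediator's mediation effect with
#'   its 95% CI.
#' @method autoplot mr_mediation
#' @export
autoplot.mr_mediation <- function(object, ...) {
  df <- dplyr::filter(object$results, .data$status == "mediated")
  ggplot(df, aes(x = .data$mediation_beta, y = .data$mediator)) +
    geom_vline(xintercept = 0, linetype = "dashed", colour = "grey50") +
    geom_errorbarh(aes(xmin = .data$mediation_ci_low,
                       xmax = .data$mediation_ci_high), height = 0.2) +
    geom_point(size = 2) +
    labs(x = "Mediation effect (95% CI)", y = NULL) +
    theme_minimal()
}

#' Leave-one-out plot
#'
#' @param loo Tibble from [leave_one_out()].
#' @return A ggplot object.
#' @export
plot_leave_one_out <- function(loo) {
  ggplot(loo, aes(x = .data$beta, y = .data$omitted)) +
    geom_vline(xintercept = 0, linetype = "dashed", colour = "grey50") +
    geom_errorbarh(aes(xmin = .data$ci_low, xmax = .data$ci_high), height = 0.2) +
    geom_point(size = 1.5) +
    labs(x = "IVW estimate omitting the variant", y = NULL) +
    theme_minimal()
}
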