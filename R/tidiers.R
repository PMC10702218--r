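#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an MR analysis
#'
#' One row per estimator, in broom column conventions.
#'
#' @param x An `mr_analysis` object.
#' @param ... Unused.
#' @return Tibble with `term, estimate, std.error, conf.low, conf.high,
#'   p.value, n_snp`.
#' @method tidy mr_analysis
#' @export
tidy.mr_analysis <- function(x, ...) {
  dplyr::transmute(x$estimates,
    term = .data$method,
    estimate = .data$beta,
    std.error = .data$se,
    conf.low = .data$ci_low,
    conf.high = .data$ci_high,
    p.value = .data$pval,
    n_snp = .data$n_snp
  )
}

#' One-row summary of an MR analysis
#'
#' @param x An `mr_analysis` object.
#' @param ... Unused.
#' @return One-row tibble with instrument count and strength,
#'   heterogeneity, and pleiotropy diagnostics.
#' @method glance mr_analysis
#' @export
glance.mr_analysis <- function(x, ...) {
  tibble::tibble(
    n_snp = x$strength$k,
    f_statistic = x$strength$f_statistic,
    r2_total = x$strength$r2_total,
    q = x$sensitivity$q$q %||% NA_real_,
    q_pval = x$sensitivity$q$pval %||% NA_real_,
    i_squared = x$sensitivity$q$i_squared %||% NA_real_,
    egger_intercept = x$sensitivity$egger_intercept$estimate %||% NA_real_,
    egger_intercept_pval = x$sensitivity$egger_intercept$pval %||% NA_real_,
    presso_global_pval = x$sensitivity$presso$global_pval %||% NA_real_,
    presso_n_outliers = if (is.null(x$sensitivity$presso)) NA_integer_
                        else length(x$sensitivity$presso$outliers)
  )
}

#' Tidy a mediation analysis
#'
#' @param x An `mr_mediation` object.
#' @param ... Unused.
#' @return The per-mediator results tibble.
#' @method tidy mr_mediation
#' @export
tidy.mr_mediation <- function(x, ...) x$results

#' One-row summary of a mediation analysis
#'
#' @param x An `mr_mediation` object.
#' @param ... Unused.
#' @return One-row tibble with the total effect and mediator counts per
#'   status.
#' @method glance mr_mediation
#' @export
glance.mr_mediation <- function(x, ...) {
  tibble::tibble(
    total_effect = x$total$beta,
    total_se = x$total$se,
    n_mediators = nrow(x$results),
    n_mediated = sum(x$results$status == "mediated"),
    n_dropped_step1 = sum(x$results$status == "dropped_step1"),
    n_screened_out = sum(x$results$status == "screened_out_lasso")
  )
}
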