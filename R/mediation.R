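#' Coefficient-product mediation effect
#'
#' The indirect (mediated) effect of an exposure on an outcome through one
#' mediator is the product of the exposure-to-mediator effect and the
#' mediator-to-outcome effect adjusted for the exposure:
#' \eqn{\beta_{med} = \beta_{XZ}\,\beta_{ZY}}. The primary SE is the
#' first-order delta method,
#' \eqn{\sqrt{\beta_{ZY}^2 se_{XZ}^2 + \beta_{XZ}^2 se_{ZY}^2}}, with a
#' normal two-sided p-value and 95% CI; a seeded parametric bootstrap
#' (products of independent normal draws of the two legs, percentile CI)
#' is available as an alternative and is labelled in the output.
#'
#' @param beta_xz,se_xz Exposure-to-mediator estimate and SE.
#' @param beta_zy,se_zy Mediator-to-outcome (exposure-adjusted) estimate
#'   and SE.
#' @param method `"delta"` (default) or `"bootstrap"`.
#' @param n_boot,seed Bootstrap controls.
#' @return One-row tibble: `beta, se, ci_low, ci_high, pval, ci_method`.
#' @export
product_mediation <- function(beta_xz, se_xz, beta_zy, se_zy,
                              method = c("delta", "bootstrap"),
                              n_boot = 10000, seed = 1L) {
  method <- match.arg(method)
  if (se_xz <= 0 || se_zy <= 0) abort("SEs must be > 0", class = "mrpath_input_error")
  beta <- beta_xz * beta_zy
  se <- sqrt(beta_zy^2 * se_xz^2 + beta_xz^2 * se_zy^2)
  if (method == "delta") {
    ci <- ci_bounds(beta, se)
    lo <- ci$low; hi <- ci$high
  } else {
    draws <- with_seed(seed, rnorm(n_boot, beta_xz, se_xz) * rnorm(n_boot, beta_zy, se_zy))
    se <- sd(draws)
    qs <- stats::quantile(draws, c(0.025, 0.975), names = FALSE)
    lo <- qs[1]; hi <- qs[2]
  }
  tibble::tibble(beta = beta, se = se, ci_low = lo, ci_high = hi,
                 pval = two_sided_p(beta / se), ci_method = method)
}

#' Mediated proportion
#'
#' The fraction of the total effect carried by one mediator,
#' \eqn{\beta_{med}/\beta_{total}}, reported in percent with a delta-method
#' CI for the ratio under the (approximating) assumption that the two
#' estimates are independent.
#'
#' @param beta_med,se_med Mediation (indirect) effect and SE.
#' @param beta_total,se_total Total effect (univariate IVW) and SE.
#' @param tol Smallest |total effect| accepted.
#' @return One-row tibble in percent: `proportion, se, ci_low, ci_high`.
#' @export
mediated_proportion <- function(beta_med, se_med, beta_total, se_total,
                                tol = 1e-10) {
  if (abs(beta_total) < tol) {
    abort("total effect too small for a mediated proportion",
          class = "mrpath_input_error")
  }
  p <- beta_med / beta_total
  se <- abs(p) * sqrt((se_med / beta_med)^2 + (se_total / beta_total)^2)
  if (beta_med == 0) se <- se_med / abs(beta_total)
  ci <- ci_bounds(p, se)
  tibble::tibble(proportion = 100 * p, se = 100 * se,
                 ci_low = 100 * ci$low, ci_high = 100 * ci$high)
}

#' Bonferroni correction for a family of mediator tests
#'
#' Significance threshold `0.05 / family_size` (e.g. 0.0167, displayed as
#' 0.017, for a family of three anthropometric mediators drawn from one
#' GWAS) and the per-test decisions.
#'
#' @param pvals Numeric p-values (optionally named).
#' @param family_size Number of tests in the family (default
#'   `length(pvals)`).
#' @param alpha Family-wise error rate (default 0.05).
#' @return List with `threshold` and `decisions` (tibble: `pval`,
#'   `significant`).
#' @export
bonferroni <- function(pvals, family_size = length(pvals), alpha = 0.05) {
  if (family_size < 1) abort("family_size must be >= 1", class = "mrpath_input_error")
  thr <- alpha / family_size
  list(
    threshold = thr,
    decisions = tibble::tibble(
      mediator = names(pvals) %||% as.character(seq_along(pvals)),
      pval = unname(pvals),
      significant = unname(pvals) < thr
    )
  )
}

#' Two-step MR mediation analysis
#'
#' The three-step procedure for a set of candidate mediators of an
#' exposure-outcome relationship, all from GWAS summary statistics:
#'
#' 1. *Step 1* — univariate IVW of the exposure on each mediator
#'    (`effect_xz`), with Bonferroni correction inside user-declared
#'    mediator families (mediators measured in the same GWAS); mediators
#'    whose corrected test fails are dropped.
#' 2. *Step 2* — LASSO screening over the exposure plus surviving
#'    mediators against the outcome removes mediators with no conditional
#'    signal; multivariable IVW on the exposure plus retained mediators
#'    gives each mediator's exposure-adjusted effect on the outcome
#'    (`effect_zy`).
#' 3. *Step 3* — the coefficient product `effect_xz * effect_zy` gives each
#'    mediation effect (delta-method SE), and its ratio to the univariate
#'    total effect gives the mediated proportion.
#'
#' @param exposure Summary-statistics tibble for the exposure.
#' @param mediators Named list of summary-statistics tibbles.
#' @param outcome Summary-statistics tibble for the outcome.
#' @param cfg A [selection_config()].
#' @param families Optional named list mapping family labels to mediator
#'   names for Bonferroni grouping; unlisted mediators form singleton
#'   families.
#' @param alpha Family-wise error rate for step 1.
#' @param use_lasso Run the LASSO screen (default TRUE; FALSE keeps all
#'   step-1 survivors).
#' @param select Select instruments from the exposure at the stated
#'   thresholds before analysis (default TRUE).
#' @param seed RNG seed (cross-validation folds and any bootstraps).
#' @return An object of class `mr_mediation`: list with `results` (one row
#'   per mediator: legs, mediation effect, mediated proportion, status),
#'   `total` (univariate IVW exposure on outcome), and `log` (every drop
#'   decision with its stage).
#' @export
run_two_step <- function(exposure, mediators, outcome,
                         cfg = selection_config(), families = NULL,
                         alpha = 0.05, use_lasso = TRUE, select = TRUE,
                         seed = 1L) {
  if (is.null(names(mediators)) || any(names(mediators) == "")) {
    abort("mediators must be a named list", class = "mrpath_input_error")
  }
  log <- list()
  note <- function(stage, what) {
    log[[length(log) + 1]] <<- tibble::tibble(stage = stage, note = what)
  }

  instruments <- if (select) select_instruments(exposure, cfg) else exposure
  note("select", sprintf("%d exposure instruments", nrow(instruments)))

  total <- mr_ivw(harmonize(instruments, outcome, cfg))
  note("total", sprintf("total effect %.4f (se %.4f)", total$beta, total$se))

  # Step 1: exposure -> mediator, Bonferroni within families
  xz <- purrr::imap(mediators, function(med, nm) {
    mr_ivw(harmonize(instruments, med, cfg))
  })
  fam_of <- function(nm) {
    hit <- purrr::detect_index(families, function(members) nm %in% members)
    if (hit > 0) names(families)[hit] else nm
  }
  fams <- vapply(names(mediators), fam_of, character(1))
  step1_keep <- character()
  for (f in unique(fams)) {
    members <- names(mediators)[fams == f]
    ps <- vapply(xz[members], function(e) e$pval, numeric(1))
    dec <- bonferroni(ps, family_size = length(members), alpha = alpha)
    keep <- members[dec$decisions$significant]
    step1_keep <- c(step1_keep, keep)
    for (m in setdiff(members, keep)) {
      note("step1", sprintf("mediator %s dropped (p=%.3g >= %.3g, family %s)",
                            m, xz[[m]]$pval, dec$threshold, f))
    }
  }

  screened_out <- character()
  zy <- list()
  if (length(step1_keep) > 0) {
    traits <- c(list(exposure = exposure), mediators[step1_keep])
    input <- mvmr_input(traits, outcome, cfg, select = select)
    keep2 <- step1_keep
    if (use_lasso && length(step1_keep) >= 1) {
      scr <- lasso_screen(input, seed = child_seed(seed, 2L))
      screened_out <- intersect(scr$screened_out, step1_keep)
      keep2 <- setdiff(step1_keep, screened_out)
      for (m in screened_out) note("step2", sprintf("mediator %s screened out by LASSO", m))
    }
    if (length(keep2) > 0) {
      fit <- mvmr_ivw(input, exposures = c("exposure", keep2))
      zy <- split(fit, fit$exposure)[keep2]
    }
  }

  rows <- purrr::imap(mediators, function(med, nm) {
    base <- tibble::tibble(
      mediator = nm,
      status = if (!nm %in% step1_keep) "dropped_step1"
               else if (nm %in% screened_out) "screened_out_lasso"
               else "mediated",
      xz_beta = xz[[nm]]$beta, xz_se = xz[[nm]]$se, xz_pval = xz[[nm]]$pval,
      zy_beta = NA_real_, zy_se = NA_real_, zy_pval = NA_real_,
      mediation_beta = NA_real_, mediation_se = NA_real_,
      mediation_ci_low = NA_real_, mediation_ci_high = NA_real_,
      mediation_pval = NA_real_,
      proportion = NA_real_, proportion_ci_low = NA_real_,
      proportion_ci_high = NA_real_,
      total_beta = total$beta, total_se = total$se
    )
    if (base$status != "mediated") return(base)
    e_zy <- zy[[nm]]
    med_est <- product_mediation(xz[[nm]]$beta, xz[[nm]]$se, e_zy$beta, e_zy$se)
    prop <- mediated_proportion(med_est$beta, med_est$se, total$beta, total$se)
    dplyr::mutate(base,
      zy_beta = e_zy$beta, zy_se = e_zy$se, zy_pval = e_zy$pval,
      mediation_beta = med_est$beta, mediation_se = med_est$se,
      mediation_ci_low = med_est$ci_low, mediation_ci_high = med_est$ci_high,
      mediation_pval = med_est$pval,
      proportion = prop$proportion, proportion_ci_low = prop$ci_low,
      proportion_ci_high = prop$ci_high
    )
  })

  structure(
    list(results = dplyr::bind_rows(rows), total = total,
         log = dplyr::bind_rows(log), seed = seed),
    class = "mr_mediation"
  )
}

#' @export
print.mr_mediation <- function(x, ...) {
  cat("Two-step MR mediation analysis\n")
  cat(sprintf("Total effect: %.3f (95%% CI %.3f to %.3f)\n",
              x$total$beta, x$total$ci_low, x$total$ci_high))
  print(dplyr::select(x$results, "mediator", "status", "mediation_beta",
                      "proportion"), ...)
  invisible(x)
}
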