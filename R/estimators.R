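#' Per-SNP Wald ratio estimates
#'
#' The building block of every univariate estimator: per variant, the ratio
#' of the outcome effect to the exposure effect, with first-order
#' delta-method standard error `se_out / |beta_exp|`. Variants with a zero
#' exposure effect are excluded with a warning.
#'
#' @param h Harmonized tibble (see [harmonize()]).
#' @return Tibble with `variant_id`, `ratio`, `ratio_se`, `weight`
#'   (inverse-variance of the ratio).
#' @export
wald_ratios <- function(h) {
  zero <- h$beta_exp == 0
  if (any(zero)) {
    warn(sprintf("%d variant(s) with zero exposure effect excluded", sum(zero)))
    h <- h[!zero, ]
  }
  tibble::tibble(
    variant_id = h$variant_id,
    ratio = h$beta_out / h$beta_exp,
    ratio_se = h$se_out / abs(h$beta_exp),
    weight = h$beta_exp^2 / h$se_out^2
  )
}

#' Inverse-variance-weighted estimator
#'
#' Weighted least squares of the outcome effects on the exposure effects
#' through the origin with weights `1/se_out^2` (equivalently the
#' inverse-variance-weighted mean of the Wald ratios under first-order
#' ratio SEs). Fixed-effects SE is \eqn{1/\sqrt{\sum \beta_{x,i}^2/se_{y,i}^2}};
#' the random-effects (multiplicative) model returns the same point estimate
#' with the SE inflated by \eqn{\max(1, \sqrt{Q/(k-1)})}, so it can never be
#' smaller than the fixed-effects SE. Random effects is the default, the
#' primary analysis model.
#'
#' @param h Harmonized tibble.
#' @param effects `"random"` (default) or `"fixed"`.
#' @return One-row estimate tibble (`method, beta, se, ci_low, ci_high,
#'   pval, n_snp`).
#' @export
mr_ivw <- function(h, effects = c("random", "fixed")) {
  effects <- match.arg(effects)
  h <- h[h$beta_exp != 0, ]
  k <- nrow(h)
  if (k < 1) abort("IVW requires at least one instrument", class = "mrpath_input_error")
  w <- 1 / h$se_out^2
  beta <- sum(w * h$beta_exp * h$beta_out) / sum(w * h$beta_exp^2)
  se_fixed <- 1 / sqrt(sum(w * h$beta_exp^2))
  if (effects == "random" && k > 1) {
    q <- sum(w * (h$beta_out - beta * h$beta_exp)^2)
    se <- se_fixed * max(1, sqrt(q / (k - 1)))
  } else {
    se <- se_fixed
  }
  new_estimate(paste0("ivw_", effects), beta, se, k)
}

#' MR-Egger regression
#'
#' Weighted regression of outcome on exposure effects with an intercept
#' (weights `1/se_out^2`), after orienting every exposure effect to be
#' non-negative (the signs of both effects are flipped together where
#' needed; the intercept's sign depends on this convention). The intercept
#' estimates the average directional pleiotropy and its two-sided p-value is
#' the pleiotropy test; the slope is the pleiotropy-corrected causal effect,
#' valid under the InSIDE assumption. Both SEs carry the multiplicative
#' overdispersion inflation \eqn{\max(1, \sqrt{Q_{egger}/(k-2)})}.
#'
#' @param h Harmonized tibble; needs at least 3 instruments.
#' @return List with `slope` (estimate tibble) and `intercept`
#'   (one-row tibble: `estimate, se, ci_low, ci_high, pval`).
#' @export
mr_egger <- function(h) {
  h <- h[h$beta_exp != 0, ]
  k <- nrow(h)
  if (k < 3) abort("insufficient instruments for Egger (k >= 3 required)",
                   class = "mrpath_input_error")
  flip <- h$beta_exp < 0
  bx <- ifelse(flip, -h$beta_exp, h$beta_exp)
  by <- ifelse(flip, -h$beta_out, h$beta_out)
  w <- 1 / h$se_out^2
  x <- cbind(intercept = 1, slope = bx)
  xtwx <- crossprod(x, w * x)
  coefs <- solve(xtwx, crossprod(x, w * by))
  resid <- by - x %*% coefs
  q_egger <- sum(w * resid^2)
  phi <- max(1, q_egger / (k - 2))
  ses <- sqrt(diag(solve(xtwx)) * phi)
  b0 <- unname(coefs["intercept", 1]); b1 <- unname(coefs["slope", 1])
  se0 <- unname(ses["intercept"]); se1 <- unname(ses["slope"])
  ci <- ci_bounds(b0, se0)
  list(
    slope = new_estimate("egger", b1, se1, k),
    intercept = tibble::tibble(
      estimate = b0, se = se0, ci_low = ci$low, ci_high = ci$high,
      pval = two_sided_p(b0 / se0)
    )
  )
}

# Weighted median of ratios at cumulative weight 0.5 with linear
# interpolation: p_i = (cumsum(w) - w/2)/sum(w) over sorted ratios.
weighted_median_point <- function(ratio, weight) {
  ord <- order(ratio)
  r <- ratio[ord]
  w <- weight[ord] / sum(weight)
  p <- cumsum(w) - w / 2
  if (0.5 <= p[1]) return(r[1])
  if (0.5 >= p[length(p)]) return(r[length(r)])
  stats::approx(p, r, xout = 0.5, ties = mean)$y
}

median_bootstrap_se <- function(h, weights_fun, n_boot, seed) {
  with_seed(seed, {
    k <- nrow(h)
    est <- vapply(seq_len(n_boot), function(b) {
      bx <- rnorm(k, h$beta_exp, h$se_exp)
      by <- rnorm(k, h$beta_out, h$se_out)
      keep <- bx != 0
      weighted_median_point(by[keep] / bx[keep], weights_fun(bx[keep], h$se_out[keep]))
    }, numeric(1))
    sd(est)
  })
}

#' Weighted median estimator
#'
#' Consistent when variants carrying at least half the total
#' inverse-variance weight are valid instruments. The estimate is the
#' ratio at cumulative normalized weight 0.5 over the sorted Wald ratios,
#' linearly interpolated between bracketing variants; the SE comes from a
#' seeded parametric bootstrap (per-SNP effects resampled from their normal
#' sampling distributions).
#'
#' @param h Harmonized tibble; needs at least 3 instruments.
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed RNG seed for the bootstrap.
#' @return One-row estimate tibble.
#' @export
mr_weighted_median <- function(h, n_boot = 1000, seed = 1L) {
  h <- h[h$beta_exp != 0, ]
  k <- nrow(h)
  if (k < 3) abort("median estimators require k >= 3", class = "mrpath_input_error")
  wr <- wald_ratios(h)
  beta <- weighted_median_point(wr$ratio, wr$weight)
  se <- median_bootstrap_se(h, function(bx, sy) bx^2 / sy^2, n_boot, seed)
  new_estimate("weighted_median", beta, se, k)
}

#' Simple median estimator
#'
#' The unweighted median of the Wald ratios (the weighted median with equal
#' weights): the middle ratio for odd k, the mean of the two middle ratios
#' for even k. Bootstrap SE as in [mr_weighted_median()].
#'
#' @inheritParams mr_weighted_median
#' @return One-row estimate tibble.
#' @export
mr_simple_median <- function(h, n_boot = 1000, seed = 1L) {
  h <- h[h$beta_exp != 0, ]
  k <- nrow(h)
  if (k < 3) abort("median estimators require k >= 3", class = "mrpath_input_error")
  wr <- wald_ratios(h)
  beta <- weighted_median_point(wr$ratio, rep(1, k))
  se <- median_bootstrap_se(h, function(bx, sy) rep(1, length(bx)), n_boot, seed)
  new_estimate("simple_median", beta, se, k)
}

huber_rho <- function(t, c = 1.345) {
  ifelse(abs(t) <= c, t^2 / 2, c * abs(t) - c^2 / 2)
}

#' Robust adjusted profile score (RAPS) estimator
#'
#' Maximizes the profile likelihood of the causal slope `b` over
#' standardized residuals
#' \eqn{t_i(b, \tau^2) = (\beta_{y,i} - b\,\beta_{x,i}) /
#' \sqrt{se_{y,i}^2 + b^2 se_{x,i}^2 + \tau^2}}: profiling the latent
#' per-variant instrument effects out of the bivariate normal likelihood
#' leaves \eqn{-\tfrac12 \sum_i t_i^2}, whose maximizer accounts for
#' sampling error in the exposure effects and so removes the
#' regression-dilution bias IVW suffers under weak instruments. With
#' `overdispersion = TRUE` (default) a systematic-pleiotropy variance
#' \eqn{\tau^2 \ge 0} is estimated alongside by the moment condition that
#' the standardized residuals have unit scale; an optional Huber loss on
#' \eqn{t_i} downweights outlying variants (with the matching
#' standard-normal consistency constant in the moment condition). The SE is
#' the sandwich estimate built from the per-variant profile scores. The
#' solve alternates deterministic one-dimensional optimizations starting
#' from the fixed-effects IVW value.
#'
#' @param h Harmonized tibble; needs at least 3 instruments.
#' @param overdispersion Estimate tau^2 (default TRUE).
#' @param loss `"l2"` (default) or `"huber"`.
#' @return One-row estimate tibble.
#' @export
mr_raps <- function(h, overdispersion = TRUE, loss = c("l2", "huber")) {
  loss <- match.arg(loss)
  h <- h[h$beta_exp != 0, ]
  k <- nrow(h)
  if (k < 3) abort("RAPS requires k >= 3", class = "mrpath_input_error")
  bx <- h$beta_exp; sx <- h$se_exp; by <- h$beta_out; sy <- h$se_out
  rho <- if (loss == "l2") function(t) t^2 / 2 else huber_rho

  # profiling the latent instrument effects out of the bivariate normal
  # likelihood leaves -(1/2) sum t_i(b)^2 with
  # t_i = (by - b bx)/sqrt(sy^2 + b^2 sx^2 + tau^2); no log-variance term
  tstat <- function(b, tau2) (by - b * bx) / sqrt(sy^2 + b^2 * sx^2 + tau2)
  objective <- function(b, tau2) sum(rho(tstat(b, tau2)))
  # E[psi(Z) Z] for a standard normal Z: 1 under l2, < 1 under Huber
  psi_z_mean <- if (loss == "l2") 1 else {
    stats::integrate(function(z) pmin(abs(z), 1.345) * abs(z) * stats::dnorm(z),
                     -Inf, Inf)$value
  }

  b0 <- sum(by * bx / sy^2) / sum(bx^2 / sy^2)
  b_range <- b0 + c(-1, 1) * max(1, 10 * abs(b0))
  tau_max <- 10 * stats::var(by) + 10 * mean(sy^2)
  psi <- if (loss == "l2") function(t) t else function(t) pmax(pmin(t, 1.345), -1.345)

  tau2 <- 0
  beta <- b0
  for (iter in seq_len(50)) {
    beta_new <- optimize(function(b) objective(b, tau2), interval = b_range,
                         tol = 1e-12)$minimum
    tau2_new <- tau2
    if (overdispersion) {
      # moment condition: mean psi(t) t equals its standard-normal expectation
      gap <- function(t2) mean(psi(tstat(beta_new, t2)) * tstat(beta_new, t2)) - psi_z_mean
      tau2_new <- if (gap(0) <= 0) 0 else {
        stats::uniroot(gap, c(0, tau_max), tol = 1e-12)$root
      }
    }
    done <- abs(beta_new - beta) < 1e-7 * max(1, abs(beta)) &&
      abs(tau2_new - tau2) < 1e-9 * max(1e-4, tau2)
    beta <- beta_new
    tau2 <- tau2_new
    if (done) break
    if (iter == 50) abort("RAPS failed to converge in 50 iterations",
                          class = "mrpath_convergence_error")
  }
  if (abs(beta - b_range[1]) < 1e-8 || abs(beta - b_range[2]) < 1e-8) {
    abort("RAPS solution at the search boundary: optimization failed",
          class = "mrpath_convergence_error")
  }
  # sandwich SE: bread = curvature of the profile objective, meat = sum of
  # squared per-variant profile scores, both at (beta, tau2)
  eps <- 1e-5 * max(1, abs(beta))
  dt_db <- (tstat(beta + eps, tau2) - tstat(beta - eps, tau2)) / (2 * eps)
  s_i <- psi(tstat(beta, tau2)) * dt_db
  bread <- (objective(beta + eps, tau2) - 2 * objective(beta, tau2) +
              objective(beta - eps, tau2)) / eps^2
  if (!is.finite(bread) || bread <= 0) bread <- sum(dt_db^2)
  se <- sqrt(sum(s_i^2)) / bread
  if (!is.finite(se) || se <= 0) {
    abort("RAPS sandwich standard error not positive",
          class = "mrpath_convergence_error")
  }
  new_estimate(paste0("raps", if (loss == "huber") "_huber" else ""), beta, se, k)
}

#' Cochran's Q heterogeneity test and I-squared
#'
#' Q is the inverse-variance-weighted squared deviation of the per-SNP Wald
#' ratios around the IVW estimate (first-order ratio weights); under
#' homogeneity it is asymptotically chi-squared with k-1 degrees of
#' freedom. I^2 = max(0, (Q - df)/Q) is the fraction of excess variation.
#'
#' @param h Harmonized tibble.
#' @return List with `q`, `df`, `pval`, `i_squared`.
#' @export
cochran_q <- function(h) {
  h <- h[h$beta_exp != 0, ]
  k <- nrow(h)
  if (k < 2) abort("Q requires k >= 2", class = "mrpath_input_error")
  wr <- wald_ratios(h)
  beta <- sum(wr$weight * wr$ratio) / sum(wr$weight)
  q <- sum(wr$weight * (wr$ratio - beta)^2)
  df <- k - 1
  list(q = q, df = df, pval = pchisq(q, df, lower.tail = FALSE),
       i_squared = max(0, (q - df) / q))
}

#' Leave-one-out analysis
#'
#' Recomputes the random-effects IVW estimate k times, omitting each
#' variant in turn, and flags omissions that flip the sign of the estimate
#' or change its significance at 0.05 relative to the full panel.
#'
#' @param h Harmonized tibble with k >= 2.
#' @return Tibble with one row per omitted variant (`omitted`, the estimate
#'   columns, `sign_flip`, `significance_change`).
#' @export
leave_one_out <- function(h) {
  h <- h[h$beta_exp != 0, ]
  k <- nrow(h)
  if (k < 2) abort("leave-one-out requires k >= 2", class = "mrpath_input_error")
  full <- mr_ivw(h)
  rows <- purrr::map(seq_len(k), function(i) {
    est <- mr_ivw(h[-i, ])
    dplyr::mutate(est, omitted = h$variant_id[i], .before = 1)
  })
  out <- dplyr::bind_rows(rows)
  dplyr::mutate(out,
    sign_flip = sign(.data$beta) != sign(full$beta),
    significance_change = (.data$pval < 0.05) != (full$pval < 0.05)
  )
}

#' MR-PRESSO: pleiotropy residual sum of squares and outlier test
#'
#' Global test: the observed residual sum of squares
#' \eqn{RSS = \sum_i w_i (\beta_{y,i} - \hat b_{(-i)} \beta_{x,i})^2}
#' (each variant's residual taken against the leave-one-out IVW slope,
#' weights `1/se_out^2`) is compared with its parametric null distribution,
#' obtained by redrawing outcome effects from
#' \eqn{N(\hat b_{(-i)}\beta_{x,i}, se_{y,i}^2)} `n_sim` times and
#' recomputing the statistic (including the leave-one-out slopes) on each
#' draw. Outlier test: each variant's observed residual contribution gets an
#' empirical p-value against its simulated contributions,
#' Bonferroni-adjusted over k; variants below `outlier_p` are flagged.
#' Distortion test: the change in the IVW estimate after removing flagged
#' outliers is compared with the changes produced by removing equally many
#' variants at random. All randomness is seeded; empirical p-values use the
#' add-one rank convention.
#'
#' @param h Harmonized tibble with k >= 4.
#' @param n_sim Parametric draws for the null distributions (default 1000).
#' @param seed RNG seed.
#' @param outlier_p Threshold on the Bonferroni-adjusted per-SNP p.
#' @return List with `global_rss`, `global_pval`, `outliers` (variant IDs),
#'   `outlier_pvals`, `adjusted` (IVW on the pruned panel, or NULL),
#'   `distortion_pval` (NULL when nothing is flagged).
#' @export
mr_presso <- function(h, n_sim = 1000, seed = 1L, outlier_p = 0.05) {
  h <- h[h$beta_exp != 0, ]
  k <- nrow(h)
  if (k < 4) abort("MR-PRESSO requires k >= 4", class = "mrpath_input_error")
  if (n_sim < 100) warn("n_sim < 100 gives coarse empirical p-values")
  bx <- h$beta_exp; by <- h$beta_out; sy <- h$se_out
  w <- 1 / sy^2

  loo_slopes <- function(y) {
    s1 <- sum(w * bx * y); s2 <- sum(w * bx^2)
    (s1 - w * bx * y) / (s2 - w * bx^2)
  }
  b_loo <- loo_slopes(by)
  contrib_obs <- w * (by - b_loo * bx)^2
  rss_obs <- sum(contrib_obs)

  res <- with_seed(seed, {
    mu <- b_loo * bx
    ysim <- matrix(rnorm(k * n_sim, mu, sy), k, n_sim)
    s1s <- colSums(w * bx * ysim)
    s2 <- sum(w * bx^2)
    bloos <- (matrix(s1s, k, n_sim, byrow = TRUE) - (w * bx) * ysim) /
      (s2 - w * bx^2)
    contrib_sim <- w * (ysim - bloos * bx)^2
    rss_sim <- colSums(contrib_sim)
    list(rss_sim = rss_sim, contrib_sim = contrib_sim)
  })
  global_p <- (1 + sum(res$rss_sim >= rss_obs)) / (n_sim + 1)

  p_snp <- (1 + rowSums(res$contrib_sim >= contrib_obs)) / (n_sim + 1)
  p_adj <- pmin(1, p_snp * k)
  flagged <- which(p_adj < outlier_p)

  adjusted <- NULL
  distortion_p <- NULL
  if (length(flagged) > 0 && length(flagged) < k - 1) {
    adjusted <- mr_ivw(h[-flagged, ])
    b_all <- mr_ivw(h)$beta
    d_obs <- adjusted$beta - b_all
    s1 <- sum(w * bx * by); s2 <- sum(w * bx^2)
    d_null <- with_seed(child_seed(seed, 1L), {
      vapply(seq_len(n_sim), function(s) {
        idx <- sample.int(k, length(flagged))
        (s1 - sum(w[idx] * bx[idx] * by[idx])) /
          (s2 - sum(w[idx] * bx[idx]^2)) - b_all
      }, numeric(1))
    })
    distortion_p <- (1 + sum(abs(d_null) >= abs(d_obs))) / (n_sim + 1)
  }

  list(
    global_rss = rss_obs,
    global_pval = global_p,
    outliers = h$variant_id[flagged],
    outlier_pvals = setNames(p_adj, h$variant_id),
    adjusted = adjusted,
    distortion_pval = distortion_p
  )
}

#' Run a roster of univariate MR estimators
#'
#' Convenience wrapper returning one tidy row per requested method.
#'
#' @param h Harmonized tibble.
#' @param methods Subset of `c("ivw", "ivw_fixed", "egger",
#'   "weighted_median", "simple_median", "raps")`.
#' @param n_boot Bootstrap replicates for the median estimators.
#' @param seed RNG seed for stochastic SEs.
#' @return Estimate tibble, one row per method.
#' @export
mr_estimates <- function(h,
                         methods = c("ivw", "egger", "weighted_median",
                                     "simple_median", "raps"),
                         n_boot = 1000, seed = 1L) {
  rows <- purrr::imap(setNames(methods, methods), function(m, i) {
    stream <- child_seed(seed, match(m, methods))
    switch(m,
      ivw = mr_ivw(h, "random"),
      ivw_fixed = mr_ivw(h, "fixed"),
      egger = mr_egger(h)$slope,
      weighted_median = mr_weighted_median(h, n_boot, stream),
      simple_median = mr_simple_median(h, n_boot, stream),
      raps = mr_raps(h),
      abort(paste0("unknown method: ", m), class = "mrpath_config_error")
    )
  })
  dplyr::bind_rows(rows)
}
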