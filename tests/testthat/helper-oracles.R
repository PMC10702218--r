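# Independent oracles used to cross-check the estimators. These are kept
# deliberately naive (lm fits, dense scans, KKT enumeration) and never call
# the implementation under test.

# WLS through the origin via lm(): the IVW oracle.
oracle_ivw <- function(bx, by, sy) {
  fit <- lm(by ~ 0 + bx, weights = 1 / sy^2)
  s <- summary(fit)
  k <- length(bx)
  sigma <- s$sigma
  se_fixed <- s$coefficients[1, 2] / sigma
  list(beta = unname(coef(fit)[1]),
       se_fixed = unname(se_fixed),
       se_random = unname(se_fixed * max(1, sigma)))
}

# Weighted lm with intercept: the Egger oracle.
oracle_egger <- function(bx, by, sy) {
  flip <- bx < 0
  bx <- ifelse(flip, -bx, bx)
  by <- ifelse(flip, -by, by)
  fit <- lm(by ~ bx, weights = 1 / sy^2)
  s <- summary(fit)
  sigma <- s$sigma
  list(intercept = unname(coef(fit)[1]),
       slope = unname(coef(fit)[2]),
       se_slope = unname(s$coefficients[2, 2] / min(1, sigma)),
       se_intercept = unname(s$coefficients[1, 2] / min(1, sigma)))
}

# Dense cumulative-weight scan for the weighted median: walks a fine grid of
# quantile levels and interpolates by hand.
oracle_weighted_median <- function(ratio, weight) {
  ord <- order(ratio)
  r <- ratio[ord]
  w <- weight[ord] / sum(weight)
  p <- cumsum(w) - w / 2
  if (0.5 <= p[1]) return(r[1])
  if (0.5 >= p[length(p)]) return(r[length(r)])
  i <- max(which(p < 0.5))
  r[i] + (r[i + 1] - r[i]) * (0.5 - p[i]) / (p[i + 1] - p[i])
}

# KKT enumeration for the K = 2 weighted LASSO (no intercept):
#   min_b (1/(2n)) sum w_i (y_i - x_i' b)^2 + lam1 |b1| + lam2 |b2|
# Enumerates active sets and sign patterns and returns the solution whose
# KKT conditions hold.
oracle_lasso_k2 <- function(x, y, w, lam) {
  n <- length(y)
  a <- crossprod(x, w * x) / n
  cvec <- drop(crossprod(x, w * y)) / n
  ok <- function(b) {
    g <- drop(a %*% b) - cvec
    all(vapply(1:2, function(j) {
      if (abs(b[j]) > 1e-12) abs(g[j] + lam[j] * sign(b[j])) < 1e-8
      else abs(g[j]) <= lam[j] + 1e-8
    }, logical(1)))
  }
  cands <- list(c(0, 0))
  for (s in c(-1, 1)) {
    cands <- c(cands,
               list(c((cvec[1] - lam[1] * s) / a[1, 1], 0)),
               list(c(0, (cvec[2] - lam[2] * s) / a[2, 2])))
  }
  for (s1 in c(-1, 1)) for (s2 in c(-1, 1)) {
    b <- tryCatch(solve(a, cvec - lam * c(s1, s2)), error = function(e) NULL)
    if (!is.null(b)) cands <- c(cands, list(b))
  }
  for (b in cands) if (ok(b)) return(b)
  stop("no KKT point found")
}

# Build a harmonized tibble directly from effect vectors.
toy_harmonized <- function(bx, by, sx = 0.01, sy = 0.01, eaf = NULL) {
  k <- length(bx)
  tibble::tibble(
    variant_id = sprintf("rs%03d", seq_len(k)),
    chrom = "1",
    pos = seq_len(k) * 2e7,
    effect_allele = "A",
    other_allele = "G",
    eaf = eaf %||% rep(0.3, k),
    beta_exp = bx,
    se_exp = rep_len(sx, k),
    beta_out = by,
    se_out = rep_len(sy, k),
    allele_flipped = FALSE,
    strand_flipped = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Harmonized panel drawn from the generator (noisy, known truth).
sim_harmonized <- function(n_snps = 50, causal = 0.3, seed = 1, ...) {
  sim <- simulate_pair(sim_config(n_snps = n_snps, causal_effect = causal,
                                  seed = seed, ...))
  harmonize(sim$exposure, sim$outcome)
}
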