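test_that("Wald ratios match hand division and flag zero exposure effects", {
  h <- toy_harmonized(bx = c(0.10, 0.2, -0.1), by = c(0.05, 0, 0.02))
  wr <- wald_ratios(h)
  expect_equal(wr$ratio, c(0.5, 0, -0.2))
  expect_equal(wr$ratio_se, h$se_out / abs(h$beta_exp))
  hz <- toy_harmonized(bx = c(0.1, 0), by = c(0.05, 0.01))
  expect_warning(wr2 <- wald_ratios(hz), "zero exposure effect")
  expect_equal(nrow(wr2), 1)
})

test_that("IVW with one instrument equals its Wald ratio", {
  h <- toy_harmonized(bx = 0.1, by = 0.05, sy = 0.02)
  est <- mr_ivw(h)
  expect_equal(est$beta, 0.5)
  expect_equal(est$se, 0.02 / 0.1)
})

test_that("IVW equals the closed-form WLS oracle; fixed and random share beta", {
  set.seed(7)
  for (rep in 1:5) {
    k <- sample(5:40, 1)
    bx <- rnorm(k, 0, 0.05)
    by <- 0.3 * bx + rnorm(k, 0, 0.01)
    sy <- runif(k, 0.005, 0.02)
    h <- toy_harmonized(bx = bx, by = by, sy = sy)
    fixed <- mr_ivw(h, "fixed")
    random <- mr_ivw(h, "random")
    o <- oracle_ivw(bx, by, sy)
    expect_equal(fixed$beta, o$beta, tolerance = 1e-10)
    expect_equal(random$beta, o$beta, tolerance = 1e-10)
    expect_equal(fixed$se, o$se_fixed, tolerance = 1e-10)
    expect_equal(random$se, o$se_random, tolerance = 1e-10)
    expect_gte(random$se, fixed$se)
  }
})

test_that("homogeneous ratios give Q = 0 and identical fixed/random SE", {
  bx <- c(0.1, 0.2, 0.4)
  h <- toy_harmonized(bx = bx, by = 0.25 * bx)
  expect_equal(mr_ivw(h, "fixed")$se, mr_ivw(h, "random")$se)
  expect_equal(mr_ivw(h)$beta, 0.25)
})

test_that("Egger matches the weighted-lm oracle and its exact identities", {
  set.seed(11)
  k <- 20
  bx <- rnorm(k, 0.05, 0.03)
  by <- 0.01 + 0.4 * bx + rnorm(k, 0, 0.005)
  sy <- runif(k, 0.004, 0.01)
  h <- toy_harmonized(bx = bx, by = by, sy = sy)
  e <- mr_egger(h)
  o <- oracle_egger(bx, by, sy)
  expect_equal(e$slope$beta, o$slope, tolerance = 1e-10)
  expect_equal(e$slope$se, o$se_slope, tolerance = 1e-10)
  expect_equal(e$intercept$estimate, o$intercept, tolerance = 1e-10)
  expect_equal(e$intercept$se, o$se_intercept, tolerance = 1e-10)
  # noiseless, no pleiotropy: intercept exactly 0, slope exactly causal
  h0 <- toy_harmonized(bx = bx, by = 0.4 * bx, sy = sy)
  e0 <- mr_egger(h0)
  expect_equal(e0$intercept$estimate, 0, tolerance = 1e-12)
  expect_equal(e0$slope$beta, 0.4, tolerance = 1e-12)
  # orientation convention: pre-flipping exposure signs changes nothing
  flip <- rep(c(1, -1), length.out = k)
  hf <- toy_harmonized(bx = flip * bx, by = flip * by, sy = sy)
  ef <- mr_egger(hf)
  expect_equal(ef$slope$beta, e$slope$beta, tolerance = 1e-12)
  expect_equal(ef$intercept$estimate, e$intercept$estimate, tolerance = 1e-12)
  expect_error(mr_egger(toy_harmonized(bx = c(0.1, 0.2), by = c(0, 0))),
               class = "mrpath_input_error")
})

test_that("Egger intercept recovers planted directional pleiotropy", {
  # effects oriented to the exposure-increasing allele, as instrument lists
  # are published: directional pleiotropy is only identified under a
  # consistent allele orientation
  ints <- vapply(1:60, function(s) {
    h <- sim_harmonized(n_snps = 80, causal = 0.3, seed = s,
                        n_outcome = 37037,
                        instrument_effect = function(n) abs(rnorm(n, 0, 0.035)),
                        pleiotropy_mode = "directional",
                        pleiotropy_mean = 0.01, pleiotropy_scale = 0.01)
    mr_egger(h)$intercept$estimate
  }, numeric(1))
  expect_lt(abs(mean(ints) - 0.01), 3 * sd(ints) / sqrt(length(ints)))
})

test_that("weighted median follows the cumulative-weight convention", {
  h <- toy_harmonized(bx = c(1, 1, 1), by = c(0.1, 0.2, 0.9), sy = 1)
  expect_equal(mr_weighted_median(h, n_boot = 50)$beta, 0.2)
  expect_equal(mr_simple_median(h, n_boot = 50)$beta, 0.2)
  # unequal weights: check against the independent scan
  sy <- c(sqrt(2), 2, 2)  # weights 0.5, 0.25, 0.25 after normalization
  h2 <- toy_harmonized(bx = c(1, 1, 1), by = c(0.1, 0.2, 0.9), sy = sy)
  wm <- mr_weighted_median(h2, n_boot = 50)
  expect_equal(wm$beta, oracle_weighted_median(c(0.1, 0.2, 0.9), c(0.5, 0.25, 0.25)),
               tolerance = 1e-12)
  expect_equal(wm$beta, 0.1 + 0.1 * (0.5 - 0.25) / 0.375, tolerance = 1e-12)
})

test_that("median conventions: odd middle value, even midpoint, random oracle", {
  h_odd <- toy_harmonized(bx = rep(1, 5), by = c(0.5, 0.1, 0.3, 0.9, 0.2), sy = 1)
  expect_equal(mr_simple_median(h_odd, n_boot = 50)$beta, 0.3)
  h_even <- toy_harmonized(bx = rep(1, 4), by = c(0.1, 0.4, 0.2, 0.8), sy = 1)
  expect_equal(mr_simple_median(h_even, n_boot = 50)$beta, 0.3)
  set.seed(21)
  for (rep in 1:10) {
    k <- sample(4:30, 1)
    r <- rnorm(k)
    w <- runif(k)
    h <- toy_harmonized(bx = rep(1, k), by = r, sy = 1 / sqrt(w))
    expect_equal(mr_weighted_median(h, n_boot = 10)$beta,
                 oracle_weighted_median(r, w), tolerance = 1e-10)
  }
})

test_that("weighted median resists <50% contamination that moves IVW", {
  h <- sim_harmonized(n_snps = 50, causal = 0.3, seed = 2, n_outcome = 37037)
  bad <- 1:20
  h$beta_out[bad] <- h$beta_out[bad] + 0.5
  ivw_shift <- abs(mr_ivw(h)$beta - 0.3)
  wm_shift <- abs(mr_weighted_median(h, n_boot = 50, seed = 1)$beta - 0.3)
  expect_gt(ivw_shift, 0.1)
  expect_lt(wm_shift, ivw_shift / 2)
  expect_lt(wm_shift, 0.1)
})

test_that("median bootstrap SEs are seed-reproducible", {
  h <- sim_harmonized(n_snps = 30, causal = 0.2, seed = 6)
  a <- mr_weighted_median(h, n_boot = 200, seed = 99)
  b <- mr_weighted_median(h, n_boot = 200, seed = 99)
  expect_identical(a, b)
  c <- mr_weighted_median(h, n_boot = 200, seed = 100)
  expect_false(identical(a$se, c$se))
})

test_that("RAPS limiting cases: IVW-fixed at zero exposure noise, exact truth", {
  set.seed(13)
  k <- 25
  bx <- rnorm(k, 0, 0.05)
  by <- 0.3 * bx + rnorm(k, 0, 0.008)
  sy <- runif(k, 0.005, 0.015)
  h <- toy_harmonized(bx = bx, by = by, sx = 1e-12, sy = sy)
  raps <- mr_raps(h, overdispersion = FALSE)
  ivw <- mr_ivw(h, "fixed")
  expect_equal(raps$beta, ivw$beta, tolerance = 1e-6)
  # noiseless data return the causal effect essentially exactly
  h0 <- toy_harmonized(bx = bx, by = 0.3 * bx, sx = 1e-12, sy = sy)
  expect_equal(mr_raps(h0, overdispersion = FALSE)$beta, 0.3, tolerance = 1e-6)
  expect_equal(mr_raps(h0, overdispersion = TRUE)$beta, 0.3, tolerance = 1e-6)
})

test_that("RAPS is less biased than IVW under weak instruments", {
  res <- vapply(1:150, function(s) {
    h <- sim_harmonized(n_snps = 40, causal = 0.4, seed = s,
                        n_exposure = 20000, n_outcome = 37037,
                        instrument_effect = list(dist = "normal", mean = 0, sd = 0.015))
    c(ivw = mr_ivw(h)$beta, raps = mr_raps(h)$beta)
  }, numeric(2))
  bias_ivw <- abs(mean(res["ivw", ]) - 0.4)
  bias_raps <- abs(mean(res["raps", ]) - 0.4)
  expect_lt(bias_raps, bias_ivw)
})

test_that("huber-loss RAPS tolerates a gross outlier better than l2", {
  h <- sim_harmonized(n_snps = 40, causal = 0.3, seed = 5, n_outcome = 37037)
  h$beta_out[1] <- h$beta_out[1] + 1
  l2 <- mr_raps(h, loss = "l2")
  hub <- mr_raps(h, loss = "huber")
  expect_lt(abs(hub$beta - 0.3), abs(l2$beta - 0.3) + 0.02)
  expect_equal(hub$method, "raps_huber")
})

test_that("estimators are scale- and sign-equivariant", {
  h <- sim_harmonized(n_snps = 30, causal = 0.25, seed = 8)
  ests <- mr_estimates(h, n_boot = 100, seed = 3)
  # outcome scaling by c > 0 scales beta and se by c
  c0 <- 3.7
  h_scaled <- dplyr::mutate(h, beta_out = beta_out * c0, se_out = se_out * c0)
  ests_scaled <- mr_estimates(h_scaled, n_boot = 100, seed = 3)
  expect_equal(ests_scaled$beta, ests$beta * c0, tolerance = 1e-6)
  expect_equal(ests_scaled$se, ests$se * c0, tolerance = 1e-4)
  # negating exposure betas negates every estimate
  h_neg <- dplyr::mutate(h, beta_exp = -beta_exp)
  ests_neg <- mr_estimates(h_neg, n_boot = 100, seed = 3)
  expect_equal(ests_neg$beta, -ests$beta, tolerance = 1e-6)
})
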