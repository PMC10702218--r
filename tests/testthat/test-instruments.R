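toy_stats <- function(pval, pos = seq_along(pval) * 2e7, chrom = "1",
                      ea = "A", oa = "G", eaf = 0.3, id = NULL) {
  k <- length(pval)
  tibble::tibble(
    variant_id = id %||% sprintf("rs%03d", seq_len(k)),
    chrom = rep_len(chrom, k), pos = pos,
    effect_allele = rep_len(ea, k), other_allele = rep_len(oa, k),
    eaf = rep_len(eaf, k), beta = 0.1, se = 0.01, pval = pval, n = 10000L
  )
}

test_that("significance threshold keeps P < 5e-8 only", {
  stats <- toy_stats(c(1e-9, 1e-7, 1e-10))
  sel <- select_instruments(stats)
  expect_setequal(sel$variant_id, c("rs001", "rs003"))
})

test_that("greedy clumping keeps the lowest p-value within an LD block", {
  stats <- toy_stats(c(1e-9, 1e-12), pos = c(1000, 2000))
  ld <- matrix(c(1, 0.9, 0.9, 1), 2, dimnames = list(stats$variant_id, stats$variant_id))
  sel <- select_instruments(stats, ld = ld)
  expect_equal(sel$variant_id, "rs002")
  # independent SNPs at the same distance are both kept
  ld0 <- matrix(c(1, 0, 0, 1), 2, dimnames = list(stats$variant_id, stats$variant_id))
  expect_equal(nrow(select_instruments(stats, ld = ld0)), 2)
  # far apart, high R^2: outside the window, both kept
  far <- toy_stats(c(1e-9, 1e-12), pos = c(1000, 2e7))
  expect_equal(nrow(select_instruments(far, ld = ld)), 2)
})

test_that("palindrome and exclusion filters remove the expected rows", {
  stats <- toy_stats(rep(1e-9, 10))
  stats$effect_allele[3] <- "A"; stats$other_allele[3] <- "T"
  stats$effect_allele[7] <- "C"; stats$other_allele[7] <- "G"
  cfg <- selection_config(exclusion_list = "rs005")
  sel <- select_instruments(stats, cfg)
  expect_equal(nrow(sel), 7)
  expect_false(any(c("rs003", "rs005", "rs007") %in% sel$variant_id))
  dropped <- attr(sel, "dropped")
  expect_setequal(dropped$reason[dropped$variant_id %in% c("rs003", "rs007")],
                  "palindromic")
  # opt-in frequency rescue keeps palindromes far from EAF 0.5
  cfg2 <- selection_config(palindrome_eaf_band = 0.1)
  sel2 <- select_instruments(stats, cfg2)
  expect_equal(nrow(sel2), 10)
})

test_that("selection errors when nothing survives, naming the filter", {
  stats <- toy_stats(c(0.5, 0.9))
  expect_error(select_instruments(stats), class = "mrpath_no_instruments")
})

test_that("selection is idempotent and invariant to input row order", {
  set.seed(1)
  stats <- toy_stats(runif(20, 1e-12, 1e-8))
  ld <- diag(20); dimnames(ld) <- list(stats$variant_id, stats$variant_id)
  sel1 <- select_instruments(stats, ld = ld)
  again <- select_instruments(sel1, ld = ld)
  expect_equal(again$variant_id, sel1$variant_id)
  shuffled <- stats[sample(nrow(stats)), ]
  sel2 <- select_instruments(shuffled, ld = ld)
  expect_equal(sel2$variant_id, sel1$variant_id)
})

test_that("harmonization aligns, flips and drops alleles correctly", {
  exp <- toy_stats(rep(1e-9, 5))
  exp$beta <- c(0.10, 0.10, 0.10, 0.10, 0.10)
  out <- exp
  out$beta <- rep(0.05, 5)
  # row 2: swapped alleles; row 3: strand complement; row 4: strand + swap;
  # row 5: incompatible
  out$effect_allele[2] <- "G"; out$other_allele[2] <- "A"; out$beta[2] <- -0.05
  out$eaf[2] <- 0.7
  out$effect_allele[3] <- "T"; out$other_allele[3] <- "C"
  out$effect_allele[4] <- "C"; out$other_allele[4] <- "T"; out$beta[4] <- -0.05
  out$effect_allele[5] <- "T"; out$other_allele[5] <- "G"
  h <- harmonize(exp, out)
  expect_equal(nrow(h), 4)
  expect_equal(h$beta_out, rep(0.05, 4))
  expect_equal(h$allele_flipped, c(FALSE, TRUE, FALSE, TRUE))
  expect_equal(h$eaf_out[2], 0.3)
  expect_equal(attr(h, "dropped")$reason, "incompatible_alleles")
})

test_that("palindromic variants are dropped in harmonization regardless of EAF", {
  exp <- toy_stats(rep(1e-9, 2))
  exp$effect_allele[2] <- "T"; exp$other_allele[2] <- "A"; exp$eaf[2] <- 0.1
  out <- exp
  h <- harmonize(exp, out)
  expect_equal(h$variant_id, "rs001")
  expect_equal(attr(h, "dropped")$reason, "palindromic")
})

test_that("harmonization errors with zero overlap", {
  exp <- toy_stats(rep(1e-9, 3))
  out <- toy_stats(rep(1e-9, 3), id = c("rsX", "rsY", "rsZ"))
  expect_error(harmonize(exp, out), class = "mrpath_harmonize_error")
})

test_that("strand-complementing every outcome row leaves the result unchanged", {
  exp <- toy_stats(rep(1e-9, 6), ea = "A", oa = "G")
  out <- exp; out$beta <- rnorm(6, 0.05, 0.01)
  h1 <- harmonize(exp, out)
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  out2 <- out
  out2$effect_allele <- unname(comp[out$effect_allele])
  out2$other_allele <- unname(comp[out$other_allele])
  h2 <- harmonize(exp, out2)
  expect_equal(h2$beta_out, h1$beta_out)
  expect_true(all(h2$strand_flipped))
})

test_that("swapping outcome alleles with negated beta is an involution", {
  exp <- toy_stats(rep(1e-9, 6))
  out <- exp; out$beta <- rnorm(6, 0.05, 0.01)
  h1 <- harmonize(exp, out)
  out2 <- out
  out2$effect_allele <- out$other_allele
  out2$other_allele <- out$effect_allele
  out2$beta <- -out$beta
  out2$eaf <- 1 - out$eaf
  h2 <- harmonize(exp, out2)
  expect_equal(h2$beta_out, h1$beta_out)
  expect_equal(h2$eaf_out, h1$eaf_out)
  expect_true(all(h2$allele_flipped))
})

test_that("F statistic matches hand arithmetic for a single instrument", {
  h <- toy_harmonized(bx = 0.1, by = 0.05, eaf = 0.3)
  expect_warning(instrument_strength(h, n_exposure = 1000),
                 class = "mrpath_weak_instruments")
  res <- suppressWarnings(instrument_strength(h, n_exposure = 1000))
  expect_equal(res$r2_total, 2 * 0.1^2 * 0.3 * 0.7)
  expect_equal(res$f_statistic, (998 / 1) * (0.0042 / (1 - 0.0042)), tolerance = 1e-10)
  expect_equal(round(res$f_statistic, 2), 4.21)
  expect_equal(res$formula_used, "few_snp")
})

test_that("null effects give zero R^2 and F", {
  h <- toy_harmonized(bx = rep(0, 3), by = rep(0, 3))
  res <- suppressWarnings(instrument_strength(h, n_exposure = 1000))
  expect_equal(res$r2_total, 0)
  expect_equal(res$f_statistic, 0)
})

test_that("many-SNP R^2 matches independent evaluation of the printed form", {
  set.seed(2)
  k <- 12
  n <- 50000
  eaf <- runif(k, 0.1, 0.9)
  se <- 1 / sqrt(2 * n * eaf * (1 - eaf))
  bx <- rnorm(k, 0, 0.05)
  h <- toy_harmonized(bx = bx, by = bx * 0.3, sx = se, eaf = eaf)
  h$se_exp <- se
  res <- instrument_strength(h, n_exposure = n)
  brute <- vapply(seq_len(k), function(i) {
    num <- 2 * eaf[i] * (1 - eaf[i]) * bx[i]^2
    num / (num + 2 * n * eaf[i] * (1 - eaf[i]) * se[i]^2)
  }, numeric(1))
  expect_equal(res$r2_snp, brute, tolerance = 1e-12)
  expect_equal(res$formula_used, "many_snp")
  expect_equal(res$f_statistic,
               ((n - k - 1) / k) * (sum(brute) / (1 - sum(brute))),
               tolerance = 1e-12)
})

test_that("instrument-strength guards: sample size and weak-instrument gate", {
  h <- toy_harmonized(bx = rep(0.1, 5), by = rep(0.05, 5))
  expect_error(instrument_strength(h, n_exposure = 6), class = "mrpath_input_error")
  # deliberately weak panel: expected per-SNP F well below 10
  sim <- simulate_pair(sim_config(n_snps = 30, n_exposure = 5000,
                                  instrument_effect = list(dist = "normal", mean = 0, sd = 0.01),
                                  seed = 3))
  hw <- harmonize(sim$exposure, sim$outcome)
  expect_warning(instrument_strength(hw, n_exposure = 5000),
                 class = "mrpath_weak_instruments")
})
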