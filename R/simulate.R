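#' Configure a synthetic GWAS simulation
#'
#' Builds the configuration object consumed by [simulate_pair()],
#' [simulate_mediation()] and [simulate_mvmr()]. The generator produces
#' two-sample GWAS summary statistics directly (no individual-level
#' genotypes): per-SNP instrument effects on a unit-variance exposure,
#' standard errors from the per-allele variance approximation
#' \eqn{se_i \approx 1/\sqrt{2 N p_i (1-p_i)}}, and outcome effects equal to
#' `causal_effect` times the latent instrument effect plus optional
#' horizontal pleiotropy and independent sampling noise.
#'
#' Defaults emulate a large-biobank behavioural exposure (N = 422,218)
#' against a consortium-scale quantitative outcome, with per-SNP effects
#' drawn from N(0, 0.035^2) on standardized traits and effect-allele
#' frequencies uniform on (0.1, 0.9).
#'
#' @param n_snps Number of independent biallelic SNPs.
#' @param n_exposure,n_outcome GWAS sample sizes for the exposure and
#'   outcome studies (non-overlapping samples).
#' @param causal_effect True causal slope of the exposure on the outcome
#'   (log-odds per unit exposure for binary outcomes).
#' @param instrument_effect Either a function `f(n)` returning `n` latent
#'   per-SNP exposure effects, or a list `list(dist = "normal", mean, sd)`.
#' @param eaf_range Length-2 interval inside (0, 1) for effect-allele
#'   frequencies.
#' @param pleiotropy_mode One of `"none"`, `"balanced"` (zero-mean direct
#'   SNP-outcome effects), `"directional"` (mean `pleiotropy_mean`, violating
#'   the zero-mean but not the InSIDE assumption), or `"correlated"` (mean
#'   proportional to the instrument effect via `pleiotropy_cor`, violating
#'   InSIDE).
#' @param pleiotropy_scale SD of the direct SNP-outcome effects.
#' @param pleiotropy_mean Mean direct effect under `"directional"` mode.
#' @param pleiotropy_cor Proportionality constant linking pleiotropy to the
#'   instrument effect under `"correlated"` mode.
#' @param mediator_chain Optional mediation structure: either a single list
#'   `list(effect_xz=, effect_zy=, direct_effect=)` or a named list of
#'   mediator chains `list(bmi = list(effect_xz=, effect_zy=), ...)` together
#'   with a shared `direct_effect` (see [simulate_mediation()]). Each chain
#'   may set `gamma_sd`, the SD of the mediator's own genetic component.
#' @param palindrome_frac Fraction of SNPs assigned palindromic (A/T or C/G)
#'   allele pairs; default 0 so synthetic panels survive palindrome filters.
#' @param seed Integer RNG seed; every random draw flows through it.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_snps = 100L,
                       n_exposure = 422218L,
                       n_outcome = 898130L,
                       causal_effect = 0,
                       instrument_effect = list(dist = "normal", mean = 0, sd = 0.035),
                       eaf_range = c(0.1, 0.9),
                       pleiotropy_mode = c("none", "balanced", "directional", "correlated"),
                       pleiotropy_scale = 0,
                       pleiotropy_mean = 0,
                       pleiotropy_cor = 0.5,
                       mediator_chain = NULL,
                       palindrome_frac = 0,
                       seed = 1L) {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  if (n_snps < 1) abort("n_snps must be >= 1", class = "mrpath_config_error")
  if (n_exposure < 2 || n_outcome < 2) {
    abort("sample sizes must be >= 2", class = "mrpath_config_error")
  }
  if (length(eaf_range) != 2 || eaf_range[1] <= 0 || eaf_range[2] >= 1 ||
      eaf_range[1] > eaf_range[2]) {
    abort("eaf_range must be an interval inside (0, 1)", class = "mrpath_config_error")
  }
  if (pleiotropy_scale < 0) {
    abort("pleiotropy_scale must be >= 0", class = "mrpath_config_error")
  }
  if (pleiotropy_mode == "directional" && pleiotropy_mean == 0) {
    abort("directional pleiotropy requires a nonzero pleiotropy_mean",
          class = "mrpath_config_error")
  }
  effect_fun <- as_effect_fun(instrument_effect)
  structure(
    list(
      n_snps = as.integer(n_snps),
      n_exposure = as.integer(n_exposure),
      n_outcome = as.integer(n_outcome),
      causal_effect = causal_effect,
      instrument_effect = effect_fun,
      eaf_range = eaf_range,
      pleiotropy_mode = pleiotropy_mode,
      pleiotropy_scale = pleiotropy_scale,
      pleiotropy_mean = pleiotropy_mean,
      pleiotropy_cor = pleiotropy_cor,
      mediator_chain = mediator_chain,
      palindrome_frac = palindrome_frac,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

as_effect_fun <- function(spec) {
  if (is.function(spec)) return(spec)
  if (is.list(spec) && identical(spec$dist, "normal")) {
    mean <- spec$mean %||% 0
    sd <- spec$sd %||% stop()
    return(function(n) rnorm(n, mean, sd))
  }
  if (is.list(spec) && identical(spec$dist, "uniform")) {
    return(function(n) runif(n, spec$min, spec$max))
  }
  abort("instrument_effect must be a function or list(dist = 'normal'|'uniform', ...)",
        class = "mrpath_config_error")
}

# Variant scaffold shared by all simulators: ids, positions spaced 20 Mb
# apart on one synthetic chromosome (wider than the default clump window, so
# default panels are clumping-neutral), allele pairs, frequencies.
simulate_variants <- function(config) {
  n <- config$n_snps
  eaf <- runif(n, config$eaf_range[1], config$eaf_range[2])
  nonpal <- list(c("A", "G"), c("A", "C"), c("G", "A"), c("C", "A"),
                 c("T", "G"), c("T", "C"), c("G", "T"), c("C", "T"))
  pal <- list(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))
  use_pal <- runif(n) < config$palindrome_frac
  pick <- function(pool) pool[[sample.int(length(pool), 1)]]
  alleles <- t(vapply(use_pal, function(p) if (p) pick(pal) else pick(nonpal),
                      character(2)))
  tibble::tibble(
    variant_id = sprintf("rs%06d", seq_len(n)),
    chrom = "1",
    pos = seq_len(n) * 2e7,
    effect_allele = alleles[, 1],
    other_allele = alleles[, 2],
    eaf = eaf
  )
}

# Per-allele SE for a unit-variance trait at sample size N.
allele_se <- function(n_sample, eaf) 1 / sqrt(2 * n_sample * eaf * (1 - eaf))

summary_table <- function(variants, beta_latent, n_sample, noise = TRUE) {
  se <- allele_se(n_sample, variants$eaf)
  beta <- beta_latent + if (noise) rnorm(nrow(variants), 0, se) else 0
  dplyr::mutate(
    variants,
    beta = beta,
    se = se,
    pval = two_sided_p(beta / se),
    n = as.integer(n_sample)
  )
}

draw_pleiotropy <- function(config, beta_true) {
  n <- length(beta_true)
  switch(config$pleiotropy_mode,
    none = rep(0, n),
    balanced = rnorm(n, 0, config$pleiotropy_scale),
    directional = rnorm(n, config$pleiotropy_mean, config$pleiotropy_scale),
    correlated = rnorm(n, config$pleiotropy_cor * beta_true, config$pleiotropy_scale)
  )
}

#' Simulate a two-sample exposure/outcome GWAS pair
#'
#' Draws latent per-SNP instrument effects, builds exposure summary
#' statistics with sampling noise at `n_exposure`, and outcome summary
#' statistics whose latent effects are `causal_effect` times the latent
#' instrument effect plus horizontal pleiotropy, with independent sampling
#' noise at `n_outcome` (the two-sample design: no shared individuals).
#'
#' @param config A [sim_config()].
#' @return A list with elements `exposure`, `outcome` (summary-statistics
#'   tibbles with columns `variant_id, chrom, pos, effect_allele,
#'   other_allele, eaf, beta, se, pval, n`) and `truth` (latent effects,
#'   pleiotropy, and the config).
#' @export
#' @examples
#' sim <- simulate_pair(sim_config(n_snps = 20, causal_effect = 0.3, seed = 7))
#' head(sim$exposure)
simulate_pair <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    variants <- simulate_variants(config)
    beta_true <- config$instrument_effect(config$n_snps)
    alpha <- draw_pleiotropy(config, beta_true)
    exposure <- summary_table(variants, beta_true, config$n_exposure)
    outcome <- summary_table(variants, config$causal_effect * beta_true + alpha,
                             config$n_outcome)
    list(
      exposure = exposure,
      outcome = outcome,
      truth = list(
        beta_true = beta_true,
        pleiotropy = alpha,
        causal_effect = config$causal_effect,
        config = config
      )
    )
  })
}

normalize_chains <- function(chain) {
  if (is.null(chain)) {
    abort("config$mediator_chain must be set for simulate_mediation()",
          class = "mrpath_config_error")
  }
  if (!is.null(chain$effect_xz)) {
    chains <- list(mediator = list(effect_xz = chain$effect_xz,
                                   effect_zy = chain$effect_zy,
                                   gamma_sd = chain$gamma_sd %||% 0.035))
    return(list(chains = chains, direct = chain$direct_effect %||% 0))
  }
  direct <- chain$direct_effect %||% 0
  chains <- chain[setdiff(names(chain), "direct_effect")]
  chains <- purrr::map(chains, function(ch) {
    list(effect_xz = ch$effect_xz, effect_zy = ch$effect_zy,
         gamma_sd = ch$gamma_sd %||% 0.035)
  })
  list(chains = chains, direct = direct)
}

#' Simulate an exposure -> mediator(s) -> outcome chain
#'
#' Each mediator's latent per-SNP effect is `effect_xz` times the exposure's
#' latent effect plus an independent mediator-specific genetic component
#' (SD `gamma_sd`), so that exposure and mediator effects are not collinear
#' and multivariable models are identified. The outcome's latent effect is
#' `direct_effect` times the exposure signal plus `effect_zy` times each
#' mediator signal. The truth record carries the implied total effect
#' `direct_effect + sum(effect_xz * effect_zy)`.
#'
#' @param config A [sim_config()] with `mediator_chain` set.
#' @return A list with `exposure`, `mediators` (named list of
#'   summary-statistics tibbles), `outcome`, and `truth` (latent effects and
#'   the true total, direct, indirect effects and mediated proportions).
#' @export
simulate_mediation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  spec <- normalize_chains(config$mediator_chain)
  with_seed(config$seed, {
    variants <- simulate_variants(config)
    beta_x <- config$instrument_effect(config$n_snps)
    gamma <- purrr::map(spec$chains, function(ch) rnorm(config$n_snps, 0, ch$gamma_sd))
    beta_z <- purrr::imap(spec$chains, function(ch, nm) ch$effect_xz * beta_x + gamma[[nm]])
    beta_y <- spec$direct * beta_x
    for (nm in names(spec$chains)) {
      beta_y <- beta_y + spec$chains[[nm]]$effect_zy * beta_z[[nm]]
    }
    exposure <- summary_table(variants, beta_x, config$n_exposure)
    mediators <- purrr::map(beta_z, function(bz) {
      summary_table(variants, bz, config$n_exposure)
    })
    outcome <- summary_table(variants, beta_y, config$n_outcome)
    indirect <- purrr::map_dbl(spec$chains, function(ch) ch$effect_xz * ch$effect_zy)
    total <- spec$direct + sum(indirect)
    list(
      exposure = exposure,
      mediators = mediators,
      outcome = outcome,
      truth = list(
        beta_x = beta_x,
        beta_z = beta_z,
        beta_y = beta_y,
        direct_effect = spec$direct,
        indirect_effects = indirect,
        total_effect = total,
        mediated_proportions = if (total != 0) indirect / total else indirect * NA,
        config = config
      )
    )
  })
}

#' Simulate correlated exposures for multivariable MR
#'
#' Generates `K` exposures whose latent per-SNP effects are multivariate
#' normal with correlation `cor_matrix` and per-exposure SD taken from the
#' instrument-effect distribution's scale, plus an outcome whose latent
#' effect is the linear combination of the latent exposure effects with
#' coefficients `direct_effects`.
#'
#' @param config A [sim_config()].
#' @param direct_effects Numeric vector of true direct effects, one per
#'   exposure; its length sets `K`. Names become exposure labels.
#' @param cor_matrix Optional K x K positive-definite correlation matrix for
#'   the latent exposure effects (default identity).
#' @param effect_sd Per-exposure SD of latent effects (recycled to K).
#' @return A list with `exposures` (named list of tibbles), `outcome`, and
#'   `truth`.
#' @export
simulate_mvmr <- function(config, direct_effects, cor_matrix = NULL,
                          effect_sd = 0.035) {
  stopifnot(inherits(config, "sim_config"))
  k <- length(direct_effects)
  labels <- names(direct_effects) %||% paste0("exposure", seq_len(k))
  if (is.null(names(direct_effects))) names(direct_effects) <- labels
  if (is.null(cor_matrix)) cor_matrix <- diag(k)
  if (!isTRUE(all.equal(cor_matrix, t(cor_matrix))) ||
      any(eigen(cor_matrix, symmetric = TRUE, only.values = TRUE)$values <= 1e-10)) {
    abort("cor_matrix must be symmetric positive definite",
          class = "mrpath_config_error")
  }
  sds <- rep_len(effect_sd, k)
  sigma <- diag(sds, k) %*% cor_matrix %*% diag(sds, k)
  ch <- chol(sigma)
  with_seed(config$seed, {
    variants <- simulate_variants(config)
    z <- matrix(rnorm(config$n_snps * k), config$n_snps, k)
    beta_mat <- z %*% ch
    colnames(beta_mat) <- labels
    exposures <- purrr::map(setNames(labels, labels), function(lab) {
      summary_table(variants, beta_mat[, lab], config$n_exposure)
    })
    outcome <- summary_table(variants, drop(beta_mat %*% direct_effects),
                             config$n_outcome)
    list(
      exposures = exposures,
      outcome = outcome,
      truth = list(beta_mat = beta_mat, direct_effects = direct_effects,
                   config = config)
    )
  })
}
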