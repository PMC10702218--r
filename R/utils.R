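#' @importFrom rlang .data abort warn inform %||%
#' @importFrom stats pnorm qnorm pchisq rnorm rbinom runif sd var weighted.mean
#'   coef optim optimize setNames
#' @importFrom utils head
NULL

# Run code under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards. Seeds below 2^31 only.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive a stream-specific child seed so that independent stochastic
# sub-procedures (bootstrap, PRESSO null draws, CV folds) never share a stream.
child_seed <- function(seed, stream) {
  (as.integer(seed) * 48271L + as.integer(stream)) %% 2147483587L
}

two_sided_p <- function(z) 2 * pnorm(-abs(z))

# Two-sided normal 95% interval, the CI convention used for every estimator.
ci_bounds <- function(beta, se, level = 0.95) {
  z <- qnorm(1 - (1 - level) / 2)
  list(low = beta - z * se, high = beta + z * se)
}

is_palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

complement_allele <- function(a) {
  unname(c(A = "T", T = "A", C = "G", G = "C")[a])
}

new_estimate <- function(method, beta, se, n_snp, level = 0.95) {
  ci <- ci_bounds(beta, se, level)
  tibble::tibble(
    method = method,
    beta = beta,
    se = se,
    ci_low = ci$low,
    ci_high = ci$high,
    pval = two_sided_p(beta / se),
    n_snp = as.integer(n_snp)
  )
}
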