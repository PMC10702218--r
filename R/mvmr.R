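#' Assemble a multivariable MR design from per-trait summary statistics
#'
#' Takes one summary-statistics table per exposure plus an outcome table,
#' selects instruments per exposure, forms the union of the per-exposure
#' instrument sets (the common convention when no joint analysis of the
#' exposures is available), harmonizes every trait pairwise to the outcome,
#' and re-expresses all effects in the outcome's allele orientation so the
#' design matrix is sign-consistent across exposures. Variants missing from
#' any exposure table are dropped (no imputation).
#'
#' @param exposures Named list of summary-statistics tibbles.
#' @param outcome Summary-statistics tibble.
#' @param cfg A [selection_config()] used for per-exposure instrument
#'   selection and harmonization.
#' @param select Apply the significance/clumping filter per exposure before
#'   taking the union (default TRUE; set FALSE to use all shared variants,
#'   e.g. on synthetic panels built as instruments).
#' @return Tibble with `variant_id, chrom, pos, beta_out, se_out` and a
#'   `beta_<label>`/`se_<label>` column pair per exposure; exposure labels
#'   stored in the `exposures` attribute.
#' @export
mvmr_input <- function(exposures, outcome, cfg = selection_config(), select = TRUE) {
  if (length(exposures) < 1) abort("need at least one exposure", class = "mrpath_input_error")
  labels <- names(exposures)
  if (is.null(labels) || any(labels == "")) {
    abort("exposures must be a named list", class = "mrpath_input_error")
  }
  ids <- unique(unlist(purrr::map(exposures, function(ex) {
    sel <- if (select) select_instruments(ex, cfg) else ex
    sel$variant_id
  })))
  per_exposure <- purrr::imap(exposures, function(ex, lab) {
    sub <- dplyr::filter(ex, .data$variant_id %in% ids)
    h <- harmonize(sub, outcome, cfg)
    # re-orient to the outcome's reported effect allele
    s <- ifelse(h$allele_flipped, -1, 1)
    tibble::tibble(
      variant_id = h$variant_id, chrom = h$chrom, pos = h$pos,
      beta_out = s * h$beta_out, se_out = h$se_out,
      beta_exp = s * h$beta_exp, se_exp = h$se_exp
    ) |>
      dplyr::rename_with(~ paste0(sub("_exp$", "_", .x), lab),
                         dplyr::ends_with("_exp"))
  })
  out <- purrr::reduce(per_exposure, function(a, b) {
    dplyr::inner_join(a, dplyr::select(b, -"beta_out", -"se_out", -"chrom", -"pos"),
                      by = "variant_id")
  })
  out <- dplyr::arrange(out, .data$chrom, .data$pos)
  attr(out, "exposures") <- labels
  out
}

mvmr_design <- function(input, exposures = NULL) {
  labels <- exposures %||% attr(input, "exposures") %||%
    sub("^beta_", "", grep("^beta_", names(input), value = TRUE))
  x <- as.matrix(input[paste0("beta_", labels)])
  colnames(x) <- labels
  list(labels = labels, x = x, y = input$beta_out, w = 1 / input$se_out^2)
}

#' Multivariable IVW: direct effects of each exposure
#'
#' Weighted least squares of the outcome effects on the K-column matrix of
#' exposure effects, no intercept, weights `1/se_out^2`. Each coefficient
#' is the direct effect of that exposure conditional on the others.
#' Standard errors come from the weighted normal equations with the
#' multiplicative overdispersion inflation \eqn{\max(1, \sqrt{Q/(n-K)})}
#' (the multivariable analogue of random-effects IVW). With K = 1 this
#' reduces exactly to univariate IVW.
#'
#' @param input An [mvmr_input()] tibble.
#' @param exposures Optional character vector of exposure labels (defaults
#'   to the attribute set by [mvmr_input()]).
#' @return Estimate tibble with one row per exposure (`exposure` column).
#' @export
mvmr_ivw <- function(input, exposures = NULL) {
  d <- mvmr_design(input, exposures)
  n <- nrow(d$x); k <- ncol(d$x)
  if (n <= k) abort("MVMR requires more variants than exposures",
                    class = "mrpath_input_error")
  xtwx <- crossprod(d$x, d$w * d$x)
  qr_x <- qr(xtwx)
  if (qr_x$rank < k) {
    abort(paste0("rank-deficient MVMR design; collinear exposures among: ",
                 paste(d$labels, collapse = ", ")),
          class = "mrpath_input_error")
  }
  beta <- solve(xtwx, crossprod(d$x, d$w * d$y))
  resid <- d$y - d$x %*% beta
  q <- sum(d$w * resid^2)
  phi <- max(1, q / (n - k))
  ses <- sqrt(diag(solve(xtwx)) * phi)
  dplyr::bind_rows(purrr::map(seq_len(k), function(j) {
    dplyr::mutate(
      new_estimate("mvmr_ivw", unname(beta[j, 1]), unname(ses[j]), n),
      exposure = d$labels[j], .before = 1
    )
  }))
}

#' LASSO screening of exposures in a multivariable design
#'
#' L1-penalized weighted regression on the same design and weights as
#' [mvmr_ivw()] (no intercept), used to screen out exposures that carry no
#' conditional signal on the outcome. Exposure columns are standardized to
#' unit weighted variance inside the solver and coefficients are reported
#' back on the original scale. The penalty weight is chosen by seeded
#' n-fold cross-validation with the one-standard-error rule unless a fixed
#' `lambda` is supplied. Exposures with a zero coefficient at the chosen
#' penalty are reported as screened out.
#'
#' @param input An [mvmr_input()] tibble with K >= 2 exposures.
#' @param exposures Optional exposure labels.
#' @param lambda Optional fixed penalty; skips cross-validation.
#' @param n_folds Cross-validation folds (default 10).
#' @param seed RNG seed for fold assignment.
#' @param penalty_factor Per-exposure penalty multipliers (0 leaves an
#'   exposure unpenalized); recycled to K.
#' @return List with `retained`, `screened_out`, `coefficients` (named, at
#'   the chosen lambda, original scale), `lambda`, and `path` (tibble of
#'   the full coefficient path).
#' @export
lasso_screen <- function(input, exposures = NULL, lambda = NULL,
                         n_folds = 10, seed = 1L, penalty_factor = NULL) {
  d <- mvmr_design(input, exposures)
  k <- ncol(d$x)
  if (k < 2) abort("LASSO screening requires K >= 2 exposures",
                   class = "mrpath_input_error")
  pf <- rep_len(penalty_factor %||% 1, k)
  wn <- d$w / mean(d$w)
  sds <- sqrt(colSums(wn * d$x^2) / nrow(d$x))
  xs <- sweep(d$x, 2, sds, "/")

  fit_path <- glmnet::glmnet(xs, d$y, weights = wn, intercept = FALSE,
                             standardize = FALSE, penalty.factor = pf,
                             thresh = 1e-12)
  if (is.null(lambda)) {
    foldid <- with_seed(seed, sample(rep_len(seq_len(n_folds), nrow(xs))))
    cv <- glmnet::cv.glmnet(xs, d$y, weights = wn, intercept = FALSE,
                            standardize = FALSE, penalty.factor = pf,
                            foldid = foldid, thresh = 1e-12)
    lambda <- cv$lambda.1se
    if (all(abs(as.numeric(coef(cv, s = "lambda.min"))[-1]) < 1e-12)) {
      warn("all coefficients zero even at lambda.min; returning empty retained set")
    }
  }
  co_std <- as.numeric(coef(fit_path, s = lambda, exact = TRUE, x = xs, y = d$y,
                            weights = wn, intercept = FALSE, standardize = FALSE,
                            penalty.factor = pf))[-1]
  co <- co_std / sds
  names(co) <- d$labels
  path <- tibble::as_tibble(t(as.matrix(fit_path$beta)) / rep(sds, each = length(fit_path$lambda)))
  names(path) <- d$labels
  path <- dplyr::mutate(path, lambda = fit_path$lambda, .before = 1)
  retained <- d$labels[abs(co) > 1e-12]
  list(
    retained = retained,
    screened_out = setdiff(d$labels, retained),
    coefficients = co,
    lambda = lambda,
    path = path
  )
}
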