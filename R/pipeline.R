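sumstats_cols <- c("variant_id", "chrom", "pos", "effect_allele",
                   "other_allele", "eaf", "beta", "se", "pval", "n")

# on-disk header of the TSV dialect
sumstats_header <- c(variant_id = "SNP", chrom = "chr", pos = "pos",
                     effect_allele = "effect_allele", other_allele = "other_allele",
                     eaf = "eaf", beta = "beta", se = "se", pval = "pval",
                     n = "samplesize")

#' Read GWAS summary statistics from a delimited text file
#'
#' Reads the tab-separated dialect written by [write_summary_stats()]
#' (header `SNP chr pos effect_allele other_allele eaf beta se pval
#' samplesize`). Alternate column names are handled through `column_map`, a
#' named character vector mapping internal names (`variant_id`, `chrom`,
#' `pos`, `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pval`,
#' `n`) to the names used in the file. Rows with non-positive SEs or
#' frequencies outside (0, 1) are rejected, with counts reported.
#'
#' @param path File path.
#' @param column_map Optional named character vector of column renames.
#' @return Summary-statistics tibble; dropped-row counts in the
#'   `dropped` attribute.
#' @export
read_summary_stats <- function(path, column_map = NULL) {
  map <- sumstats_header
  if (!is.null(column_map)) map[names(column_map)] <- column_map
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(unname(map), names(raw))
  if (length(missing) > 0) {
    abort(paste0("missing required column(s): ", paste(missing, collapse = ", ")),
          class = "mrpath_input_error")
  }
  out <- tibble::as_tibble(setNames(raw[unname(map)], names(map)))
  out <- dplyr::mutate(out,
    variant_id = as.character(.data$variant_id),
    chrom = as.character(.data$chrom),
    pos = as.numeric(.data$pos),
    effect_allele = toupper(.data$effect_allele),
    other_allele = toupper(.data$other_allele),
    dplyr::across(c("eaf", "beta", "se", "pval"), as.numeric),
    n = as.integer(.data$n)
  )
  bad_se <- !is.finite(out$se) | out$se <= 0
  bad_eaf <- !is.finite(out$eaf) | out$eaf <= 0 | out$eaf >= 1
  bad <- bad_se | bad_eaf
  if (any(bad)) {
    inform(sprintf("dropped %d row(s): %d with se <= 0, %d with eaf outside (0,1)",
                   sum(bad), sum(bad_se), sum(bad_eaf)))
  }
  out <- out[!bad, ]
  if (anyDuplicated(out$variant_id)) {
    abort("duplicate variant IDs in summary statistics", class = "mrpath_input_error")
  }
  attr(out, "dropped") <- c(se = sum(bad_se), eaf = sum(bad_eaf))
  out
}

#' Write GWAS summary statistics as tab-separated text
#'
#' @param stats Summary-statistics tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(stats, path) {
  out <- stats[sumstats_cols]
  names(out) <- unname(sumstats_header)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Transform a log-scale estimate to the odds-ratio scale
#'
#' Exponentiates the estimate and its CI bounds: OR = exp(beta). For
#' binary outcomes analyzed on the log-odds scale this converts a slope of
#' 0.49 to an OR of about 1.64.
#'
#' @param estimate Estimate tibble (rows from any estimator).
#' @return The tibble with `or`, `or_ci_low`, `or_ci_high` columns added.
#' @export
or_transform <- function(estimate) {
  dplyr::mutate(estimate,
    or = exp(.data$beta),
    or_ci_low = exp(.data$ci_low),
    or_ci_high = exp(.data$ci_high)
  )
}

#' Configure a full MR analysis run
#'
#' @param selection A [selection_config()].
#' @param methods Estimators to run (see [mr_estimates()]).
#' @param sensitivity Subset of `c("q", "egger_intercept", "loo", "presso")`.
#' @param direction `"forward"` or `"reverse"` (reverse swaps the exposure
#'   and outcome roles wholesale).
#' @param report_scale `"beta"` or `"or"`.
#' @param n_boot Bootstrap replicates for median SEs.
#' @param presso_n_sim Parametric draws for MR-PRESSO.
#' @param seed RNG seed; required, every random draw flows through it.
#' @return A list of class `mr_config`.
#' @export
mr_config <- function(selection = selection_config(),
                      methods = c("ivw", "egger", "weighted_median",
                                  "simple_median", "raps"),
                      sensitivity = c("q", "egger_intercept", "loo", "presso"),
                      direction = c("forward", "reverse"),
                      report_scale = c("beta", "or"),
                      n_boot = 1000,
                      presso_n_sim = 1000,
                      seed = 1L) {
  direction <- match.arg(direction)
  report_scale <- match.arg(report_scale)
  if (is.null(seed)) abort("seed must be set", class = "mrpath_config_error")
  structure(
    list(selection = selection, methods = methods, sensitivity = sensitivity,
         direction = direction, report_scale = report_scale, n_boot = n_boot,
         presso_n_sim = presso_n_sim, seed = as.integer(seed)),
    class = "mr_config"
  )
}

#' Run the univariate MR pipeline
#'
#' Orchestrates instrument selection, harmonization, the instrument-strength
#' check, the estimator roster, and the requested sensitivity analyses for
#' one exposure-outcome pair. In reverse mode the roles of the two tables
#' are swapped before anything else, probing reverse causation.
#'
#' @param exposure,outcome Summary-statistics tibbles.
#' @param config An [mr_config()].
#' @param ld Optional pairwise-R^2 matrix for clumping.
#' @return An object of class `mr_analysis`: list with `estimates` (tidy
#'   tibble, OR columns added when `report_scale = "or"`), `strength`
#'   ([instrument_strength()] output), `sensitivity` (list with any of
#'   `q`, `egger_intercept`, `loo`, `presso`), `harmonized`, `config`, and
#'   `log` (dropped variants by stage).
#' @export
run_mr_pipeline <- function(exposure, outcome, config = mr_config(), ld = NULL) {
  if (config$direction == "reverse") {
    tmp <- exposure; exposure <- outcome; outcome <- tmp
  }
  instruments <- select_instruments(exposure, config$selection, ld = ld)
  h <- harmonize(instruments, outcome, config$selection)
  strength <- instrument_strength(h, n_exposure = exposure$n[1])

  estimates <- mr_estimates(h, config$methods, n_boot = config$n_boot,
                            seed = config$seed)
  if (config$report_scale == "or") estimates <- or_transform(estimates)

  sens <- list()
  if ("q" %in% config$sensitivity && nrow(h) >= 2) sens$q <- cochran_q(h)
  if ("egger_intercept" %in% config$sensitivity && nrow(h) >= 3) {
    sens$egger_intercept <- mr_egger(h)$intercept
  }
  if ("loo" %in% config$sensitivity && nrow(h) >= 2) sens$loo <- leave_one_out(h)
  if ("presso" %in% config$sensitivity && nrow(h) >= 4) {
    sens$presso <- mr_presso(h, n_sim = config$presso_n_sim,
                             seed = child_seed(config$seed, 99L))
  }

  structure(
    list(
      estimates = estimates,
      strength = strength,
      sensitivity = sens,
      harmonized = h,
      config = config,
      log = dplyr::bind_rows(
        attr(instruments, "dropped"),
        attr(h, "dropped")
      )
    ),
    class = "mr_analysis"
  )
}

#' @export
print.mr_analysis <- function(x, ...) {
  cat(sprintf("MR analysis (%s direction): %d instruments, F = %.1f\n",
              x$config$direction, x$strength$k, x$strength$f_statistic))
  print(x$estimates, ...)
  if (!is.null(x$sensitivity$q)) {
    cat(sprintf("Cochran's Q = %.2f (df %d, p = %.3g), I^2 = %.1f%%\n",
                x$sensitivity$q$q, x$sensitivity$q$df, x$sensitivity$q$pval,
                100 * x$sensitivity$q$i_squared))
  }
  if (!is.null(x$sensitivity$egger_intercept)) {
    cat(sprintf("Egger intercept = %.4f (p = %.3g)\n",
                x$sensitivity$egger_intercept$estimate,
                x$sensitivity$egger_intercept$pval))
  }
  if (!is.null(x$sensitivity$presso)) {
    cat(sprintf("MR-PRESSO global p = %.3g; %d outlier(s)\n",
                x$sensitivity$presso$global_pval,
                length(x$sensitivity$presso$outliers)))
  }
  invisible(x)
}

#' Serialize an analysis to JSON
#'
#' Writes the estimates, strength, and sensitivity summaries as a JSON
#' report; byte-identical for identical inputs and seeds.
#'
#' @param x An `mr_analysis` or `mr_mediation` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(x, path) {
  payload <- if (inherits(x, "mr_analysis")) {
    list(
      estimates = x$estimates,
      strength = x$strength[c("r2_total", "f_statistic", "k", "n", "formula_used")],
      sensitivity = list(
        q = x$sensitivity$q,
        egger_intercept = x$sensitivity$egger_intercept,
        presso = if (!is.null(x$sensitivity$presso)) {
          x$sensitivity$presso[c("global_rss", "global_pval", "outliers",
                                 "distortion_pval")]
        }
      ),
      seed = x$config$seed
    )
  } else if (inherits(x, "mr_mediation")) {
    list(results = x$results, total = x$total, log = x$log, seed = x$seed)
  } else {
    abort("unsupported object", class = "mrpath_input_error")
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
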