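#' Configure instrument selection and harmonization
#'
#' Defaults follow standard two-sample MR practice: genome-wide significance
#' at P < 5e-8, greedy LD clumping at R^2 <= 0.001 within a 10 Mb window,
#' unconditional removal of palindromic (A/T, C/G) variants, and an optional
#' user-supplied exclusion list standing in for manual pleiotropy screening
#' (e.g. Phenoscanner lookups done offline).
#'
#' @param pval_threshold Genome-wide significance threshold (keep P < this).
#' @param clump_r2 Maximum pairwise LD R^2 between retained instruments.
#' @param clump_window Clumping window in base pairs.
#' @param drop_palindromes Drop all A/T and C/G variants (default TRUE).
#' @param exclusion_list Character vector of variant IDs to remove.
#' @param palindrome_eaf_band Optional relaxation: when set to a half-width
#'   `b`, palindromic variants whose effect-allele frequency is farther than
#'   `b` from 0.5 are retained (strand resolvable from frequency); default
#'   `NULL`, i.e. never rescued.
#' @return A list of class `selection_config`.
#' @export
selection_config <- function(pval_threshold = 5e-8,
                             clump_r2 = 0.001,
                             clump_window = 1e7,
                             drop_palindromes = TRUE,
                             exclusion_list = character(),
                             palindrome_eaf_band = NULL) {
  if (pval_threshold <= 0 || pval_threshold > 1) {
    abort("pval_threshold must be in (0, 1]", class = "mrpath_config_error")
  }
  if (clump_r2 < 0 || clump_r2 > 1) {
    abort("clump_r2 must be in [0, 1]", class = "mrpath_config_error")
  }
  if (clump_window <= 0) abort("clump_window must be > 0", class = "mrpath_config_error")
  structure(
    list(pval_threshold = pval_threshold, clump_r2 = clump_r2,
         clump_window = clump_window, drop_palindromes = drop_palindromes,
         exclusion_list = as.character(exclusion_list),
         palindrome_eaf_band = palindrome_eaf_band),
    class = "selection_config"
  )
}

keep_palindrome <- function(eaf, cfg) {
  if (!cfg$drop_palindromes) return(rep(TRUE, length(eaf)))
  if (is.null(cfg$palindrome_eaf_band)) return(rep(FALSE, length(eaf)))
  abs(eaf - 0.5) > cfg$palindrome_eaf_band
}

#' Select genetic instruments from one trait's summary statistics
#'
#' Applies, in order: the genome-wide significance filter
#' (`pval < pval_threshold`), the exclusion list, palindromic-variant
#' removal, and greedy LD clumping (sort survivors by ascending p-value and
#' accept each variant unless it lies within `clump_window` of an already
#' accepted variant with pairwise R^2 above `clump_r2`). Without a supplied
#' LD matrix all variants are treated as independent, so clumping removes
#' nothing; real-data use requires a user-supplied R^2 matrix. Ties in
#' p-value are broken by genomic coordinate then variant ID, and the output
#' is ordered by genomic coordinate, so selection is invariant to input row
#' order.
#'
#' @param stats Summary-statistics tibble (as produced by [simulate_pair()]
#'   or [read_summary_stats()]).
#' @param cfg A [selection_config()].
#' @param ld Optional symmetric pairwise-R^2 matrix with dimnames containing
#'   the variant IDs of `stats`.
#' @return The retained rows of `stats`, ordered by `chrom`, `pos`, with a
#'   `dropped` attribute recording each removed variant and the filter that
#'   removed it.
#' @export
select_instruments <- function(stats, cfg = selection_config(), ld = NULL) {
  dropped <- list()
  note <- function(df, reason) {
    if (nrow(df)) tibble::tibble(variant_id = df$variant_id, reason = reason)
  }

  sig <- dplyr::filter(stats, .data$pval < cfg$pval_threshold)
  dropped$pval <- note(dplyr::anti_join(stats, sig, by = "variant_id"), "pval_above_threshold")

  kept <- dplyr::filter(sig, !(.data$variant_id %in% cfg$exclusion_list))
  dropped$excl <- note(dplyr::anti_join(sig, kept, by = "variant_id"), "exclusion_list")

  pal <- is_palindromic(kept$effect_allele, kept$other_allele)
  rescue <- keep_palindrome(kept$eaf, cfg)
  keep_row <- !pal | rescue
  dropped$pal <- note(kept[!keep_row, ], "palindromic")
  kept <- kept[keep_row, ]

  if (nrow(kept) == 0) {
    failing <- if (nrow(sig) == 0) "pval_threshold" else "palindrome/exclusion filters"
    abort(paste0("no instruments survive ", failing),
          class = "mrpath_no_instruments")
  }

  # greedy clump: ascending p, ties by coordinate then id
  ord <- order(kept$pval, kept$chrom, kept$pos, kept$variant_id)
  cand <- kept[ord, ]
  accepted <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    ok <- TRUE
    if (!is.null(ld)) {
      prev <- which(accepted)
      for (j in prev) {
        same_chr <- cand$chrom[i] == cand$chrom[j]
        near <- abs(cand$pos[i] - cand$pos[j]) <= cfg$clump_window
        r2 <- ld_lookup(ld, cand$variant_id[i], cand$variant_id[j])
        if (same_chr && near && r2 > cfg$clump_r2) { ok <- FALSE; break }
      }
    }
    accepted[i] <- ok
  }
  dropped$clump <- note(cand[!accepted, ], "ld_clump")
  out <- dplyr::arrange(cand[accepted, ], .data$chrom, .data$pos, .data$variant_id)
  if (nrow(out) == 0) abort("no instruments survive LD clumping",
                            class = "mrpath_no_instruments")
  attr(out, "dropped") <- dplyr::bind_rows(dropped)
  out
}

ld_lookup <- function(ld, id1, id2) {
  if (id1 %in% rownames(ld) && id2 %in% colnames(ld)) ld[id1, id2] else 0
}

#' Harmonize exposure and outcome summary statistics
#'
#' Inner-joins the two tables on variant ID and aligns the outcome effects
#' to the exposure's effect allele: rows whose outcome alleles are swapped
#' have `beta_out` negated and frequency reflected (`allele_flipped` flag);
#' rows matching only after strand complementation are complemented first;
#' rows whose alleles match neither orientation are dropped. Palindromic
#' variants are dropped by default because their strand cannot be resolved
#' from alleles alone (never frequency-inferred unless
#' `palindrome_eaf_band` is set).
#'
#' @param exposure,outcome Summary-statistics tibbles.
#' @param cfg A [selection_config()] (controls palindrome handling).
#' @return A harmonized tibble with columns `variant_id, chrom, pos, eaf,
#'   beta_exp, se_exp, beta_out, se_out, allele_flipped, strand_flipped` and
#'   a `dropped` attribute; errors if no variants overlap.
#' @export
harmonize <- function(exposure, outcome, cfg = selection_config()) {
  joined <- dplyr::inner_join(
    exposure,
    dplyr::select(outcome, "variant_id",
                  ea_out = "effect_allele", oa_out = "other_allele",
                  eaf_out = "eaf", beta_out = "beta", se_out = "se"),
    by = "variant_id"
  )
  if (nrow(joined) == 0) {
    abort("no overlapping variants between exposure and outcome",
          class = "mrpath_harmonize_error")
  }
  missing_in_outcome <- dplyr::anti_join(exposure, outcome, by = "variant_id")

  same <- joined$ea_out == joined$effect_allele & joined$oa_out == joined$other_allele
  swap <- joined$ea_out == joined$other_allele & joined$oa_out == joined$effect_allele
  c_ea <- complement_allele(joined$ea_out)
  c_oa <- complement_allele(joined$oa_out)
  strand_same <- !same & !swap & c_ea == joined$effect_allele & c_oa == joined$other_allele
  strand_swap <- !same & !swap & c_ea == joined$other_allele & c_oa == joined$effect_allele

  pal <- is_palindromic(joined$effect_allele, joined$other_allele)
  rescue <- keep_palindrome(joined$eaf, cfg)
  drop_pal <- pal & !rescue
  unresolved <- !(same | swap | strand_same | strand_swap)

  flip <- swap | strand_swap
  out <- tibble::tibble(
    variant_id = joined$variant_id,
    chrom = joined$chrom,
    pos = joined$pos,
    effect_allele = joined$effect_allele,
    other_allele = joined$other_allele,
    eaf = joined$eaf,
    beta_exp = joined$beta,
    se_exp = joined$se,
    beta_out = ifelse(flip, -joined$beta_out, joined$beta_out),
    se_out = joined$se_out,
    eaf_out = ifelse(flip, 1 - joined$eaf_out, joined$eaf_out),
    allele_flipped = flip,
    strand_flipped = strand_same | strand_swap
  )

  dropped <- dplyr::bind_rows(
    if (nrow(missing_in_outcome)) {
      tibble::tibble(variant_id = missing_in_outcome$variant_id,
                     reason = "missing_in_outcome")
    },
    if (any(drop_pal)) tibble::tibble(variant_id = out$variant_id[drop_pal],
                                      reason = "palindromic"),
    if (any(unresolved & !drop_pal)) {
      tibble::tibble(variant_id = out$variant_id[unresolved & !drop_pal],
                     reason = "incompatible_alleles")
    }
  )
  out <- out[!(drop_pal | unresolved), ]
  if (nrow(out) == 0) {
    abort("no variants remain after harmonization", class = "mrpath_harmonize_error")
  }
  attr(out, "dropped") <- dropped
  out
}

#' Instrument strength: per-SNP and total R-squared and the F statistic
#'
#' Computes the variance in the exposure explained by the instruments and
#' the F statistic \eqn{F = \frac{N-k-1}{k}\,\frac{R^2}{1-R^2}}. With fewer
#' than 5 instruments the per-SNP contribution is
#' \eqn{R^2_i = 2\beta_i^2 p_i(1-p_i)}; with 5 or more it is the
#' standard-error-based form
#' \eqn{R^2_i = \frac{2 p_i(1-p_i)\beta_i^2}{2 p_i(1-p_i)\beta_i^2 +
#' 2 N p_i(1-p_i) se_i^2}}, which is better behaved for larger panels (the
#' boundary between the two conventions is set at k = 5). A mean F below 10
#' triggers a weak-instrument warning.
#'
#' @param harmonized A harmonized tibble (or any tibble with `beta_exp`,
#'   `se_exp`, `eaf`).
#' @param n_exposure Exposure GWAS sample size N.
#' @return A list with `r2_snp`, `r2_total`, `f_statistic`, `k`, `n`,
#'   `formula_used`, `weak`.
#' @export
instrument_strength <- function(harmonized, n_exposure) {
  k <- nrow(harmonized)
  if (k < 1) abort("need at least one instrument", class = "mrpath_input_error")
  if (n_exposure <= k + 1) {
    abort("exposure sample size must exceed k + 1", class = "mrpath_input_error")
  }
  b <- harmonized$beta_exp
  p <- harmonized$eaf
  few <- k < 5
  r2_snp <- if (few) {
    2 * b^2 * p * (1 - p)
  } else {
    se <- harmonized$se_exp
    (2 * p * (1 - p) * b^2) / (2 * p * (1 - p) * b^2 + 2 * n_exposure * p * (1 - p) * se^2)
  }
  r2 <- sum(r2_snp)
  if (r2 >= 1) abort("total R^2 >= 1: degenerate input", class = "mrpath_input_error")
  f <- ((n_exposure - k - 1) / k) * (r2 / (1 - r2))
  weak <- f < 10
  if (weak) {
    warn(sprintf("mean instrument F = %.2f < 10: estimates may suffer weak-instrument bias", f),
         class = "mrpath_weak_instruments")
  }
  list(r2_snp = r2_snp, r2_total = r2, f_statistic = f, k = k,
       n = n_exposure, formula_used = if (few) "few_snp" else "many_snp",
       weak = weak)
}
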