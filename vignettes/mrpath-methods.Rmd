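---
title: "Methods: two-sample MR, multivariable adjustment and mediation in mrpath"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample MR, multivariable adjustment and mediation in mrpath}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrpath)
```

## The problem

Mendelian randomization (MR) estimates the causal effect of an exposure on
an outcome from GWAS summary statistics, using genetic variants as
instrumental variables. Because alleles are fixed at conception, a variant
that robustly changes the exposure provides a natural experiment that is
immune to classical confounding and reverse causation — provided the
variant affects the outcome *only* through the exposure. `mrpath`
implements the full summary-data workflow around this idea: instrument
selection and harmonization, a roster of univariate estimators with
different robustness properties, heterogeneity and pleiotropy diagnostics,
multivariable MR (MVMR) for direct effects, and two-step mediation analysis
that decomposes a total causal effect into mediator-specific indirect
effects. A typical application is a behavioural exposure (say, leisure
sedentary time measured in a half-million-person biobank) against a
cardiometabolic outcome such as type 2 diabetes on the log-odds scale, with
adiposity, lipid and education traits as candidate mediators.

## Models and estimators

For each variant $i$ the data are the harmonized pairs
$(\hat\beta_{x,i}, se_{x,i})$ and $(\hat\beta_{y,i}, se_{y,i})$ from
non-overlapping samples. All estimators are built from the Wald ratios
$\hat\theta_i = \hat\beta_{y,i}/\hat\beta_{x,i}$ with first-order delta
SEs $se_{y,i}/|\hat\beta_{x,i}|$ (the alternative second-order weights are
deliberately not the default; the first-order convention matches the
standard toolchain).

* **IVW** — weighted least squares of $\hat\beta_y$ on $\hat\beta_x$
  through the origin, weights $1/se_y^2$. The fixed-effects SE is
  $1/\sqrt{\sum \hat\beta_{x,i}^2/se_{y,i}^2}$; the random-effects
  (multiplicative overdispersion) model keeps the same point estimate and
  inflates the SE by $\max(1, \sqrt{Q/(k-1)})$, so it can never undercut
  the fixed-effects SE. Random effects is the default and the primary
  estimate: heterogeneity between variants is the rule, not the exception.
* **MR-Egger** — the same weighted regression with a free intercept after
  orienting all exposure effects non-negative. The intercept estimates the
  average directional pleiotropy (its two-sided test is the pleiotropy
  diagnostic); the slope is a pleiotropy-corrected effect valid under the
  InSIDE assumption. Both SEs carry the $\max(1,\sqrt{Q_E/(k-2)})$
  inflation. The orientation convention matters for the *sign* of the
  intercept and is stated in the function documentation.
* **Weighted and simple median** — the ratio at cumulative normalized
  weight 0.5 over the sorted Wald ratios, linearly interpolated at the
  positions $p_i = (\mathrm{cum}(w_i) - w_i/2)/\sum w$; consistent while
  valid instruments carry a majority of the weight. The simple median is
  the equal-weight special case (middle ratio for odd $k$, midpoint of the
  two middle ratios for even $k$). SEs come from a seeded parametric
  bootstrap (default 1000 draws) that resamples both effect columns from
  their sampling distributions.
* **RAPS** — profiling the latent per-variant instrument effects out of the
  bivariate normal likelihood leaves the objective
  $\tfrac12\sum_i t_i^2$ with
  $t_i(b,\tau^2) = (\hat\beta_{y,i}-b\hat\beta_{x,i}) /
  \sqrt{se_{y,i}^2 + b^2 se_{x,i}^2 + \tau^2}$. Minimizing over $b$
  accounts for exposure-side sampling error and removes the
  regression-dilution bias that IVW suffers under weak instruments. The
  overdispersion $\tau^2 \ge 0$ (on by default) is estimated by the moment
  condition that the $t_i$ have unit scale; a Huber loss on $t_i$ is
  available behind a flag, with the matching standard-normal consistency
  constant in the moment condition. The SE is a sandwich estimate from the
  per-variant profile scores. During development an objective with an
  extra $\tfrac12\log v_i$ term was tried and rejected: it is not the
  profile likelihood and visibly re-introduces attenuation — the test
  suite's weak-instrument comparison against IVW guards the correct form.

Confidence intervals are normal-theory $\hat\beta \pm 1.96\,se$ throughout,
and p-values are two-sided normal. For binary outcomes all arithmetic
stays on the log-odds scale; `or_transform()` exponentiates estimates and
CI bounds for reporting.

## Instrument selection and harmonization

`select_instruments()` applies, in order: the genome-wide significance
filter ($P < 5\times10^{-8}$), a user exclusion list (the offline stand-in
for manual pleiotropy screening of each variant), unconditional removal of
palindromic A/T and C/G variants, and greedy LD clumping (sort by
ascending $p$, accept unless within 10 Mb of an accepted variant with
$R^2 > 0.001$). Two deliberate choices:

* Without a user-supplied LD matrix, variants are treated as independent
  and clumping is a no-op. No LD reference is ever downloaded; real-data
  clumping requires the caller to pass pairwise $R^2$. The synthetic
  generator spaces variants 20 Mb apart so default panels are
  clumping-neutral by construction.
* Palindromes are never rescued by allele frequency by default; an opt-in
  `palindrome_eaf_band` keeps palindromic variants whose EAF is far from
  0.5. Ties in the clumping order are broken by genomic coordinate then
  variant ID, making selection deterministic and invariant to row order.

`harmonize()` inner-joins on variant ID and aligns the outcome to the
exposure's effect allele, trying direct match, allele swap (negate
$\hat\beta_y$, reflect EAF), strand complement, and complement-plus-swap,
in that order; unresolvable rows are dropped with a logged reason.

Instrument strength uses $F = \frac{N-k-1}{k}\frac{R^2}{1-R^2}$ with the
per-variant $R^2_i = 2\beta_i^2 p_i(1-p_i)$ for panels of fewer than 5
variants and the SE-based
$R^2_i = \beta_i^2/(\beta_i^2 + N\,se_i^2)$ form otherwise. The two
conventions come from different strength-reporting traditions for small
and large panels; neither source convention covers $5 \le k \le 10$, so
the boundary is set at $k = 5$ — the SE-based form is the better-behaved
estimator and the gap has to be closed deterministically. A mean $F < 10$
raises a weak-instrument warning.

## Sensitivity analyses

Cochran's $Q$ (first-order ratio weights, against the IVW estimate) with
$I^2 = \max(0, (Q - df)/Q)$; leave-one-out IVW with flags for omissions
that flip the sign or the 0.05 significance; and MR-PRESSO. The PRESSO
global statistic is the weighted residual sum of squares with each
variant's residual taken against the leave-one-out slope; its null
distribution is built by redrawing outcome effects from
$N(\hat b_{(-i)}\hat\beta_{x,i}, se_{y,i}^2)$ and recomputing the
statistic — including the leave-one-out slopes — on every draw. Per-variant
outlier p-values are empirical ranks Bonferroni-adjusted over $k$, and the
distortion test compares the outlier-removal shift against removals of
random subsets of the same size. Empirical p-values use the add-one rank
convention, so with `n_sim` draws the smallest attainable per-variant
adjusted p is $k/(n_\mathrm{sim}+1)$ — reliably flagging one outlier among
50 variants at 0.05 therefore needs $n_\mathrm{sim} \gtrsim 1000$, which
is why the default is 1000 and the detection experiments use 2000.

## Multivariable MR and LASSO screening

`mvmr_ivw()` regresses the outcome effects on the $K$-column matrix of
exposure effects (no intercept, weights $1/se_y^2$); each coefficient is a
direct effect conditional on the other exposures, with SEs from the
weighted normal equations inflated by $\max(1,\sqrt{Q/(n-K)})$. The
design is assembled by `mvmr_input()`, which takes the union of the
per-exposure instrument sets, harmonizes every trait pairwise to the
outcome, and re-expresses all effects in the outcome's allele orientation
so the columns are sign-consistent.

`lasso_screen()` solves the same weighted problem with an L1 penalty
(glmnet's coordinate descent; exposure columns standardized to unit
weighted second moment internally, coefficients reported on the original
scale). The penalty is chosen by seeded 10-fold cross-validation with the
one-SE rule — the source conventions do not pin down a selection rule, so
the most conservative standard rule was adopted and a fixed-`lambda`
argument is exposed for exact reproduction attempts. All columns are
penalized by default (whether the exposure of interest should be exempt is
genuinely open; `penalty_factor = 0` for selected columns covers the other
convention). Exposures with a zero coefficient at the chosen penalty are
"screened out"; the full path is returned for audit.

## Two-step mediation

`run_two_step()` implements the three-step procedure:

1. univariate IVW of the exposure on each candidate mediator
   (`effect_xz`), with Bonferroni correction *within declared families* of
   mediators measured in the same GWAS (e.g. 0.05/3 ≈ 0.017 for three
   anthropometric traits); failures are dropped;
2. LASSO screening over the exposure plus surviving mediators against the
   outcome, then MVMR for each retained mediator's exposure-adjusted
   effect (`effect_zy`);
3. the coefficient product `effect_xz * effect_zy` as the mediation
   (indirect) effect, with the delta-method SE
   $\sqrt{\beta_{zy}^2 se_{xz}^2 + \beta_{xz}^2 se_{zy}^2}$, and the
   mediated proportion as its ratio to the univariate total effect, in
   percent, with a ratio delta-method CI that assumes the two estimates
   are independent (a reasonable approximation in the two-sample setting,
   and a documented limitation — the numerator and denominator share the
   outcome GWAS).

The delta-method CI is the primary interval; a seeded parametric
bootstrap (products of independent normal draws, percentile CI) is
available and labelled in the output, because product-of-coefficient
intervals are known to be sensitive to the normal approximation near zero.
Proportions of different mediators are reported independently and are not
normalized: with correlated mediators they can legitimately sum past 100%.

## The synthetic GWAS generator

`simulate_pair()`, `simulate_mediation()` and `simulate_mvmr()` generate
summary statistics directly — no individual-level genotypes — because the
analysis consumes only summary data. Per variant: EAF uniform on
(0.1, 0.9); latent instrument effect from a configurable distribution
(default $N(0, 0.035^2)$ on standardized traits); SE from the per-allele
variance approximation $1/\sqrt{2Np(1-p)}$ for a unit-variance trait (the
source GWAS do not state trait variances, so all traits are standardized);
observed effects are latent effects plus independent $N(0, se^2)$ noise in
each sample (the two-sample property). Defaults emulate the motivating
setting: exposure $N = 422{,}218$ (a UK-Biobank-scale behavioural GWAS)
and outcome $N = 898{,}130$ (a large case-control meta-analysis on the
log-odds scale). Binary outcomes are represented on the log-odds scale
directly; no liability-threshold simulation.

Horizontal pleiotropy is a per-variant direct effect on the outcome:
`balanced` (zero mean), `directional` (mean `pleiotropy_mean`, InSIDE
holds), or `correlated` (mean proportional to the instrument effect,
violating InSIDE). Mediator chains give each mediator its own independent
genetic component `gamma_sd` on top of the exposure-driven signal — without
it the exposure and mediator columns are collinear in the latent limit and
the MVMR step is unidentified; `gamma_sd` also acts as balanced pleiotropy
from the univariate exposure–outcome viewpoint, which is realistic.

What the generator does *not* emulate: LD between variants (independent
biallelic SNPs spaced 20 Mb apart; an LD matrix can be supplied to
exercise clumping), sample overlap, case-control ascertainment, allele
frequency spectra, or winner's-curse selection effects. Passing tests on
synthetic data therefore validate the estimators' arithmetic and
statistical calibration under the stated model, not robustness to every
real-data pathology.

## Validation experiments and problem sizes

The acceptance suite fixes the following experiments (all seeded):

* **Worked arithmetic** — coefficient products, the log-OR total-effect
  conversion and the Bonferroni threshold against published worked values.
* **Oracle equivalence** — IVW against closed-form weighted least squares
  (`lm`), the weighted median against an independent cumulative-weight
  scan, and the LASSO against a KKT-enumeration oracle on $K=2$ designs,
  all to $10^{-6}$ or better.
* **Parameter recovery** — 500 replicates at $k = 100$, causal slope 0.2,
  exposure $N = 422{,}218$, outcome $N = 37{,}037$ (a MAGIC-scale
  quantitative trait), instrument effects $N(0, 0.045^2)$ (≈8% of
  exposure variance). All five estimators must be within 3 Monte-Carlo
  SEs of the truth and IVW coverage within 92–98%. These conditions come
  from a design-stage power analysis: the bias floor of first-order IVW is
  its regression dilution $\approx \beta\,\overline{se_x^2}/\sigma_b^2$,
  and the experiment must keep that floor well under the Monte-Carlo
  resolution $3\,sd/\sqrt{500}$ for the check to be informative about
  implementation errors rather than about the estimator's known
  first-order bias. The harness feeds the full simulated panel to the
  estimators without a significance pre-filter, deliberately avoiding
  winner's-curse contamination of the bias measurement. The
  directional-pleiotropy arm (Egger intercept recovery) draws oriented
  effects $U(0.02, 0.08)$, mimicking a published significance-selected
  panel: with near-zero signed effects, orientation flips driven by
  exposure-side noise cancel part of the planted pleiotropy — a real
  property of MR-Egger, not an implementation artifact.
* **Calibration** — Cochran's $Q$ against $\chi^2_{k-1}$
  (Kolmogorov–Smirnov over 2000 null replicates at $k=10$ with strong
  instruments, so first-order ratio weights are exact); MR-PRESSO global
  false-positive rate within 2.5 points of 5% over 500 runs; ≥95%
  detection of a planted 10-SD outlier among 50 variants over 100 runs.
* **End-to-end mediation** — 25 replicates of a two-mediator chain
  (`effect_xz` 0.28 and 0.13, `effect_zy` 0.82 and 0, direct effect 0.26,
  $k=150$): the mediation effect and mediated proportion must be centred
  on the generator truth within 3 Monte-Carlo SEs, per-replicate
  delta-method CI coverage must sit within a binomial 3-SE band of the
  nominal 95%, and the zero-direct-effect mediator must be removed at the
  LASSO step in ≥90% of replicates. The inert mediator's `gamma_sd` is
  0.01 so that its exposure→mediator leg is reliably significant and the
  screening decision is genuinely made by the LASSO, not upstream.

These sizes keep the full suite under a few minutes on one CPU while
leaving the Monte-Carlo checks well-powered.

## Known limitations

* First-order Wald-ratio weights throughout (exact-ratio weights are not
  implemented); RAPS is the weak-instrument-robust alternative.
* The mediated-proportion CI assumes independence of the indirect and
  total estimates; both use the same outcome GWAS, so the interval is
  approximate.
* Naive reverse-direction MR is provided as a mode, but when the forward
  effect is strong the exposure's instruments propagate to the outcome
  and reverse estimates are expected to be "significant" at $1/\beta$ —
  interpretation requires outcome-specific instruments, which the
  generator does not create.
* No proxy-variant search, no Steiger filtering, no mode-based
  estimators, and no Bayesian model-comparison machinery.
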