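---
title: "Methods: one-sample summary-level MR of dietary micronutrient intake and incident CKD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: one-sample summary-level MR of dietary micronutrient intake and incident CKD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nutrimr)
```

# The design

Mendelian randomization (MR) uses genetic variants as instrumental variables
for a modifiable exposure. A variant is a valid instrument if it is (1)
associated with the exposure, (2) independent of exposure-outcome
confounders, and (3) affects the outcome only through the exposure (the
exclusion restriction). When those hold, the per-SNP **Wald ratio**
$r_j = \hat\Gamma_j / \hat\gamma_j$ — the outcome association divided by the
exposure association — estimates the causal effect, and combining ratios
across independent instruments gives a usable estimate even from summary
statistics alone.

`nutrimr` implements the complete summary-level workflow for the setting it
was built around: dietary micronutrient intake (phosphorus, vitamins B2, B6
and C, from food-frequency-questionnaire GWAS in a Korean population cohort)
as exposures, and incident chronic kidney disease (CKD) — an eGFR decline to
below 60 mL/min/1.73 m² during follow-up — as the outcome. It ships the four
published per-instrument tables as plain-text fixtures, and a cohort
simulator so that every stage, from genotypes to estimates, runs and can be
calibrated without access to the restricted cohort.

This is a *one-sample* design (exposure and outcome associations estimated in
the same cohort). The estimators themselves are the standard summary-level
ones; the one-sample origin matters mainly for interpretation (weak-instrument
bias is toward the observational association rather than the null), which is
why the package also provides instrument-strength levers in the simulator.

# Instrument selection

The selection cascade mirrors common GWAS practice, with each stage
configurable through `selection_config()` and every exclusion logged with a
reason code:

1. **Suggestive significance filter**: keep exposure associations with
   $p < 1\times10^{-5}$ (strict inequality). Dietary-intake GWAS rarely yield
   genome-wide-significant hits, so the conventional suggestive threshold is
   the discovery cutoff.
2. **LD clumping** (`ld_clump()`): greedy, deterministic — repeatedly take
   the smallest-p remaining variant and discard variants within 250 kb on the
   same chromosome with $r^2 \ge 0.1$ against it. The source analysis states
   clumping without parameters; 0.1/250 kb are standard stringent defaults
   and both are configurable. Ties in p are broken by (chrom, pos, snp_id) so
   the result is independent of input order. Variants missing from the LD
   matrix are treated as unlinked; variants with missing positions are
   treated as within-window (conservative).
3. **Harmonization** (`harmonize()`): align outcome to the exposure's effect
   allele, flipping the outcome beta's sign (and complementing its allele
   frequency) for swapped alleles, trying strand complement before declaring
   alleles irreconcilable. Palindromic variants (A/T, C/G) are excluded when
   the exposure effect-allele frequency lies in the intermediate band
   [0.40, 0.60] — inside that band the frequency carries no strand
   information. A palindromic variant with *missing* frequency is excluded
   for the same reason. The band is configurable.
4. **Outcome-association screen**: instruments should be unrelated to CKD
   directly, operationalized as dropping instruments whose two-sided normal
   outcome p (from $|\hat\Gamma_j/\hat\sigma_{Y j}|$) is below $10^{-5}$,
   mirroring the exposure threshold.
5. **Mapped-phenotype screen** (`screen_mapped_phenotypes()`): a file-based
   stand-in for a GWAS-Catalog lookup. An instrument is kept iff any of its
   previously reported phenotypes matches a dietary-intake pattern
   (default substring `"intake"`). Unannotated variants are kept: the
   published instrument sets retain variants whose only reported phenotypes
   are the dietary intakes themselves, so absence of annotation is treated
   as absence of evidence of pleiotropy, not evidence of it. This keep rule
   is an interpretation — the published sets also retain variants co-mapped
   to non-dietary traits (HDL, BMI, gastric cancer), which only a
   keep-if-any-dietary-phenotype rule reproduces.

The published upstream counts (e.g. 147 candidate phosphorus SNPs reduced to
19 and then 11) depend on unpublished LD structure and annotation judgments,
so they are not reproducible from public information; the packaged final
instrument sets (11/13/11/10 variants) are what the package regression-tests.

# The six estimators

All estimators consume the harmonized quadruple
$(\hat\gamma_j, \hat\sigma_{X j}, \hat\Gamma_j, \hat\sigma_{Y j})$, written
`bx, sx, by, sy` in code.

**IVW** (`mr_ivw()`): fixed-effect inverse-variance weighted mean of the Wald
ratios with first-order weights $w_j = \hat\gamma_j^2/\hat\sigma_{Y j}^2$:
$\hat\beta = \sum w_j r_j / \sum w_j$, $SE = (\sum w_j)^{-1/2}$. The
fixed-effect convention is deliberate: it exactly reproduces the published
standard errors on the fixture sets (e.g. vitamin B6 1.623 vs printed 1.624,
vitamin C 1.276 vs 1.275), which a multiplicative random-effects model would
not.

**Radial IVW** (`mr_radial_ivw()`): regression through the origin of
$\sqrt{w_j}\, r_j$ on $\sqrt{w_j}$. With first-order weights the slope is
algebraically identical to IVW; the default uses *modified second-order*
weights $w_j = (\hat\sigma^2_{Y j}/\hat\gamma_j^2 +
\hat\beta^2\hat\sigma^2_{X j}/\hat\gamma_j^2)^{-1}$, iterated to convergence,
which is what distinguishes the published radial point estimates from plain
IVW (−4.016 vs −4.014 for B6). The SE uses the regression's estimated
residual variance, $SE = \sqrt{\hat\sigma^2_{res}/\sum w_j}$ with
$\hat\sigma^2_{res} = Q/(k-1)$ — the only convention consistent with the
published radial SEs falling *below* the IVW SEs under low heterogeneity.
Per-SNP heterogeneity contributions $Q_j = w_j (r_j - \hat\beta)^2$ sum to
the global Cochran-type $Q$ and flag outliers on the $\chi^2_1$ reference.

**MR-Egger** (`mr_egger()`): instruments are first re-oriented so every
$\hat\gamma_j > 0$ (a joint sign flip, under which ratios are invariant but
the intercept is not — orientation is mandatory and makes the reported fit
flip-invariant); then weighted least squares of `by` on `bx` with an
unconstrained intercept and weights $1/\hat\sigma^2_{Y j}$. The intercept
estimates average directional pleiotropy. SEs are scaled by the estimated
residual SD floored at 1 (underdispersion never tightens the fixed-effect
SEs); p-values use a $t_{k-2}$ reference, which is what the published
intercept p-values follow (the normal reference differs in the second
decimal). Note the published B6 Egger *slope* (−4.477) is not recoverable
from the published per-SNP table under either orientation convention even
though the same fit reproduces the published intercept (−0.026) exactly;
the slope therefore carries no reproduction test.

**Medians** (`mr_simple_median()`, `mr_weighted_median()`,
`mr_penalized_weighted_median()`): the simple median is the unweighted median
of ratios (mean of the central two for even counts). The weighted median
sorts ratios, normalizes weights, forms cumulative mid-point scores
$s_j = \sum_{i\le j} w_i - w_j/2$ and interpolates linearly at $s = 0.5$;
it is consistent when up to half the weight lies on invalid instruments.
The penalized variant computes one-step heterogeneity contributions about
the weighted-median estimate, converts them to upper-tail $\chi^2_1$
probabilities $q_j$, and multiplies weights by $\min(1, 20\, q_j)$
(`penalty_scale = 20`), leaving consistent instruments untouched while
shrinking gross outliers. Median SEs come from a parametric bootstrap
(5,000 replicates by default, seeded, per-SNP betas resampled from normals
at their reported SEs); the seed is recorded in every estimate. The
published weighted-median values differ by about 2% from the interpolation
formula applied to the printed (rounded) inputs, so they are reproduced
with tolerance rather than asserted tightly.

p-values are two-sided normal for all methods except Egger's
$t_{k-2}$, matching the published tables.

# Pleiotropy diagnostics

**Egger intercept test** (`egger_intercept_test()`) re-exports the intercept
above.

**MR-PRESSO global test** (`mr_presso_global()`): for each SNP the
leave-one-out IVW estimate $\hat\beta_{(-j)}$ defines the expected outcome
beta; the observed residual sum of squares is
$RSS = \sum_j (\hat\Gamma_j - \hat\beta_{(-j)}\hat\gamma_j)^2 /
\hat\sigma^2_{Y j}$. The null distribution is simulated by drawing
$\hat\Gamma^*_j \sim N(\hat\beta_{(-j)}\hat\gamma_j, \hat\sigma_{Y j})$ and
recomputing the RSS — including the leave-one-out estimates — `nsim` times
(default 10,000; the p-value lattice is $(1 + \#\{RSS^* \ge RSS\})/(nsim+1)$,
so p can never be exactly 0). Per-SNP outlier p-values come from each SNP's
own simulated residual distribution, Bonferroni-flagged. The distortion test
is omitted: the analysis this package reproduces does not report one. The
seed is mandatory in reports; results are bit-for-bit reproducible given
(instruments, nsim, seed).

**Funnel data** (`funnel_data()`): per-SNP ratio against precision
$|\hat\gamma_j|/\hat\sigma_{Y j}$ with IVW and Egger reference lines; the
package emits plot *data* rather than figures so reports are reproducible
without a display.

# Phenotyping

`egfr_ckd_epi()` evaluates the CKD-EPI creatinine equation
$141 \cdot \min(Scr/\kappa, 1)^{\alpha} \cdot \max(Scr/\kappa, 1)^{-1.209}
\cdot 0.993^{Age} \cdot 1.018[\text{female}]$ with
$\kappa = 0.7/0.9$ mg/dL and $\alpha = -0.329/-0.411$ (female/male); no race
coefficient is used. `classify_incident_ckd()` applies the single-crossing
rule: subjects below 60 at baseline are excluded; a subject at or above 60
at baseline is an incident case iff *any* follow-up eGFR falls below 60. The
source definition does not require a confirmatory second measurement, so
none is required here; eGFR is not rounded before the comparison; age is
taken per visit. `scr_for_egfr()` inverts the equation in creatinine — used
by the simulator to construct trajectories with prescribed crossings.

# Polygenic-score validation

`compute_prs()` forms $PRS_s = \sum_i \beta_i \cdot dosage_{si}$ — an
unstandardized weighted sum, exactly as the source defines it — with
per-SNP mean imputation of missing dosages by default (count reported) or a
strict error mode. `prs_trait_association()` is closed-form simple least
squares of measured intake on the score with a $t_{n-2}$ p-value. The
published PRS slopes require the restricted cohort and are used only to set
the simulator's effect scales.

# The simulator

`sim_config()` defaults encode the study conditions: 5,078 subjects with a
14% incident-CKD fraction (708 cases), per-SNP exposure effects of magnitude
0.015–0.1 (the range spanned by the published instrument tables), instruments
jointly explaining about 2% of exposure variance (a realistic dietary-intake
GWAS signal), and biennial visits over 12 years.

* **Genotypes**: a latent Gaussian copula per LD block thresholded at each
  SNP's allele frequency, so every SNP is in exact Hardy–Weinberg
  proportions marginally while within-block dosages are correlated; blocks
  are independent. No attempt is made to mimic realistic LD maps,
  imputation, or chip-specific missingness.
* **Traits**: exposure $= \sum_j \gamma_j g_j + \lambda c + \varepsilon$
  with the noise variance solved from the target genetic $R^2$; outcome
  liability $= \beta_{causal}\cdot exposure + \delta' g + \lambda c + e$
  with optional balanced or directional direct effects $\delta$ (violating
  the exclusion restriction on a configurable fraction of SNPs); the case
  indicator thresholds the liability at the quantile giving exactly
  `round(case_fraction_target * n)` cases.
* **Creatinine**: trajectories are built by inverting CKD-EPI at target
  eGFR values — cases drop to 40–57 from a random follow-up visit onward,
  non-cases never fall below 65 — plus 1% lognormal measurement noise,
  small enough that no trajectory crosses the 60 threshold spuriously. This
  guarantees the phenotyping module recovers the simulated case labels; it
  does not emulate gradual real-world eGFR decline.
* **GWAS scan**: closed-form per-SNP linear regression for continuous
  traits; per-SNP logistic Wald fits (score-test fallback under separation)
  for binary traits. The scan is unadjusted additive regression — the source
  GWAS's covariates and intake transformation are unstated, so none are
  imposed.
* **QC** (`qc_filter()`): call rate ≥ 95%, MAF ≥ 1%, and a Hardy–Weinberg
  chi-square (1 df) test at $p \ge 5\times10^{-5}$. The source describes a
  permutation-style HWE test without details; the chi-square test is the
  standard choice and the threshold is what matters. The false-drop
  calibration of the test is checked at a scaled threshold/SNP count
  (400 SNPs) so the suite stays fast.

## Calibration choices

Estimator recovery and IVW coverage are checked with 50 instruments,
n = 5,000, genetic $R^2 = 0.25$ ("strong instruments"), a causal effect of
0.3 on the liability scale, no confounding and no pleiotropy, over 200
replicates. Two deliberate choices:

* The outcome GWAS for calibration runs on the *continuous liability*, not
  the thresholded case indicator: with a binary outcome and logistic fits
  the estimand shifts (non-collapsibility of the odds ratio), and no
  summary-level estimator would be expected to centre exactly on
  $\beta_{causal}$. The binary path is exercised separately.
* Because exposure and outcome come from the same simulated sample, the
  outcome residual variance (and hence `sy`) absorbs the causal component of
  the exposure noise, making the first-order IVW intervals mildly
  conservative; the causal effect and noise scales above keep that
  conservatism within the accepted 92–98% coverage band rather than
  inflating it.

What passing these checks shows is that the estimators are unbiased and
approximately calibrated *under the generator's assumptions* — independent
(or block-exchangeable) SNPs, linear effects, normal noise, no selection on
significance. It does not certify behaviour under winner's curse, weak
instruments, or real LD, all of which can be explored by moving the
corresponding configuration fields.

# Reproduction of the published tables

`reproduce_reference_analysis()` runs all six estimators plus both
pleiotropy diagnostics on the four packaged instrument sets and writes a
comparison table against the published values with explicit tolerance bands
(packaged alongside the reference values, not hard-coded in test logic):
±0.05 on IVW/radial betas and SEs, ±0.01 on the simple median (which equals
the Wald ratio of the median instrument exactly), ±0.005–0.01 on Egger
intercepts. The printed inputs are rounded to 2–3 decimals, which bounds the
agreement achievable by *any* reimplementation; the bands reflect that. The
MR-PRESSO p is compared only within Monte-Carlo tolerance since the source
reports no simulation settings.

# Known limitations

* The exposure tables print effect-allele frequencies but not the other
  allele, so the fixtures are treated as pre-harmonized (which they are).
* The published Egger slopes and (to ~2%) weighted-median estimates are not
  exactly recoverable from the printed per-SNP inputs; see above.
* LD clumping parameters, the palindromic frequency band, and the outcome
  screen threshold are documented defaults, not published values.
* The simulator's creatinine mechanism is designed for label consistency,
  not biological realism.
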