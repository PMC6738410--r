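---
title: "MethylTL: models, design choices and what the tests show"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MethylTL: models, design choices and what the tests show}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of the science it implements:
the estimator and the statistics around it, the assumptions baked into
the synthetic-cohort generator, the numerical choices, and the limits of
what a green test suite demonstrates.

## The estimator

A methylation-based telomere-length clock is a sparse linear model

$$\widehat{TL}_s = \beta_0 + \sum_j w_j \,\beta_{js}$$

where $\beta_{js}\in[0,1]$ is the methylation fraction of CpG $j$ in
sample $s$, and the output is in kilobases because the training target
(mean terminal-restriction-fragment length) is. The kilobase unit is a
convention inherited from training, not a claim that the output *is* a
physical telomere length; in cultured cells the estimate keeps falling
with population doublings even when telomerase holds telomeres constant,
so it is better read as a record of replicative history.

### Training protocol

`trainClock()` fits the elastic net
$$\min_{\beta_0, w}\; \frac{1}{2n}\sum_i (y_i-\beta_0-x_i'w)^2 +
\lambda\Big[\alpha\|w\|_1 + \tfrac{1-\alpha}{2}\|w\|_2^2\Big]$$
with `glmnet` doing the coordinate descent. Fixed choices, and why:

* **alpha = 0.5** is the default mixing parameter, the convention for
  this family of kilobase-scale clocks.
* **Predictors are standardized with population (1/n) variance** and
  coefficients reported back on the beta scale — the convention of the
  solver this protocol is defined around.
* **Lambda grid**: 100 log-spaced values from $\lambda_{max}$ (the
  smallest penalty that zeroes every coefficient, computed from the
  standardized correlation bound
  $\max_j |\langle \tilde x_j, y-\bar y\rangle|/(n\alpha)$) down to
  $\lambda_{max} r$, $r = 0.01$ when $p \ge n$ and $10^{-4}$ otherwise.
* **CV loss is mean squared error** (the regression default), averaged
  over folds; its standard error is the SD of per-fold errors divided by
  $\sqrt{\text{folds}}$. The **lambda.1se rule** picks the largest
  penalty whose CV error is within one SE of the minimum — deliberately
  sparser and more stable than the CV minimiser.
* **Fold assignment is a seeded random permutation** into nearly equal
  blocks; the seed is a required argument and the assignment is stored
  in the returned `CVPath`, so a training run is exactly repeatable.
* The final model is refit on all data at the chosen penalty. For rule
  `"fixed"` the package refits a dedicated path ending exactly at the
  requested lambda at convergence threshold $10^{-12}$, so off-grid
  penalties are solved rather than interpolated; coefficients below
  $10^{-9}\,\mathrm{sd}(y)$ — solver noise on a kilobase scale — are
  snapped to zero.

A constant training target returns an intercept-only model with a
warning rather than an error: the degenerate answer is well-defined.

### Application and age adjustment

`applyClock()` computes the weighted sum. Missing probes are an **error
by default**; `"mean_impute"` substitutes training means stored in the
model, and the number of imputed probes is reported per sample.
Rescaling over whichever probes happen to be present is deliberately not
offered — it silently changes the estimator.

`adjustForAge()` regresses the estimate on age by OLS and returns the
raw residual (negative = shorter than expected for age). Adjustment is
**per group** (per cohort) when a grouping is supplied, since pooling
cohorts with different age structures folds cohort effects into the
residual. Groups need at least 3 samples and nonzero age variance;
otherwise residualisation is undefined and the function says so.

## Association statistics

* **`bicor()`** implements the biweight midcorrelation from its
  definition: observations are median-centred, weighted by
  $(1-u^2)^2\,I(|u|<1)$ with $u = (x-\mathrm{med})/(9\,\mathrm{MAD})$
  (unscaled MAD), and the weighted midcovariance is normalised. A
  variable with zero MAD falls back to Pearson-style terms (mean
  centring, unit weights) for that variable; zero variance in both
  paths is an error, not an NA.
* **`linearAssoc()`** is OLS with Wald t tests; aliased (perfectly
  collinear) designs are an error naming the dropped terms rather than a
  silent drop. Cluster ids switch the variance to the cluster-robust
  sandwich — the implementable common denominator for pedigree and
  repeated-measure correlation (mixed models are out of scope).
* **`smokingAssoc()`** encodes the two-tier exposure convention of
  multi-cohort smoking analyses: pack-years when available, otherwise
  ever/never, adjusting for age and (when present with variation) sex
  and ethnicity. The returned t statistic is the per-cohort input to the
  Stouffer combination.
* **`coxAssoc()`** maximises the Cox partial likelihood with **Efron
  tie handling** (the modern default) and reports the hazard ratio per
  unit exposure. With a cluster id (or `robust = TRUE`) standard errors
  are the Huber sandwich estimator.

Two-sided p values and Wald tests are used throughout.

## Meta-analysis rules

`fixedEffectMeta()` pools with inverse-variance weights and reports
Cochran's $Q$ against $\chi^2_{k-1}$ ("Het. P"). `stoufferMeta()`
combines $Z = \sum_i \sqrt{n_i} z_i / \sqrt{\sum_i n_i}$.

Two conventions are worth making explicit:

* **Per-cohort t statistics are consumed directly as z scores.** This
  is the convention under which the bundled seven-cohort smoking
  statistics combine to the published row exactly (Z = −8.55 for the
  methylation outcome, −2.19 for measured TL); an exact t→z transform
  is available via `tToZ = TRUE` for users who prefer it. At the
  per-cohort sample sizes involved (97–878) the difference is in the
  second decimal.
* **Combined n is the sum of the per-study n** (3,898 for the bundled
  table). The published combined row prints 4,039; whether unlisted
  samples entered that count is not stated in the source material, so
  the discrepancy is surfaced rather than reconciled — the combined Z
  itself reproduces exactly from the listed rows.

## Enrichment

Coordinates are 1-based and fully closed internally; BED input is
converted on read and back on write, so BED round-trips are identity.
Distance to a chromosome end is $\min(pos,\; L - pos + 1)$ and
"sub-telomeric at D Mb" means distance $\le D\times10^6$. Both ends of
every chromosome count as tails; acrocentric p-arms are not
special-cased, because the literal both-ends reading is the only one the
method statements support.

`setOverlapTest()` computes the inclusive upper tail $P(X \ge k)$ of the
hypergeometric — inclusive being the standard enrichment convention —
by log-sum-exp over log probability masses, so p-values at the 1e-15
scale keep full relative accuracy. Tests verify it against direct
`choose()` enumeration on every instance with $N \le 30$ and against
factorial arithmetic up to $N = 170$ (the overflow limit of doubles).

Two background sizes circulate for the 450K/EPIC intersection (450,161
and 453,093); the package takes the background as an explicit argument
rather than resolving the discrepancy. With N = 453,093, K = 52,916,
n = 140, k = 51 the exact upper tail is 2.9e-14, one order of magnitude
above the published 2.6e-15; since two background sizes and two mQTL
counts appear in the source material, agreement is asserted at
order-of-magnitude level only.

## The synthetic-cohort generator

`simulateCohort()` exists so that every downstream stage has a testable
ground truth. What it emulates:

* **True TL**: linear in age, sex, BMI and pack-years with the
  published multivariate coefficients as defaults (intercept 8.43 kb,
  −0.022 kb/yr, +0.132 kb female, −0.007 kb per kg/m², −0.022 kb per
  pack-year), plus Gaussian noise. The noise SD default of **1.0 kb**
  was chosen by variance accounting: with uniform ages on 22–93 the age
  term contributes an SD of 0.45 kb, so total SD ≈ 1.12 kb puts the
  age–TL correlation near −0.40, the measured-TL regime (meta-analyses
  put it at roughly −0.30 to −0.34 in adults). Measured TL adds a
  0.15 kb assay-noise term (~2% CV of a 7 kb mean).
* **Causal CpGs** couple to centred true TL through a
  **linear-with-clipping** link: slope ±0.02 beta units per kb (random
  sign), baseline U(0.2, 0.8), Gaussian measurement noise (SD 0.02),
  clipped to [0,1]. Linear-with-clipping rather than logistic keeps the
  OLS recovery oracle exact away from the bounds; the clipping fraction
  is reported in the truth record so tests can confirm they sit in the
  linear region. At these defaults a single causal CpG carries a
  correlation of ~0.75 with true TL, so a 30-CpG clock can reach
  held-out correlations near 1 — the planted-recovery tests check the
  machinery, not a realistic effect-size ceiling.
* **Non-causal CpGs** are probe-specific Beta noise (precision 50,
  means U(0.05, 0.95)). Real array covariance structure is *not*
  emulated (see Limitations).
* **Survival** is exponential with log-hazard `log(0.37)` per kb of
  age-adjusted true TL and baseline hazard 0.03/yr; censoring is an
  independent exponential with rate chosen so the censored fraction is
  the configured rate (default 0.7) at the reference level. Since the
  Cox analyses are semi-parametric, any proportional-hazards generator
  suffices; exponential is the simplest.
* **Manifest**: probes placed uniformly over hg19 chr1–chr22 (lengths
  bundled as a plain-text table, overridable — hg19 being the
  450K-era standard), with a configurable fraction of causal CpGs
  forced into 3 Mb sub-telomeric windows.

`simulatePassaging()` reproduces the in-vitro dissociation: population
doublings per passage follow the verbatim convention
$(\log_{10}h-\log_{10}s)\times 3.32$ (3.32 ≈ 1/log10 2, so one exact
doubling yields 0.99942, not 1 — kept deliberately), the
methylation-TL track declines linearly in cumulative PD regardless of
the telomerase flag, and only the simulated TRF track responds to
telomerase.

## Problem sizes and stochastic test design

The suites run at sizes chosen to make the statistics sharp but the run
quick: planted-clock recovery at n = 500 × p = 2000 with 30 causal
CpGs; slope recoveries at n = 1,500–5,000; the smoking type-I-error
simulation at 1,000 null cohorts of n = 120; Cox null coverage over 200
replicates of n = 400 (≈120 events each — Wald intervals are
asymptotic, and at a few dozen events their small-sample
anticonservatism is a property of the method, not a bug in the code).
Single-draw "within 2 SE" checks are calibrated to fail 5% of the time
by construction, so where a recovery check is not pinned to a stated
condition the suite instead pools the standardized deviation across
independent replicates, which detects bias more powerfully at a ~0.3%
false-alarm rate.

## Known limitations

* Passing tests on the generator shows the estimator machinery is
  correct, **not** that a clock trained on real arrays will behave as
  well: real beta values have probe–probe correlation, batch structure,
  cell-composition confounding and non-Gaussian noise that the
  generator does not emulate.
* idat-level preprocessing, normalization and cell-count imputation are
  out of scope; beta matrices and imputed fractions are plain inputs.
* Pedigree correlation is handled by sandwich standard errors, not
  kinship mixed models.
* The exact published 140-CpG selection is not reproducible even in
  principle from public information (fold seeding and standardization
  of the original training are unstated), so the bundled 140-CpG
  coefficient file is a clearly-labelled synthetic stand-in with the
  published sign structure (72 negative, 68 positive weights), used to
  exercise the loader and the enrichment pipeline.
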