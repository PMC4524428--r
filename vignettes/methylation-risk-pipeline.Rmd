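---
title: "Genome-wide blood methylation and prospective cancer risk: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genome-wide blood methylation and prospective cancer risk: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methrisk)
```

## The scientific question

Tumour tissue is pervasively hypomethylated relative to normal tissue, and
the loss is not confined to repetitive elements: it spreads across gene
bodies, CpG-island shelves and open-sea sequence. `methrisk` implements an
analysis pipeline for asking a prospective version of that question in
*blood*: do women whose peripheral-blood DNA shows lower genome-wide
methylation — years before any diagnosis — carry a higher risk of breast
cancer? The design is a nested matched case–control study inside a
prospective cohort: incident cases are paired with cancer-free controls
matched on age and recruitment, methylation is measured on the Illumina
450k array (or, for pooled validation, by whole-genome bisulphite
sequencing), and the per-sample *mean β across probes* becomes the exposure
in a conditional logistic risk model.

The package covers the full chain: quality-control exclusion ledgers,
imputation and normalisation, white-cell probe filtering and deconvolution,
exposure construction, matched risk models, a probe-wise two-stage scan,
coverage-weighted pooled-WGBS summaries, and cross-study random-effects
meta-analysis, plus generators for synthetic data with the statistical
structure all of this assumes.

## The exposure: genome-wide methylation and its per-SD coding

For sample $i$, the exposure is $\bar\beta_i$, the arithmetic mean of the
β values (methylated fraction, in $[0,1]$) over a probe set — all probes,
or a genomic feature class (island / shore / shelf / open sea; promoter =
TSS200 ∪ TSS1500 ∪ 5′UTR ∪ 1st exon; gene body; 3′UTR; intergenic).

Risk models use two codings:

* **Quartiles**: boundaries are the 25/50/75% quantiles of the *control*
  distribution (linear-interpolation quantiles; values exactly on a
  boundary go to the lower quartile), and all subjects are labelled by
  those control-derived boundaries.
* **Pseudo-continuous per SD**: each subject is assigned the median
  control value of its quartile, then centred and scaled. Whose mean/SD
  define the scale is genuinely open (the source description is ambiguous
  between controls only and all subjects); we default to controls only so
  that the exposure scale is defined without reference to the outcome, and
  expose `scale_on = "all"` as the alternative.

The quartile-median coding is a deliberate coarsening — it trades
efficiency for robustness to outliers in the exposure tail — and it
attenuates a truly linear effect slightly toward the null. Calibration
checks of the estimator therefore inject and estimate the effect on the
same (continuous, standardized) exposure; the pseudo-continuous route is
exercised by the null-calibration checks, where attenuation is irrelevant.

## Matched risk models

With 1:1 matching, the conditional likelihood for pair $p$ with case
exposure difference $d_p = x_{p,\text{case}} - x_{p,\text{control}}$ is

$$L(\beta) = \prod_p \frac{e^{\beta d_p}}{1 + e^{\beta d_p}},$$

a no-intercept logistic model on within-pair differences with outcome
fixed at 1. `clogit_pairs()` maximises it by Newton–Raphson (gradient norm
< 1e-8); age enters as the within-pair age difference, because matching is
within ±5 years and residual differences remain. Complete separation (all
informative differences one-signed) is detected *before* optimisation and
raised as an error — a silently returned huge finite estimate is worse
than no estimate. Pairs with $d_p = 0$ are uninformative and are counted
separately; a fully degenerate exposure returns coefficient 0 with an
infinite, flagged SE.

Supporting analyses mirror the study design: quartile odds ratios against
a fixed Q1 reference, an unconditional logistic confirmation with
pair-clustered sandwich covariance (`robust_logistic()`), a paired
Wilcoxon signed-rank test (exact null for ≤25 tie-free differences,
otherwise the tie/continuity-corrected normal approximation), a
two-sample Kolmogorov–Smirnov comparison, ROC AUC as case-over-control
Mann–Whitney concordance with a DeLong confidence interval, and stratified
conditional fits (time to diagnosis, ER status) tested for homogeneity
with Cochran's Q — the heterogeneity test is not named in the source
description, and Q over stratum log-ORs is the conventional choice.

The individual risk distribution comes from a conditional model on a cubic
B-spline basis of the *continuous* exposure (the pseudo-continuous coding
has only four distinct values, which cannot support interior knots).
Degrees of freedom default to 4 with knots at exposure quantiles; the
fitted log relative risks are centred so the population mean log-RR is 0
(`center = "median"` is available, as the reference subject is not fixed
by the source description), and the 2.5/50/97.5 percentiles of
$e^{\log RR}$ summarise the distribution.

## Probe-wise two-stage scan

Technical variation on the array (chip, position on chip) is removed
per probe by a maximum-likelihood beta regression — logit mean link,
constant precision $\phi$, alternating Fisher scoring on the mean
coefficients and guarded Newton steps on $\log\phi$ to joint gradient norm
< 1e-8 — and the *response residuals* $y - \hat\mu$ carry forward.
(Standardized residuals are available via the stage-1 fit attributes; the
source description says only "residuals", and response residuals keep the
β-scale interpretation.) β values are clamped to $[10^{-6}, 1-10^{-6}]$
so the likelihood is finite at observed 0/1.

Stage 2 is a Poisson GLM of the case indicator on the residual
methylation and age, with $\log(\text{person-years})$ as offset — the
standard device whose Wald test approximates Cox partial-likelihood
inference for incidence data. On a binary indicator the Poisson variance
is conservative ($\mu$ vs $\mu(1-\mu)$), so stage-2 p values are valid but
not exactly uniform under the null; the family-wise error of the
Bonferroni-thresholded scan stays below nominal, which the acceptance
checks verify by simulation. The fitter is an in-package IRLS loop kept
deliberately lean — a genome-wide scan calls it once per probe — and is
asserted equal to `stats::glm` to 1e-8 in the unit tests.

`ewas_scan()` applies both stages per probe, flags
$p < \alpha/n_\text{probes}$, tallies direction (hypo- vs hypermethylated
in cases), and continues past per-probe failures, logging them.

## Preprocessing

* **Exclusion ledgers** record every QC step as (label, probes removed,
  samples removed) with running totals that must reconcile with the matrix
  dimensions; removals exceeding the remaining count are errors, not
  clamps.
* **Missingness filters**: probes missing in strictly more than 20% of
  samples, then samples missing strictly more than 5% of remaining probes
  ("not detected" is operationalised as missing-fraction; detection
  p-values require raw intensities, which are out of scope).
* **kNN imputation** works in probe space: Euclidean distance on shared
  samples against fully observed probes, mean of the k = 10 nearest (the
  method is named in the source, k is not; 10 is the conventional
  default).
* **Batch adjustment** is the empirical-Bayes location/scale method on
  M-values: per-probe standardisation, normal prior on per-batch means and
  inverse-gamma prior on per-batch variances (moments across probes),
  iterated shrinkage, rescaling. After adjustment each probe is recentred
  so its pooled mean is preserved exactly — a contract the downstream
  conservation checks rely on. Singleton batches are errors.
* **Peak-based type II correction**: per sample, the unmethylated and
  methylated density modes of type I and type II probes are located on the
  M scale (kernel density, bandwidth 0.5 M, modes at least 2 M apart) and
  type II M-values are linearly mapped so its modes land on type I's.
  BMIQ — the alternative the original analysis preferred — needs its own
  mixture machinery; the peak-based method was co-validated as performing
  equivalently on well-separated peaks, and any β-transformer can be
  substituted ahead of this step. A unimodal sample is an error naming the
  sample.
* The order is batch adjustment, then peak correction, matching the stated
  processing order. Whether imputation preceded batch adjustment outside
  the PCA is ambiguous in the source; both orders run, and the PCA
  entry point requires a complete matrix explicitly.

## White-cell composition

Whole-blood methylation mixes cell types. From a purified-cell reference
panel, `find_celltype_probes()` flags probes whose β differs between each
cell type and a baseline (PBMC replicates by default; the panel average is
the configurable alternative since the baseline for granulocytes is not
pinned down) by simple linear regression on the type indicator —
identically the pooled-variance t test — at p < 1e-7 **and** |Δβ| > 0.05
(the sign is applied as absolute value). The union across types is
removed from analysis. `estimate_cell_proportions()` projects a sample
onto the reference mean profiles under proportions ≥ 0 and sum ≤ 1
(nonnegative least squares with a slack component for the sum cap — the
standard reference-based deconvolution contract).

## Pooled WGBS summaries

Pooled libraries give one methylation fraction per CpG per pool, with
very uneven coverage. Each site's weight is 1 at or above the pool median
coverage, and drops by 0.1 for each *complete* 10%-of-median decrement
below it, floored at 0; the decrement count uses exact integer arithmetic
on read counts so a site exactly 10% below the median gets 0.9. Two open
boundary choices are parameters: coverage exactly at the median gets full
weight (the printed rule says "greater than"; penalising the median site
would be perverse), and a "started-decrement" variant is available. The
pool median is computed once over all sites, before feature subsetting.
Feature summaries use interval overlap (GenomicRanges, 1-based inclusive
coordinates matching Bismark coverage output); pool contrasts report
case-minus-control differences in percentage points.

## Meta-analysis

Study records are (OR, 95% CI, n); `ci_to_se()` recovers the log-OR and
its SE as $(\ln u - \ln l) / (2 \times 1.959964)$ (the full-precision
normal quantile; printed CIs rounded to two decimals are accepted as-is).
Cochran's Q with inverse-variance weights tests homogeneity on $k-1$
degrees of freedom, and the DerSimonian–Laird estimator
$\hat\tau^2 = \max(0, (Q - (k-1))/(\sum w - \sum w^2/\sum w))$ feeds the
random-effects summary. No Knapp–Hartung adjustment is applied, matching
the conventional tooling for this design. `forest_table()` lays the
studies and the summary out for plotting or export.

## Sample PCA and covariate screening

`pca_samples()` decomposes the transposed, probe-centred M-value matrix;
`pc_covariate_assoc()` screens each component against covariates —
continuous ones by the univariate regression slope (equivalent to the
Pearson test; the source table's test is not named), categorical ones per
level against the reference level, and the chip variable as the minimum p
over chip indicators, where a small value flags residual batch structure.

## What the synthetic data emulates — and what it does not

`generate_pairs()` draws per-probe baselines from a three-component
mixture on the logit scale (unmethylated/intermediate/methylated modes at
−2.6/0/+2.2, category-dependent mixing so islands sit low and gene bodies
high), then adds a shared pair effect, a per-subject genome-wide offset,
per-probe chip offsets, and per-probe subject noise; cases receive
category-targeted logit shifts, and missingness is completely at random.
Default scales are calibrated to the study conditions: per-sample
genome-wide mean SD ≈ 0.4 percentage points, within-pair exposure
correlation ≈ 0.4 at genome scale (the within-pair correlation is not
reported anywhere, so it is an explicit parameter), and the default case
shift (−0.029 logit on gene-body/shelf/open-sea probes) produces the
≈ −0.2 pp genome-wide case–control difference. A nonzero
`effect_logor_per_sd` instead assigns case status within each pair with
the conditional-logistic probability implied by the members' genome-wide
means, so the injected per-SD log-OR is the exact estimand of
`clogit_pairs()`.

WGBS pools draw per-site depth from a negative binomial (the source states
only "50× coverage"; mild overdispersion, size 20) and methylated reads
binomially; the case pool's truth is shifted at gene-body sites.
Reference panels plant an exact number of discriminating probes at
|Δβ| = 0.2 against a replicate noise SD of 0.01.

Passing tests on these generators demonstrate *statistical* correctness —
estimator calibration, error control, recovery of injected effects — under
the assumed structure. They do not demonstrate robustness to what real
arrays add: probe-specific chemistry artefacts, cell-composition
confounding correlated with outcome, SNPs under probes, non-random
missingness, or population stratification.

## Problem sizes and numerical choices

Simulation-based checks use sizes chosen to keep the full suite
comfortably reproducible on a laptop while leaving Monte-Carlo error well
inside the asserted margins: 200 replicates of 500 pairs for per-SD
recovery and CI coverage; 500 replicates of 1,000-probe null scans (30
pairs each) for family-wise error; 2,000 null datasets of 200 pairs for
the Wald test's type-I error; 100 simulations for batch-adjustment
verification; 200,000 CpG sites at 50× for the pooled-WGBS contrast, where
binomial noise alone sets the ±0.1 pp recovery margin. Fisher scoring and
Newton loops stop at gradient norm 1e-8 (50–100 iteration caps, which are
errors when hit, never silent returns); β is clamped at 1e-6 from the
boundary; z = 1.959964 is used internally wherever a 95% interval is
constructed.

## Known limitations

Raw-intensity processing (background subtraction, dye-bias correction,
detection p-values), BMIQ itself, reference-free cell-mixture adjustment,
and sequencing read QC/alignment are out of scope by design. The
two-stage scan's stage-2 p values are conservative on binary outcomes (see
above). The NNLS sum-cap uses a heavy-equality-row augmentation rather
than a full active-set QP, which is exact to ~1e-8 — ample for proportions
asserted to ±0.05. The peak-correction mode finder requires genuinely
bimodal samples and will (correctly) refuse heavily degraded ones.
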