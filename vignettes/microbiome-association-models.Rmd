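---
title: "Multi-model multivariable association testing for microbiome features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-model multivariable association testing for microbiome features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mbassoc)
```

## The problem

Case/control microbiome studies rarely admit a single obviously-correct
regression model. Covariates such as delivery mode, diet, age and medication
use all shape the gut community, and several of them are typically correlated
with the phenotype of interest. The practical consequence is that an
association between a microbial feature and a clinical variable can appear,
vanish, or move to a different variable depending on which covariates the
analyst includes. mbassoc makes that instability a first-class object of
study: it fits the *same* per-feature multivariable model family under
several candidate covariate sets over identical data, and aligns the results
so that each feature-variable association can be traced across models.

## The model

For each microbial feature $j$, after preprocessing (below), the transformed
relative abundance $y_{ij}$ of sample $i$ is modelled as

$$
y_{ij} = \beta_{0j} + \sum_k \beta_{kj} x_{ik} + u_{s(i),j} +
\varepsilon_{ij}, \qquad u_{s,j} \sim N(0, \sigma_u^2),\;
\varepsilon_{ij} \sim N(0, \sigma_e^2),
$$

where the $x_{ik}$ are the model's fixed-effect covariates — treatment-coded
indicators for each non-reference level of a categorical variable, plain
columns for continuous variables — and $u_{s(i),j}$ is a per-subject random
intercept that absorbs the repeated-measures structure of a longitudinal
cohort. With no random variables the model reduces to ordinary least squares
and Wald tests use the exact $t$ distribution on residual degrees of
freedom; with random intercepts the model is fitted by REML (via lme4) and
Wald tests use the normal approximation. We deliberately do not use
Satterthwaite or Kenward-Roger degrees of freedom: with hundreds of samples
and modest numbers of fixed effects the normal approximation is accurate,
and it keeps the per-feature fit cheap and stable across thousands of fits.
The approximation is exercised explicitly in the tests: on data simulated
with zero between-subject variance, mixed-model estimates must match the
OLS fit to $10^{-3}$.

All nominal p-values of one model run — every feature crossed with every
tested term — form a single Benjamini-Hochberg family, and the adjusted
q-values are the significance currency everywhere downstream. We adjust per
run (not across runs) so that adding a candidate model never changes an
existing model's q-values; the cross-model comparison would otherwise be
unstable under exactly the manipulation it is meant to study.

Failed fits never abort a run: constant features are reported as
`skipped_constant`, inestimable or non-converged fits as `fit_failed`, and
their missing p-values are excluded from the BH family size. Singular
(boundary) mixed fits — a variance component estimated at zero — keep their
fixed-effect estimates, which are then numerically the OLS estimates; only
genuine non-convergence is reported as failure.

## Preprocessing

Three steps run before any fitting, in this order:

1. **Total-sum scaling.** Each sample row is divided by its total, so
   features become relative abundances summing to 1. Samples with zero total
   cannot be normalised and are dropped with a logged warning.
2. **Low-abundance filter.** A feature is removed iff its total normalised
   abundance over all samples is *strictly* less than `1e-4`. The boundary is
   deliberately strict (a feature summing to exactly `1e-4` is retained) and
   tested at the boundary.
3. **Arcsine square-root transform (AST).** $y = \arcsin\sqrt{x}$ maps
   $[0,1]$ onto $[0, \pi/2] \approx [0, 1.57079]$, spreading small
   proportions while keeping zeros at zero — a sensible variance-stabilising
   choice for sparse compositional data. The transform is a per-run toggle
   (`ast = FALSE` passes abundances through untouched) for users whose input
   is already on a suitable scale.

**Missing metadata.** A sample with a missing value in a model variable is
excluded from that model's fit only (complete-case mask per model). The same
sample remains visible in detail views as an explicit `"NA"` category, which
never contributes to any statistic. A model that does not use the affected
variable keeps the sample. No per-feature outlier removal is performed; the
preprocessing contract is exactly the three steps above.

## Variable typing and reference levels

String metadata columns are categorical. Numeric columns with at most four
distinct non-missing values are treated as categorical, five or more as
continuous; missing values never count as a level (missingness is handled by
the complete-case contract, not as a category). User-supplied kinds override
inference. Categorical levels sort lexicographically (C collation, so
results do not depend on the session locale), the first level is the default
reference, and a per-model override can re-reference any variable. Random
variables are always grouping factors, whatever their storage type.

## Comparing models

`compare_models()` keeps every feature whose q-value falls strictly below
the threshold (default 0.2) in at least one model, and records q for *all*
(model, variable, level) columns of those features, including
non-significant ones — seeing an association dissolve is exactly as
informative as seeing it appear. The heatmap colours only cells with
q below the display threshold; cells for terms a feature was never tested
under (possible when models disagree on preprocessing flags) are drawn grey
("not tested"), distinct from white ("not significant"). The long-format
TSV is the canonical export; the wide matrix is derived for plotting.

## Detail views and faceting

`association_detail()` returns one record per sample — including samples the
model masked out — with the transformed abundance the model actually saw.
Unfaceted categorical plots annotate each reference-vs-level bracket with
the model's q-value. Faceting splits the panel by another variable's levels
("NA" panel last); model q-values are then dropped and replaced by two-sided
Welch t-tests computed within each facet from *all* plotted samples, with no
model-based masking. Welch (unequal variances) is used because it is the
default of the plotting ecosystem this workflow emulates; only
reference-vs-level comparisons are tested, for consistency with the bracket
convention. A comparison with fewer than two samples on a side, or constant
values on both sides, is reported `untestable` rather than failing. Box
geometry uses linearly interpolated quartiles (R's default `quantile`
type 7), fixed so the plotted statistics are testable.

## The synthetic cohort generator

`generate_cohort()` is the package's self-contained test bed. It emulates
the structure of a longitudinal infant cohort: 160 subjects by 6
visits (ages ~2-12 months), binary disease with prevalence 0.5, binary
probiotic use drawn *conditionally on disease* (0.6 given disease, 0.1
given health — the confounding channel), independent delivery mode and
3-level diet, and 50 compositional features. Latent abundances are built on
the AST scale — baseline + planted effects + subject intercept + Gaussian
noise — clamped to $[0, \pi/2]$, back-transformed by $\sin^2$, and
renormalised to closure.

Numerical sizing matters here, and was done analytically before any testing:
the expected closure total is
$\sum_f \mathbb{E}[\sin^2(b_f + u + e)] \approx \sum_f \sin^2(b_f) +
n_f\,\sigma^2$, so with 50 features and total noise SD
$\sqrt{0.06^2 + 0.05^2} \approx 0.078$ the noise term alone contributes
~0.3. Baselines are therefore drawn from $U(0.08, 0.155)$, making the
expected total ~1.02; renormalisation then perturbs planted effects only at
second order, and fitted coefficients are directly comparable to the
planted truth. (An earlier sizing that ignored the $n_f\sigma^2$ term gave
totals near 2 and attenuated every planted coefficient by ~30% — the
analysis above is what the defaults encode.) Default planted effects are
+0.10 AST units on disease, +0.008 per month of age, and +0.08 on formula
diet; the confounder scenario plants +0.3 on probiotic use. Two per cent of
subjects have missing reported probiotic status (the *true* status still
drives the planted effect), exercising the NA contract end to end.

What the generator does *not* emulate: phylogenetic correlation between
taxa, zero-inflation beyond clamping, overdispersion, and real abundance
distributions. Passing tests therefore demonstrate the statistical
machinery — calibration, recovery, FDR control, confounder attribution —
under a clean compositional data-generating process, not robustness to every
pathology of real 16S data.

## Validation performed by the test suite and acceptance script

All problem sizes are the generator defaults (960 samples, 50 features);
replicate counts are 10 (null calibration) and 25 (recovery, confounder
shift).

- **Oracle equivalence.** BH q-values against a brute-force step-up
  enumeration on 1,000 random p-vectors; single-binary-covariate OLS
  p-values against the closed-form pooled t-test, and facet Welch p-values
  against the closed-form Welch statistic, both to $10^{-10}$.
- **Null calibration.** With no planted effects and no subject variance,
  per-run p-values are Kolmogorov-Smirnov-uniform (p > 0.01) in at least 9
  of 10 seeds.
- **Parameter recovery.** Per replicate, the mean absolute error of the
  planted coefficients stays below twice the mean reported standard error;
  required in at least 95% of 25 replicates.
- **Confounder shift.** In the confounded scenario the planted feature is
  significant on disease (q < 0.2) in the model lacking probiotics, and on
  probiotics — with an inflated disease q — once probiotics enters; required
  in at least 90% of 25 replicates.
- **Determinism.** Identical configurations reproduce byte-identical result
  TSVs.

`scripts/acceptance.R` recomputes all of these from scratch at run time for
any seed.

## Known limitations

- Mixed-model p-values are asymptotic; for very small cohorts (tens of
  samples) the normal approximation is anti-conservative and the OLS path
  or a dedicated small-sample method is preferable.
- Multiple random variables are supported as crossed random intercepts via
  lme4's formula interface, but the tested path is the single grouping
  factor (subject) that longitudinal designs need.
- No interaction terms, random slopes, zero-inflated likelihoods, or
  non-Gaussian links — the model family is deliberately the simple,
  comparable one.
- The BH family is per model run; q-values are not comparable as posterior
  error probabilities *across* models, only as each model's own FDR
  currency.
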