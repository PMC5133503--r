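---
title: "Constrained multivariate association for longitudinal traits in pedigrees"
author: "longvc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constrained multivariate association for longitudinal traits in pedigrees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(longvc)
```

## The problem

Longitudinal cohorts measure the same quantitative trait — here the
running example is systolic blood pressure (SBP) — at several visits, yet
most genetic association analyses use a single time point or discard the
repeat structure. When a variant's effect is stable over time, the
repeats carry replicated information about the same genetic signal, and a
model that uses all of them jointly should detect smaller effects than a
single-visit analysis. In family studies the additional complication is
relatedness: phenotypic resemblance between relatives must be absorbed by
a polygenic covariance term or every test is miscalibrated.

`longvc` implements a measured-genotype variance-component framework for
exactly this setting and compares three strategies:

* **constrained** — all k repeated measurements are modelled jointly and
  the variant's mean effect is forced equal across visits
  (`beta_1 = ... = beta_k = beta`), giving a 1-df likelihood-ratio test;
* **unconstrained** — per-visit effects `beta_t` estimated freely, a k-df
  test;
* **average** — a univariate test on the per-individual mean of available
  visits.

A fourth, gene-centric, strategy replaces the single-variant fixed effect
with a variance component carried by a region-local empirical kinship
matrix (`h2_geff`), tested on the boundary of the parameter space.

## The model

For individual i with trait vector `y_i = (y_i1, ..., y_ik)'` the stacked
model over all n individuals is multivariate normal with mean

```
E[y_it] = mu_t + x_i' b_t + g_i beta_t
```

(`x_i` covariates, `g_i` the 0/1/2 ALT dosage) and covariance

```
Omega = 2 Phi (x) G + I_n (x) E (+ K (x) u u')
```

where `Phi` is the pedigree kinship matrix computed by the recursive
tabular method, `G` and `E` are unstructured k-by-k additive-genetic and
environmental covariance matrices across visits, and, in gene-centric
models, `K` is a standardized (VanRaden-type) genetic relationship matrix
built from the variants of one region with per-visit loadings `u`. All
parameters are estimated by maximum likelihood; mean coefficients are
profiled out by GLS at every step, and the covariance parameters are
optimized on a log-Cholesky scale so `G` and `E` remain positive
semidefinite without explicit constraints.

Tests are likelihood-ratio tests. The constrained and average tests
compare against `beta = 0` with one degree of freedom; the unconstrained
test uses k degrees of freedom. The gene-centric test of
`sigma2_geff = 0` sits on the boundary of the parameter space, so its
null is the 1/2:1/2 mixture of a point mass at zero and a 1-df
chi-square; a statistic of exactly zero is reported as `p = 1` so that
boundary fits are never read as suggestive. For the multivariate
gene-centric model with free per-visit kernel loadings the exact
simultaneous-boundary mixture is analytically messy, and a plain k-df
chi-square upper tail is used instead; this choice is conservative.

### Numerical strategy

`Omega` is block-diagonal by pedigree, and for complete (no missing
visit) data the per-pedigree eigendecomposition of `2 Phi` reduces one
likelihood evaluation to n independent k-by-k problems; the inner loop is
compiled code with closed-form small-matrix inverses and an analytic
gradient of the profile likelihood (envelope theorem at the GLS
coefficients). Region kernels enter through the Woodbury identity, so
the cost stays linear in n for m region variants. Missing visits are
handled by row/column deletion from the stacked system (an MAR
assumption) in a dense fallback path; the two paths agree to numerical
precision on complete data and that agreement is part of the test suite.

Optimization uses `nlminb` starts from a moment (Haseman–Elston-style)
estimator — regressing rotated residual cross-products on the
relationship eigenvalues gives closed-form starting values for `G` and
`E` — with sample-covariance splits as fallback restarts when the first
attempt genuinely fails. Boundary optima (a genetic variance near zero,
a cross-visit genetic correlation of 1) are legitimate and are flagged,
not retried. Alternative fits are warm-started from their null fit, which
also enforces `logL_alt >= logL_null` exactly; LRT statistics are clipped
at zero and a statistic below `-1e-6` is treated as an upstream
optimization failure.

## A worked example

```{r example, eval = FALSE}
cfg <- simConfig(nPedigrees = 4, totalSize = 160,
                 causal = data.frame(maf = 0.2, varFrac = 0.05))
rep <- simReplicate(cfg, seed = 42)
assocTest(rep$genos, rep$phen, rep$ped,
          covariates = c("age", "sex", "smoke"),
          variantIds = "causal_1")
```

The README shows the numbers this prints and how to read them.

## What the synthetic generator emulates

The generator mirrors the design of a large family-based blood-pressure
study: 20 extended pedigrees totalling 849 individuals over 3–4
generations, three visits of an SBP-like trait, age/sex/smoking
covariates, gene-dropped biallelic genotypes, and variant effects that
are constant over time. Its defaults are the package's study conditions:

* nine causal variance fractions
  `0.0278, 0.0206, 0.0149, 0.0143, 0.011, 0.0081, 0.004, 0.0027, 0.0017`
  — read as *proportions* of trait variance. (The alternative reading as
  percentages would make every effect invisible at this sample size; the
  proportion reading reproduces the qualitative power ordering.) The
  per-allele effect for fraction V at frequency p is
  `beta = sqrt(V * sigma2_total / (2 p (1 - p)))`.
* polygenic heritability 0.40 per visit with genetic cross-visit
  correlation 1.0 (time-stable genetic effects); environmental
  correlation 0.4 between visits. These put the phenotypic cross-visit
  correlation near 0.6–0.7, typical of repeated blood-pressure measures.
* covariate effects on the trait-SD scale: 0.01 per year of age, 0.30
  for sex, 0.25 for smoking (prevalence 0.2); baseline age ~ N(45, 12)
  rounded and clipped to 18–85, visits 5 years apart; per-visit
  intercepts rise by 0.1 SD per visit.
* causal-variant MAF defaults to 0.2; null variants draw MAFs uniformly
  from (0.05, 0.5).

Per-replicate seeds are split from the master seed by a fixed counter
stride so any replicate can be re-run alone. The pedigree set is held
fixed across replicates, as in the study design being emulated;
genotypes are redrawn per replicate by default (`regenotype = FALSE`
reuses one draw, mimicking a fixed observed genotype panel).

What the generator does **not** emulate: linkage disequilibrium (variants
are dropped independently, including within a region), ascertainment,
medication use or secular trends beyond the fixed per-visit intercepts,
non-Gaussian trait distributions, and genotyping error. Calibration and
power results on these simulations therefore demonstrate correctness of
the statistics under the model's own assumptions, not robustness to
real-data artifacts.

## Design choices that were genuinely open

* **Covariance algebra.** The direct-product form
  `2 Phi (x) G + I (x) E` is the standard multivariate extension of the
  univariate polygenic model and is fixed here as the model definition.
* **Kernel formula.** The region kernel is the standardized GRM
  `K = (1/m) sum_j (g_j - 2 p_j)(g_j - 2 p_j)' / (2 p_j (1 - p_j))`,
  which puts `sigma2_geff` on the same scale as the polygenic component;
  REF/ALT orientation cancels by centering. Other local-kinship
  estimators scale differently, so `h2_geff` values are comparable only
  within one choice of kernel. Both `2 Phi` and `K` are retained in the
  model simultaneously, so `h2_geff` measures the *departure* of local
  sharing from pedigree expectation.
* **Multivariate kernel effects.** Across visits the kernel component is
  rank-1, `K (x) u u'`, i.e. a regional genetic effect perfectly
  correlated over time with per-visit loadings `u_t`; the "constrained"
  variant forces the `u_t` equal. A per-visit-independent alternative
  (diagonal instead of rank-1) would contradict the time-stable-effects
  premise and costs k-1 extra boundary parameters.
* **Covariate screening** is marginal — one candidate at a time in the
  polygenic model for the time-averaged trait, retained at p < 0.05 —
  matching the convention of the variance-component software this design
  follows. The candidate set is age (centered), sex, age x sex, age
  squared, age squared x sex, and smoking.
* **Missing dosages** are mean-imputed (2 x ALT frequency) at test time.
  Half-specified parents in pedigree files get a synthesized anonymous
  founder (with a warning) instead of a hard error; individuals
  phenotyped or genotyped but absent from the pedigree are a hard error,
  since silently treating them as founders would corrupt `Phi`.
* **Tally ties.** Replicate counts use strict `p < threshold`;
  a p-value exactly at a threshold does not count.
* **Degenerate inputs.** Monomorphic variants return `p = 1` with a
  flag; constant covariate candidates are skipped with a warning; a
  rank-deficient mean design and a zero-variance trait are errors.

## Problem sizes used in the checks

The statistical acceptance checks simulate at the emulated design scale
(20 pedigrees, 849 individuals, 3 visits): 500 replicates for null
calibration of all four tests at alpha 0.05 and 0.01, 200 replicates for
the power ordering of the three single-variant strategies at a threshold
of 5e-5, and 100 replicates for parameter recovery (polygenic share,
shared SNV beta, cross-visit genetic correlation). The gene-dropping
cross-check of the recursive kinship algorithm uses 1e5 drops on 20
random pedigrees of up to 20 members. These sizes give Monte-Carlo
standard errors comfortably below the tolerances being asserted while
keeping a full run in the minutes range.

## Known limitations

* ML, not REML: variance components carry the usual O(p/n) downward
  bias from estimating mean parameters; at n = 849 this is negligible
  for the tests but visible if you compare variance estimates against
  REML software.
* The asymptotic chi-square and mixture nulls are used at all sample
  sizes; very small studies (tens of individuals) should not rely on the
  tail calibration.
* No ascertainment correction, dominance variance, gene-by-age
  interaction, or X-linked kinship.
* The unconstrained gene-centric p-value is conservative by
  construction (see above).
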