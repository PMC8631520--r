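---
title: "Whole-tumor texture analysis for phyllodes tumor grading: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-tumor texture analysis for phyllodes tumor grading: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phyllotex)
```

## The problem

Phyllodes tumors of the breast are graded benign versus borderline/malignant,
and the grade decides the extent of surgery. Conventional MR morphology
separates the grades poorly; quantitative texture analysis of the
contrast-enhanced volume is a candidate discriminator because the
borderline/malignant stroma is more heterogeneous. `phyllotex` implements the
complete analysis chain for this question: whole-tumor gray-level
normalization and quantization, a 314-feature texture extractor, a four-stage
feature-selection cascade ending in a backward-stepwise logistic grading
model, and the evaluation layer (ROC with DeLong machinery, Hosmer–Lemeshow
calibration, contingency tests for categorical imaging findings, inter-rater
ICC). Because the patient images behind the original study are not publicly
deposited, the package ships a synthetic 3D lesion-phantom generator that
reproduces the *statistical structure* the analysis assumes, so every stage is
exercised end to end by code alone.

## Gray-level normalization and quantization

All texture statistics operate on discrete gray levels inside the manually
delineated whole-tumor VOI. Intensities `x` are clipped to the window
\[μ − 3σ, μ + 3σ\], with μ and σ the mean and *population* standard deviation
over the VOI voxels, and mapped linearly onto `Ng` levels:

```
level = 1 + floor((x_clipped − (μ − 3σ)) / (6σ) · Ng),   upper endpoint → Ng
```

The resulting levels are invariant under any positive affine intensity
rescaling, which removes scanner brightness/contrast variation — the point of
the procedure. Numerical choices:

* **Ng = 64 (default, configurable).** The bit depth is a convention; the
  1..64 scale matches the magnitudes that whole-lesion breast-MRI texture
  reports print for histogram features (means and percentiles in the 20–50
  range). Levels are 1-based so histogram/co-occurrence index arithmetic
  follows the classical formula conventions.
* **Population σ** (denominator Np), matching the printed variance definition
  used by this analysis family.
* **σ = 0** (constant VOI) maps every voxel to level 1 with a warning rather
  than erroring, so degenerate phantoms remain usable in tests.
* The mask is used exactly as given: no morphological cleaning, no
  reorientation of the NIfTI arrays.

## The feature set

314 features per lesion under the default configuration, named after the
field's established registry conventions (`feature_registry()` is the single
source of truth):

| family | count | construction |
|---|---|---|
| histogram | 9 | Mean, Variance (population), Skewness, excess Kurtosis, percentiles 1/10/50/90/99 (smallest level whose cumulative count reaches the quantile) |
| co-occurrence (GLCM) | 275 | 11 Haralick statistics × 5 directions (3 axes + 2 in-plane diagonals) × distances 1–5; symmetric accumulation, both-ends-in-VOI pairs only |
| run length (RLM) | 25 | 5 statistics × 5 directions (Z, horizontal, vertical, 45°, 135°); runs break at non-VOI voxels |
| absolute gradient | 5 | central differences on the quantized levels at voxels whose 6-neighborhood lies inside the VOI |

Three conventions deserve note. Entropy-type features use the natural
logarithm (the base only rescales them). Co-occurrence matrices are
normalized to probabilities; the classical software this emulates prints
angular second moment medians far above 1, which is impossible for a
normalized Σp², so no attempt is made to match those magnitudes — only
within-cohort contrasts are meaningful. Features whose defining denominator
degenerates (correlation of a zero-variance matrix, moments of an empty
gradient field) are reported as missing *with a recorded reason* rather than
as 0, so the selection stage can drop them transparently.

## The selection cascade

`run_cascade()` chains four stages, each recording every removal and its
reason in a trace; kept sets are nested and the procedure is deterministic.

1. **Variance threshold (0.8, strict `<`)** on the *raw* feature scale. The
   source protocol standardizes before thresholding, but z-scored columns all
   have variance 1, which would make a 0.8 threshold vacuous — the order here
   is variance filter first, standardization second (configurable via
   `standardize_first`). A consequence worth knowing: small-scale families
   (normalized angular second moment, entropies) are removed at this stage by
   construction.
2. **Standardization** to z-scores (sample SD); parameters are stored in the
   fitted model so it can score raw features later.
3. **Gated univariate tests.** Per feature: if both class distributions pass
   Kolmogorov–Smirnov normality (p > 0.05, against a normal with estimated
   moments — the Lilliefors correction is noted as an option but the plain
   test is the default) and Levene homogeneity (mean-centered, p > 0.05), a
   pooled-variance t-test; otherwise Mann–Whitney U (normal approximation,
   tie-corrected, no continuity correction). Keep p < 0.05.
4. **Univariate logistic screen** (Wald p < 0.05). Perfect separation makes
   the Wald test meaningless; separated features are flagged and *kept* —
   in small cohorts separation is the strongest signal, not an artifact.
5. **Backward-stepwise multivariate logistic regression**: iteratively remove
   the feature with the largest likelihood-ratio removal p while it exceeds
   0.10 (a standard statistical-package default; the protocol states neither
   the criterion nor the threshold). Aliased features are removed first.
   When the full model is saturated or separated, every removal has LR p = 1;
   these ties are broken by removing the feature with the weakest *marginal*
   (single-predictor) deviance reduction, so the features with the strongest
   standalone support survive the degenerate phase. No multiple-testing
   correction is applied anywhere in the cascade, matching the protocol being
   reproduced (this is documented, not endorsed).

With 47 lesions and hundreds of informative candidates the final model is
overfit by construction (training AUC near 1); this mirrors how such small
single-center radiomics studies evaluate themselves, and it is why the null
behavior tests score on independent cohorts (below).

## Evaluation layer

* **AUC** is the Mann–Whitney estimator (ties count ½), with DeLong
  placement-value variance. The 95% CI is built on the logit scale so it
  respects \[0, 1\] (normal-scale CI available). The operating point is the
  Youden maximum, ties broken toward the higher (more specific) threshold.
* **Paired DeLong test** for correlated AUCs; identical rankings give a
  degenerate variance and p = 1 with a flag.
* **Hosmer–Lemeshow**: decile-of-risk groups (ties kept together), χ² with
  G − 2 degrees of freedom, degenerate groups merged with a neighbor. The
  G − 2 reference is calibrated for *fitted* probabilities; feeding true
  external probabilities makes the statistic ~χ²_G and the test liberal.
* **Pearson χ² without continuity correction** for 2×K findings tables —
  this choice exactly reproduces the recomputable printed p-values of the
  source cohort's contingency rows (0.014, 0.916, 0.851, 0.466); with the
  Yates correction none of them match. Fisher's exact test is available for
  2×2 tables.
* **ICC(2,1)** — two-way random effects, absolute agreement, single
  measures — with the conventional agreement bands (poor → excellent, upper
  bounds closed).
* **The published grading model** is shipped as a frozen evaluator
  (`evaluate_published_model()`): five fixed coefficients on z-scored inputs
  and intercept −4.552. It is a pure function; no fitting path can alter it.

## The phantom generator

`generate_lesion()` builds a lobulated ellipsoid mask (low-order angular
perturbation of the radius), fills it with a Gaussian random field
(squared-exponential correlation at a chosen length, implemented by separable
Gaussian smoothing of white noise with σ = ℓ/√2), adds white noise, optional
bright focal patches, and an optional zero-enhancement cystic cavity — a
single sphere (regular wall) or a union of offset spheres (irregular wall),
always strictly inside the mask.

The two classes are driven by a latent severity `u` with overlapping ranges
(benign-like `u ~ U(0, 0.65)`, malignant-like `u ~ U(0.35, 1)`); severity
raises lobulation, shortens the correlation length (3.5 → 0.9 voxels),
darkens the base enhancement, and adds a few small but very bright focal
patches. Two consequences give the class contrasts their direction:

* The thin, extreme bright tail inflates σ, so after μ±3σ normalization the
  bulk of a severe lesion is compressed into fewer, lower levels — histogram
  **Mean, Variance and Perc.90% fall** with severity (the benign class's
  higher values also reflect its small dark cavity being clipped at the lower
  window edge).
* The shorter correlation length fragments the volume into many short runs
  concentrated on few levels, so **gray-level non-uniformity rises** with
  severity.

The overlap of the severity ranges caps the achievable class separation near
the published texture-model AUC (≈ 0.89 at the population level) instead of
letting the classes separate perfectly. Cohort composition defaults to 26
benign-like and 21 malignant-like lesions on 32×32×24 grids; cystic-component
and wall-regularity frequencies follow the published findings table
(85% cystic in both classes; irregular walls in 61% of malignant-like vs 23%
of benign-like cyst-bearing lesions), and the findings CSV is derived from
the actually generated geometry. Every artifact is a pure function of
(spec, seed).

**What the phantoms do not emulate.** No MRI physics (coil profiles, bias
fields, k-space artifacts), no pharmacokinetic enhancement curves, no
inter-observer segmentation variability. One known contrast is deliberately
not reproduced: the angular-second-moment direction comes out *reversed*
relative to the source cohort (severity concentrates the level histogram,
which raises Σp²); the generator's verified contrasts are Mean, Variance,
Perc.90% and the GLevNonU family. Passing tests therefore demonstrate that
the pipeline recovers the statistical structure the generator plants — not
that it would reproduce the source study's numbers on real images.

**What "recovering planted signal" means.** The severity mechanism imprints
on most of the 314 features at once, and many are statistical near-duplicates
(histogram Variance versus co-occurrence sum-of-squares, for example). Which
member of an equivalent family the stepwise model retains is a tie-break
artifact, not science. Signal recovery is therefore defined at the population
level: `planted_signal_features()` labels a feature as signal-carrying when
its single-feature class AUC on an independent fixed-seed reference cohort
(50 + 50 lesions) departs from 0.5 by at least 0.20, and the recovery check
asks that the final model contain at least one such feature — i.e. that
selection returns signal rather than noise. The named-feature recovery
question is answered at the cascade's retention screens, where the histogram
location family and the GLevNonU family are reliably kept.

## Problem sizes used by the test suite

Oracle-equivalence suites run on exhaustive small cases (volumes up to 5³,
2–4 gray levels, AUC samples up to n = 30). Calibration suites use 1000
paired-DeLong null replicates at n = 100 and 500 Hosmer–Lemeshow replicates
at n = 500. Cohort-level properties use the default 26 + 21 cohort across 20
master seeds for recovery, and 20-vs-20 cohorts for direction checks. These
sizes were chosen so the whole suite exercises every claim at meaningful
power while remaining a routine desk run.

## Known limitations

* The cascade's final model is evaluated in-sample, exactly as the emulated
  protocol does; no cross-validation or external validation is provided
  (deliberately out of scope).
* The variance threshold on raw scales makes stage-1 survival depend on
  feature units; this is inherent to the emulated protocol and is the reason
  normalized-scale families cannot reach the final model under defaults.
* Absolute feature magnitudes are not comparable to reports produced by the
  classical texture software, whose scaling of several families is
  undocumented; only within-cohort contrasts are interpretable.
* The published-model evaluator expects z-scores computed on *its own
  cohort's* standardization, which is unavailable; it is exact as an equation
  but cannot be anchored to new raw data.
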