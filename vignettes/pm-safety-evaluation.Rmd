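---
title: "An integrated evaluation model for herbal-batch safety: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An integrated evaluation model for herbal-batch safety: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmtox)
```

## The evaluation model

`pmtox` implements an integrated safety-evaluation pipeline for commercial
batches of *Polygonum multiflorum* (PM) decoction pieces, linking three layers
of evidence:

1. **Chemical composition.** Each batch is a vector of 26 quantified
   compound concentrations (mg/g dry weight) in four classes: 12
   anthraquinones, 5 stilbene glycosides, 4 flavonoids, 5 phenols. Batches
   are first screened against the pharmacopoeial limit for the dominant
   stilbene glycoside THSG (>= 1.0% w/w, i.e. 10 mg/g; the boundary is
   inclusive, "not less than"), then grouped by agglomerative hierarchical
   clustering on the autoscaled profiles, with PCA as an unsupervised check.
2. **Hepatotoxicity.** CCK-8 viability, `(dosing - blank)/(control - blank)`,
   is fitted with a four-parameter logistic (Hill) curve; the IC50 maps each
   group onto three toxicity tiers (low > 450 ug/mL, high < 390 ug/mL,
   medium in between). Differential constituents between toxicity groups are
   found by two-class OPLS-DA (VIP) combined with Welch t-tests under
   Benjamini–Hochberg FDR: a compound is a marker when VIP > 1 **and**
   q < 0.05 (both strict).
3. **Morphology.** Decoction-piece color is summarized per batch from 40
   readings (4 anatomical regions x 2 surfaces x 5 sites) into mean RGB and
   CIELAB channels, the overall color parameter
   $E^*_{ab} = \sqrt{L^{*2} + a^{*2} + b^{*2}}$, and intensity-invariant
   normalized RGB; normalized channels are regressed against IC50.

Candidate toxic constituents are then examined jointly with the
"One-belt, One-line" Loewe equivalent-dose analysis described below.

## The combination model

For two drugs with single-agent viability curves
$v(d) = floor + (ceiling - floor)\,/\,(1 + (d/IC_{50})^{h})$ and effects
expressed as percent inhibition $E = 100(1 - v)$, the dose of drug 2 is
converted into *equivalent* drug-1 units by pushing its effect through the
inverse of drug 1's curve (and vice versa). Two additive predictions result
for a dose pair $(d_1, d_2)$:

$$f = E_1(d_1 + \mathrm{eq}_1(d_2)), \qquad g = E_2(d_2 + \mathrm{eq}_2(d_1)).$$

The pointwise band between $f$ and $g$ is the additive **belt**; the
observed combination effects $Y_{obs}$ form the **line**. The dose-based
combination indices are $CI_{d1} = Y_{obs}/f$ and $CI_{d2} = Y_{obs}/g$, and
a pair is judged **synergistic** when both exceed 1, **antagonistic** when
both are at or below 1, and **additive** when the observed line falls inside
the belt (exactly one index above 1). A published footnote variant of the
rule (synergy both > 1, addition both <= 1, antagonism both < 1) overlaps
for both-below-1 pairs and contradicts the tabulated judgments it
accompanies; it is retained as `mode = "strict"` for fidelity, with the
row-pattern rule as the default.

Two properties anchor the implementation and are enforced by tests:

* **Sham consistency.** A drug combined with itself at any dose split gives
  $CI_{d1} = CI_{d2} = 1$ to 1e-6 for any Hill curve — the classical Loewe
  check.
* **Exact inversion.** Curve inversion is analytic for Hill curves;
  `equivalent_dose()` composed with the target curve reproduces the source
  effect to 1e-6. `loewe_effect()` solves the full Loewe equation
  $d_1/D_1(y) + d_2/D_2(y) = 1$ by bisection (tolerance 1e-12); for
  equal-slope curves it coincides with the equivalent-dose prediction.

Reported effects are rounded to 2 decimals and CI values to 4 decimals with
half-up ties, matching the field's reporting convention; all internal
computation is unrounded. Note that at an exactly additive point the CI sits
on the judgment boundary, so the label of a noise-free sham pair is decided
by floating-point residue; judgments are meaningful only away from CI = 1.

## Chemometric engine

* **Scaling.** Unit-variance autoscaling is the default (the convention of
  the major chemometrics packages), with Pareto and none as options;
  constant columns are centered, scaled by 1, and flagged.
* **PCA** is plain SVD on the column-centered matrix; explained variance
  fractions are $s_k^2/\sum_i s_i^2$.
* **Cross-validated Q2 for PCA** uses Wold element-wise deletion: matrix
  cells are assigned to 7 folds by a seeded permutation, held-out cells are
  imputed by an EM-style iterative SVD with k components, and
  $Q^2_k = 1 - PRESS_k/SS$. Element deletion was chosen over row deletion
  because it validates the low-rank structure itself rather than row
  predictability; commercial implementations use proprietary variants of the
  same idea, so third-decimal agreement with them is not expected.
* **OPLS-DA** is the single-response Trygg–Wold decomposition: Y-orthogonal
  components are stripped from X before one predictive PLS component is
  fitted against the class vector encoded -1/+1. With zero orthogonal
  components it reduces exactly to one-component PLS1 (verified against an
  independent implementation). The default is one orthogonal component;
  `"auto"` adds components while the 7-fold row-wise cross-validated Q2
  gains at least 0.01. **VIP** is computed on the predictive component only
  (one value per compound), so $\sum_j VIP_j^2 = p$ exactly.
* **Permutation test** (default 200x): the class vector is permuted, the
  model refitted, and R2Y/Q2 recorded. The Q2 intercept comes from the
  least-squares line through $(|cor(y, y_{perm})|, Q^2)$ including the
  original model at correlation 1. The model is valid when every permuted
  Q2 lies below the original and the intercept is negative.
* **HCA** delegates to Lance–Williams agglomeration (Ward on Euclidean
  distance by default, average/complete and correlation distance as
  options), cut at k clusters.

All internally seeded computations (fold assignments, permutations, the
generators below) derive per-stream seeds from one master seed and restore
the caller's RNG state, so independent analyses never couple through the
global generator.

## What the synthetic generator emulates — and what it does not

No batch-level measurements are published for the original 61-batch study,
so the package ships a generator whose defaults encode the study design and
act as the package's fixed study conditions:

* 61 batches in four latent groups (5/17/21/18, read off the published
  batch lists), 26 compounds with the class structure above.
* Concentrations are log-normal around per-group means (positive,
  right-skewed, like real quantification data); the CV parameterizes the
  log-scale sigma mean-preservingly, default 0.22. Group means put THSG at
  6/12.5/43/25 mg/g for groups A-D — group A below the qualification limit,
  THSG > 90% of its class everywhere — and give the four reported marker
  compounds (THSG, EG, emodin, catechin) strong group contrasts while the
  remaining 22 compounds carry only mild class-level multipliers. This makes
  the four groups recoverable from the whole profile (Ward/Euclidean HCA
  reaches adjusted-Rand agreement >= 0.9 with the generating labels) while
  the discriminant weight concentrates where the study found it: THSG and
  EG lead the VIP ranking for the B-vs-C contrast.
* Viability plates follow per-group Hill curves (IC50s 540/480/360/420
  ug/mL for A-D, matching the published tier structure) with additive
  Gaussian viability noise truncated at 0 (default SD 0.05, replicate-scale
  scatter, 4 wells per dose).
* Combination rays draw observed effects from the exact Loewe surface;
  a potency-shift factor multiplies one drug's effective dose to inject
  synergy or antagonism.
* Chromaticity readings are Gaussian around group-and-region channel means
  (white-ish for low-toxicity B, light yellow for high-toxicity C,
  yellow-brown for medium D), with CIELAB re-derived from the noisy RGB via
  the sRGB/D65/2-degree conversion — the common image-editing default, since
  no color profile is stated for the source workflow.

At these effect sizes several class-level differences besides the designed
markers also pass the VIP-and-q rule in the default B-vs-C contrast; the
strict "exactly the designated markers" property is therefore validated on a
dedicated two-group design (`synthetic_two_group_config()`) in which the 24
non-marker compounds have identical means and any extra flag is a false
positive by construction. That design uses 100 batches per group: with two
genuine markers present, the BH step-up admits a null compound at roughly
$p \le 3\alpha/m$, and only at this sample size is the corresponding
correlation small enough that such a compound cannot also clear VIP > 1 —
at the 61-batch scale the conjunction rule's false-flag rate is set by this
arithmetic, not by the implementation.

What passing these tests does **not** show about real data: the generator
draws compounds independently within groups (no within-class correlation
beyond group structure), uses a single noise level for all compounds, and
has no batch-level covariates (origin, storage, drying); real chromaticity
also varies with imaging conditions the generator does not model. Published
statistics computed on the real batches — PCA percentages, OPLS-DA R2/Q2,
the per-compound VIP/p table, batch and positive-control IC50s,
compositional shares — are consequently not reproduction targets; the
published combination table, which is printed in full, is the one exact
reproduction target and ships as a plain-text fixture.

## Numerical choices and degenerate inputs

* Hill fits run on log(IC50) with a deterministic multi-start over a
  log-spaced IC50 grid spanning the dosed range (12 starts), via
  Levenberg–Marquardt least squares. Asymptotes are fixed at 0/1 by default
  (free four-parameter fits need >= 4 distinct doses and are optional)
  because sparse dose grids rarely pin both asymptotes. Replicates are
  averaged with inverse-variance weights when replicate scatter is
  available. Flat response data return `converged = FALSE` rather than an
  error; IC50s outside the dosed range are flagged `extrapolated`.
* The equivalent-dose conversion maps dose 0 to 0, and effects beyond the
  target curve's attainable inhibition to an infinite equivalent dose; the
  additive prediction then saturates at the target ceiling and is flagged.
* BH q-values, Welch tests, one-way ANOVA with Tukey HSD, and per-channel
  OLS go through the standard R implementations behind the package's module
  surfaces; degenerate inputs (single-class labels, groups smaller than 2,
  constant color channels, p-values outside [0, 1]) raise informative
  errors.
* Color aggregation computes hierarchical means on raw channels first and
  derives E\*ab and normalized RGB from the batch means (the aggregate-then-
  derive order); for the complete balanced design this equals the grand
  mean. Summaries from fewer than 40 records are flagged incomplete.
  E\*ab depends only on squared CIELAB coordinates, so it conflates red and
  green casts of equal chroma — a limitation of the descriptor itself,
  retained deliberately.

## Problem sizes

The shipped analysis scripts and tests use the study-scale design (61
batches, 26 compounds, 10-dose plates with 4 replicates, 200 permutations)
directly; replicated validation experiments use 50-100 seeded repetitions,
and the two-group marker validation uses 100 batches per group as justified
above. A complete workflow run (`analysis/01_simulate.R` through
`06_chromaticity.R`) takes well under a minute.

## Known limitations

* Only two-class OPLS-DA is provided (the evaluation model only contrasts
  group pairs); multi-class questions go through PCA/HCA.
* The dose-based CI is the only combination index implemented; the
  median-effect (Chou–Talalay) variant is intentionally out of scope.
* Cross-validated Q2 values differ in detail from proprietary chemometrics
  software on identical data because fold assignment schemes differ.
* The mg/g <-> percent conversion assumes a dry-weight basis; no moisture
  correction is applied.
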