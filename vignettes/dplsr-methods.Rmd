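---
title: "Discriminant PLS with separation rotation and subsampled loadings"
author: "dplsr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discriminant PLS with separation rotation and subsampled loadings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dplsr)
```

## The problem and the model

Multiplexed immunoassays measure dozens of cytokines in culture media and
a handful of phosphorylated signaling proteins in cell lysates, across a
few experimental conditions with only 3–4 independent cultures each. With
`p` (up to 32) analytes and `n` (≈15) samples, per-analyte testing is
underpowered and ignores covariation; discriminant partial least squares
regression (D-PLSR) instead asks for the *profile* — a weighted
combination of analytes — whose per-sample values separate the
conditions.

The pipeline is: total-protein normalization → per-analyte z-scoring →
2-LV D-PLSR → in-plane separation rotation → Monte Carlo subsampling of
the loadings. Each stage is a small, separately testable function;
`runPipeline()` composes them.

### Normalization and standardization

Conditions that stimulate proliferation put more cells — hence more total
protein and more of *every* secreted analyte — into a well. Dividing each
sample's measurements by its total protein (µg) removes this abundance
confound; the synthetic generator plants exactly this confound (raw
values proportional to total protein) so the tests can demonstrate that
normalization, and nothing else, removes it. Whether a phospho panel that
was already loaded at equal protein per well should be divided again is
assay-dependent and genuinely ambiguous from the available methods
descriptions, so it is a per-panel flag
(`normalizeProtein = c(cytokine = TRUE, phospho = TRUE)`), defaulting to
normalizing both panels, since the data entering the analysis are
described as normalized to total protein throughout.

Each analyte column is then z-scored with the sample (n−1) SD. The removed
means/SDs are kept in the `NormalizedMatrix` so either convention can be
audited. Missing entries are rejected at ingest rather than imputed —
silent imputation would shift loadings invisibly. A zero-variance analyte
is an error by default (`onZeroVariance = "drop"` opts into dropping it
with a warning), because a constant column usually signals an assay
failure rather than biology.

### The discriminant encoding

All `k` conditions enter the response as a column-centered one-hot
indicator, not a binary target-vs-rest contrast: the scores plot is
expected to segregate *all* groups simultaneously (normoxia low-left,
hypoxia upper-left, target right), which a binary response cannot
express. The target condition influences only the rotation stage. `Y` is
centered but not variance-scaled — with a near-balanced one-hot design the
column variances are already comparable, and the choice is recorded in the
exported model for audit.

### NIPALS and its numerical choices

Latent variables are extracted by the classical alternating updates with
rank-one deflation of both blocks. Choices that the underlying algorithm
leaves open, fixed here:

* **Initialization**: `u` starts from the response column with the largest
  sum of squares — deterministic, no random restarts.
* **Convergence**: change in the unit-norm weight vector `< 1e-10`, at
  most 1000 iterations per component; non-convergence is flagged on the
  model (and surfaced by `show()`), not fatal.
* **Components**: 2 by default — the analysis lives in the LV1–LV2 plane;
  `nComponents` is exposed, bounded by `min(n − 1, p)`.
* Two useful identities anchor the tests: with a single centered response
  the first weight vector is `Xᵀy/‖Xᵀy‖` in closed form, and in general it
  is the dominant left singular vector of `XᵀY` — both are checked against
  independent oracles (direct formula, `svd()`, and `mixOmics::pls`).

### The separation rotation

PLS orders components by explained covariance, not by how well they
separate the group of interest, so the interesting contrast may lie
oblique in the LV1–LV2 plane. An orthogonal rotation
`R(θ) = [[cos θ, −sin θ], [sin θ, cos θ]]` applied to scores and loadings
keeps the fitted subspace and all norms intact while re-aiming LV1. The
criterion "best separates" is made precise as a Welch-style standardized
mean difference between target and non-target rotated-LV1 scores
(variance term 0 for singleton groups); it is scale-free and matches the
visual convention of the target clustering to the right. Since the
original criterion is not documented, the criterion is a pluggable
function argument; the Welch form is the default, not a claim of numeric
equivalence to the original analysis.

The search is an exhaustive uniform grid over `[0, 2π)`, 3600 steps
(0.1°) by default: the criterion is cheap and need not be smooth, the
grid is deterministic, ties break toward the smallest angle, and because
the criterion is signed and antiperiodic (`f(θ+π) = −f(θ)`) the maximum
automatically lands the target on the positive side. The grid, not a
closed form, also keeps swapped-in criteria supported unchanged.

### Monte Carlo subsampling

With ~15 samples, loadings can be sensitive to individual cultures. Each
of 1000 iterations draws `round(0.8·n)` samples (half-up rounding: 12 of
15; clamped to ≥ 2) *without replacement, unstratified* — plain random
sampling, matching the stated procedure. Because one condition has only
3 cultures, a draw can annihilate a condition and make its centered
indicator column degenerate; such draws are redrawn (counted, budgeted at
100 per iteration) rather than stratified away, staying closest to plain
subsampling while keeping every refit well-posed.

Three propagation rules matter:

* **No re-standardization**: the subsample inherits the full-data
  z-scoring — the data are standardized once, before modeling. (A
  `rezscore` flag opts into per-iteration re-scoring.) Consequently the
  refit's X block is only approximately centered, and the refit skips the
  centering assertion.
* **Sign correction**: each refit LV1/LV2 loading vector is multiplied by
  the sign of its scalar product with the *total* model's corresponding
  unrotated loading vector (`sign(0) := +1`, a measure-zero convention),
  flipping the whole vector jointly so the refit model stays
  self-consistent. Loadings — the plotted quantity — are the vectors
  compared.
* **Rotation propagation**: the *total* model's θ is applied to every
  iteration's corrected loadings; iterations are not re-rotated.

Per-analyte means and SDs (n−1) across iterations give the error bars.
All draws come from one seeded generator (R's default Mersenne-Twister),
consumed strictly in iteration order with redraws in-line, so a summary
is bit-reproducible from its seed on any platform with the same R RNG.

## The synthetic generator

`generatePanel()` emulates the study design the pipeline targets: 4
conditions (normoxia ± bFGF, hypoxia ± bFGF), 3+4+4+4 cultures, 32
cytokines and 8 phospho-proteins measured on the *same* cultures (the two
panels share each sample's total protein). Raw values are
`baseline × conditionMultiplier × (totalProtein/reference)` with
multiplicative lognormal noise (sdlog 0.25 ≈ 25% CV, typical
between-culture variability for such assays; a gaussian mode, clipped at
0, exists for analytic checks). Lognormal is the default because
concentrations are positive and right-skewed. Condition multipliers
realize planted effects stated in within-condition SDs: by default 2–3 SD
effects whose directions mirror the reported biology (G-CSF-, IL-9-,
MIP-like cytokines and phospho-cJun/Mek1-like analytes up under
hypoxia+bFGF; p38-/Jnk-like down; MCP-1-/Stat1-like tracking hypoxia
alone), with magnitudes being configuration, not truth. Total-protein
means rise from 8 µg (normoxia) to 15 µg (hypoxia+bFGF), standing in for
differential proliferation.

What it does **not** emulate: correlated analytes (drawn independently
unless the user supplies effects that induce correlation through shared
conditions), bead-level artifacts, plate effects, detection limits.
Passing recovery tests therefore shows the pipeline recovers structure of
this planted, independent-noise kind — not that it is robust to every
failure mode of real multiplexed data.

## Problem sizes in the tests

The tests run at the study's own scale (15 × 32 and 15 × 8). The
parameter-recovery check uses 100 generator seeds at 200 subsampling
iterations per panel; the null-calibration check uses 50 seeds × 500
label permutations; the sign-correction check runs the full 1000
iterations once. These sizes give stable pass/fail behavior for the
stochastic properties while keeping a complete test run in minutes on one
core.

## Known limitations

* The separation criterion is a documented choice, not a reconstruction;
  analyses sensitive to the exact criterion should pass their own via
  `rotateForSeparation(criterion = ...)`.
* With `k` conditions the one-hot response makes LV1/LV2 a compromise
  across all class contrasts; a target that separates only on LV3 of a
  higher-component model is out of reach of the default 2-LV plane.
* The Monte Carlo SDs quantify subsampling stability, not sampling
  uncertainty of the population — with n = 15 they should be read as
  error bars on the fitted model, not confidence intervals.
* `welchSeparation` returns ±Inf when both group variances vanish along a
  direction; the grid search handles this, but a pluggable criterion
  should do the same.
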