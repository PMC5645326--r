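# dplsr

Discriminant partial least squares regression (D-PLSR) for multiplexed
cytokine and phospho-protein panels, with an orthogonal rotation of the
latent-variable plane that separates a target culture condition and Monte
Carlo subsampled error bars on the loadings.

## Who this is for

Labs running multiplexed immunoassays (Luminex-style) across a small number
of experimental conditions — the motivating setting is mesenchymal stromal
cells cultured under a 2×2 design of oxygen tension (normoxia vs 5% O₂
hypoxia) and bFGF supplementation, with 3–4 independent cultures per
condition, a 32-analyte secreted-cytokine panel and an 8-analyte MAPK
phospho-protein panel. The question the analysis answers: *which weighted
combination of analytes distinguishes one condition (here hypoxia+bFGF)
from the rest, and how stable is each analyte's contribution?*

## The method

1. **Normalization.** Each sample's measurements are divided by that
   sample's total protein (µg), correcting for unequal cell numbers caused
   by differential proliferation; each analyte column is then z-scored
   (mean 0, SD 1, `n−1` denominator), giving the model matrix `X` (n × p).
2. **D-PLSR.** The conditions are encoded as a column-centered one-hot
   indicator `Y` (n × k). NIPALS extracts latent variables: per component,
   alternating updates `w ∝ Xᵀu`, `t = Xw`, `q ∝ Yᵀt`, `u ∝ Yq` to
   convergence, then rank-one deflation `X ← X − tpᵀ` with `p = Xᵀt/tᵀt`.
   Two latent variables (LV1, LV2) are kept; each sample's scores place it
   in the LV1–LV2 plane, each analyte's loadings give its contribution.
3. **Separation rotation.** An orthogonal rotation by angle θ within the
   LV1–LV2 plane is chosen on a 0.1° grid so that the rotated LV1 best
   separates the target condition from all other samples, measured by a
   Welch-style standardized mean difference
   `(m_t − m_o)/√(s_t²/n_t + s_o²/n_o)`; the sign convention puts the
   target group on the right.
4. **Monte Carlo subsampling.** 1000 iterations; each draws 80% of the
   samples without replacement (12 of 15), refits the model, multiplies
   each refit LV by the sign of its scalar product with the corresponding
   total-model LV (resolving the sign indeterminacy of latent vectors),
   applies the *total model's* rotation, and accumulates. Per-analyte mean
   ± SD of the rotated LV1/LV2 loadings become the bar chart with error
   bars.

A seeded synthetic generator (`generatePanel()`, `makeDefaultFixture()`)
emulates this study design with planted positive/negative target
correlates and a condition-dependent total-protein confound, and records
the ground truth so recovery can be tested.

## Worked example

```r
library(dplsr)
rep <- runPipeline(seed = 7, nIterations = 1000)  # synthetic two-panel run
print(rep)
#> RunReport (seed 7 )
#>  cytokine: 32 analytes, theta = 179.7 deg, separation score 17.324
#>  phospho: 8 analytes, theta = 173.4 deg, separation score 13.720
lt <- rep$cytokine$loadingsTable
head(lt[order(lt$rank), ], 4)
#>       analyte lv1_mean  lv1_sd lv2_mean lv2_sd rank
#> 2    IL9_like   0.3225 0.08535  0.01172 0.1368    1
#> 1   GCSF_like   0.3037 0.09553  0.03400 0.1455    2
#> 26 CYT20_null   0.2311 0.08977 -0.11402 0.1296    3
#> 3   MIP2_like   0.2116 0.11653  0.12052 0.1121    4
```

The separation score is the Welch criterion along rotated LV1 (larger =
cleaner separation of hypoxia+bFGF samples); θ is the rotation applied to
the plane; `lv1_mean ± lv1_sd` are the Monte Carlo loading bars. Here the
analytes planted as hypoxia+bFGF correlates (IL-9-, G-CSF-, MIP-like)
dominate the ranking — with n = 15 and 25% noise a null analyte can land
between them, which is exactly the instability the error bars quantify —
and `rep$<panel>$scoresTable` holds the per-sample rotated scores for the
condition scatter. On files instead of synthetic data:

```r
rep <- runPipeline(cytokinePath = "cytokines.csv", phosphoPath = "phospho.csv",
                   targetCondition = "hypoxia_bFGF",
                   outputDir = "results", plots = TRUE)
```

Input files are CSV/TSV with columns `sample_id`, `condition`,
`total_protein`, then one column per analyte. A thin CLI with `simulate`,
`run` and `plot` subcommands ships in `inst/scripts/dplsr-cli.R`.

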