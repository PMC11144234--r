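# fireveg

Post-fire vegetation assessment from satellite vegetation-index rasters, for
remote-sensing ecologists and fire-response analysts who need to answer three
questions about a burned landscape: *what changed*, *how is it trending*, and
*will it recover*.

The package implements an integrated pipeline:

- **Five-class NDVI mapping** — per-pixel classification of NDVI ∈ [−1, 1]
  into no vegetation [−1, 0), bare [0, 0.1), low [0.1, 0.25), moderate
  [0.25, 0.4) and high vegetation [0.4, 1].
- **Bi-temporal change detection** — a sparse autoencoder (loss
  L(x, x̂) + λ·Σ|a|, or L(x, x̂) + Σⱼ KL(ρ‖ρ̂ⱼ) with ρ̂ⱼ the mean activation
  of hidden unit j) feeds deep embedded clustering: Student-t soft
  assignments qᵢⱼ ∝ (1 + ‖zᵢ − μⱼ‖²/α)^−(α+1)/2 sharpened toward the target
  pᵢⱼ = (qᵢⱼ²/fⱼ)/Σ(q²/f) by minimising KL(P‖Q). One shared model clusters
  both epochs' class-map patches; pixels whose cluster-implied vegetation
  class differs between epochs form the binary change map.
- **Sen's-slope trend analysis** — per-pixel slope
  median{(xⱼ − xᵢ)/(tⱼ − tᵢ) : i < j} of annual maximum EVI composites, with
  greening/browning fractions (slope beyond ±zero_band) and areas in km².
- **Regrowth possibility** — a stacking ensemble (logistic regression, SVM,
  decision tree, random forest, naive Bayes under a logistic generalizer fit
  on out-of-fold predictions) on soil attributes.
- **Recovery mapping** — an adversarially trained encoder–decoder with gated
  self-attention and summation skips against a conditional PatchGAN critic,
  trained on temporal pairs of post-fire composites; evaluated with MAE, MSE,
  MSLE, RMSE, the Huber loss (½r² for |r| ≤ δ, δ(|r| − ½δ) beyond), and a
  Breusch–Pagan-type homoscedasticity diagnostic (n·R² ~ χ²₁).

All neural components (autoencoder, DEC, generator, discriminator) are
implemented in plain, seeded matrix algebra — no deep-learning framework is
required — and every stage comes with seeded synthetic-scene generators with
known ground truth, so the whole pipeline is testable without satellite
downloads.

## Worked example

```r
library(fireveg)

# a 64x64 bi-temporal scene with a known burn scar (250 m pixels)
sc <- make_burn_pair(scene_config(size = 64, seed = 7))
cm <- detect_change(sc$pre, sc$post,
                    cfg = sparse_ae_config(hidden = c(16, 4), epochs = 60, seed = 1))
cm
#> <change_map> 64 x 64  changed 854 / 4096 unmasked
m <- change_metrics(sc$truth$binary, cm$binary)
sprintf("precision %.3f  recall %.3f  F1 %.3f  IoU %.3f",
        m$precision, m$recall, m$f1, m$iou)
#> "precision 0.953  recall 0.988  F1 0.970  IoU 0.942"
```

The detector recovered 854 changed pixels; 95.3 % of flagged pixels lie in
the true scar and 98.8 % of the scar was found (the residual disagreement is
the one-pixel halo at the scar boundary, where patch context straddles it).

```r
# ten years of annual composites: 60 % greening / 40 % browning ground truth
st <- make_trend_stack(trend_stack_config(size = 64, seed = 7))
sl <- slope_raster(st$rasters, st$years)
greening_browning(sl, zero_band = 0.005)
#> <trend_summary> greening 0.600 (153.625 km2)  browning 0.400 (102.375 km2)
#>   neutral 0.000  [zero band 0.005]

sens_slope(c(1, 3, 2), 1:3)   # pairwise slopes {2, 0.5, -1} -> median
#> [1] 0.5

# regrowth possibility from soil attributes (rule + 5 % label noise)
tab <- make_soil_table(2000, noise_rate = 0.05, seed = 7)
ev <- stack_holdout_eval(tab, stack_config(seed = 7))
ev$stack_accuracy
#> [1] 0.936
```

The trend summary matches the generator's truth exactly at this noise level
(fractions 0.600/0.400; areas = pixels × 0.0625 km² at 250 m), and the
stacking ensemble recovers the soil rule at 93.6 % held-out accuracy.

A command-line workflow wrapping these stages (subcommands `simulate`,
`change`, `trend`, `regrowth`, `recover`) is installed at
`inst/cli/fireveg`; every run writes its resolved configuration and a file
manifest next to its outputs.

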