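---
title: "Methods: post-fire vegetation assessment with fireveg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: post-fire vegetation assessment with fireveg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

fireveg assesses wildfire impact on vegetation from satellite vegetation-index
rasters in three stages — bi-temporal change detection, multi-year trend
analysis, and recovery mapping — plus a tabular model for regrowth potential.
This vignette documents the models, their assumptions, the tunable parameters,
and the design choices made where the methodology was genuinely open.

## Raster model and the five NDVI classes

All grid operations work on `index_raster` objects: a numeric matrix in
\[-1, 1\] (NDVI or EVI), a nodata mask (stored as `NA`), a pixel size in
metres, and opaque placement metadata. No reprojection or resampling is
performed; every multi-raster operation requires aligned grids, which mirrors
how practitioners pre-process composites upstream.

NDVI is computed as (NIR − Red)/(NIR + Red) and EVI as
G(NIR − Red)/(NIR + C1·Red − C2·Blue + L) with the standard MODIS
coefficients G = 2.5, C1 = 6, C2 = 7.5, L = 1 (all exposed as arguments).
Classification uses five half-open intervals
\[−1, 0), \[0, 0.1), \[0.1, 0.25), \[0.25, 0.4), \[0.4, 1\] — no vegetation,
bare, low, moderate, high. Published range tables for these classes often
overlap at the low/moderate boundary (0.24 vs 0.25); the half-open convention
with breakpoint 0.25 is deterministic and covers \[−1, 1\] totally, and the
breakpoints are configurable through `class_scheme()`.

**File formats.** No GeoTIFF library is required: TIFF output stores the
values as a 32-bit sample plane rescaled to \[0, 1\] plus a second plane
carrying the nodata mask, with georeferencing in a JSON sidecar. Round trips
are exact to about 5e-10 (the 32-bit quantization), which is far below any
index precision that matters at 250 m. PNG output is 8-bit (quantization
2/255 on the \[-1, 1\] scale) and intended for visualisation.

## Change detection: sparse autoencoder + deep embedded clustering

Both epochs are first classified into the five NDVI classes; the class maps
(codes scaled to \[0, 1\]) are the network input, so the detector reasons over
vegetation classes rather than raw reflectance. Each unmasked pixel
contributes one feature row: its patch × patch neighbourhood, reflect-padded
at borders.

The sparse autoencoder minimises mean squared reconstruction error plus a
sparsity penalty on its designated hidden layer, either
λ·Σ|a| (L1) or a Bernoulli KL term Σ_j KL(ρ ‖ ρ̂_j), where ρ̂_j is the batch
mean activation of unit j. Architecture decision: the encoder's hidden layers
are sigmoid — so ρ̂ is bounded in (0, 1) and the Bernoulli divergence is well
defined — while the bottleneck itself is **linear**. A sigmoid bottleneck
compresses the embedding toward the target rate and destroys the geometry the
clustering phase depends on; penalising the wide sigmoid layer and keeping a
linear code preserves it. With a single hidden layer the (sigmoid) bottleneck
carries the penalty. Defaults: widths 16 → 4, KL mode with kl_weight 0.1 and
ρ = 0.1 (L1 available with λ), Adam at 5e-3, 60 epochs, batch 256, all
seeded. ρ̂ values outside (0, 1) are clamped to \[1e-7, 1 − 1e-7\] with a
logged message, never an exception.

Deep embedded clustering then alternates: a Student-t soft assignment
q_ij ∝ (1 + ‖z_i − μ_j‖²/α)^−(α+1)/2 (α = 1), a sharpened target
p_ij = (q_ij²/f_j)/Σ(q²/f) with f_j = Σ_i q_ij floored at 1e-12, and Adam
minimisation of KL(P‖Q) with respect to both centroids and encoder weights
(standard DEC gradients, verified against finite differences in the test
suite). Centroids initialise from k-means on the embeddings (10 restarts, up
to 5 reseeds on empty clusters; when n = k each point is its own centroid,
which base k-means does not support). Training stops when fewer than 0.1 % of
points change hard assignment between target updates. Hard assignments use
first-index tie-breaking — `max.col`'s default random tie-breaking silently
violates determinism.

**From clusters to a change map.** One shared DEC model (k = 5, one cluster
per vegetation class) is fit on the pooled features of both epochs; the
pooled matrix is ordered canonically (epoch with the smaller value sum first)
so the result is invariant to swapping the epochs. Each cluster is then
mapped to the majority NDVI class (centre pixel) of its members, and a pixel
is *changed* where its mapped class differs between epochs. The mapping step
matters: when a scene occupies fewer than five classes, DEC necessarily
splits the dominant class into multiple clusters, and raw cluster-label
disagreement registers spurious change between two clusters that both mean
"high vegetation". Ties in the majority vote break to the lower class code.

**Patch size.** The default context is 5 × 5. A 3 × 3 context leaves the
patch vector dominated by single pixels, so observation noise that pushes one
pixel across a class threshold in one epoch moves the whole patch between
clusters and costs precision; a 5 × 5 context dilutes single-pixel flicker
while widening the boundary halo by only one pixel. Both are configurable.

Precision, recall, F1, accuracy and IoU against a reference mask come from
`change_metrics()`; zero-division cases return 0 with a warning.

## Sen's-slope trend analysis

Annual series are built by `annual_max_composite()` (per-pixel, nodata-aware
maximum per year, with an optional month filter — "growing-season maximum"
versus "annual maximum" differs between products, so the filter is explicit).
The per-pixel trend is Sen's slope, the median of all pairwise slopes
(x_j − x_i)/(t_j − t_i), i < j, with years as the abscissa; irregular gaps
are handled by the denominator, and the even-count median is the mean of the
two central values. Pixels with fewer than two valid years are nodata.

Greening/browning fractions count pixels with slope above/below ±`zero_band`
among unmasked pixels; areas are pixel counts times (pixel_size/1000)². The
neutral band is explicit (default 0) because published fraction tables
commonly do not sum to one, implying an unstated band; exposing it makes the
bookkeeping exact: greening + browning + neutral = 1. No significance test
(e.g. Mann–Kendall) is applied — the rule is magnitude-only by design, and a
significance filter is a natural extension.

## Regrowth possibility: stacking ensemble on soil attributes

Five base learners — logistic regression, radial SVM, decision tree, random
forest, naive Bayes — are cross-fit on seeded stratified folds (default 5);
a logistic-regression generalizer is trained **only on out-of-fold
probability features**, so no meta-feature ever saw its own label (the
label-shuffle control in the tests verifies the absence of leakage: held-out
accuracy collapses to the majority rate). Base learners are refit on the full
table for prediction. Numeric soil attributes (pH, nitrogen, organic carbon,
bulk density) are standardised; the soil group is one-hot encoded against the
training vocabulary, with unseen groups mapped to the all-zero encoding and
flagged in the output. Latitude/longitude are excluded from the features by
default — they index location, not soil quality — with a flag to include
them.

One determinism note: libsvm's probability calibration uses an internal
cross-validation with its own RNG that ignores R's seed. The SVM probability
feature is therefore produced by Platt scaling fitted deterministically with
`glm` on the decision values.

## Recovery mapping: adversarial encoder–decoder

The recovery network is trained on temporal pairs: a post-fire composite at
time t as input and the composite of the same scene at t + Δ as target. The
method is unsupervised in the sense that no labels are needed — the later
composite itself supervises — and this temporal-pair conditional reading is a
documented design choice: pixelwise regression metrics (MAE/MSE/…) against a
real later composite are only defined under it.

*Generator*: n_down (default 3) stride-2 3×3 convolutions with ReLU,
channels doubling from base_channels (default 16); a self-attention block
after the third downsampling stage, implemented as a gated residual
(out = x + γ·attention(x)) with γ initialised to 0 so training starts as a
plain encoder–decoder — at desk scales this is markedly more stable;
mirrored nearest-neighbour-upsample + conv stages with **summation** skip
connections (additive, not concatenative); dropout (default 0.25) after each
skip merge; a tanh output convolution bounding the map in (−1, 1).

*Discriminator*: a conditional PatchGAN — three stride-2 3×3 leaky-ReLU
(slope 0.2) convolutions with instance normalisation after convolutions 2
and 3, then a stride-1 convolution to a 1-channel patch logit map (no global
pooling); a 64×64 input yields an 8×8 patch map. Normalisation is instance
norm only: at the batch sizes used here batch statistics are too noisy to
stabilise training, and per-sample normalisation of the middle layers is the
standard PatchGAN practice.

*Losses*: non-saturating adversarial loss for both players; the generator
adds λ_rec·L1(output, target) (default 100) and both add l2·Σ‖W‖² over all
convolution weights (default 1e-4). Adam (β1 = 0.5) for both players; all
initialisation, batching and dropout derive from one seed, so the loss log is
bitwise reproducible on one machine. Non-finite losses abort with
diagnostics. Every layer's backward pass is hand-derived and checked against
finite differences in the tests.

Inference is deterministic (dropout off). Rasters larger than the training
tile are covered with half-tile-overlapping windows and averaged. The
optional recovery-level map buckets the NDVI class change between input and
generated output into regressed (< 0), stable (0), recovering (+1),
recovered (≥ +2).

*Evaluation*: MAE, MSE, MSLE, RMSE, Huber over unmasked pixels. MSLE shifts
values by +1 so logarithms are defined on \[-1, 1\] data. Huber uses the
quadratic branch r²/2 for |r| ≤ δ and δ(|r| − δ/2) beyond, δ = 1 by default;
both branches agree at |r| = δ. The homoscedasticity diagnostic regresses
squared residuals on fitted values and refers n·R² to χ²(1) — the
studentised Breusch–Pagan statistic — with verdicts homoscedastic
(p > 0.05), heteroscedastic, or degenerate (constant fitted values).

## What the synthetic scenes emulate — and what they do not

The generators reproduce the *structure* of the study data, not its physics:

- `make_burn_pair()`: a spatially autocorrelated background NDVI field
  (Gaussian-smoothed white noise — the simplest controllable model of
  vegetation autocorrelation), mean 0.55 and spatial sd 0.08 (healthy cover),
  a rasterized polygon scar depressing the index by 0.45 (to bare/low
  classes), and i.i.d. observation noise of sd 0.02 per epoch, within the
  0.02–0.05 cross-sensor NDVI uncertainty reported for MODIS/VIIRS products.
  Scars are polygons rather than pixel sets so detectors are exercised on
  boundary behaviour.
- `make_trend_stack()`: 10 annual composites at 64×64 and 250 m, with 60 %
  of pixels greening and 40 % browning at ±0.01 index/year and noise sd
  0.001 (slope an order of magnitude above noise); the realized fractions
  are recorded exactly.
- `make_recovery_pairs()`: scar scenes whose target epoch relaxes toward the
  background by a known recovery coefficient (default 0.6) plus noise —
  MAE between input and target is then known in closed form.
- `make_soil_table()`: attributes uniform over plausible ranges and a binary
  label from the rule 5.5 ≤ pH ≤ 7.5 ∧ nitrogen > 3 g/kg, flipped with
  probability 0.05; the analytic prevalence is recorded.

Passing on these scenes demonstrates that the algorithms recover known
structure under realistic noise; it does **not** demonstrate performance on
real composites, whose artefacts (clouds, sensor drift, phenology,
mixed-severity burns, spatially correlated noise) the generators deliberately
omit.

## Numerical choices and problem sizes

Degenerate inputs are handled explicitly: zero-denominator index pixels are
masked; empty rasters yield zero fractions; ρ̂ and cluster frequencies are
floored rather than erroring; constant fitted values give a "degenerate"
homoscedasticity verdict; n = k clustering bypasses k-means. Stopping
tolerances: DEC relabelling threshold 0.001; Adam ε 1e-8; probability floors
1e-12. The bundled test-suite and acceptance runs use 64×64 scenes, 10-year
stacks, 2000-row soil tables, and 200 recovery pairs of 32×32 for 30 epochs
with 16 base channels — sizes chosen so the full DEC and adversarial
pipelines train in minutes on one CPU while every statistical property under
test remains comfortably measurable. Larger rasters and deeper networks are
reachable through the config objects.

## Known limitations

- The change detector assumes radiometrically consistent, aligned epochs; it
  has no cloud/shadow handling.
- DEC inherits k-means' sensitivity to initialisation; the embedding from a
  small sparse autoencoder can merge genuinely adjacent clusters. Blob
  recovery is reliable for well-separated structure, not for overlapping
  populations.
- The adversarial model is desk-scale: it demonstrates the architecture and
  training dynamics, not remote-sensing-grade recovery mapping.
- TIFF round-trips are exact only to 32-bit quantization, and model
  checkpoints for the tree/forest learners use RDS (no practical plain-text
  form exists).
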