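---
title: "dryshift: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{dryshift: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: what each stage
models, which tunable parameters matter and why their defaults are what they
are, what the synthetic-data generator does and does not emulate, and where
the design was genuinely open. It states no empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## 1. The problem

Tropical dry forest (TDF) is a seasonally deciduous, fragmented biome that
is spectrally confusable with open fields and regrowth, and it concentrates
in cloud-prone valleys where optical time series are gappy and labeled
reference maps are scarce and coarse. The package's premise is that two
complementary measures help: SAR backscatter, which is cloud-independent and
sensitive to canopy structure, fused with fine-resolution optical
reflectance; and semi-supervised training, which stretches a small label
budget with machine-generated pseudo-labels. Every stage is exercised on
synthetic scenes whose ground truth is known by construction, so the
pipeline's claims are testable without satellite data.

## 2. Synthetic paired scenes (`scene_config`, `generate_label_map`, `render_scene`)

**Label field.** White Gaussian noise on the fine grid is smoothed with a
separable Gaussian kernel (sd = `smoothness` pixels, default 6) and cut at
empirical quantiles into `n_classes` classes. This is the simplest seedable
construction that yields contiguous, irregular, fragmented patches of
near-equal area — the geometry that makes TDF mapping hard — and the
quantile cut guarantees every class comfortably exceeds a 1% area floor.
`smoothness = 0` degenerates to per-pixel independent labels, which the
tests use for binomial sanity checks.

**Sensor models.** Optical bands are class mean + additive Gaussian noise
(sd `optical_noise_sd`, default 0.02 reflectance units), clipped to [0,1] —
the standard first-order model for a calibrated surface-reflectance product.
SAR is generated at half resolution by a 2×2 block mean of the per-class
backscatter field (pixel-is-area, top-left aligned, fixing the 5 m → 10 m
correspondence) multiplied by unit-mean gamma speckle with `speckle_looks`
L = 4 by default: mean 1, variance 1/L, the canonical multi-look intensity
speckle model. The tests verify the first two sample moments and the 1/√L
coefficient of variation at n ≥ 10⁴ pixels. `speckle_looks = Inf` disables
speckle for noise-free oracles.

**Class spectra.** The class roster is {0 other, 1 urban, 2 agriculture,
3 forest, 4 water, 5 TDF}. No spectral statistics are published for the
real classes, so the built-in 8-band means are chosen for *separability*,
ordered the way a field scientist would expect (water dark everywhere,
urban bright in SAR double-bounce, vegetation NIR-high, TDF between
agriculture and forest). This is a deliberate idealization: a green test
establishes that the pipeline recovers a learnable signal, not that it
would reach the same accuracy on real mosaics, where class overlap,
phenology, terrain and georeferencing error all bite. Class 0 ("other")
exists because clustering uses k = 6 while supervised metrics report 5
classes; it is excluded from loss and metrics by default.

**Temporal change.** `inject_change()` grows a spatially contiguous patch
(breadth-first search over the source class, restarting across components)
until `change_fraction` of the source class is converted, within one pixel
of rounding; `generate_series()` re-renders each epoch with fresh
observation noise while labels persist. The truth mask makes change
recovery exactly measurable.

## 3. Raster preparation

- **Median compositing** reduces a stack of acquisitions per band and pixel
  to the median of valid observations; even counts average the two middle
  values (standard convention). Pixels with no valid observation become
  nodata.
- **Normalization** is global min-max to [0,1], fitted on training patches
  only and applied frozen to validation/test/inference data; out-of-range
  held-out values are clipped to keep the documented range contract (the
  alternative — letting them overshoot — would silently violate the
  network's input contract).
- **Chunking** lays a regular non-overlapping grid of 576-px optical /
  288-px SAR windows (a constant ground footprint; any even size works at
  desk scale). Edge remnants are dropped, not padded, so every sample has
  the same footprint.
- **Splits** are assigned at whole-tile granularity (tiles are t×t blocks
  of adjacent patches, default t = 2 — the grouping limits leakage through
  spatial autocorrelation; the size is a package choice, as only the
  grouping principle is specified): 30% of tiles to test, then 85/15 of the
  remainder to train/val, with largest-remainder rounding at each stage.
  1000 single-patch tiles therefore give exactly 595/105/300, i.e.
  59.5/10.5/30%.
- **Resampling** offers blockwise max/mean pooling and bilinear up-sampling
  with pixel-centre alignment under the pixel-is-area convention.

## 4. The Y-Net and its training

**Architecture.** Each sensor has a stem of one conv block
(2 × [3×3 conv → batch norm → ReLU]); the optical stem is max-pooled once so
both stems meet on the coarse grid, where their feature maps are
concatenated — early fusion, immediately after the first convolution. A
shared encoder–decoder follows with widths doubling per level
(`base_width` 16 at desk scale, 64 at full scale; `depth` 4 by default,
2–3 in tests). Skip connections come from the shared encoder at every
scale, from the SAR stem at the coarse decoder scale, and from the
pre-pool optical stem at the fine scale; a final 2× up-sampling stage puts
logits on the fine grid. The published description of the architecture
names the Y-shape, the early concatenation and skip connections from both
encoders but not the internal widths or depth, so those are declared
defaults, not reconstructions. One wording ambiguity ("up-sampled optical"
vs. pooling) was resolved in favour of pooling the optical stem onto the
SAR grid, which is the only reading consistent with fusion *after the
first convolution*. The baseline `build_unet_concat()` instead max-pools
the optical input itself onto the coarse grid and feeds the 10-channel
concatenation to a standard U-Net, with the same output contract so the
two are directly comparable.

**Implementation.** No deep-learning framework is available in the target
environment, so convolutions (im2col + GEMM), batch norm, pooling,
up-sampling, the soft Jaccard loss gradient, AdamW and the one-cycle
schedule are implemented in the package (R + RcppArmadillo). The entire
backward pass is validated against central finite differences (relative
error ~10⁻¹⁰) in `test-ynet.R`'s training-step test and was verified layer
by layer during development.

**Loss.** Soft Jaccard with ε = 10⁻⁶ smoothing, uniform class weighting,
class 0 ignored by default. It is bounded in [0,1], 0 at a perfect one-hot
prediction, and has the closed-form value 2/3 for p = 0.5 on balanced
binary labels — all asserted in tests.

**Optimization.** AdamW (β = 0.9/0.999, decoupled weight decay 5·10⁻⁴ on
convolution kernels only — decaying batch-norm affine parameters or biases
is known to hurt), one-cycle learning rate stepped per batch (cosine
warm-up over 30% of the step budget from peak/25, cosine anneal to
peak/10⁴ — the scheduler's conventional shape, since only "modulated each
step" is specified), batch 10, up to 300 epochs, early stop after 10
epochs without validation-loss improvement with best-checkpoint
restoration (a standard practice the source is silent on).

**Desk-scale learning rate.** The default peak rate 1.58·10⁻⁴ is the
published full-scale setting (thousands of 576-px patches, hundreds of
epochs). The package's recovery experiments train ~25 patches of 32 px for
≤ 40 epochs — about 100 optimizer steps — where that rate cannot move the
network out of initialization; they therefore use a peak rate of 3·10⁻³,
the usual rate-for-budget rescaling. This is a stated property of the
desk-scale world, fixed once; acceptance thresholds were not adjusted to
outcomes.

## 5. Pseudo-labeling

The 10-feature stack is Red, Green, Blue, NIR, GNDVI, NDVI and the four SAR
bands bilinearly up-sampled 2× onto the fine grid, each feature min-max
normalized per scene so neither sensor dominates the Euclidean metric.
Three k-means variants are fitted with k = 6 (matching the class count):
uniform-random initialization, k-means++ seeding, and k-means++ in the
subspace of the first k−1 principal components — the dimensionality that
the PCA/k-means equivalence result motivates; the source names the method
but not the number. All variants use Lloyd iterations (max 300, the
standard tolerance) and 10 restarts with the best within-cluster sum of
squares kept; restarts are essential because even seeded k-means hits
local optima that merge spectrally adjacent classes, and a one-shot
pseudo-labeler has no later chance to recover.

Clusters map to classes by argmax overlap on the *labeled training subset
only* (ties to the lowest class id; empty clusters to class 0 with a
warning), and the mapping is frozen. Per pixel, 2-of-3 majority voting
decides the pseudo-label; three-way disagreements fall to the k-means++
variant, the one judged most reliable. Pseudo-labels are generated once and
never refined, and no confidence filtering is applied — both deliberate
properties of the modeled workflow, with iterative self-training and
thresholding explicitly out of scope.

## 6. Semi-supervised assembly, metrics

`assemble_ssl_dataset()` supports the two published compositions: *ratio*
mode keeps the training-set size fixed while replacing `round(r·N)` samples
with pseudo-labeled ones (r ∈ [0, 0.9]), and *augment* mode appends extra
pseudo-labeled patches to the full labeled set. Pseudo-labels enter the
loss exactly like ground truth.

`evaluate_map()` reports overall accuracy, per-class IoU = TP/(TP+FP+FN)
and F1 = 2TP/(2TP+FP+FN), unweighted means, and the row-normalized
confusion matrix in percent (rows are ground-truth classes). The identity
F1 = 2·IoU/(1+IoU) links every IoU/F1 pair and is asserted on random
evaluations. Classes absent from both maps are excluded from the mean with
a warning rather than zero-filled, so small-scene tests stay meaningful.
Published aggregate mIoU figures are internally inconsistent with their own
per-class rows (by ~0.001–0.009) and are deliberately not used as test
oracles; the per-class identities are.

## 7. Change detection and the hectare ledger

Per model and epoch pair, a target-class loss mask is
`t1 = target ∧ t2 ≠ target`; the ensemble mask keeps pixels where at least
k = 3 of n = 5 models agree, which is monotone shrinking in k and invariant
to model order (both property-tested). The majority vote is applied to the
binary loss mask, not to full transition codes — the modeled workflow votes
on target-class loss. Per-epoch class areas come from the pixel-wise
plurality consensus of the model maps (ties to the lowest class id), so
areas always sum to the scene area; percent change uses half-even rounding
to one decimal, and the error margin is `trunc(area × rate)` — truncation,
not rounding, because only truncation reproduces both published margin
values (223.03 → 223 and 235.74 → 235, where rounding would give 236) from
the 1.2% misclassification rate. The epoch-1 baseline area can be supplied
externally (`baseline_area_ha`) when it comes from a reference map rather
than the model grid.

## 8. Hotspot statistics

Gi\* on raw binary change pixels is degenerate (every changed pixel has the
same value), so changed pixels are first binned into an analysis grid —
counts per cell are the variable whose clustering is of interest. The
statistic uses binary fixed-distance-band weights including self (the
starred variant); the default band radius of 1.5 cell units includes
diagonal neighbours (centre distance √2 ≈ 1.414), i.e. a queen+self
neighbourhood — note that a radius in [1, √2) gives rook+self instead, and
the brute-force oracle tests cover both. With binary weights
Σ w² = W, and a constant field (S = 0) or an all-neighbour cell
(W_i = n) is defined to score z = 0. Significance uses the conventional
two-sided normal thresholds 1.645/1.96/2.576; no multiple-testing
correction is applied, matching the modeled workflow. The weight scheme,
distances and thresholds are declared conventions — the source does not
state its GIS defaults.

## 9. What a green test establishes — and what it does not

The synthetic world is separable by construction: class means are distinct,
noise is homoscedastic, speckle is uncorrelated, co-registration is exact
and labels are perfect. Green acceptance tests therefore establish
*mechanical correctness* (shapes, gradients, votes, arithmetic, seeded
reproducibility) and *recoverability of a known signal* (pseudo-label
accuracy 1.0 on noiseless scenes; ≥ 0.90 held-out accuracy for a width-16
Y-Net in minutes; an injected 10% forest loss recovered within one
percentage point through 2%-noise classifier stubs). They do not establish
real-world accuracy, robustness to label noise, phenological drift,
georeferencing error, or transfer across regions — all of which the
full-scale workflow must face.

## 10. Numerical and degenerate-input conventions

- Normalized-difference indices define 0/0 = 0; degenerate normalization
  bands (max = min) map to 0.
- Softmax is computed with per-pixel max subtraction; probabilities sum to
  1 within 10⁻⁵ and zero inputs yield finite outputs.
- Windows are 0-based, half-open, top-left origin, pixel-is-area
  throughout; the SAR grid is exactly half the optical grid.
- All stochastic operations take explicit seeds; identical (config, seed)
  gives bit-identical outputs, which the suite asserts for the generator,
  the splits, the clusterers and the training loop.
- Inference-time scenes must be exact multiples of the patch size: the
  chunker drops edge remnants during training, but silent gaps in a
  stitched prediction would corrupt area accounting, so `predict_map()`
  errors instead.

## 11. Known limitations

The simulator has no topography, incidence-angle or layover effects, no
spatially correlated speckle, no clouds beyond binary validity masks, and
no label noise. The network trains on one CPU at widths far below the
full-scale setting; no GPU path is provided. Per-pixel probabilistic
uncertainty is not propagated into the change ledger — the 5-model vote is
the package's (and the modeled workflow's) practical surrogate for model
uncertainty.
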