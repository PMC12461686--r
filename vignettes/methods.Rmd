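---
title: "Neural-network surrogate embeddings: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neural-network surrogate embeddings: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the method

Nonlinear dimensionality reduction — t-SNE and UMAP above all — has become
the default lens for high-dimensional omics data, but both algorithms are
transductive: they embed exactly the samples they were given, at a cost that
grows at least quadratically (exact t-SNE) with sample count. Mass
spectrometry imaging runs produce $10^5$–$10^6$ pixel spectra, Hi-C contact
matrices at kilobase resolution have millions of rows, and neither fits the
conventional algorithms in memory or time. There is also no way to place a
newly acquired sample into an existing embedding without recomputing it, and
no way to read off which features drive a position in the reduced space.

`netembed` addresses all three limitations with one construction:

1. **Subsample.** Select a tractable subset — deterministically, every
   $n$-th sample (`every_nth()`), or at random (`random_subset()`).
2. **Reference embedding.** Embed the subset with exact t-SNE or UMAP under
   a correlation distance metric ($1 - r$ between sample vectors),
   `embed_reference()`, and min-max normalize the coordinates to the unit
   cube (`normalize_embedding()`).
3. **Forward network.** Train a multilayer perceptron from the subset's
   feature vectors to its embedding coordinates (`fit_forward()`). Applying
   it (`predict()`) places the *remaining* samples — and any future data —
   into the same space in a single streamed pass.
4. **Inverse network.** Train the reverse regression, coordinates to
   features (`fit_inverse()`). Evaluated at any point of the reduced space
   (`reverse_query()`, `centroid_spectrum()`) it returns a *pseudo-spectrum*
   of signed per-feature contributions, which `rank_drivers()` turns into a
   ranked driver list and `ppm_match()` annotates against a user-supplied
   mass table.
5. **Cross-omics transfer.** For matched samples the same trainer learns to
   map one modality's features into another modality's reduced space
   (`fit_cross()`, `project_cross()`), so a phenotype visible only in, say,
   transcriptomics becomes recoverable from metabolomics measurements.

The surrogate is a regression on the embedding *coordinates*, not a
re-derivation of the t-SNE/UMAP objective: this is what makes the backend
interchangeable — everything downstream of `embed_reference()` consumes only
an `embedding` object, and both backends are driven by the same precomputed
correlation-distance matrix.

## Parameters that matter

| Parameter | Default | Where | Why |
|---|---|---|---|
| perplexity | 30 | `embed_reference()` | conventional t-SNE neighbourhood size |
| exaggeration | 4 | `embed_reference()` | early-exaggeration factor of the exact backend |
| metric | correlation | `embed_reference()` | scale-free comparison of spectra; intensity units cancel |
| out dims | 3 | `embed_reference()` | coordinates double as RGB channels for image rendering; 2 supported |
| n_neighbors / min_dist | 30 / 0.3 | `embed_reference()` | UMAP defaults |
| split | 70/15/15 | `train_config()` | train / test / validation convention of the surrogate trainer |
| max_epochs | 1000 | `train_config()` | epoch cap; early stopping usually ends training sooner |
| hidden | 128, 64 | `train_config()` | two tanh layers; enough capacity for $p \le$ a few thousand features |
| l2 | 1e-4 | `train_config()` | weight shrinkage (see below) |
| k | 10 | `novelty_score()` | neighbour order of the novelty distance |
| quantile | 0.99 | `calibrate_threshold()` | training self-score quantile used as novelty threshold |
| tol_ppm | 5 | `ppm_match()` | conventional exact-mass annotation tolerance |

**Bayesian regularization surrogate.** The original formulation of this
method trained its networks with Bayesian regularization, which is specific
to one toolbox. `netembed` substitutes L2 weight decay combined with
validation-based early stopping (restore-best-weights, patience 100). Both
impose the same shrinkage prior on the weights; the decay strength is an
explicit `train_config()` knob and is recorded in the serialized map.

**Optimizer.** Minibatch Adam (batch 256, step $3\times10^{-3}$, halved —
with a restart from the best weights — whenever the validation loss
plateaus for half the patience window), standardized
inputs and targets (z-scores from the training split, stored in the map and
re-applied at prediction time). Targets of forward and cross maps are the
unit-cube-normalized coordinates, so inverse corner queries like
$[1,0,0]$ are meaningful and rendered colours equal coordinates.

## Diagnostics: how fidelity is measured

* **Forward (and cross) maps** report the squared Pearson correlation
  between reference and predicted coordinates, per embedding dimension, on
  the held-out test split; the *minimum* over dimensions is the headline
  number (conservative — a map is only as good as its worst axis). Pearson
  $r^2$ is invariant to the affine scale of either side, which is the right
  property for coordinates that are themselves only defined up to scale.
* **Inverse maps** report, per held-out sample, the squared Pearson
  correlation between the true and reconstructed feature vector — the
  spectral-similarity reading of reconstruction quality — summarized as the
  mean (and median) over samples, alongside per-feature $r^2$. A pooled
  per-feature minimum would be dominated by whichever feature carries the
  least structure and is not what spectral fidelity means.

`rand_index()` (plain, unadjusted — pair-agreement fraction) and
`lda_loo()` (leave-one-out linear discriminant accuracy) evaluate
segmentations and classifications on the reduced coordinates.

## Numerical choices and degenerate inputs

* **Correlation distance** errors on zero-variance sample vectors rather
  than emitting NaN; tiny negative distances from floating-point rounding
  are clipped to 0.
* **Embedding normalization** maps a zero-range dimension to the constant 0
  and flags it; the stored minima/ranges make the transform invertible for
  non-degenerate dimensions, and the operation is idempotent.
* **LDA** regularizes the pooled within-class covariance with
  $\varepsilon I$, $\varepsilon = 10^{-6}\,\mathrm{tr}(\Sigma)/d$, so
  constant embedding directions cannot make it singular. Priors are
  proportional to class frequency — the natural choice when the class mix
  of the evaluation set mirrors the training set, and the only
  frequency-aware option that needs no extra input.
* **Driver ranking** breaks magnitude ties by ascending m/z; `k` larger
  than the feature count clips with a warning.
* **`split_data()`** uses largest-remainder rounding, so set sizes are
  always within one sample of the exact fractions and sum to $n$.
* **Chunked prediction** (`predict(..., chunk_size = )`) standardizes and
  propagates each chunk independently; outputs are independent of the chunk
  size up to last-ulp floating-point rounding (the BLAS selects different
  kernels for different matrix shapes).
* **2-D renderings** use a four-corner colour square (blue, red, green,
  yellow at $(0,0)$, $(1,0)$, $(0,1)$, $(1,1)$, blended bilinearly), keeping
  the red/green/blue/yellow corner semantics of 3-D renderings.

## What the synthetic generators emulate — and what they do not

The package's test and acceptance harness runs entirely on synthetic data
from three generators, each a pure function of its seed:

* `synth_msi()` — an imaging dataset: contiguous regions (Voronoi partition
  of the raster), a shared log-normal baseline spectrum (sdlog 1.2, matching
  the orders-of-magnitude dynamic range of real spectra), per-region
  log-normal fold effects (sdlog 0.6), and per region two planted marker
  features, intense inside the region and near-absent elsewhere. Noise is
  multiplicative log-normal (sdlog 0.25) plus an additive Gaussian floor (1%
  of the median baseline), clipped at zero. `synth_replicate()` redraws only
  the noise — a serial section.
* `synth_matched()` — matched two-modality samples with a shared class
  variable and nested "cell line" nuisance structure: modality B separates
  classes cleanly (log-scale effect 2), modality A is dominated by the line
  structure (effect 2) with an attenuated class signal (0.3).
* `synth_outliers()` — a clustered training set plus an in-distribution
  replicate and a novel cluster displaced by a configurable multiple of the
  within-cluster spread.

These generators reproduce the *statistical shape* that the method relies
on — cluster structure under correlation distance, regions that are
spatially contiguous, markers that drive specific regions, modalities of
unequal class separability — but not instrument artifacts: no peak-shape or
centroiding effects, no spatial intensity drift, no batch effects, no
chemical noise correlated across adjacent m/z bins, and no realistic Hi-C
polymer physics (the contact-list generator exists for I/O testing only).
Passing tests therefore demonstrate the pipeline's correctness and its
behaviour under controlled conditions, not performance on any particular
instrument's data.

## Problem sizes used by the test and acceptance harness

The unit and property tests run on dozens-to-hundreds of samples. The
acceptance tests exercise every end-to-end claim at desk scale — an imaging
fixture of 12,000 pixels × 300 features (6 regions), subsampled every 10th
pixel to 1,200 reference samples, plus matched-omics fixtures of 160
samples and outlier fixtures of 400 training samples. The
`scripts/acceptance.R` script runs the headline benchmark at the full
stated scale: 50,000 pixels × 500 features, subsampled every 10th to 5,000
reference samples, exact t-SNE, both network directions.

## Known limitations

* Exact t-SNE is $O(n^2)$ in the subset size; subsets beyond ~10,000
  samples are better served by the UMAP backend.
* The surrogate can only interpolate the reference geometry: structure
  absent from the subset (rare cell types, small lesions) cannot appear in
  the projected embedding. Novelty scoring (`novelty_score()`) exists
  precisely to flag such samples rather than silently misplacing them —
  but note that the k-NN embedding-distance score can miss samples the
  forward net happens to extrapolate onto an existing cluster; the
  round-trip reconstruction score (supply `inv =`) detects those, and is
  the score to prefer for feature-space novelty.
* Pseudo-spectra are regression outputs, not physical spectra: values may
  be negative, and extrapolated queries (far outside the unit cube) warn.
* Cross-omics projection assumes the paired samples cover the joint
  distribution; a pairing broken by sample mix-ups is detectable only
  through its collapsed held-out $r^2$ (the trainer warns when it cannot
  beat a constant predictor).
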