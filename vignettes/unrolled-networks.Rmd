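---
title: "Deep memory unrolled networks: model, design choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deep memory unrolled networks: model, design choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(demun)
```

## The reconstruction problem

A compressive imaging system observes `y = A x* + w`, with `x*` a vectorized
`side x side` image, `A` an `m x n` operator with `m <= n`, and `w` i.i.d.
Gaussian noise of standard deviation `sigma`. Were the set `C` of plausible
images known, projected gradient descent (PGD) would recover `x*` by
alternating a gradient step on `||y - A x||^2` with a projection onto `C`:

    x~_i   = x_i + mu A'(y - A x_i)
    x_{i+1} = P_C(x~_i).

Unrolled networks fix `T` iterations of this scheme and replace each
projection with a trainable DnCNN, trained end to end on measurement/image
pairs. This package implements that construction together with the
deep-memory generalization in which the gradient step itself is learned:

    x~_i = alpha_i x_i + sum_{j=0..i} beta_{j,i} A'(y - A x_j),

with `x_0 = 0` and every `alpha_i`, `beta_{j,i}` trainable. Fixing
`alpha_i = 1`, `beta_{i,i} = mu` and the rest to zero recovers PGD; suitable
triangular coefficient patterns reproduce Nesterov's accelerated method, and
the Onsager-corrected residual of approximate message passing (AMP) has the
same "weighted sum of past gradients" structure. The memory scheme therefore
lets training select the algorithm instead of the practitioner. Equivalently,
the update is a one-by-one convolution over the channel stack
`[x_i, g_0, ..., g_i]`; `demun_step(..., as_conv1x1 = TRUE)` evaluates that
view and agrees with the term-by-term sum to machine precision.

## Measurement operators

Two families are provided, both with exact adjoints under a fixed row-major
vectorization:

* **Gaussian**: dense `A` with entries i.i.d. `N(0, 1/m)`, so every column
  has unit expected energy. This is the classical compressed-sensing
  ensemble and the one AMP's Onsager correction assumes.
* **Undersampled 2D-DCT**: `A = S F` with `F` the orthonormal type-II 2D
  DCT and `S` a row selection, applied matrix-free (two small matrix
  products and a gather). Because the kept rows are orthonormal,
  `A A' = I` at every sampling rate. The selection pattern is a
  configuration switch — `uniform-random-rows` (seeded, the default) or
  `low-frequency-first` — because undersampling masks are
  application-specific and no single choice is canonical.

`model_dense()` materializes either operator for audits; all tests of the
matrix-free paths compare against it.

## Losses

For a trace `x_1 ... x_T` the package implements the last-layer loss
`||x_T - x*||^2`, the weighted intermediate loss
`sum_i omega^(T-i) ||x_i - x*||^2` with `omega` in `(0, 1]`, and the skip-L
loss summing the error at every L-th step counting back from `T`. The three
families are connected by exact identities (`skip = 1` equals `omega = 1`;
`skip = T` and `omega -> 0` approach the last-layer loss), which the test
suite asserts on random traces. Losses are pixel sums per image, averaged
over the batch — keeping the written norms literal while making gradient
magnitudes independent of batch size. The `omega` grid of the sensitivity
study (`1, 0.95, 0.85, 0.75, 0.5, 0.25, 0.1, 0.01` plus skip-5) ships as
`loss_preset_grid()`.

## Projector and training

The projector is a standard DnCNN: input conv + ReLU, `L` blocks of
conv + batch norm + ReLU, and a single-channel output conv, all 3x3 and
same-padded so one architecture serves any resolution (the robustness
studies sweep 32-80 px). Projector weights are **not** shared across steps
(a `share_weights` switch exists for ablation). The residual form
`x_{i+1} = x~_i + P(x~_i)` is a per-config flag. With batch norm on,
intermediate convs carry no bias (BN's shift absorbs it); the output conv
keeps its bias. Parameter counts follow the closed form in
`dncnn_param_count()` and are asserted against the built networks.

No deep-learning framework is involved: convolutions run as im2col + BLAS
matrix products, and the full backward pass — through the projectors, batch
norm, the residual connections, *and* the measurement operator inside every
stored gradient `g_j = A'(y - A x_j)` — is written out analytically. The
test suite verifies this end-to-end gradient against central finite
differences at relative error below `1e-5` for all trainable parameters and
all schemes. Optimization is Adam (default `lr = 1e-3`, batch 16).

### Initialization

Memory coefficients start at the PGD view with `mu = 1/sigma_max(A)^2`
(`stable_step_size()`, computed by power iteration; exactly 1 for the DCT
operator). Starting from the largest provably non-expansive gradient step
matters: for a Gaussian operator at sampling rate 0.25,
`||A||^2 ~ (1 + sqrt(n/m))^2 ~ 9`, so a unit initial step makes the unrolled
linear part expansive (roughly 8x per step), and training must first undo
that amplification — at small scale it simply stalls. With the stable step
the untrained network already is convergent PGD, and training only improves
on it. The scalar `mu` of the PGD/Nesterov baselines is itself trainable
(shared across steps).

### Scheme-specific notes

* **Nesterov** uses the canonical schedule
  `gamma_i = (t_{i-1} - 1)/t_i`, `t_i = (1 + sqrt(1 + 4 t_{i-1}^2))/2`,
  with no momentum on the first step.
* **AMP** uses the denoising form with residual
  `z_t = y - A x_t + z_{t-1} * div`, where `div` is the divergence of the
  previous denoising step normalized by `m`. The divergence is estimated
  with Rademacher (Hutchinson) probes, which are exact for linear denoisers
  at any probe count — that closed form (`c n / m` for `eta(v) = c v`)
  anchors the tests. Inside the trainable network the Onsager coefficient is
  treated as a constant during backpropagation (stop-gradient); the classic
  soft-threshold AMP in `amp_recover()` is the fully verified reference
  path, reaching NMSE below -30 dB on a 10-sparse signal at `n = 256`,
  `m = 128` within 30 iterations.

## Synthetic data

Three seeded generators stand in for natural-image training sets:
`cartoons` (piecewise-constant ellipses, rectangles and triangles — sharp
edges, the structure SSIM rewards), `grf` (band-limited Gaussian random
fields with power-law spectrum `(1 + |f|)^(-gamma)`, mimicking 1/f image
statistics), and `dct_sparse` (exactly k-sparse in the 2D-DCT domain — the
sanity tier where DCT-operator recovery is nearly trivial). Images are
min-max rescaled to `[0, 1]`; generation depends only on
`(kind, count, side, seed)`. These stand-ins exercise edges, spectra and
sparsity but make no claim of distributional equivalence to photographic
data: passing toy studies demonstrates that the machinery trains and ranks
design choices sensibly, not that the printed large-scale numbers transfer.
PNG and CSV loaders accept user images (BT.601 luma conversion, center-crop,
bilinear resize).

## Metrics and conventions

PSNR uses peak 1.0 (images normalized to `[0, 1]`) and caps zero-MSE pairs
at 100 dB. SSIM uses the standard constants: 11x11 Gaussian window with
sigma 1.5, `K1 = 0.01`, `K2 = 0.03`, data range 1.0, population covariance;
it agrees with scikit-image's implementation to `1e-6`. Summary tables
report mean and sample standard deviation (ddof = 1) over test images. Input
SNR is defined as `10 log10(mean ||A x||^2 / (m sigma^2))` over a test set;
doubling `sigma` lowers it by exactly `20 log10(2) ~ 6.02` dB. No formula
pins this convention uniquely — averaging and normalization choices differ
across the literature — so it is documented here and kept out of any claim
that depends on the convention.

## The toy tier

The default `experiment_config()` is the package's one-CPU study scale,
chosen once: side 16 at sampling rate 0.25, `T = 4`, `L = 3`, width 16,
200 training cartoons and 40 test images, Adam `lr = 1e-3`, 15 epochs,
batch 16. At that scale one training run takes about 90 s, and the
acceptance suite repeats the central comparisons over 3 seeds: supervising
every step (`omega = 1`) versus the last layer only, residual versus direct
projections, and trained networks versus the `A'y` back-projection
baseline. These are *direction* checks of the design-choice hypotheses —
small-scale, few-seed, and run on synthetic cartoons — not reproductions of
the large-scale magnitudes, which require the original training corpus and
GPU-scale optimization of 30-step networks.

## Numerical choices and degenerate inputs

* Vectorization is row-major and shared by forward and adjoint, so the
  adjoint contract `<Ax, r> = <x, A'r>` holds to rounding error.
* `sigma = 0` reproduces noiseless measurements bit-exactly (no RNG draw).
* Gradient histories are recomputed from stored iterates rather than
  cached; equality of both strategies is part of the scheme's definition.
* Batch norm uses biased batch variance, momentum 0.1, eps 1e-5; evaluation
  uses running statistics.
* All randomness (weights, data, noise, shuffling, probes) flows through
  explicit seeds; every constructor restores the caller's RNG state.
* Degenerate requests fail with typed errors (`demun_config_error`,
  `demun_shape_error`, `demun_state_error`) naming expected and actual
  sizes.

## Known limitations

* Training is CPU-bound pure R; it is engineered for correctness and the
  toy/small tiers, not for the 50x50, `T = 30` scale of the full study.
* Trainable AMP uses a stop-gradient Onsager coefficient; fully
  differentiating the divergence probe is future work.
* Complex-valued k-space operators, coil maps and CT projectors are out of
  scope, as are perceptual losses and non-DnCNN projectors.
* Whether the memory coefficients should be constrained (e.g. `alpha = 1`)
  is left open; the package trains them freely and exposes the PGD view as
  initialization.
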