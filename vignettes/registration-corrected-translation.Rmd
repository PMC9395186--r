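---
title: "Registration-corrected adversarial image translation: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Registration-corrected adversarial image translation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`swinreg` trains a generator $G$ to map a source-modality image $x$ to a
target-modality image, a registration network $R$ predicting a dense
displacement field $\varphi = R(G(x), y)$, and a patch discriminator $D$,
under

$$\mathcal{L} = \kappa\,\mathcal{L}_{Adv} + \lambda\,\mathcal{L}_{Corr}
  + \mu\,\mathcal{L}_{Smooth},$$

with $\mathcal{L}_{Corr} = \mathbb{E}\,\lVert y - G(x)\circ\varphi
\rVert_1$ (the generated image is warped *before* the L1 is taken) and
$\mathcal{L}_{Smooth} = \mathbb{E}\,\lVert \nabla\varphi \rVert^2$. The
idea: when the supervision target $y$ is spatially misaligned with the
anatomy of $x$, plain L1 teaches $G$ a blurred compromise of displaced
targets; letting a registration network absorb the displacement turns
misalignment into correctable label noise. $R$ exists only at training
time — inference applies $G$ alone (a flag exposes the
translated-then-registered output for inspection).

Attention follows the shifted-window construction: features are cut into
$m\times m$ windows, each flattened to $m^2$ row-major tokens, and each
head computes $\mathrm{softmax}(QK^\top/\sqrt{d} + B)V$ with $d = C/h$ and
a learnable relative-position bias $B$ indexed by the $(2m-1)^2$ distinct
2D offsets. Layers alternate unshifted and $\lfloor m/2\rfloor$-shifted
windows; shifted layers use the standard cyclic roll plus an additive
mask that confines attention to tokens from the same pre-shift region.

Two places in the source description are internally inconsistent and were
resolved to the conventions of the cited Swin/SwinIR architecture, which
the rest of the text follows: the attention scaling is $1/\sqrt{d}$ (the
printed form collapses the exponent), and the bias table is
$(2m-1)\times(2m-1)$ (the printed $(2m-1)\times(2m+1)$ cannot index
$m^2 \times m^2$ pairwise offsets).

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| $\kappa,\lambda,\mu$ | 1, 20, 10 | loss weights; the published operating point of the greedy sweep |
| learning rate | 1e-4 | Adam, betas (0.5, 0.999); the GAN convention |
| epochs | 80 | published setting; desk-scale tests use 2–15 |
| window $m$ | 8 (4 in tests) | attention window side, pixels |
| embed dim $C$ / heads $h$ | 60 / 6 | lightweight SwinIR-style width (unstated in the source; widths only change capacity) |
| RSTBs × STLs | 4 × 6 | generator depth |
| STR levels / base channels | 4 / 16 | encoder depth, width doubling per level (capped at 8×) |
| `deform_amplitude` | 2 px | max displacement magnitude of synthetic misalignment — the "small mismatch" regime the correction loss assumes |
| `deform_smoothness` | 4 px | Gaussian sd of the misalignment field |
| `noise_sd`, `blur_sd` | 0.01, 0.5 | phantom intensity noise and edge softness |

Design choices where the source is silent, each fixed once:

* **Generator output**: sigmoid, guaranteeing the [0, 1] range the data
  normalisation promises. The recovery head is a 3×3 convolution; a
  subpixel (pixel-shuffle) head is available behind a flag but with
  upscale factor 1 it reduces to a convolution, since translation is
  same-resolution.
* **Adversarial form**: the discriminator minimises the logit-space
  negative of the minimax value; the generator uses the non-saturating
  $-\log\sigma(D(G(x)))$, whose gradient direction matches the saturating
  form. All log-sigmoids are computed in logit space, so the losses are
  finite for any finite logits. $D$ sees the *raw* $G(x)$ — the
  adversarial loss is written on $G(x)$, registration affects only the
  correction term (a flag allows the alternative).
* **Discriminator**: a patch discriminator (stride-2 3×3 convolutions,
  LeakyReLU 0.2, instance norm from the second block); the source says
  only "convolution-based", and patch classifiers are the standard choice
  for same-resolution translation.
* **Smoothness reduction**: Eq.-level text gives only
  $\lVert\nabla\varphi\rVert^2$; this package uses forward finite
  differences and takes the mean over pixels, components and batch of the
  squared gradient magnitude summed over the two directions (a unit-slope
  field scores 0.5). Means rather than sums keep $\mu$ and $\lambda$
  resolution-independent.
* **Warping**: bilinear, displacement in pixel units added to the
  identity grid, border-clamped out-of-range samples; clamped coordinates
  get zero flow gradient. A zero field is the exact identity.
* **Flow head**: zero-initialised, so training starts from the identity
  warp; this stabilises the early adversarial phase.
* **STR details**: Swin layers sit after each downsampling convolution
  (their exact placement is unstated); stages smaller than the window
  skip them. Decoder upsampling is nearest-neighbour + convolution
  ("alternative up-sampling" is not specified further).
* **Update schedule**: one discriminator step on the detached generator
  output, then one joint $G$+$R$ step, per batch.
* **Padding**: when a feature map is not a multiple of $m$, it is
  reflect-padded bottom/right before windowing and cropped after.

## What the phantom generator does and does not emulate

Each sample renders one random labelled ellipse "anatomy" under two
monotone lookup tables whose tissue ordering is mutually reversed —
modality A bright where B is dark — so translation is learnable as
intensity remapping conditioned on local structure, the same abstract
task as T1→T2 synthesis. Misaligned mode warps the target by a fresh
Gaussian-smoothed random field of known amplitude (stored as ground
truth); unpaired mode pairs each source with a *different* sample's
target via a derangement, so no accidental alignment exists. Fresh
per-sample deformations force the registration network to condition on
its inputs rather than memorise one field.

Not emulated: MR physics (relaxometry, bias fields, k-space artifacts,
Rician noise), pathology, 3D continuity across slices, and realistic
anatomy. A green test therefore establishes that the optimisation
behaves as designed — misalignment is absorbed by $R$, contrast is
inverted by $G$ — not that clinical-quality synthesis is achieved; the
published clinical numbers need the real datasets and GPU-scale training
and are out of scope by design.

## Numerical and scale choices

* The package carries its own tape-based reverse-mode autodiff engine
  (with C++ kernels for batched matmul, gather/scatter and the bilinear
  warp), because the target environment provides no deep-learning
  framework for R. Every operation's gradient is tested against central
  finite differences.
* PSNR is capped at 100 dB when MSE < 1e-10; the data range is fixed at
  1. SSIM uses the 11×11 Gaussian window, sd 1.5, Wang constants, and the
  valid-region mean — verified to 1e-6 against scikit-image's
  `structural_similarity` in its `gaussian_weights` configuration.
* Desk-scale test runs shrink widths/depths (e.g. $C=16$, 2 RSTBs × 2
  STLs, 32×32 phantoms) and epochs; thresholds asserted by the acceptance
  tests (≥50 % registered-L1 reduction, <1 px mean endpoint error, ≥5 dB
  over an untrained baseline, the ablation ordering) are unchanged.
* Learning rates at desk scale: registration-only fitting uses
  1e-3–2e-3 — at a few hundred steps the published 1e-4 has not moved
  the zero-initialised flow head measurably. The scaled-down ablation uses
  per-network rates (G 5e-4, R 2e-3, D 2e-4): the registration branch is
  non-adversarial and tolerates a faster rate, while the discriminator is
  slowed because the observed small-scale failure mode is a
  discriminator-wins collapse. Rates are always identical across the
  scenarios being compared, and `train_config()` defaults keep the
  published uniform rate.
* Seeded determinism is end-to-end: initialisation, shuffling and data
  generation all derive from one master seed, and two runs with the same
  configuration produce bitwise-identical checkpoints.

## Known limitations

* 2D slices only; volumetric training is future work in the source and
  out of scope here.
* The pure-R/C++ engine is orders of magnitude slower than a GPU
  framework; the published 80-epoch, 1000-image training regime is
  reachable but slow, and the test suite deliberately stays at desk
  scale.
* The registration network offers no diffeomorphic guarantee (no
  scaling-and-squaring, no inverse consistency); for the small smooth
  fields of the phantom world this does not bind.
* Unpaired training uses the same objective with deranged targets; there
  is no cycle term, so unpaired results depend entirely on the
  registration network's ability to absorb anatomy differences.
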