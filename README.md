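# swinreg

Multi-modal medical image translation with a shifted-window (Swin)
transformer GAN whose training objective is corrected by a learned
deformable registration network.

## The problem

Multi-contrast MRI shows the same anatomy under different intensity
mappings (T1, T2, FLAIR, ...). Synthesizing a missing contrast from an
acquired one is an image-to-image translation problem, but supervised
translation needs pixel-aligned source/target pairs — and real pairs are
misaligned by motion and anatomical change between scans. `swinreg`
implements a three-network answer:

* **Generator (STG)** — a same-resolution SwinIR-style network: a shallow
  3×3 convolution, a stack of residual Swin transformer blocks (RSTBs,
  each `Conv(STL_n(...STL_1(x))) + x`), a post-body convolution, a long
  skip connection carrying the low-frequency content straight to a
  convolutional recovery head with a sigmoid output in [0, 1]. Windowed
  attention is `softmax(QKᵀ/√d + B) V` per `m × m` window with a learnable
  relative-position bias `B` and alternating window shifts of `⌊m/2⌋`.
* **Registration network (STR)** — a U-shaped encoder–decoder (stride-2
  3×3 convolutions + LeakyReLU(0.2), Swin layers in the encoder, skip
  connections, zero-initialised flow head) predicting a dense displacement
  vector field `φ = R(G(x), y)` in pixels.
* **Patch discriminator** — stride-2 convolutions emitting a grid of
  real/fake logits.

Training minimises

```
L = κ·L_adv + λ·L_corr + μ·L_smooth,   (κ, λ, μ) = (1, 20, 10)
L_corr   = E ‖ y − G(x) ∘ φ ‖₁          (warp before the L1)
L_smooth = E ‖ ∇φ ‖²                    (mean squared forward differences)
```

so spatial misalignment between `y` and the anatomy of `x` is treated as
*correctable label noise*: the registration network absorbs the
deformation during training, and inference uses the generator alone.

Because no public MRI data ships with the package, a synthetic phantom
module generates multi-modal pairs with known ground truth: shared
elliptical anatomy, two mutually inverted intensity lookup tables
(T1-vs-T2-like contrast inversion), optional smooth misalignment fields of
known amplitude, and aligned / misaligned / unpaired sampling modes.

Everything — including a tape-based reverse-mode autodiff engine with
RcppArmadillo kernels — is self-contained; no deep-learning framework is
required.

## Worked example

```r
library(swinreg)

# 40 aligned 32x32 phantom pairs; hold out 8 for scoring
ds <- make_dataset(phantom_config(n_samples = 40, mode = "aligned", seed = 1))
sp <- split_dataset(ds, holdout = 0.2, seed = 1)

cfg <- train_config(
  epochs = 8, seed = 1, scenario = "mmtrans",
  generator = stg_config(n_rstb = 2, n_stl_per_rstb = 2,
                         swin = swin_config(window = 4, embed_dim = 16,
                                            num_heads = 2)),
  registration = str_config(levels = 2, base_channels = 8, window = 4,
                            n_stl_encoder = 1),
  discriminator = disc_config(base_channels = 12))
ck <- train(cfg, sp$train)
evaluate(ck, sp$holdout)$metrics
```

On this seed the run prints

```
metrics over 8 image(s):
  PSNR   13.58 +/- 1.03 dB
  MAE    12.66 +/- 1.71 (x 10^-2)
  SSIM  0.4216 +/- 0.0755
```

i.e. after eight desk-scale epochs the generator already inverts the
tissue contrast: ~13.6 dB against an untrained baseline of ~8 dB (PSNR is
`10·log10(1/MSE)` on the [0, 1] scale, MAE is shown ×100 as is
conventional, SSIM uses the 11×11 Gaussian window of sd 1.5). Longer
training and wider networks improve all three numbers; the published
operating point trains 80 epochs.

The four-scenario ablation (`baseline_gan`, `swin_g`, `swin_g_plus_r`,
`mmtrans`) and the greedy one-at-a-time weight sweep are driven by
`run_ablation()` and `run_sweep()`.

## Command line

```sh
Rscript -e 'swinreg::run_cli()' simulate --out data --n 32 --mode misaligned --save-dvf
Rscript -e 'swinreg::run_cli()' train    --data data --out ck.rds --epochs 20
Rscript -e 'swinreg::run_cli()' evaluate --checkpoint ck.rds --data data --out results
Rscript -e 'swinreg::run_cli()' translate --checkpoint ck.rds data/sample001_x.png
Rscript -e 'swinreg::run_cli()' ablate   --data data --epochs 5 --out ablation.tsv
Rscript -e 'swinreg::run_cli()' sweep    --data data --param kappa --values 0.01,1,100
```

Images are 16-bit grayscale PNG (reader/writer built in; PGM and NIfTI-1
slices are also read), displacement fields are `.npy`, metrics tables are
TSV.

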