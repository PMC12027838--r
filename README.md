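# dsclpgan

Dual-stream contrastive latent projection GAN for brain-MRI augmentation,
implemented as an R package at desk (single-CPU) scale.

## The problem

Tumor classifiers for brain MRI are limited by small, imbalanced labelled
datasets.  One remedy is GAN-based augmentation: generate realistic,
*diverse* variants of each training slice and let a classifier train on the
enlarged set.  `dsclpgan` implements such a framework for grayscale 2-D
slices with four labels (0 no tumor, 1 meningioma, 2 glioma, 3 pituitary):

* **Dual-stream generator.**  An encoder maps an input slice `x` to a
  latent code `z` (dimension 100), split into a global stream `z_g` and a
  local stream `z_l` (50 + 50).  Each stream is perturbed with its own
  Gaussian noise, and a dual-path decoder (coarse skip-connected global
  path, fine local path) produces `x' = σ(G_s(z) + G_l(z))` — the two
  components add exactly pre-activation, and a bounded activation keeps
  the image in [0, 1].  With zero noise the generator is a plain
  autoencoder.
* **Contrastive latent projection (CLP).**  Two perturbed views of the same
  image are projected by a small head and pulled together with an InfoNCE
  loss over temperature-scaled cosine similarities,
  `L = -log[ exp(cos(z1,z2)/τ) / (exp(cos(z1,z2)/τ) + Σ_j exp(cos(z1,zj)/τ)) ]`,
  with the other images in the batch as negatives.
* **Three discriminators.**  `D1` classifies real and generated images into
  the four classes (and doubles as the downstream tumor classifier); `D2`
  is a patch critic emitting a 16×16 grid of realness scores with
  ~15-pixel receptive fields; `D3` scores the DC-centered log-magnitude
  Fourier spectrum to enforce frequency-statistics consistency.
  Discriminators minimize
  `λ_cls·L_cls + λ_adv·L_D2 + λ_freq·L_D3`; the generator minimizes the
  non-saturating counterparts plus `λ_clp·L_CLP` and an L1 reconstruction
  term.

The layers and the reverse-mode automatic differentiation behind them are
implemented in the package itself (compiled convolution kernels + a small
tape in R), keeping the dependency footprint to standard R packages; the
gradients are validated against finite differences and closed-form oracles
in the test suite.  A synthetic brain-phantom module (elliptical brain, smooth texture,
bias field, class-dependent enhancing lesions) makes every experiment
reproducible without external data.

## Worked example

```r
library(dsclpgan)

spec <- phantom_spec()                       # 64x64 synthetic T1-CE slices
phantom <- make_phantom(spec, label = 2, seed = 7)
#> image_sample ph-7-2: 64x64, label 2

dat <- make_dataset(spec, 256, seed = 11)    # labelled phantom dataset
cfg <- train_config(preset = "desk", seed = 1)
#> train_config [desk]: batch 16, 5 epochs, lr 0.002, tau 0.5, sigma 0.5/0.5, seed 1

state <- fit(dat, cfg)                       # ~1 minute on one CPU
tail(state$history[, c("epoch", "g_total", "clp", "recon", "val_ssim", "val_psnr")], 3)
#>   epoch g_total    clp  recon val_ssim val_psnr
#> 4     3  6.5696 2.7739 0.2066   0.1459  12.7943
#> 5     4  5.8296 2.7740 0.1704   0.2439  14.1281
#> 6     5  5.3715 2.7677 0.1489   0.2675  15.0070

out <- generate(state$model, phantom$pixels, sigma_global = 0.5,
                sigma_local = 0.5, seed = 3)
ssim(phantom$pixels, out$image)              # 0.2241
psnr(phantom$pixels, out$image)              # 14.1 dB

aug <- augment_dataset(dat[1:10], state, level = 3, seed = 2)
length(aug)                                  # 40 = 10 * (1 + 3)
```

The history shows what five desk epochs buy: the generator loss and the L1
reconstruction term fall steadily and validation SSIM of zero-noise
reconstructions rises from ~0.03 at initialization to ~0.27, while the
contrastive loss is still near its chance level (`ln 16 ≈ 2.77`) — the
contrastive structure needs more epochs to emerge (see the methods
vignette).  Generated variants are diverse (seeded noise on both latent
streams) but, at this training scale, still far from the source image in
SSIM terms.

`diversity_eval()` measures the downstream payoff: it trains a fresh copy
of the small `D1` classifier per augmentation-diversity level (level `k` =
`k` generated variants per training image, each level with the same fixed
gradient-step budget) and reports held-out accuracy per level.

## Command line

```sh
inst/cli/dsclpgan train    --preset desk --data phantom --n 256 --seed 1 --out run1
inst/cli/dsclpgan generate --checkpoint run1/checkpoint.rds --data phantom --n 4 --level 5 --out run1/gen
inst/cli/dsclpgan evaluate --checkpoint run1/checkpoint.rds --data phantom --n 200 --levels 0,1,3 --seeds 1,2,3 --out run1/eval
```

Each command writes a `manifest.json` (config snapshot, seed, checksums);
`train` accepts a YAML config, `generate` writes PNG or single-slice NIfTI
variants plus a `labels.csv` sidecar, `evaluate` writes an accuracy CSV and
a metric report JSON.

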