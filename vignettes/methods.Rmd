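---
title: "Methods: diffusion-guided fracture localization on phantom radiographs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diffusion-guided fracture localization on phantom radiographs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the approach

Thin fracture lines in bone radiographs are a classic anomaly-detection
target: plentiful healthy images, scarce and expensively annotated abnormal
ones, and anomalies that occupy a tiny fraction of the pixels. `scafdl`
implements a reconstruction-based, self-supervised pipeline in three stages:

1. **Pseudofracture synthesis.** A healthy image `N` is turned into a
   labelled training pair without any manual annotation. A binary foreground
   mask `F` restricts anomalies to the bone; a random polyline shape `P`
   (two border endpoints, `k ~ U{1..5}` interior points, rasterized and
   dilated) is clipped to it, `M = F ⊙ P`; a texture patch `T` is blended at
   opacity `β`, `A = βT + (1-β)N`; and the pseudofracture image is
   `S = M ⊙ A + (1-M) ⊙ N`. Low interior-point counts give near-linear
   fissures, high counts give irregular trajectories, so one mechanism spans
   the subtle-to-complex severity range.
2. **Guided diffusion reconstruction.** A DDPM noise predictor
   `ε̂_θ(x_t, t)` is trained (on normal samples only) under the standard
   forward process `x_t = √ᾱ_t x_0 + √(1-ᾱ_t) ε`. At inference a single
   denoising step at a short time step `t_s` is *guided* by the model's own
   clean-image predictions at a medium and a long step: both `x̂_0`
   predictions are renoised to `t_s`, their deviations from `x_{t_s}` form
   `Δ = w₁(x_{t_s|x̂0,m} − x_{t_s}) + w₂(x_{t_s|x̂0,l} − x_{t_s})`, the
   predicted noise is corrected to `ε_g = ε̂_θ(x_{t_s}, t_s) − √(1-ᾱ_{t_s})Δ`,
   and a final one-step inversion yields the reconstruction. Short steps
   preserve structure; long steps erase anomalies; the combination does both.
3. **Saliency localization.** An encoder-decoder segmentation network with a
   squeeze-and-excitation block at the end of each encoder stage maps the
   channel-concatenated `(image, reconstruction)` pair to a per-pixel
   anomaly probability through a terminal sigmoid. It is trained against the
   synthesis masks with `L_mask = L_smoothL1 + γ_mask · L_focal` while the
   denoiser simultaneously minimizes the gated noise MSE
   `L_noise = ⅓(1-y) Σ_t ‖ε_t − ε̂_t‖²`; the total objective is their sum.

Evaluation uses the image-level top-K score (mean of the K largest saliency
values), image and pixel AUROC (midrank tie convention), and the per-region
overlap (PRO) curve — mean `|P∩G|/|G|` over anomalous images against the
pooled false-positive rate over all images' normal pixels — integrated up to
FPR = 30% and normalized (the PRO-score).

## Key parameters

| parameter | default | meaning |
|---|---|---|
| `guidance w1, w2` | 0.5, 0.5 | weight of the medium/long-step guidance terms |
| time-step triple | segment upper bounds (fixed mode) | short/medium/long steps; random mode samples one per segment per training batch |
| `β` (blend opacity) | `U(0.5, 1)` per sample | texture dominance inside the anomaly |
| shape thickness | 1 px dilation radius | fracture lines 2–3 px wide |
| batch ratio | 0.5 | half normal, half pseudofracture per batch (a batch of 16 holds 8 + 8) |
| focal `α` | 0.75 | positive-pixel weight, anomalies being rare |
| focal `γ` | 2 → 3.5, linear per epoch | focusing ramp over training |
| `γ_mask` | 1 | focal weight inside the mask loss |
| image-score K | 50 | top-K pixels averaged, kept absolute across resolutions (config override available) |
| PRO FPR cap | 0.3 | integration limit of the PRO curve |

Two profiles are shipped. The **desk** profile — 32×32 images, `T = 200`
with segments `(0,60], (60,100], (100,140]`, denoiser widths 8/16/32 with a
depth-2 transformer mid-block, localizer widths 8/16/24 with SE ratio 4,
batch 16, Adam at `lr = 1e-3` — is the configuration every test, example and
the acceptance script use; its problem sizes (60 training phantoms, 20 + 20
test images, 1200 optimization steps) were chosen so a full three-seed
learning check runs comfortably on one CPU core. The **paper** profile
records the full-scale setup (128×128, `T = 1000`, triple 300/500/700,
transformer depth 12, `lr = 1e-5`, 1500 epochs, batch 16) and is stored as
configuration only.

## The phantom generator: what it emulates, and what it does not

Clinical radiograph crops of a single bone are emulated by a seeded
generator: a bright super-ellipse foreground (random area fraction 20–50%,
aspect, exponent and orientation) carrying a smooth multiplicative
"bone-density" field, over a darker background with 1–3 faint elongated
distractor blobs standing in for neighboring bones, global Gaussian
smoothing and pixel noise. True test fractures are inscribed as darkened
polylines crossing the bone's short axis in three severities — `subtle`
(16–24% intensity drop), `line` (42–52%), `displaced` (wider track, 48–58%
drop plus a 1–2 px band shift) — a working proxy for occult / nondisplaced /
displaced appearance with no claim of radiological realism. Test sets draw
severities at 0.2 / 0.5 / 0.3: visible fracture lines dominate clinical
series while truly occult cases are the minority. The texture bank
alternates band-limited bright noise ("bone-overlap-like", standing in for
lateral-view overlap regions whose true statistics we cannot emulate) and
near-uniform dark patches ("background-like").

Passing tests on phantoms therefore demonstrate that the machinery — the
synthesis algebra, the guided reconstruction, the joint training dynamics
and the metric stack — behaves as specified, and that the pipeline learns to
localize anomalies it has never seen labelled. They do not demonstrate
clinical performance: phantoms lack trabecular texture, projection effects,
exposure variation between devices, and anatomy-specific confounders.

## Numerical and design choices

- **Diffusion algebra.** Linear β schedule from 1e-4 to 0.02 (the standard
  DDPM default), ᾱ₀ ≡ 1, 1-based step indexing; `predict_x0` rejects
  `t = 0`, where the inversion is ill-posed. The radical convention
  (√ᾱ, √(1-ᾱ)) is used consistently so the one-step inversion exactly
  undoes the forward map — verified to 1e-6 for every `t` in the tests.
- **Noise reuse.** One shared noise realization is used for all three
  forward diffusions and both renoisings inside a reconstruction. This makes
  the whole guided map deterministic given the draw and admits an analytic
  oracle: with a denoiser that is exact for a fixed target `x*`,
  substitution through the guidance chain collapses to
  `x0_guide = x* + (1-ᾱ_{t_s})(w₁+w₂)(x* − x_in)`, which the implementation
  must (and does) reproduce to 1e-6 across a grid of steps and weights.
  Fresh-noise mode is available behind a flag.
- **Detached reconstruction.** The mask loss never backpropagates through
  the reconstruction into the denoiser; Stage II is trained purely by noise
  prediction on normal samples, which is the published rationale for
  excluding pseudofractures from the reconstruction loss. The flag exists
  but only the detached mode is implemented.
- **Triple sampling.** A fresh random triple is drawn per training batch
  (per-epoch sampling would merely coarsen the same distribution);
  evaluation uses the fixed segment-upper-bound triple.
- **Mask augmentation order.** Aggressive shape transforms (rotation ±90°,
  shear 0–40°, translation ±50%, scale 50–100%) are applied to the fracture
  shape *before* foreground clipping, so containment `M ⊆ F` holds by
  construction; the milder pair augmentation (three ops drawn without
  replacement from gamma, brightness, solarize, autocontrast, equalize,
  rotation ±45°) applies geometric ops identically to image and mask.
  Hue/saturation shifts are dropped deliberately: inputs are single-channel.
- **Normal samples in the mask loss.** Normal (`y = 0`) samples contribute
  empty-mask targets to `L_mask`, teaching the localizer to stay quiet on
  healthy images.
- **Focal ramp granularity.** `γ` is interpolated linearly in the epoch
  index between its endpoints (2 and 3.5); `γ_mask` defaults to 1 since no
  published value exists.
- **Foreground backends.** The clinical foreground segmenter is replaced by
  two backends: `oracle` (the phantom's stored mask) and `threshold` (Otsu,
  largest connected component, hole fill — via EBImage). On default
  phantoms the threshold backend reaches IoU ≥ 0.90 against the oracle on
  every tested seed.
- **PRO details.** Binarization is strict `>`; the threshold sweep uses the
  sorted unique saliency values subsampled to ≤ 256 levels extended by
  sentinels spanning the all-positive/all-negative extremes; FPR pools
  non-anomalous pixels across *all* test images while PRO excludes normal
  images; duplicate FPR values keep the dominating (max-PRO) operating
  point; the curve is linearly interpolated at the 30% cap. AUROC uses
  midranks, equivalent to pairwise comparison with ties counted ½.
- **Numerical safety.** Saliency is clamped 1e-6 away from {0, 1} inside
  the focal loss; images are clipped to [0, 1] after blending,
  augmentation and reconstruction; 8-bit PNG round trips are asserted to
  1/255.
- **Networks.** Implemented natively (RcppArmadillo, single precision,
  hand-written backward passes, Adam): no deep-learning runtime exists in
  the target environment, and the two small architectures — the U-Net noise
  predictor with a transformer mid-block (multi-head self-attention,
  residual connections, layer norm, additive sinusoidal time embedding on
  the mid tokens) and the SE-U-Net localizer — are part of the method
  itself. Backward passes are validated against directional finite
  differences; gradient-gated samples are skipped in the conv GEMMs, which
  matters because half of each batch is gated out of the noise loss. The
  localizer's output bias is initialized to −2, the usual focal-loss prior
  trick, so early saliency sits near 0.12 rather than 0.5. The desk widths
  are deliberately narrow; widening them (and deepening the mid-block
  toward the paper profile) is the first knob to turn on real data.

## Known limitations

- The phantom generator is a stand-in; none of the numbers produced here
  transfer to clinical data.
- The full-scale profile is stored but not exercised by the test suite; at
  128×128 and depth 12 the native engine works but is slow compared to a
  GPU-backed framework.
- Only the detached training mode is implemented (see above).
- Displaced-fracture emulation shifts a band of pixels; it does not model
  genuine cortical displacement geometry.
- The PRO curve treats each anomalous image's ground truth as one region;
  multi-component masks are averaged per image, not per connected
  component.
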