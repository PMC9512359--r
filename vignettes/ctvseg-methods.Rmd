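---
title: "Cascaded anatomy-guided CTV segmentation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cascaded anatomy-guided CTV segmentation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

The clinical target volume (CTV) in cervical-cancer brachytherapy is the
gross tumour plus its suspected microscopic extension.  Because that
extension is not visible even on T2-weighted MRI, manual CTV contours vary
considerably between radiation oncologists, and automating the contour is
harder than segmenting a visible organ.  `ctvseg` implements a fully
automated coarse-to-fine cascade that exploits a robust anatomical prior:
the cervix sits posterior to the bladder, and the bladder — the brightest
structure on T2-weighted pelvic MRI — is easy to segment.

The cascade has three stages:

1. **Bladder localization.** The native volume is histogram-equalized,
   min-max normalized, cropped and resampled to a coarse grid of
   94 x 94 x 50 voxels at 3.0 x 3.0 x 3.2 mm centred at the volume centre,
   and segmented by a 3-D U-Net.  The prediction is thresholded at 0.5 and
   reduced to its largest 26-connected component, because downstream only
   its *centroid* matters and spurious islands would bias it.
2. **CTV centre and span.** The CTV centre is estimated 39 mm posterior to
   the bladder centroid (population mean; the SD about it is 10 mm),
   laterally and superior-inferiorly aligned.  Every axial slice is
   cropped to 128 x 128 px at 1 x 1 mm about that centre and classified by
   a 2-D attention U-Net; after thresholding, 8-connected components
   smaller than 50 px are removed, and a slice is CTV-positive iff any
   pixel survives.  The superior-inferior span is the longest run of
   positive slices tolerating gaps of at most 2 slices — sparse false
   positives far from the CTV are thereby ignored.  The CTV-specific ROI
   is 128 x 128 in-plane at 1 x 1 mm, spans the detected slices plus a
   2-slice margin at 1.6 mm pitch, and is never shallower than 15 slices
   (one block).
3. **Block-based segmentation.** 3-D blocks of 128 x 128 x 15 voxels are
   extracted from the ROI with stride 1 along the superior-inferior axis
   only, segmented independently by a 3-D U-Net, thresholded, and fused by
   the **union rule**: a voxel is CTV if any covering block said so.
   Majority voting (strictly more than half of the covering blocks, with
   per-voxel cover counts near the edges) is provided for comparison; by
   construction the majority mask is always contained in the union mask.
   The fused ROI mask is resampled (nearest-neighbour) back to the native
   grid.

Monte-Carlo dropout supplies per-voxel uncertainty: the block model is
run repeatedly with dropout active (100 samples by default) and, for every
ROI voxel, the sampled probabilities are pooled over draws and over the
covering blocks.  Both the mean-probability map and the per-voxel sample
SD are returned: descriptions of "the mean of the predictions
illustrating uncertainty" conflate a point estimate with a dispersion
statistic, so exposing both is the unambiguous reading.  The per-voxel SD
is the uncertainty scalar used in tests and overlays.

## Networks

All three networks share one encoder-decoder template
(`network_spec()`): per level, two (3-per-axis convolution, per-sample
spatial normalization, ReLU) blocks; filter counts start at
`base_filters` and double per level; factor-2 max pooling between encoder
levels; a final 1 x 1 convolution with sigmoid.  Three choices deserve
comment:

* **Upsampling** is nearest-neighbour interpolation followed by a 1 x 1
  channel-halving convolution rather than a transposed convolution.  The
  SI pooling schedule depends on the input (15-slice blocks are never
  pooled along SI; a 50-slice bladder crop is pooled once), so a
  transposed-convolution kernel sized by the pooling factor would make the
  weight shapes input-dependent.  The interpolation + 1 x 1 form keeps one
  weight set valid for every admissible input and avoids checkerboard
  artefacts.
* **Pooling with odd sizes.** In-plane sizes must divide `2^(depth-1)`
  (a shape error names the offending axis otherwise); along SI the volume
  is pooled only at levels where the current size is even.  This is what
  lets the 128 x 128 x 15 block survive a multi-level encoder.
* **Normalization** uses each sample's own spatial statistics (per
  channel) in training *and* inference, so prediction is deterministic
  and there is no train/test statistics mismatch at batch size 1.
* **Attention gates** (span network) are additive: the coarser decoder
  feature is upsampled, passed through a 1 x 1 convolution, added to a
  1 x 1-convolved skip feature, ReLU-ed, reduced to one channel, and
  squashed by a sigmoid; the resulting [0, 1] coefficient multiplies the
  skip features.
* The final convolution's bias is initialized to -3 (prior-probability
  initialization): foreground is a small fraction of any of the three
  targets, and starting the sigmoid low removes the long initial phase in
  which the optimizer only learns to suppress background.

Dropout layers sit at the bottleneck and after the coarser decoder
levels; the finest decoder level carries none, because dropping
full-resolution features immediately before the output head injects so
much gradient noise that short training runs stall (the block stage
needed three times the optimizer steps in pilots with it).  The default
rate is 0.5; the desk-scale block model uses 0.2.  Dropout can be kept
active at inference for Monte-Carlo sampling, whose prediction variance
comes from the bottleneck draw.

The layers (direct 3-D/2-D convolution, pooling, upsampling,
normalization, attention, dropout) and the backward passes are
implemented natively in C++; gradients are verified against central
finite differences in the test suite.

## Training protocol

Every stage minimizes the soft-Dice loss `1 - (2*sum(p*t) + 1) /
(sum(p) + sum(t) + 1)` — the direct differentiable complement of the DSC
evaluated during training — with AdaDelta (rho = 0.95, eps = 1e-6), a
seeded 10% validation split (`max(1, round(0.1 n))` samples), per-epoch
validation DSC monitoring, checkpointing of the best model and a final
best-vs-final selection: the returned weights are whichever of the best
checkpoint and the final-epoch model has the higher validation DSC.

One modification matters at desk scale.  Classical AdaDelta starts with
both accumulators at zero, which caps the first updates near
`sqrt(eps) = 1e-3` and needs thousands of iterations to ramp up — fine
for the clinical regime (hundreds of volumes times 100 epochs),
hopeless for a few hundred optimizer steps.  Two knobs address this.
`train_config(init_step=)` seeds the squared-update accumulator
`E[dx^2]` with `init_step^2`, declaring a plausible initial RMS update
scale (`init_step = 0` restores the classical cold start).
`train_config(max_step=)` caps the accumulated RMS scale: AdaDelta's
step magnitude self-reinforces, and on small, steep problems the
uncapped acceleration eventually overshoots and can collapse the
sigmoid output; the cap bounds it without otherwise changing the
normalization (`max_step = Inf` is classical).  The desk-scale protocol
uses init_step 1e-2 (2e-2 for the block stage), cap 5e-2, rho 0.9 and
batch size 1 to maximize the number of optimizer steps per pass over the
data.

Augmentations follow the stages: span-detection samples are oversampled
on CTV-bearing slices by re-cropping with a random in-plane shift of up
to 10 px of the crop centre (countering the roughly one-third/two-thirds
slice class imbalance), and 3-D samples can be augmented with uniform
integer translations up to 5 voxels plus in-plane rotations up to 10
degrees; magnitudes are configurable and deliberately small relative to
the 128-px field of view.

## The synthetic phantom population

No public dataset exists for this task, so the package ships a generator
(`generate_phantom()`) that emulates the spatial statistics the cascade
relies on, on a desk-scale grid of 128 x 128 x 64 voxels at
1 x 1 x 1.6 mm:

* a bright (0.9) smooth ellipsoidal **bladder** in the anterior half,
  volume drawn log-uniformly in 15-35 cm^3;
* a darker (0.45) irregular **CTV** blob whose centre is drawn
  N(39, 10^2) mm posterior to the bladder centre with small lateral
  (SD 2 mm) and SI (SD 5 mm) jitter; its volume is drawn log-uniformly in
  3.93-60 cm^3 — the clinical lower end is kept and the upper end is
  scaled to what the 128-mm grid can hold at the drawn offsets
  (clinically the distribution is strongly right-skewed, which
  log-uniform sampling covers without fitting);
* background 0.2, all modulated by a smooth multiplicative bias field
  (amplitude 0.1) plus additive Gaussian noise (SD 0.03 of the dynamic
  range).

The CTV's irregular surface is an ellipsoid perturbed radially by a
smooth random *even* function of direction (two random symmetric
quadratic forms).  Point symmetry is deliberate: it keeps the blob's
centroid exactly at its drawn centre, so the realized bladder-to-CTV
offset distribution reproduces N(39, 10^2) without rasterization bias;
blob centres are snapped to the voxel lattice for the same reason.  Where
a draw would overlap the structures, the bladder wins (the CTV is carved),
and draws whose centre misses the grid abort with a generation error.

What the phantom does *not* model: anatomy other than the bladder (no
rectum, sigmoid or femoral heads), realistic MR texture, intra-patient
longitudinal correlation (samples are i.i.d.), or partial-volume effects.
Consequently, passing desk-scale tests demonstrates that the pipeline's
geometry, fusion and uncertainty machinery are correct and that the
networks can learn the anatomical prior — not that clinical-grade accuracy
transfers to real MRI.

## Numerical choices and degenerate inputs

* Grid convention: 0-based voxel indices; the world coordinate of a voxel
  is its centre; crops are half-open voxel ranges; axis 2 increases
  anterior to posterior so "posterior" is +y.
* Resampling outside the source extent fills with 0 (cropped MR is black).
* Histogram equalization is global over the volume with 256 bins
  (slice-wise available as a flag); a constant volume equalizes to a
  constant and min-max normalization maps it to zeros.
* Thresholding is strict (`p > t`), so a probability exactly at the
  threshold is background.
* ROIs shallower than one block are reflect-padded along SI; the padded
  slices are excluded from fused outputs.
* HD95 pools both directed nearest-surface distance sets and takes the
  linearly interpolated 95th percentile of the pooled set (symmetric by
  construction); surfaces are foreground voxels with a background
  face-neighbour, and distances are measured in world mm so anisotropic
  spacing is honoured.
* The paired t-test of two identical score vectors is reported as
  t = 0, p = 1; constant nonzero differences are an error.

## Desk-scale problem sizes

The shipped desk protocol (`cascade_specs_desk()`, `train_cascade()`)
trains base-4-filter networks (bladder depth 2, span depth 3 with
attention, block depth 3 with dropout 0.2 — the extra level widens the
in-plane receptive field enough to tell the anterior bladder margin from
the CTV inside the 128 mm window) on 40 phantoms: the bladder stage on
the 40 coarse crops for 6 epochs, the span stage on 20 slices per
phantom (12 shifted positives + 8 negatives) for 5 epochs, the block
stage on blocks extracted at stride 2 for 3 epochs, all at batch size 1;
evaluation uses 10 held-out phantoms.  These sizes were
chosen as the smallest population on which the full cascade reliably
recovers the phantom CTV (mean held-out DSC >= 0.8); the tests and the
acceptance script both regenerate them from seeds.

## Known limitations

* The uncertainty maps are epistemic-only in the MC-dropout sense and are
  not calibrated against multi-observer contour variability.
* The 39 mm posterior offset is a population constant; a patient whose
  bladder-cervix geometry deviates strongly would rely on the span
  network's shift tolerance.
* Majority fusion uses per-voxel cover counts near the SI edges; with
  stride 1 and depth 15 the interior cover is exactly 15.
* MetaImage support covers uncompressed scalar images only.
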