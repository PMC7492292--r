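---
title: "Vertebral bone-marrow-fat quantification from water-fat MRI: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vertebral bone-marrow-fat quantification from water-fat MRI: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Bone marrow fat (BMF) fraction in the lumbar vertebral bodies is an emerging
quantitative imaging biomarker for chronic low back pain and for skeletal and
metabolic disease. Chemical-shift water-fat MRI (Dixon imaging, reconstructed
with an iterative least-squares decomposition) yields four co-registered maps
per sagittal slice -- water signal, fat signal, fat fraction (FF, in percent)
and R2* -- from which BMF is read off as the mean FF inside a vertebral
region of interest. The bottleneck is segmentation: drawing the five lumbar
bodies by hand takes minutes per slice. `spinefat` implements the automated
alternative end to end: a multi-channel U-Net segments vertebral bodies, a
geometric post-processing stage turns the binary prediction into per-level
ROIs (L1-L5), and the BMF is quantified and evaluated with the full agreement
battery used in this literature.

# The segmentation model

The segmenter is the classic depth-4 U-Net: a contracting path of paired 3x3
convolutions (ReLU) with 2x2 max pooling, base width 64 filters doubling per
stage; an expansive path of 2x nearest-neighbour upsampling, a 3x3
convolution, concatenation with the matching encoder feature map and two more
convolutions; and a 1x1 sigmoid output head. All slices are processed as
independent 2D samples with the four maps stacked as input channels. Input
sizes must be divisible by `2^depth`; `model_scale` shrinks every filter
count proportionally so the same architecture runs on a single CPU in tests.

Training minimises the soft Jaccard distance

$$L = 1 - \frac{|X \cap Y| + s}{|X \cup Y| + s},$$

with per-pixel products/sums over each slice and the smooth term $s$
(default 100), under Adam (learning rate 1e-4, batch size 4), a
subject-level validation holdout (default fraction 7/31), and early stopping
on validation loss with best-weight restoration. Probability maps are
binarized at a strict threshold of 0.5 (`p > 0.5`; exact ties go to
background -- a documented tie-break, since sigmoid outputs hit 0.5 only on a
set of measure zero).

## Two numerical choices that matter

**Initialisation with unnormalised inputs.** The input channels are
deliberately left at their raw values (no normalisation, no cropping), so
their scales differ by orders of magnitude (signal in arbitrary units near 1,
FF 0-100, R2* of order 100 1/s). With a generic He initialisation the
initial logits are enormous, the sigmoid saturates, and -- because the
Jaccard loss pushes every background pixel downward indefinitely while
Adam turns even underflowed-but-consistent gradients into full-size steps --
training freezes in an all-empty prediction. `train_unet()` therefore
applies a one-off, data-driven rescaling of the initial weights
(`calibrate_unet()`, the layer-sequential unit-variance scheme): each
convolution's weights are divided once by the standard deviation of its
pre-activations on a small calibration batch. This alters only the starting
point of optimisation -- the data remain unnormalised, and a trained model's
predictions are an ordinary deterministic function of the raw inputs.

**The smooth term scales with the mask, not the image.** $s$ appears as a
phantom intersection in both numerator and denominator. With the clinical
geometry (256 x 256 slices, masks of roughly 4,000 pixels) $s = 100$ is a
mild regulariser. On small test phantoms (64 x 64, masks of ~150 pixels) the
same $s$ makes the background-suppression gradient dominate the
positive-pixel gradient about tenfold even at zero overlap, and every run
collapses into the empty-mask attractor. Desk-scale tests therefore set
`smooth = 1` (about 1% of the mask area, the same ratio the default has at
clinical scale). This is the single scale-dependent parameter in the
package; the default remains 100.

Logits are clipped so probabilities stay within about `[1e-7, 1 - 1e-7]`,
the usual backend-epsilon hygiene, keeping saturated pixels numerically
recoverable.

# ROI derivation and the half-area rule

The binary prediction is decomposed per slice into 8-connected components
(diagonal bridges occur at this in-plane resolution); components under
`min_area_px` (default 20) are discarded as binarization speckle. Components
are merged across slices into body "tracks" by nearest-centroid matching
(default radius 15 px, at most one skipped slice). The five largest
interior tracks become L1-L5 in superior-to-inferior order; tracks touching
the superior or inferior image border are partially visible adjacent bodies
(T12 above, sacrum below), labelled T12/S1 and excluded from quantification.
With fewer than five interior tracks the available ones are labelled
top-down and a warning is raised.

For each level, a slice's ROI enters quantification only if its area
strictly exceeds half of that body's **maximum cross-sectional area over
slices** ("more than half the area" of the body). The reference area is not
defined further in the source methodology; the maximum over slices is chosen
as the most stable per-body proxy. This is the single most consequential
interpretation in the module: a median or mid-sagittal reference would admit
slightly different edge slices. The rule is strict (`>`), so a single-slice
body is always retained and exact-half areas are excluded.

# BMF quantification

BMF per vertebral body is the **unweighted mean of per-slice ROI means** --
each retained slice contributes equally regardless of its pixel count. That
weighting is forced by the methodology this package implements ("mean value
of the fat fraction map in each ROI on a slice-by-slice basis, then averaging
for all slices"); the pixel-pooled mean is available behind
`weighted = TRUE` but is not the default and the two differ whenever slice
areas differ. Non-finite FF pixels (possible after division by near-zero
signal) are excluded from slice means and counted in the report.

# Evaluation statistics

All statistics are implemented from their definitions and verified against
independent brute-force oracles in the test suite:

* **Overlap**: DSC $= 2TP/(2TP+FP+FN)$ and IoU $= TP/(TP+FP+FN)$ from pixel
  confusion counts; by construction DSC equals the F1 score and
  $DSC = 2\,IoU/(1+IoU)$. Evaluation defaults to slices on which the
  reference mask contains vertebra pixels, the scope used when scoring
  against manual segmentations; whole-volume scope is a flag.
* **Cohen's kappa** with chance agreement from per-annotator empirical class
  priors; for two classes linear weighting coincides with the unweighted
  statistic (accepted for interface parity).
* **ROC AUC** as the normalized Mann-Whitney statistic (ties half-credited),
  with the DeLong structural-components variance and a 95% normal CI clipped
  to [0, 1]. **PR AUC** by step-wise integration over unique thresholds with
  no precision envelope.
* **Bland-Altman**: differences oriented manual − automatic (negative bias
  means the automatic method reads higher); limits of agreement are
  bias ± 1.96 sample SD, the bias CI uses SD/√n.
* **Repeatability**: ICC(2,1) -- two-way random effects, absolute agreement,
  single measure -- from the paired ANOVA decomposition, and the short-term
  precision error as the RMS coefficient of variation with the two-point SD
  $|d|/\sqrt2$. Identical test-retest input yields ICC 1 and precision error
  0 exactly, the degenerate regime a near-perfect workflow reports.

# The synthetic phantom: what it emulates and what it does not

Because clinical series cannot be redistributed, the package carries a
generator whose defaults are the stated world of the pipeline: 20 sagittal
slices of 256 x 256, vertebrae visible on a contiguous block of 5-7
mid-sagittal slices, per-body true FF drawn from Normal(33.1, 8)% truncated
to [5, 70]% (33.1% is the control-cohort mean the workflow is anchored to;
the SD is a generator choice), a dark cortical rim (default 2 px) excluded
from the ground truth, and optional partially visible T12/sacrum bodies at
the stack borders to exercise the level-assignment logic. Confounders --
a high-FF subcutaneous fat band, low-FF paraspinal muscle, intermediate-FF
discs -- prevent trivial thresholding; R2* is elevated inside trabecular
bone. Voxel synthesis follows the acquisition algebra: `fat = S·FF/100`,
`water = S·(1−FF/100)` with a smooth shading field `S`; independent Gaussian
noise (default SD 5% of mean tissue signal) is added to the water and fat
channels and FF is recomputed from the noisy channels, preserving the
`fat/(fat+water)` coupling, then clipped to [0, 100]. Within-body FF texture
is centred per body and slice, so noise-free quantification closes exactly
on the stated truth at any heterogeneity.

The phantom is *not* a physical MR simulation: noise is Gaussian rather than
Rician, there are no coil, chemical-shift or field-map artifacts, no
pathology, and tissue intensity scales are free parameters. A green
end-to-end test therefore establishes that the implementation recovers known
truth under its own stated world -- not that the printed clinical numbers
(DSC 0.849, bias −0.605%, kappa 0.798) are reproduced; those depend on
restricted data.

One deliberate geometric consequence: the subcutaneous fat band is separated
from the spine by muscle, so a dilated (over-segmented) ROI absorbs cortical
rim (FF 10%), disc (20%) and air first. Partial-volume overreach therefore
biases BMF *toward the neighbouring tissue's FF* -- downward for typical
marrow -- and the directionality test asserts exactly that, with the bias
monotone in the overreach.

# Degenerate inputs, tolerances, tie-breaks

* Empty union in overlap scores: defined as perfect (1) when both masks are
  empty in scope.
* Zero-denominator classification scores surface as `NA`, never as 0.
* Kappa with both raters constant: 1 if equal, 0 with a warning if not.
* Binarization ties (p exactly 0.5) go to background; the complement
  identity `binarize(p) == 1 − binarize(1−p)` holds off ties.
* Mask round-trips are bit-exact for binary masks in all three formats
  (NIfTI uint8, DICOM 8-bit, PNG); DICOM 16-bit quantitative maps use
  RescaleSlope/Intercept and are exact only for integer-valued data.
* Sub-seeds are derived from one master seed and stay below 2^31; all
  stochastic steps (phantom anatomy, noise, splits, shuffling, init) are
  reproducible from the spec/config seeds, and the inference path is fully
  deterministic.

# Known limitations

* Training at full clinical scale (256 x 256, scale 1.0) is possible but
  slow on one CPU; the architecture is exercised at reduced scale in tests.
* Level assignment assumes the canonical orientation (rows
  superior-to-inferior); readers must reorient header-flagged data.
* The centroid-tracking radius (default 15 px) is tuned to clinical
  geometry; small test phantoms use a proportionally smaller radius.
* The linear-mixed-model and repeated-measures ANOVA analyses surrounding
  the repeatability study are out of scope; ICC(2,1) and the RMS-CV
  precision error are the implemented repeatability surface.
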