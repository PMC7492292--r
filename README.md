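# spinefat

Automated lumbar vertebral body segmentation and bone-marrow-fat (BMF)
quantification from four-channel water-fat (Dixon/IDEAL) MRI, in R.

## The problem

Vertebral bone marrow fat fraction is a quantitative imaging biomarker for
chronic low back pain and skeletal/metabolic disease. Chemical-shift
water-fat MRI yields four co-registered sagittal maps per subject — water
signal, fat signal, fat fraction (FF, %) and R2\* — and BMF per vertebral
body is the mean FF over a body's region of interest. Manual segmentation of
L1–L5 takes minutes per slice; `spinefat` automates the whole workflow:

1. **Segmentation** — a 2D multi-channel U-Net (depth 4, 64 base filters,
   `model_scale` for CPU-sized variants; conv/pool/upsample kernels in
   RcppArmadillo) trained with the soft Jaccard distance loss
   `1 − (|X∩Y|+s)/(|X∪Y|+s)` under Adam (lr 1e-4, batch 4, subject-level
   validation holdout, early stopping). Probability maps are binarized at a
   strict 0.5 threshold.
2. **ROI derivation** — per-slice 8-connected components, merged into body
   tracks across slices; the five largest interior tracks become L1–L5
   top-down, border-touching partial bodies become T12/S1 and are excluded;
   a slice ROI is retained iff its area strictly exceeds half of that body's
   maximum cross-sectional area ("more than half the area" rule).
3. **Quantification** — BMF per body = unweighted mean of per-slice ROI
   means of the FF map (each slice counts equally).
4. **Evaluation** — DSC/IoU (`DSC = 2TP/(2TP+FP+FN)`, `IoU = TP/(TP+FP+FN)`),
   sensitivity/specificity/precision/F1/accuracy, Cohen's κ, ROC AUC with
   DeLong variance, PR AUC, Bland-Altman bias ± 1.96 SD limits of agreement,
   ICC(2,1) and RMS-CV short-term precision error.

Because clinical data are restricted, the package includes a synthetic
spine-phantom generator (`phantom_spec()`, `generate_phantom()`,
`generate_cohort()`, `simulate_rater()`) with voxel-accurate ground truth:
lordotic column of superelliptic vertebral bodies with dark cortical rims,
discs, paraspinal muscle and subcutaneous fat confounders, known per-body
fat fractions (default Normal(33.1, 8)% truncated to [5, 70]%), and noise
applied on the water/fat channels with FF recomputed from the noisy
channels. IO covers NIfTI-1, DICOM (Secondary-Capture-style series) and PNG
mask stacks.

## Worked example

Desk-scale end to end (64 × 64 phantoms, reduced model; a few minutes on one
CPU):

```r
library(spinefat)

spec <- phantom_spec(image_size = 64, n_slices = 10,
                     visible_slice_range = c(4, 6), cortical_rim_px = 1,
                     seed = 1)
cohort <- generate_cohort(12, spec, seed = 1)

cfg <- train_config(max_epochs = 8, early_stopping_patience = 2,
                    validation_fraction = 0.25, model_scale = 0.25,
                    smooth = 1, seed = 2)
model <- train_unet(cohort, cfg)
print(model)
#> <unet> depth 4, filters 16/32/64/128/256, input 64x64x4, 2,158,849 parameters (trained)
#>   8 epochs, best validation loss 0.0387 (epoch 6)

new <- generate_phantom(phantom_spec(image_size = 64, n_slices = 10,
                                     visible_slice_range = c(4, 6),
                                     cortical_rim_px = 1, seed = 99))
prob <- predict(model, new$series, type = "prob")
mask <- binarize(prob, 0.5)
rois <- filter_rois_by_area(assign_vertebra_labels(
  extract_components(mask, min_area_px = 8), match_radius_px = 6))
quantify_bmf(new$series, rois)
#> <bmf_report> subject phantom_99
#>   L1: 25.14% BMF over 4 slice(s), 109 pixels
#>   L2: 37.04% BMF over 4 slice(s), 92 pixels
#>   L3: 24.08% BMF over 2 slice(s), 68 pixels
#>   L4: 27.46% BMF over 4 slice(s), 92 pixels
#>   L5: 22.29% BMF over 4 slice(s), 109 pixels

round(new$truth$true_ff_pct, 2)   # the phantom's stated truth
#>    L1    L2    L3    L4    L5
#> 25.67 38.21 24.28 28.35 22.72

agreement_report(mask, new$truth$mask, prob = prob)
#> <agreement_report>
#>   DSC 0.979  IoU 0.959  kappa 0.978
#>   sensitivity 0.978  specificity 0.999  precision 0.980  accuracy 0.999
#>   ROC AUC 1.000 (95% CI 0.9999-1.0000)  PR AUC 0.997
```

The reported per-body BMF lands within ~1 percentage point of the phantom's
known fat fractions using fully automatic ROIs, and the predicted mask
overlaps the rim-excluded ground truth at DSC ≈ 0.98. `run_pipeline()`
bundles the same steps per subject and writes BMF/ROI CSVs, an evaluation
JSON, a Bland-Altman plot and a run manifest.

## Acceptance script

`scripts/acceptance.R` re-runs the package's main computation from scratch:
it generates a phantom cohort, trains the reduced U-Net, segments held-out
phantoms, quantifies BMF and evaluates agreement, then writes the acceptance
report JSON to `--out`:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Documentation

The methods vignette (`vignettes/spinefat-methods.Rmd`) describes the model
and its assumptions, the ROI rules and their interpretation, the phantom's
stated world and what a green test does and does not establish, numerical
choices (initialisation with unnormalised inputs, the scale of the loss
smooth term, tie-breaks, degenerate inputs) and known limitations.
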