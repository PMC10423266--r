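---
title: "Predicting 2-year time-to-progression in DLBCL from PET maximum intensity projections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting 2-year time-to-progression in DLBCL from PET maximum intensity projections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Baseline FDG-PET of diffuse large B-cell lymphoma shows the tumour burden
directly: lesions take up far more tracer than normal tissue, and summary
features of the segmented tumour — metabolic tumour volume (MTV, mL) and
the dissemination distance Dmax_bulk (cm, from the largest lesion to the
farthest other lesion) — predict whether a patient will progress within two
years (TTP1) or not (TTP0). Segmenting lesions for those features is
interactive and observer-dependent, which motivates learning the outcome
directly from images.

`petmip` predicts P(TTP1) from a *pair* of 2-d maximum intensity
projections (coronal and sagittal) rather than the 3-d volume. A MIP pixel
is the maximum SUV along the viewing ray, so lesions — the hottest
structures apart from brain and bladder — survive the projection, while the
data size drops by two orders of magnitude. The classifier is a dual-branch
convolutional network: each view passes through an identical (but not
weight-tied) stack of four valid 3×3 convolutions with 16, 32, 64 and 128
feature maps, each followed by ReLU and spatial dropout of 0.35, with max
pooling of size (3,3), (3,3) and (2,2) after the first three blocks and
global average pooling after the fourth; the two 128-vectors are
concatenated into a dense layer with two outputs and a softmax, so
P(TTP0) + P(TTP1) = 1. Training uses Adam with learning rate 5e-5 decayed
per step by `lr/(1 + 1e-6 t)` and categorical cross-entropy.

Three training schemes are provided. The *lesion* scheme trains on lesion
MIPs (tumour intensities only) for 200 epochs. The *MIP* and *BR-MIP*
schemes first train on binary lesion masks for 200 epochs — learning
tumour geometry without intensity — and then fine-tune the same weights for
300 epochs on full or brain-removed intensity MIPs, with fold membership
held fixed across the two stages and the optimiser state re-initialised.
Per subset, the fold with the highest validation AUC is kept.

## Image standardisation

Projections are resampled bilinearly to 4 mm pixels and centred on a
zero-filled 275 × 200 canvas (110 × 80 cm), a fixed physical frame that
makes images comparable across scanners and body sizes. Processing order is
project → resample → centre → normalize, so interpolation sees raw SUV.
Normalization divides by a fixed cap of SUV 40 and truncates above it;
without truncation the bladder (SUV ≈ 45 in the phantoms) rather than the
tumours would set the intensity scale. When the source grid is already at
4 mm the embedding snaps to whole pixels, so values pass through exactly;
masks are resampled nearest-neighbour to stay binary. Projections larger
than the canvas raise an error rather than silently cropping or rescaling —
a deliberate choice, since any automatic correction would change the
physical scale the network sees.

Brain removal operates in 3-d before projection so both views stay
consistent: the connected component of voxels above SUV 3 whose centroid
lies in the top 15% of the occupied cranio-caudal extent and whose volume
is 0.5–2.5 L is deleted. Scans without such a component (no head in the
field of view) pass through unchanged with a notice. A lesion that touches
the brain merges into its component and would be truncated with it; this is
detected and surfaced as a warning, mirroring the ~1% truncated-lesion
failure rate expected of automated brain removal.

## Lesion segmentation and features

Tumours are segmented as voxels with SUV ≥ 4.0 (inclusive, keeping boundary
voxels) grouped by 26-connectivity — the standard convention for MTV tools,
so diagonal contacts join. Components are labelled in decreasing voxel
count. MTV is voxel count times voxel volume; Dmax_bulk is the
centroid-to-centroid distance from the largest lesion (ties to the lower
label) to the farthest other lesion, zero with at most one lesion. The
manual deletion of physiological uptake used in clinical workflows is
replaced by an explicit `physiological_mask` argument; on phantoms the
ground-truth brain/bladder/liver masks are passed, which makes threshold
segmentation recover the planted lesions exactly. No minimum component size
is imposed by default.

## The class-balancing subset scheme

With 244 TTP0 and 52 TTP1 patients, training on the raw cohort would
reward always predicting TTP0. The sampling scheme shuffles the TTP0
patients into five near-equal strata (49/49/49/49/48), pairs each stratum
with *all* 52 TTP1 patients, and tops each subset up with three TTP0
patients borrowed from three distinct other strata — yielding subsets A–D
of 104 patients at exactly 50% prevalence and subset E of 103 (51 TTP0).
A patient may be borrowed by several subsets but never twice into one.
Within each subset, five cross-validation folds are stratified by label so
both train (~80%) and validation (~20%) retain the 50% prevalence; the
extra patients from uneven division are rotated across folds so fold sizes
differ by at most one (a 104-patient subset validates on 21/21/21/21/20).
For cohorts of other sizes the same construction generalises: strata of
near-equal size, borrow count `n1 - max(stratum size)` clamped at zero.

## The synthetic phantom generator

The phantoms emulate the statistical structure the pipeline relies on, not
PET physics. A body ellipsoid at SUV 1 carries a brain sphere (SUV 8,
radius 50 mm ≈ 0.52 L, placed in the cranial 15% so brain removal engages),
a bladder sphere (SUV 45, above the normalization cap so truncation
engages), a liver ellipsoid (SUV 2, below the segmentation threshold), and
0–15 spherical lesions with radii 6–15 mm and SUVs uniform in 5–20 — all
above the 4.0 threshold, so ground truth equals threshold segmentation.
Spheres were chosen because their analytic volume provides an exact oracle
for MTV; lesions are kept mutually separated by two voxel widths so
rasterized lesions never merge under 26-connectivity. Outcome labels are
Bernoulli with `logit P(TTP1) = β0 + β_mtv log MTV + β_dmax Dmax + ε`. The
default `outcome_model(-10.5, 2, 0.05, 0.5)` gives ≈20% prevalence,
matching the imbalance of a first-line DLBCL trial cohort; the
strong-signal condition used in the cohort-level tests
(`outcome_model(-14.3, 4, 0, 0)`) centres prevalence near 50% for the
generator's MTV distribution (mean log MTV ≈ 3.59) and plants a signal
whose Bayes AUC from log MTV alone is ≈ 0.92. Each patient consumes an
independent RNG substream derived from the cohort seed and patient index,
so cohorts are reproducible patient-by-patient, and the geometry-only fast
path (`rasterize = FALSE`) draws identical lesions and labels.

What the phantoms deliberately omit: attenuation and scanner point-spread,
Poisson noise, respiratory motion, irregular lesion shapes, and
physiological uptake adjacent to tumours. Tests passing on phantoms
therefore demonstrate that the machinery is correct and that the network
can extract a planted burden signal — not that clinical performance would
match.

## Training at desk scale

The full schedules (200 pre-training and 300 fine-tuning epochs at learning
rate 5e-5) are the package defaults (`model_config("full")`). The test
suite and examples use the `"desk"` profile: 20/30 epochs with learning
rate 1e-3. A few hundred optimiser steps at 5e-5 would barely move
He-initialised weights; scaling the step size up roughly in proportion to
the shortened schedule preserves the character of the optimisation while
keeping a training run around a minute on one core. Batch size (16) and
the categorical cross-entropy loss are surfaced in `model_config()` as
explicit choices. Cohort-level checks use 200-patient phantom cohorts with
an 80/20 stratified held-out split; at that size the desk profile reaches
held-out AUC ≈ 0.89 on the strong-signal condition and stays at chance on
a null cohort.

The network is implemented in single-precision C++ (im2col + GEMM) with
all randomness — weight initialisation, spatial dropout, batch shuffling —
drawn from R's RNG, so `set.seed()` makes training bit-reproducible. BLAS
is pinned to one thread for the duration of a call: the GEMMs involved are
small and skinny, and thread oversubscription is slower than a single
core. Gradients are verified against central finite differences in the
test suite. Numerical details: softmax is computed with max subtraction;
the loss adds 1e-12 inside the log; pooling windows that do not fit are
dropped (275 × 200 → 11 × 7 after the fourth block); spatial dropout uses
inverted scaling so inference needs no correction.

## Evaluation and plausibility

AUC uses the rank (Mann–Whitney) formulation with midrank ties. The
decision cut-off is 0.5 with `>=` counting as positive; with no positives
(or negatives) the corresponding rate is reported as `NA` rather than 0.
Paired AUCs are compared with the DeLong test computed from per-patient
structural components; a zero-variance difference (e.g. comparing a score
vector with itself) returns p = 1 with a degeneracy flag instead of 0/0.
The IPI comparator uses the raw 0–5 score for ROC and calls IPI ≥ 4
high-risk — a simplification of external IPI-based models, documented as
such. Calibration fits `label ~ p` by maximum-likelihood logistic
regression on the selected model's validation predictions (not training
predictions, to avoid optimism); under perfect separation a weakly
ridge-penalised fit (λ = 0.01) is substituted with a notice. Because the
calibration is strictly monotone whenever its slope is positive, it cannot
change the AUC — asserted in the tests.

The ablation analysis replaces lesion pixels by the mean of in-body,
non-lesion pixels ("background" is defined as exactly-zero canvas pixels)
and re-predicts. On strong-signal phantom cohorts the mean calibrated
P(TTP1) collapses (0.55 → 0.08 in the packaged experiment, sign test
p < 1e-10) while lesion-free patients are bit-identical before and after —
together evidence that the network uses tumour pixels, not canvas
artefacts. The mask-pre-training transfer is sanity-checked on phantoms
sharing tumour geometry: averaged over seeds, mask-trained weights start
with lower cross-entropy and much higher AUC on intensity MIPs than fresh
weights. (At long pre-training schedules the cross-entropy half of that
comparison can invert — a confidently mis-calibrated model under domain
shift can have higher CE than an indifferent fresh one — so the check uses
a modest pre-training depth where both the CE and the rank criterion are
stable.)

## Design choices where the design was open

* **Axis convention** fixed package-wide as `(z, y, x)` with the head at
  index 1; NIfTI I/O permutes to and from the conventional `(x, y, z)`.
* **QC boundaries**: liver SUVmean accepted on the closed interval
  [1.3, 3.0]; glucose must be strictly below 11 mmol/L. Only these two
  criteria are implemented; the fuller clinical QC protocol is out of
  scope. SUV conversion from raw DICOM activity is likewise out of scope —
  inputs are assumed to be SUV already.
* **Canvas alignment** is centred on both axes; symmetric padding keeps
  the frame flip-friendly.
* **"Decay rate"** is implemented as per-step learning-rate decay (the
  Adam-compatible reading); weight decay is not conflated with it.
* **Stage-2 fine-tuning** re-initialises the optimiser state but not the
  dense head; no data augmentation is used anywhere.
* **Borrowed patients** may repeat across subsets (sampling with
  replacement across, without replacement within), matching the scheme's
  "three subjects from the other subsets".
* **Dmax_bulk** is centroid-to-centroid; surface distances, minimum
  component sizes and alternative thresholds are configurable but off by
  default.

## Known limitations

Phantom realism is intentionally minimal (see above). The desk profile's
AUC figures characterise the synthetic benchmark only. The brain-removal
volume window assumes adult head sizes; pediatric or partially-imaged
heads would need retuned bounds. Thresholds (SUV 4.0, cap 40, cut-off 0.5)
transfer to other cohorts only approximately — the cut-off in particular
may need adjustment on external data, and no automatic transfer rule is
provided.
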