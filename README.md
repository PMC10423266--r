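# petmip

Outcome prediction in diffuse large B-cell lymphoma (DLBCL) from baseline
FDG-PET maximum intensity projections (MIPs).

## What this package does

Roughly one third of DLBCL patients progress or relapse within two years of
first-line therapy. Quantitative baseline-PET features — metabolic tumour
volume (MTV, the total volume of tumour above an SUV threshold) and the
dissemination feature Dmax_bulk (the distance from the largest lesion to the
farthest other lesion) — are established prognostic factors, but extracting
them requires interactive tumour segmentation. `petmip` implements an
alternative: a convolutional network that predicts the probability of
progression within two years, P(TTP1), directly from two 2-d maximum
intensity projections of the SUV volume, together with everything needed to
train and interrogate such a model:

* **MIP engine** — coronal and sagittal projections placed on a fixed
  275 × 200 pixel canvas at 4 × 4 mm, normalized by a fixed cap
  (SUV 40, values above truncated); lesion MIPs, binary lesion masks,
  brain-removed MIPs, and tumour-ablated MIPs.
* **Lesion features** — SUV ≥ 4.0 threshold segmentation into 26-connected
  components, MTV (mL) and Dmax_bulk (cm).
* **Cohort sampling** — the class-balancing subset scheme: the majority
  TTP0 class is split into five strata paired with *all* TTP1 patients plus
  three TTP0 borrowed from other strata, giving five ~50%-prevalence
  subsets (104/104/104/104/103 patients for a 244 TTP0 / 52 TTP1 cohort),
  each with label-stratified five-fold cross-validation.
* **Dual-branch CNN** — one branch per view (four 3 × 3 valid convolutions
  with 16/32/64/128 feature maps, ReLU, spatial dropout 0.35, max pooling
  (3,3)/(3,3)/(2,2), global average pooling), concatenated into a two-way
  softmax head; Adam with learning rate 5e-5 and per-step decay 1e-6.
  Three training schemes: lesion MIPs only; lesion-mask pre-training
  followed by fine-tuning on full MIPs ("MIP CNN") or brain-removed MIPs
  ("BR-MIP CNN"). The implementation is self-contained C++ (im2col + GEMM).
* **Evaluation** — rank-based AUC, sensitivity/specificity at the 0.5
  cut-off, the DeLong test for paired AUCs, an IPI baseline (high risk at
  IPI ≥ 4), logistic probability calibration, prediction-vs-feature
  association, and a tumour-ablation plausibility analysis in which lesion
  pixels are replaced by the mean non-background intensity.
* **Synthetic phantoms** — whole-body SUV phantoms (body, brain, bladder,
  liver, 0–15 spherical lesions) with outcome labels drawn from a logistic
  model on log MTV and Dmax_bulk, so the entire pipeline runs and is tested
  without any clinical data.

## Worked example

Generate a 200-patient synthetic cohort whose labels depend strongly on
tumour burden, train the lesion-MIP scheme at the reduced "desk" profile,
and evaluate on a held-out split:

```r
library(petmip)

imgs <- cohort_images(200, outcome_model(beta0 = -14.3, beta_mtv = 4,
                                         beta_dmax = 0, noise_sd = 0),
                      variants = "lesion", seed = 101)
labels <- setNames(imgs$table$label, imgs$table$patient_id)
ids <- imgs$table$patient_id
val <- withr::with_seed(5, unlist(lapply(split(ids, labels[ids]),
                                         function(g) sample(g, round(0.2 * length(g))))))
model <- train_cnn(imgs$mips$lesion, labels,
                   train_ids = setdiff(ids, val), val_ids = val,
                   config = model_config("desk", seed = 7), epochs = 20)
model$provenance$cv_auc
#> [1] 0.8939394
```

The held-out AUC of 0.89 says the network ranks a random progressing
patient above a random non-progressing one 89% of the time — close to the
0.92 attainable from the true log-MTV signal planted by the generator.
Ablating the tumours from the images of a trained MIP-scheme model collapses
its calibrated probabilities (from a mean of 0.55 to 0.08 on the same
held-out patients in the packaged experiment), confirming the predictions
are driven by tumour pixels rather than background.

The full pipeline (phantoms → MIPs → subsets → training → evaluation) is
available as one call:

```r
run <- run_pipeline(run_config(n_patients = 100, scheme = "br_mip",
                               subsets = "A", profile = "desk", seed = 7))
tidy(run)
```

A thin command-line wrapper lives at `inst/cli/petmip`.

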