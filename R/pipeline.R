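#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end run: phantom cohort size and
#' outcome model, training scheme, subsets, epoch profile and the decision
#' thresholds (SUV segmentation threshold 4.0, SUV normalization cap 40,
#' probability cut-off 0.5). All defaults are overridable; the full config
#' is embedded in every output's provenance.
#'
#' @param n_patients cohort size.
#' @param seed master seed for the run.
#' @param scheme `"lesion"`, `"mip"` or `"br_mip"`.
#' @param subsets subset letters to train, or `"all"`.
#' @param profile epoch profile, `"desk"` or `"full"`.
#' @param outcome an [outcome_model] for the synthetic labels.
#' @param n_lesions_range,grid_shape phantom geometry.
#' @param suv_threshold,suv_cap,cutoff decision thresholds.
#' @param epochs_stage1,epochs_stage2 optional epoch overrides (defaults come
#'   from the profile).
#' @param out_dir output directory, or `NULL` to keep results in memory.
#' @return A `run_config`.
#' @export
run_config <- function(n_patients = 100, seed = 1L,
                       scheme = c("lesion", "mip", "br_mip"),
                       subsets = "A", profile = c("desk", "full"),
                       outcome = outcome_model(),
                       n_lesions_range = c(1, 15),
                       grid_shape = c(160, 100, 70),
                       suv_threshold = SUV_THRESHOLD, suv_cap = SUV_CAP,
                       cutoff = 0.5, epochs_stage1 = NULL,
                       epochs_stage2 = NULL, out_dir = NULL) {
  scheme <- match.arg(scheme)
  profile <- match.arg(profile)
  if (identical(subsets, "all")) subsets <- LETTERS[1:5]
  if (!all(subsets %in% LETTERS[1:5]))
    abort("`subsets` must be letters A-E or 'all'")
  structure(list(
    n_patients = as.integer(n_patients), seed = as.integer(seed),
    scheme = scheme, subsets = subsets, profile = profile, outcome = outcome,
    n_lesions_range = n_lesions_range, grid_shape = grid_shape,
    suv_threshold = suv_threshold, suv_cap = suv_cap, cutoff = cutoff,
    epochs_stage1 = epochs_stage1, epochs_stage2 = epochs_stage2,
    out_dir = out_dir
  ), class = "run_config")
}

.config_hash <- function(config) {
  rlang::hash(config[setdiff(names(config), "out_dir")])
}

#' Stream a synthetic cohort into MIP images and features
#'
#' Generates phantoms one at a time, segments their lesions (excluding the
#' known physiological organ masks), builds the requested MIP variants and
#' per-patient PET features, and discards each 3-d volume before moving on.
#' This keeps memory proportional to the 2-d images rather than the 3-d
#' grids, so cohorts of hundreds of patients fit comfortably. Labels,
#' features and lesion geometry are identical to [generate_cohort()] with
#' the same arguments, since both share the per-patient RNG substreams.
#'
#' @inheritParams generate_cohort
#' @param variants MIP variants to build: any of `"lesion"`,
#'   `"lesion_mask"`, `"mip"`, `"brain_removed"`.
#' @param suv_threshold,suv_cap segmentation threshold and normalization cap.
#' @return A `cohort_images`: list with `mips` (per variant, a named list of
#'   per-patient `list(coronal =, sagittal =)` pairs), `table` (as in
#'   [generate_cohort()]) and `features` (as in [cohort_features()]).
#' @export
cohort_images <- function(n_patients, outcome = outcome_model(),
                          variants = c("lesion", "lesion_mask"),
                          n_lesions_range = c(1, 15),
                          lesion_radius_range_mm = c(6, 15),
                          grid_shape = c(160, 100, 70), voxel_size_mm = 4,
                          seed = 1L, suv_threshold = SUV_THRESHOLD,
                          suv_cap = SUV_CAP) {
  stopifnot(n_patients > 0,
            all(variants %in% c("lesion", "lesion_mask", "mip", "brain_removed")))
  mips <- stats::setNames(vector("list", length(variants)), variants)
  rows <- vector("list", n_patients)
  feats <- vector("list", n_patients)
  for (i in seq_len(n_patients)) {
    pat <- .cohort_patient(i, seed, outcome, n_lesions_range,
                           lesion_radius_range_mm, grid_shape, voxel_size_mm,
                           rasterize = TRUE)
    pid <- pat$row$patient_id
    rows[[i]] <- pat$row
    p <- pat$phantom
    seg <- segment_lesions(p$volume, suv_threshold,
                           physiological_mask = p$truth$organ_mask)
    feats[[i]] <- tibble::tibble(patient_id = pid, mtv_ml = seg$mtv_ml,
                                 dmax_bulk_cm = seg$dmax_bulk_cm,
                                 n_lesions = nrow(seg$lesions))
    for (v in variants) {
      pair <- switch(v,
        lesion = list(coronal = lesion_mip(p$volume, seg, "coronal", suv_cap),
                      sagittal = lesion_mip(p$volume, seg, "sagittal", suv_cap)),
        lesion_mask = list(coronal = lesion_mask_mip(p$volume, seg, "coronal"),
                           sagittal = lesion_mask_mip(p$volume, seg, "sagittal")),
        mip = list(coronal = make_mip(p$volume, "coronal", "mip", suv_cap),
                   sagittal = make_mip(p$volume, "sagittal", "mip", suv_cap)),
        brain_removed = {
          vol <- suppressMessages(remove_brain(p$volume,
                                               lesion_map = seg$label_map))
          list(coronal = make_mip(vol, "coronal", "brain_removed", suv_cap),
               sagittal = make_mip(vol, "sagittal", "brain_removed", suv_cap))
        })
      mips[[v]][[pid]] <- pair
    }
  }
  structure(list(mips = mips, table = dplyr::bind_rows(rows),
                 features = dplyr::bind_rows(feats), seed = as.integer(seed)),
            class = "cohort_images")
}

#' @export
print.cohort_images <- function(x, ...) {
  cat(sprintf("<cohort_images> %d patients, variants: %s\n", nrow(x$table),
              paste(names(x$mips), collapse = ", ")))
  invisible(x)
}

#' Run the full pipeline
#'
#' Executes phantom generation, feature extraction, MIP production, the
#' class-balancing subset scheme, CNN training under the configured scheme,
#' fold selection, and the evaluation/plausibility suite (cut-off metrics,
#' calibration, feature association, and tumour ablation for intensity
#' schemes). When `out_dir` is set, the report, predictions and partition
#' are written there together with the config hash, and re-running with an
#' identical config returns the cached report.
#'
#' @param config a [run_config].
#' @return A `petmip_run`: list with `report` (per-subset metrics),
#'   `predictions`, `features`, `partition`, `config`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  hash <- .config_hash(config)
  if (!is.null(config$out_dir)) {
    rp <- file.path(config$out_dir, "report.json")
    if (file.exists(rp)) {
      prev <- jsonlite::read_json(rp, simplifyVector = TRUE)
      if (identical(prev$config_hash, hash)) {
        inform("identical config found in out_dir; returning cached report")
        return(structure(list(report = tibble::as_tibble(prev$report),
                              config = config, config_hash = hash,
                              cached = TRUE), class = "petmip_run"))
      }
    }
  }

  variants <- switch(config$scheme,
    lesion = "lesion",
    mip = c("lesion_mask", "mip"),
    br_mip = c("lesion_mask", "brain_removed")
  )
  imgs <- cohort_images(
    config$n_patients, outcome = config$outcome, variants = variants,
    n_lesions_range = config$n_lesions_range,
    grid_shape = config$grid_shape, seed = config$seed,
    suv_threshold = config$suv_threshold, suv_cap = config$suv_cap
  )
  features <- imgs$features
  mips <- list(
    lesion = imgs$mips$lesion,
    mask = imgs$mips$lesion_mask,
    intensity = imgs$mips$mip %||% imgs$mips$brain_removed
  )
  labels <- stats::setNames(imgs$table$label, imgs$table$patient_id)

  partition <- build_subsets(imgs$table, seed = config$seed)
  cfg <- model_config(config$profile, seed = config$seed,
                      epochs_stage1 = config$epochs_stage1,
                      epochs_stage2 = config$epochs_stage2)

  reports <- list()
  predictions <- list()
  for (s in config$subsets) {
    cv <- switch(config$scheme,
      lesion = train_scheme_lesion(partition, s, mips$lesion, labels, cfg),
      mip = train_scheme_transfer(partition, s, mips$mask, mips$intensity,
                                  labels, cfg),
      br_mip = train_scheme_transfer(partition, s, mips$mask, mips$intensity,
                                     labels, cfg)
    )
    best <- select_model(cv)
    ev <- classify_at_cutoff(best$val_predictions, cutoff = config$cutoff)
    cal <- fit_calibration(best$val_predictions$p_ttp1,
                           best$val_predictions$label)
    val_ids <- best$val_predictions$patient_id
    assoc <- feature_association(
      dplyr::select(best$val_predictions, "patient_id", "p_ttp1"), features)
    abl <- if (config$scheme %in% c("mip", "br_mip")) {
      ablation_analysis(best, mips$intensity, mips$mask, cal, ids = val_ids)
    } else NULL
    reports[[s]] <- tibble::tibble(
      subset = s, scheme = config$scheme, fold = best$provenance$fold,
      cv_auc = best$provenance$cv_auc, auc = ev$auc,
      sensitivity = ev$sensitivity, specificity = ev$specificity,
      cal_intercept = cal$intercept, cal_slope = cal$slope,
      r_mtv = assoc$correlations$r[assoc$correlations$feature == "mtv_ml"],
      r_dmax = assoc$correlations$r[assoc$correlations$feature == "dmax_bulk_cm"],
      ablation_mean_change = if (is.null(abl)) NA_real_ else abl$summary$mean_change
    )
    predictions[[s]] <- dplyr::mutate(best$val_predictions, subset = s)
  }
  report <- dplyr::bind_rows(reports)
  predictions <- dplyr::bind_rows(predictions)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(
      list(config_hash = hash, seed = config$seed, report = report),
      file.path(config$out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
    write.csv(predictions, file.path(config$out_dir, "predictions.csv"),
              row.names = FALSE)
    write_partition(partition, file.path(config$out_dir, "partition.json"))
  }
  structure(list(report = report, predictions = predictions,
                 features = features, partition = partition, config = config,
                 config_hash = hash, cached = FALSE),
            class = "petmip_run")
}

#' @export
print.petmip_run <- function(x, ...) {
  cat("<petmip_run>", if (isTRUE(x$cached)) "(cached)" else "", "\n")
  print(x$report)
  invisible(x)
}

#' @rdname run_pipeline
#' @param x a `petmip_run`.
#' @param ... unused.
#' @export
#' @method tidy petmip_run
tidy.petmip_run <- function(x, ...) x$report
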