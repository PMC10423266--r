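#' Configuration for the dual-branch MIP classifier
#'
#' Architecture and optimisation settings of the two-branch convolutional
#' network: four 3x3 valid convolutions per branch with 16/32/64/128 feature
#' maps, ReLU and spatial dropout 0.35 after each convolution, max pooling
#' (3,3), (3,3), (2,2) after the first three blocks, global average pooling
#' after the fourth, branch concatenation (256 features) and a dense softmax
#' head with two outputs. Optimised with Adam (learning rate `LRt` 0.00005,
#' per-step decay `DR` 0.000001, so `lr_t = LRt / (1 + DR * t)`), categorical
#' cross-entropy, batch size 16, 200 epochs for stage-1 training and 300 for
#' stage-2 fine-tuning.
#'
#' The `"desk"` profile is a reduced preset for desk-scale experiments and
#' the test suite: 20/30 epochs with learning rate 0.001 (a few hundred
#' optimisation steps need proportionally larger steps than the full
#' 200/300-epoch schedule).
#'
#' @param profile `"full"` (complete schedule) or `"desk"` (reduced preset).
#' @param conv_feature_maps,pool_sizes architecture (fixed by design; exposed
#'   for inspection).
#' @param dropout_rate spatial dropout probability.
#' @param learning_rate,decay Adam learning rate and per-step decay.
#' @param batch_size minibatch size.
#' @param epochs_stage1,epochs_stage2 training epochs for the two stages.
#' @param seed RNG seed for weight initialisation, dropout and shuffling.
#' @return An object of class `model_config`.
#' @export
model_config <- function(profile = c("full", "desk"),
                         conv_feature_maps = c(16L, 32L, 64L, 128L),
                         pool_sizes = list(c(3, 3), c(3, 3), c(2, 2)),
                         dropout_rate = 0.35,
                         learning_rate = NULL, decay = 1e-6,
                         batch_size = 16L,
                         epochs_stage1 = NULL, epochs_stage2 = NULL,
                         seed = 1L) {
  profile <- match.arg(profile)
  defaults <- if (profile == "desk") list(lr = 1e-3, e1 = 20L, e2 = 30L)
              else list(lr = 5e-5, e1 = 200L, e2 = 300L)
  cfg <- list(
    profile = profile,
    conv_feature_maps = as.integer(conv_feature_maps),
    conv_kernel = c(3L, 3L),
    pool_sizes = pool_sizes,
    dropout_rate = dropout_rate,
    learning_rate = learning_rate %||% defaults$lr,
    decay = decay,
    batch_size = as.integer(batch_size),
    epochs_stage1 = as.integer(epochs_stage1 %||% defaults$e1),
    epochs_stage2 = as.integer(epochs_stage2 %||% defaults$e2),
    input_shape = CANVAS_SHAPE,
    seed = as.integer(seed)
  )
  stopifnot(identical(cfg$conv_feature_maps, c(16L, 32L, 64L, 128L)),
            cfg$dropout_rate >= 0, cfg$dropout_rate < 1,
            cfg$learning_rate > 0, cfg$decay >= 0, cfg$batch_size >= 1,
            cfg$epochs_stage1 >= 1, cfg$epochs_stage2 >= 1)
  structure(cfg, class = "model_config")
}

# He-normal initial weights drawn from R's RNG; conv weights stored as
# (9 * C_in) x C_out matrices matching the im2col column order.
.init_weights <- function(config) {
  cin <- c(1L, config$conv_feature_maps[-4])
  cout <- config$conv_feature_maps
  w <- list()
  for (l in 1:4) {
    fan_in <- 9L * cin[l]
    w[[paste0("W", l)]] <- matrix(rnorm(fan_in * cout[l], 0, sqrt(2 / fan_in)),
                                  fan_in, cout[l])
    w[[paste0("b", l)]] <- numeric(cout[l])
  }
  nf <- 2L * cout[4]
  w$Wd <- matrix(rnorm(nf * 2, 0, sqrt(2 / nf)), nf, 2)
  w$bd <- numeric(2)
  w
}

#' Build an untrained dual-branch model
#'
#' @param config a [model_config].
#' @return A `ttp_cnn` object holding freshly initialised weights (seeded
#'   from `config$seed`), the configuration and empty provenance.
#' @export
build_model <- function(config = model_config()) {
  stopifnot(inherits(config, "model_config"))
  weights <- withr::with_seed(config$seed, .init_weights(config))
  structure(list(weights = weights, config = config, trained = FALSE,
                 provenance = list()), class = "ttp_cnn")
}

#' Number of trainable parameters
#'
#' @param model a `ttp_cnn`.
#' @param per_branch if `TRUE`, count one convolutional branch only.
#' @return Integer parameter count.
#' @export
n_parameters <- function(model, per_branch = FALSE) {
  w <- model$weights
  branch <- sum(vapply(1:4, function(l)
    length(w[[paste0("W", l)]]) + length(w[[paste0("b", l)]]), 0))
  if (per_branch) return(as.integer(branch))
  as.integer(2 * branch + length(w$Wd) + length(w$bd))
}

#' @export
print.ttp_cnn <- function(x, ...) {
  cat(sprintf("<ttp_cnn> %s, %d parameters (%d per branch)%s\n",
              if (x$trained) "trained" else "untrained", n_parameters(x),
              n_parameters(x, per_branch = TRUE),
              if (length(x$provenance))
                sprintf("; scheme %s, subset %s, fold %s, CV-AUC %.3f",
                        x$provenance$scheme %||% "?",
                        x$provenance$subset %||% "?",
                        x$provenance$fold %||% "?",
                        x$provenance$cv_auc %||% NA) else ""))
  invisible(x)
}

# Stack a list of per-patient {coronal, sagittal} normalized mip_images into
# (275, 200, N) arrays ordered by `ids`.
.mip_stack <- function(mips, ids) {
  missing <- setdiff(ids, names(mips))
  if (length(missing))
    abort(paste("missing MIPs for patients:", paste(missing, collapse = ", ")))
  n <- length(ids)
  xc <- array(0, c(CANVAS_SHAPE, n))
  xs <- array(0, c(CANVAS_SHAPE, n))
  for (i in seq_len(n)) {
    pair <- mips[[ids[i]]]
    for (v in c("coronal", "sagittal")) {
      img <- pair[[v]]
      if (!inherits(img, "mip_image")) abort("each patient needs coronal and sagittal mip_images")
      if (!img$normalized) abort(sprintf("unnormalized %s MIP for patient %s", v, ids[i]))
    }
    xc[, , i] <- pair$coronal$pixels
    xs[, , i] <- pair$sagittal$pixels
  }
  list(xc = xc, xs = xs)
}

.label_vector <- function(labels, ids) {
  if (is.data.frame(labels))
    labels <- stats::setNames(labels$label, labels$patient_id)
  y <- labels[ids]
  if (anyNA(y)) abort("labels missing for some patients")
  as.integer(y == "TTP1")
}

#' Train the model on one train/validation split
#'
#' Low-level training driver used by the scheme functions: trains on
#' `train_ids` and reports validation predictions and AUC on `val_ids`.
#' Deterministic given `config$seed` (weight init, dropout and shuffling all
#' consume R's RNG).
#'
#' @param mips named list (by patient id) of
#'   `list(coronal =, sagittal =)` normalized [mip_image]s.
#' @param labels named character vector or tibble mapping patient ids to
#'   `"TTP0"`/`"TTP1"`.
#' @param train_ids,val_ids patient id vectors.
#' @param config a [model_config].
#' @param epochs number of epochs (defaults to `config$epochs_stage1`).
#' @param init_weights optional starting weights (for transfer training);
#'   otherwise fresh He-initialised weights. The optimiser state is always
#'   freshly initialised.
#' @return A trained `ttp_cnn` with `history` (per-epoch training loss),
#'   `val_predictions` (tibble) and provenance carrying the validation AUC.
#' @export
train_cnn <- function(mips, labels, train_ids, val_ids,
                      config = model_config("desk"), epochs = NULL,
                      init_weights = NULL) {
  stopifnot(inherits(config, "model_config"))
  epochs <- as.integer(epochs %||% config$epochs_stage1)
  ids <- c(train_ids, val_ids)
  stk <- .mip_stack(mips, ids)
  y <- .label_vector(labels, ids)
  n_train <- length(train_ids)

  fit <- withr::with_seed(config$seed, {
    w0 <- init_weights %||% .init_weights(config)
    cnn_train_cpp(w0, stk$xc, stk$xs, y, seq_len(n_train), epochs,
                  config$learning_rate, config$decay, config$batch_size,
                  config$dropout_rate)
  })
  model <- structure(list(weights = fit$weights, config = config,
                          trained = TRUE, provenance = list()),
                     class = "ttp_cnn")
  model$history <- tibble::tibble(epoch = seq_len(epochs),
                                  train_loss = as.numeric(fit$epoch_loss))
  if (length(val_ids)) {
    vi <- n_train + seq_along(val_ids)
    probs <- cnn_predict_cpp(model$weights, stk$xc[, , vi, drop = FALSE],
                             stk$xs[, , vi, drop = FALSE])
    model$val_predictions <- tibble::tibble(
      patient_id = val_ids, p_ttp0 = probs[, 1], p_ttp1 = probs[, 2],
      label = ifelse(y[vi] == 1, "TTP1", "TTP0")
    )
    model$provenance$cv_auc <- roc_auc(probs[, 2], y[vi])
  }
  model
}

.scheme_folds <- function(partition, subset_id) {
  if (!subset_id %in% names(partition$subsets))
    abort(sprintf("unknown subset '%s'", subset_id))
  partition$folds[[subset_id]]
}

#' Training scheme 1: lesion MIPs only
#'
#' Trains one model per cross-validation fold of the given subset on
#' lesion-variant MIPs (tumour intensities only) for `epochs_stage1` epochs.
#'
#' @param partition a `cohort_partition` from [build_subsets()].
#' @param subset_id subset letter.
#' @param mips named list of per-patient lesion MIP pairs.
#' @param labels patient id to label mapping.
#' @param config a [model_config].
#' @return A `cnn_cv` object: list with `models` (5 trained `ttp_cnn`s),
#'   `cv` (tibble of fold AUCs) and `scheme = "lesion"`.
#' @export
train_scheme_lesion <- function(partition, subset_id, mips, labels,
                                config = model_config("desk")) {
  folds <- .scheme_folds(partition, subset_id)
  models <- vector("list", length(folds))
  for (f in seq_along(folds)) {
    cfg <- config
    cfg$seed <- config$seed + f
    m <- train_cnn(mips, labels, folds[[f]]$train, folds[[f]]$validation,
                   cfg, epochs = config$epochs_stage1)
    m$provenance <- c(m$provenance, list(scheme = "lesion",
                                         subset = subset_id, fold = f))
    models[[f]] <- m
  }
  .cnn_cv(models, "lesion", subset_id)
}

#' Training schemes 2 and 3: lesion-mask pre-training plus fine-tuning
#'
#' Two-step transfer training: the model is first trained on binary lesion
#' masks for `epochs_stage1` epochs, then the pre-trained weights are
#' re-trained for `epochs_stage2` epochs on intensity MIPs (regular MIPs for
#' the "MIP CNN", brain-removed MIPs for the "BR-MIP CNN"). Both stages use
#' the identical fold membership; the optimiser state is re-initialised
#' between stages, the weights are not.
#'
#' @param partition,subset_id,labels,config as in [train_scheme_lesion()].
#' @param pretrain_mips named list of per-patient lesion-mask MIP pairs.
#' @param finetune_mips named list of per-patient intensity MIP pairs
#'   (variant `"mip"` or `"brain_removed"`).
#' @return A `cnn_cv` object with `scheme` `"mip"` or `"br_mip"`.
#' @export
train_scheme_transfer <- function(partition, subset_id, pretrain_mips,
                                  finetune_mips, labels,
                                  config = model_config("desk")) {
  folds <- .scheme_folds(partition, subset_id)
  v1 <- finetune_mips[[1]]$coronal$variant
  scheme <- switch(v1, mip = "mip", brain_removed = "br_mip",
                   abort("finetune MIPs must be variant 'mip' or 'brain_removed'"))
  pv <- pretrain_mips[[1]]$coronal$variant
  if (pv != "lesion_mask") abort("pretraining MIPs must be variant 'lesion_mask'")
  models <- vector("list", length(folds))
  for (f in seq_along(folds)) {
    cfg <- config
    cfg$seed <- config$seed + f
    stage1 <- train_cnn(pretrain_mips, labels, folds[[f]]$train,
                        folds[[f]]$validation, cfg,
                        epochs = config$epochs_stage1)
    cfg2 <- cfg
    cfg2$seed <- cfg$seed + 100000L
    m <- train_cnn(finetune_mips, labels, folds[[f]]$train,
                   folds[[f]]$validation, cfg2,
                   epochs = config$epochs_stage2,
                   init_weights = stage1$weights)
    m$provenance <- c(m$provenance, list(
      scheme = scheme, subset = subset_id, fold = f,
      stage1_cv_auc = stage1$provenance$cv_auc
    ))
    models[[f]] <- m
  }
  .cnn_cv(models, scheme, subset_id)
}

.cnn_cv <- function(models, scheme, subset_id) {
  cv <- tibble::tibble(
    fold = seq_along(models),
    auc = vapply(models, function(m) m$provenance$cv_auc %||% NA_real_, 0)
  )
  structure(list(models = models, cv = cv, scheme = scheme,
                 subset = subset_id), class = "cnn_cv")
}

#' @export
print.cnn_cv <- function(x, ...) {
  cat(sprintf("<cnn_cv> scheme %s, subset %s; fold AUCs: %s\n", x$scheme,
              x$subset, paste(sprintf("%.3f", x$cv$auc), collapse = ", ")))
  invisible(x)
}

#' @rdname train_scheme_lesion
#' @param x a `cnn_cv`.
#' @param ... unused.
#' @export
#' @method tidy cnn_cv
tidy.cnn_cv <- function(x, ...) x$cv

#' Keep the fold with the highest cross-validated AUC
#'
#' @param cv_result a `cnn_cv` (or plain list of trained models with
#'   validation AUC in their provenance).
#' @return The selected `ttp_cnn`; ties are broken by the lowest fold id.
#' @export
select_model <- function(cv_result) {
  models <- if (inherits(cv_result, "cnn_cv")) cv_result$models else cv_result
  aucs <- vapply(models, function(m) m$provenance$cv_auc %||% NA_real_, 0)
  if (anyNA(aucs)) abort("all candidate models need a recorded validation AUC")
  models[[which.max(aucs)]]  # which.max returns the first of tied maxima
}

#' Predict TTP probabilities for one patient
#'
#' @param object a trained `ttp_cnn`.
#' @param coronal,sagittal normalized [mip_image]s (275 x 200).
#' @param ... unused.
#' @return A tibble with `p_ttp0` and `p_ttp1` (summing to 1).
#' @export
predict.ttp_cnn <- function(object, coronal, sagittal, ...) {
  for (img in list(coronal, sagittal)) {
    if (!inherits(img, "mip_image")) abort("inputs must be mip_images")
    if (!identical(dim(img$pixels), as.integer(CANVAS_SHAPE)))
      abort(sprintf("input shape must be %d x %d", CANVAS_SHAPE[1], CANVAS_SHAPE[2]))
    if (!img$normalized) abort("inputs must be normalized")
  }
  xc <- array(coronal$pixels, c(CANVAS_SHAPE, 1))
  xs <- array(sagittal$pixels, c(CANVAS_SHAPE, 1))
  probs <- cnn_predict_cpp(object$weights, xc, xs)
  tibble::tibble(p_ttp0 = probs[1, 1], p_ttp1 = probs[1, 2])
}

#' Predict TTP probabilities for a set of patients
#'
#' @param model a trained `ttp_cnn`.
#' @param mips named list of per-patient MIP pairs.
#' @param ids patient ids to predict (default: all in `mips`).
#' @return A tibble with one row per patient: `patient_id`, `p_ttp0`,
#'   `p_ttp1`.
#' @export
predict_cohort <- function(model, mips, ids = names(mips)) {
  stk <- .mip_stack(mips, ids)
  probs <- cnn_predict_cpp(model$weights, stk$xc, stk$xs)
  tibble::tibble(patient_id = ids, p_ttp0 = probs[, 1], p_ttp1 = probs[, 2])
}
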