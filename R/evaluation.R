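.check_binary_labels <- function(labels) {
  y <- if (is.character(labels) || is.factor(labels))
    as.integer(as.character(labels) == "TTP1") else as.integer(labels)
  if (anyNA(y) || !all(y %in% c(0L, 1L))) abort("labels must be binary (0/1 or TTP0/TTP1)")
  if (length(unique(y)) < 2) abort("both classes must be present")
  y
}

#' Area under the ROC curve
#'
#' Rank (Mann-Whitney) formulation: the probability that a random positive
#' scores above a random negative, with ties contributing 1/2.
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels binary labels (0/1, logical, or `"TTP0"`/`"TTP1"`).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  y <- .check_binary_labels(labels)
  stopifnot(length(scores) == length(y))
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  r <- rank(scores)  # midranks handle ties as 1/2
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classify at a probability cut-off
#'
#' Predicts TTP1 when `p_ttp1 >= cutoff` (the boundary counts as positive)
#' and reports sensitivity, specificity and AUC. With no positives (or no
#' negatives) the corresponding rate is reported as `NA`, not 0.
#'
#' @param predictions tibble with `p_ttp1` and `label` columns (e.g. the
#'   `val_predictions` of a trained model), or a numeric vector of
#'   probabilities.
#' @param labels binary labels; required when `predictions` is a vector.
#' @param cutoff decision threshold, default 0.5.
#' @return An `eval_report`: list with `auc`, `sensitivity`, `specificity`,
#'   `cutoff`, `n_pos`, `n_neg` and the per-patient prediction table.
#' @export
classify_at_cutoff <- function(predictions, labels = NULL, cutoff = 0.5) {
  if (is.data.frame(predictions)) {
    p <- predictions$p_ttp1
    labels <- labels %||% predictions$label
  } else p <- as.numeric(predictions)
  if (is.null(labels)) abort("labels are required")
  y <- if (is.character(labels) || is.factor(labels))
    as.integer(as.character(labels) == "TTP1") else as.integer(labels)
  pred <- as.integer(p >= cutoff)
  tp <- sum(pred == 1 & y == 1); fn <- sum(pred == 0 & y == 1)
  tn <- sum(pred == 0 & y == 0); fp <- sum(pred == 1 & y == 0)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  auc <- if (length(unique(y)) == 2) roc_auc(p, y) else NA_real_
  structure(list(
    auc = auc, sensitivity = sens, specificity = spec, cutoff = cutoff,
    n_pos = sum(y == 1), n_neg = sum(y == 0),
    predictions = tibble::tibble(p_ttp1 = p, label = y, predicted = pred)
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "<eval_report> n = %d (%d TTP1 / %d TTP0)\n  AUC %.3f | sensitivity %.3f | specificity %.3f @ cutoff %.2f\n",
    x$n_pos + x$n_neg, x$n_pos, x$n_neg, x$auc, x$sensitivity,
    x$specificity, x$cutoff))
  if (!is.null(x$comparison))
    cat(sprintf("  vs comparator AUC %.3f, DeLong p = %.4g\n",
                x$comparison$auc_other, x$comparison$p_value))
  invisible(x)
}

#' @rdname classify_at_cutoff
#' @param x an `eval_report`.
#' @param ... unused.
#' @export
#' @method glance eval_report
glance.eval_report <- function(x, ...) {
  tibble::tibble(auc = x$auc, sensitivity = x$sensitivity,
                 specificity = x$specificity, cutoff = x$cutoff,
                 n_pos = x$n_pos, n_neg = x$n_neg)
}

#' @rdname classify_at_cutoff
#' @export
#' @method tidy eval_report
tidy.eval_report <- function(x, ...) x$predictions

# DeLong structural components: V10 per positive, V01 per negative
.delong_components <- function(scores, y) {
  x <- scores[y == 1]; v <- scores[y == 0]
  psi <- outer(x, v, function(a, b) (a > b) + 0.5 * (a == b))
  list(v10 = rowMeans(psi), v01 = colMeans(psi), auc = mean(psi))
}

#' DeLong test for paired AUCs
#'
#' Compares the AUCs of two score vectors evaluated on the same patients
#' using the covariance of the paired AUC estimates derived from per-patient
#' structural components. When the variance of the AUC difference is zero
#' (e.g. identical scores), the comparison is degenerate and `p = 1` is
#' returned with a flag.
#'
#' @param scores_a,scores_b paired scores on identical patients.
#' @param labels binary labels.
#' @return A tibble with `auc_a`, `auc_b`, `auc_diff`, `z`, `p_value`,
#'   `degenerate`.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  y <- .check_binary_labels(labels)
  stopifnot(length(scores_a) == length(y), length(scores_b) == length(y))
  ca <- .delong_components(scores_a, y)
  cb <- .delong_components(scores_b, y)
  m <- sum(y == 1); n <- sum(y == 0)
  s10 <- stats::cov(cbind(ca$v10, cb$v10))
  s01 <- stats::cov(cbind(ca$v01, cb$v01))
  v <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
       (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  d <- ca$auc - cb$auc
  if (!is.finite(v) || v <= .Machine$double.eps) {
    return(tibble::tibble(auc_a = ca$auc, auc_b = cb$auc, auc_diff = d,
                          z = NA_real_, p_value = 1, degenerate = TRUE))
  }
  z <- d / sqrt(v)
  tibble::tibble(auc_a = ca$auc, auc_b = cb$auc, auc_diff = d, z = z,
                 p_value = 2 * pnorm(-abs(z)), degenerate = FALSE)
}

#' IPI comparator
#'
#' The clinical baseline: the raw International Prognostic Index (0-5) is
#' used as the continuous score for ROC analysis, and patients with IPI of
#' 4 or higher are classified high-risk (predicted TTP1).
#'
#' @param records tibble with `patient_id`, `ipi_score` and (optionally)
#'   `label`.
#' @return Tibble with `patient_id`, `score`, `high_risk` (and `label` when
#'   present).
#' @export
ipi_baseline <- function(records) {
  stopifnot(is.data.frame(records), "ipi_score" %in% names(records))
  missing <- records$patient_id[is.na(records$ipi_score)]
  if (length(missing))
    abort(paste("IPI score missing for patients:", paste(missing, collapse = ", ")))
  out <- tibble::tibble(
    patient_id = records$patient_id,
    score = as.numeric(records$ipi_score),
    high_risk = records$ipi_score >= 4
  )
  if ("label" %in% names(records)) out$label <- records$label
  out
}

#' Calibrate CNN probabilities by logistic regression
#'
#' Fits `label ~ p_ttp1` by maximum likelihood (IRLS via `glm`), yielding an
#' intercept and slope that map raw network probabilities onto outcome
#' frequencies. Under perfect separation the ML fit diverges; a weakly
#' ridge-penalised fit is then used instead, with a notice. The same fit is
#' reused unchanged for ablated-MIP probabilities.
#'
#' @param p_ttp1 raw probabilities.
#' @param labels binary labels.
#' @return A `calibration_fit` with `intercept`, `slope`, `penalized`.
#' @export
fit_calibration <- function(p_ttp1, labels) {
  y <- .check_binary_labels(labels)
  stopifnot(length(p_ttp1) == length(y))
  sep <- FALSE
  fit <- withCallingHandlers(
    glm(y ~ p_ttp1, family = binomial(), control = list(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w))) {
        sep <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  # univariate complete separation: the classes do not overlap in p
  if (max(p_ttp1[y == 0]) < min(p_ttp1[y == 1]) ||
      max(p_ttp1[y == 1]) < min(p_ttp1[y == 0])) sep <- TRUE
  cf <- coef(fit)
  if (sep || !fit$converged || any(!is.finite(cf)) || any(abs(cf) > 1e3)) {
    inform("perfect separation detected; using a ridge-penalised logistic fit")
    lambda <- 1e-2
    nll <- function(b) {
      eta <- b[1] + b[2] * p_ttp1
      sum(log1p(exp(-(2 * y - 1) * eta))) + lambda * sum(b^2) / 2
    }
    opt <- stats::optim(c(0, 0), nll, method = "BFGS")
    cf <- opt$par
    penalized <- TRUE
  } else penalized <- FALSE
  structure(list(intercept = unname(cf[1]), slope = unname(cf[2]),
                 penalized = penalized, n = length(y)),
            class = "calibration_fit")
}

#' @rdname fit_calibration
#' @param fit a `calibration_fit`.
#' @param p raw probabilities to calibrate.
#' @return `apply_calibration()`: calibrated probabilities in `(0, 1)`.
#' @export
apply_calibration <- function(fit, p) {
  stopifnot(inherits(fit, "calibration_fit"))
  plogis(fit$intercept + fit$slope * p)
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf("<calibration_fit> logit(p') = %.3f + %.3f p%s (n = %d)\n",
              x$intercept, x$slope, if (x$penalized) " [ridge]" else "", x$n))
  invisible(x)
}

#' @rdname fit_calibration
#' @param x a `calibration_fit`.
#' @param ... unused.
#' @export
#' @method tidy calibration_fit
tidy.calibration_fit <- function(x, ...) {
  tibble::tibble(term = c("(Intercept)", "p_ttp1"),
                 estimate = c(x$intercept, x$slope))
}

#' Association between predictions and PET features
#'
#' Pearson correlation between predicted TTP1 probability and each PET
#' feature (MTV, Dmax_bulk), plus the per-patient scatter table for
#' plotting. A zero-variance feature yields `NA` rather than an error.
#'
#' @param predictions tibble with `patient_id` and `p_ttp1`.
#' @param features tibble with `patient_id`, `mtv_ml`, `dmax_bulk_cm` (e.g.
#'   from [cohort_features()]).
#' @return A `feature_association`: list with `correlations` (tibble:
#'   feature, r, n) and `scatter` (joined per-patient table).
#' @export
feature_association <- function(predictions, features) {
  tab <- dplyr::inner_join(predictions, features, by = "patient_id")
  if (nrow(tab) < 3) abort("need at least 3 patients")
  feats <- intersect(c("mtv_ml", "dmax_bulk_cm"), names(tab))
  cors <- purrr::map_dfr(feats, function(f) {
    x <- tab[[f]]
    r <- if (sd(x) == 0 || sd(tab$p_ttp1) == 0) NA_real_ else cor(tab$p_ttp1, x)
    tibble::tibble(feature = f, r = r, n = nrow(tab))
  })
  structure(list(correlations = cors, scatter = tab),
            class = "feature_association")
}

#' @export
print.feature_association <- function(x, ...) {
  print(x$correlations)
  invisible(x)
}

#' @rdname feature_association
#' @param x a `feature_association`.
#' @param ... unused.
#' @export
#' @method tidy feature_association
tidy.feature_association <- function(x, ...) x$correlations

#' @rdname feature_association
#' @param object a `feature_association`.
#' @export
#' @method autoplot feature_association
autoplot.feature_association <- function(object, ...) {
  long <- tidyr::pivot_longer(object$scatter,
                              dplyr::any_of(c("mtv_ml", "dmax_bulk_cm")),
                              names_to = "feature", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$value, .data$p_ttp1)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::facet_wrap(~feature, scales = "free_x") +
    ggplot2::labs(x = "feature value", y = "P(TTP1)") +
    ggplot2::theme_minimal()
}

#' Tumour-ablation plausibility analysis
#'
#' Re-predicts each patient after replacing tumour pixels in both views by
#' the mean non-background intensity ([ablate_tumours()]) and compares
#' calibrated TTP1 probabilities before and after. A model that has learnt
#' tumour information should drop after ablation; patients without lesions
#' are unchanged by construction.
#'
#' @param model a trained `ttp_cnn`.
#' @param mips named list of per-patient intensity MIP pairs.
#' @param masks named list of per-patient lesion-mask MIP pairs.
#' @param calibration a `calibration_fit` applied to both prediction sets.
#' @param ids patients to analyse (default all in `mips`).
#' @return An `ablation_analysis`: list with `table` (per patient:
#'   raw/calibrated probabilities before/after), `summary` (mean change,
#'   count crossing from > 0.6 to < 0.4, sign-test p-value) and `histogram`
#'   (binned calibrated probabilities before/after).
#' @export
ablation_analysis <- function(model, mips, masks, calibration,
                              ids = names(mips)) {
  stopifnot(inherits(model, "ttp_cnn"), inherits(calibration, "calibration_fit"))
  ablated <- lapply(ids, function(pid) {
    list(coronal = ablate_tumours(mips[[pid]]$coronal, masks[[pid]]$coronal),
         sagittal = ablate_tumours(mips[[pid]]$sagittal, masks[[pid]]$sagittal))
  })
  names(ablated) <- ids
  before <- predict_cohort(model, mips, ids)
  after <- predict_cohort(model, ablated, ids)
  tab <- tibble::tibble(
    patient_id = ids,
    p_before = before$p_ttp1, p_after = after$p_ttp1,
    cal_before = apply_calibration(calibration, before$p_ttp1),
    cal_after = apply_calibration(calibration, after$p_ttp1),
    masked_pixels = unname(vapply(ids, function(pid)
      sum(masks[[pid]]$coronal$pixels > 0.5) +
        sum(masks[[pid]]$sagittal$pixels > 0.5), 0))
  )
  changed <- tab$masked_pixels > 0 & tab$cal_before != tab$cal_after
  p_sign <- if (any(changed)) {
    dec <- sum(tab$cal_after[changed] < tab$cal_before[changed])
    binom.test(dec, sum(changed), alternative = "greater")$p.value
  } else NA_real_
  summary <- tibble::tibble(
    n = length(ids),
    mean_before = mean(tab$cal_before), mean_after = mean(tab$cal_after),
    mean_change = mean(tab$cal_after - tab$cal_before),
    n_high_to_low = sum(tab$cal_before > 0.6 & tab$cal_after < 0.4),
    sign_test_p = p_sign
  )
  breaks <- seq(0, 1, by = 0.05)
  histogram <- tibble::tibble(
    bin_lo = rep(head(breaks, -1), 2),
    bin_hi = rep(breaks[-1], 2),
    phase = rep(c("before", "after"), each = length(breaks) - 1),
    count = c(as.integer(table(cut(tab$cal_before, breaks, include.lowest = TRUE))),
              as.integer(table(cut(tab$cal_after, breaks, include.lowest = TRUE))))
  )
  structure(list(table = tab, summary = summary, histogram = histogram),
            class = "ablation_analysis")
}

#' @export
print.ablation_analysis <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<ablation_analysis> n = %d; mean calibrated P(TTP1) %.3f -> %.3f (change %.3f)\n  %d patients crossed > 0.6 to < 0.4; sign test p = %.3g\n",
    s$n, s$mean_before, s$mean_after, s$mean_change, s$n_high_to_low,
    s$sign_test_p))
  invisible(x)
}

#' @rdname ablation_analysis
#' @param x an `ablation_analysis`.
#' @param ... unused.
#' @export
#' @method tidy ablation_analysis
tidy.ablation_analysis <- function(x, ...) x$table

#' @rdname ablation_analysis
#' @export
#' @method glance ablation_analysis
glance.ablation_analysis <- function(x, ...) x$summary

#' @rdname ablation_analysis
#' @param object an `ablation_analysis`.
#' @export
#' @method autoplot ablation_analysis
autoplot.ablation_analysis <- function(object, ...) {
  long <- tidyr::pivot_longer(object$table, c("cal_before", "cal_after"),
                              names_to = "phase", values_to = "p")
  long$phase <- factor(long$phase, c("cal_before", "cal_after"),
                       c("original", "tumours ablated"))
  ggplot2::ggplot(long, ggplot2::aes(.data$p, fill = .data$phase)) +
    ggplot2::geom_histogram(breaks = seq(0, 1, 0.05), alpha = 0.6,
                            position = "identity") +
    ggplot2::labs(x = "calibrated P(TTP1)", y = "patients") +
    ggplot2::theme_minimal()
}

#' ROC curve plot for one or more score sets
#'
#' @param scores named list of numeric score vectors.
#' @param labels binary labels shared by all score sets.
#' @return A ggplot of ROC curves with AUC annotations.
#' @export
plot_roc <- function(scores, labels) {
  y <- .check_binary_labels(labels)
  df <- purrr::imap_dfr(scores, function(s, nm) {
    r <- pROC::roc(y, s, quiet = TRUE, direction = "<")
    tibble::tibble(model = sprintf("%s (AUC %.2f)", nm, as.numeric(pROC::auc(r))),
                   fpr = 1 - r$specificities, tpr = r$sensitivities)
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$fpr, .data$tpr, colour = .data$model)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey") +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity") +
    ggplot2::theme_minimal()
}
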