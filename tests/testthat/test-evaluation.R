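test_that("rank-based AUC matches hand counts, the all-pairs oracle and pROC", {
  # positives (0.35, 0.8), negatives (0.1, 0.4): 3 wins / 1 loss of 4 pairs
  expect_equal(roc_auc(c(0.35, 0.8, 0.1, 0.4), c(1, 1, 0, 0)), 0.75)
  expect_equal(roc_auc(c(5, 6, 1, 2), c(1, 1, 0, 0)), 1.0)
  expect_equal(roc_auc(rep(0.3, 6), c(1, 1, 1, 0, 0, 0)), 0.5)

  for (seed in 1:20) {
    n <- withr::with_seed(seed, sample(4:20, 1))
    y <- withr::with_seed(seed + 100, {
      y <- integer(n); y[sample(n, sample(1:(n - 1), 1))] <- 1L; y
    })
    s <- withr::with_seed(seed + 200, round(runif(n), 1))  # forces ties
    got <- roc_auc(s, y)
    expect_equal(got, auc_oracle(s, y))
    expect_equal(got, as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                                     direction = "<"))))
  }

  expect_error(roc_auc(1:3, c(1, 1, 1)), "both classes")
})

test_that("AUC is invariant under strictly increasing score transforms", {
  s <- c(0.1, 0.5, 0.2, 0.9, 0.4, 0.7)
  y <- c(0, 1, 0, 1, 0, 1)
  a <- roc_auc(s, y)
  expect_equal(roc_auc(qlogis(s), y), a)
  expect_equal(roc_auc(100 * s + 3, y), a)
  expect_equal(roc_auc(exp(s), y), a)
})

test_that("cut-off classification uses >= 0.5 and reports NA for missing classes", {
  ev <- classify_at_cutoff(c(0.7, 0.6, 0.4, 0.3), c(1, 1, 0, 0))
  expect_equal(ev$sensitivity, 1)
  expect_equal(ev$specificity, 1)
  expect_equal(ev$auc, 1)

  # the boundary probability counts as positive
  at <- classify_at_cutoff(c(0.5, 0.2), c(1, 0))
  expect_equal(at$sensitivity, 1)

  # flipping labels swaps sensitivity and specificity
  p <- c(0.9, 0.6, 0.55, 0.2, 0.4, 0.1)
  y <- c(1, 1, 0, 0, 1, 0)
  a <- classify_at_cutoff(p, y)
  b <- classify_at_cutoff(p, 1 - y)
  expect_equal(a$sensitivity, 1 - b$specificity)
  expect_equal(a$specificity, 1 - b$sensitivity)

  none <- classify_at_cutoff(c(0.3, 0.6), c(0, 0))
  expect_true(is.na(none$sensitivity))
  expect_equal(none$specificity, 0.5)
})

test_that("cut-off sweep reproduces the ROC step structure", {
  withr::with_seed(42, {
    y <- rbinom(40, 1, 0.5)
    s <- runif(40) + 0.3 * y
  })
  r <- pROC::roc(y, s, quiet = TRUE, direction = "<")
  for (cut in sort(unique(s))) {
    ev <- classify_at_cutoff(s, y, cutoff = cut)
    i <- which.min(abs(r$thresholds - cut))
    # every (sens, spec) pair at a data cut-off lies on the pROC curve
    expect_true(any(abs(r$sensitivities - ev$sensitivity) < 1e-9 &
                    abs(r$specificities - ev$specificity) < 1e-9))
  }
})

test_that("the DeLong test matches pROC and detects degenerate comparisons", {
  withr::with_seed(7, {
    y <- rep(c(0, 1), each = 15)
    a <- runif(30) + 0.4 * y
    b <- runif(30) + 0.2 * y
  })
  got <- delong_test(a, b, y)
  ref <- pROC::roc.test(pROC::roc(y, a, quiet = TRUE, direction = "<"),
                        pROC::roc(y, b, quiet = TRUE, direction = "<"),
                        method = "delong", paired = TRUE)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-8)
  expect_equal(got$auc_a, as.numeric(ref$estimate[1]))
  expect_equal(got$auc_b, as.numeric(ref$estimate[2]))

  # symmetry in the two score vectors
  swapped <- delong_test(b, a, y)
  expect_equal(swapped$p_value, got$p_value)
  expect_equal(swapped$auc_diff, -got$auc_diff)

  # identical scores: zero-variance difference flagged, p = 1
  dg <- delong_test(a, a, y)
  expect_true(dg$degenerate)
  expect_equal(dg$p_value, 1)
  expect_equal(dg$auc_diff, 0)
})

test_that("DeLong p-values agree with a paired permutation test at small n", {
  cases <- list(
    list(seed = 1, shift = 0.0),
    list(seed = 2, shift = 0.6)
  )
  for (cs in cases) {
    withr::with_seed(cs$seed, {
      y <- rep(c(0, 1), each = 6)
      a <- runif(12) + cs$shift * y
      b <- runif(12)
    })
    p_dl <- delong_test(a, b, y)$p_value
    p_perm <- delong_perm_oracle(a, b, y, n_perm = 20000, seed = 99)
    # asymptotic vs exact at n = 12: agreement within a coarse tolerance
    expect_lt(abs(p_dl - p_perm), 0.12)
  }
})

test_that("DeLong p-values are uniform under the global null", {
  ps <- vapply(1:300, function(r) {
    withr::with_seed(5000 + r, {
      y <- rep(c(0, 1), each = 30)
      delong_test(rnorm(60), rnorm(60), y)$p_value
    })
  }, 0)
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("the IPI baseline thresholds at 4 and exposes a ROC-ready score", {
  rec <- patient_records(sprintf("r%d", 1:6), rep(c("TTP0", "TTP1"), 3),
                         ipi_score = c(0, 3, 4, 5, 2, 4))
  out <- ipi_baseline(rec)
  expect_equal(out$high_risk, c(FALSE, FALSE, TRUE, TRUE, FALSE, TRUE))
  expect_equal(out$score, c(0, 3, 4, 5, 2, 4))
  expect_true(is.finite(roc_auc(out$score, out$label)))

  rec$ipi_score[2] <- NA
  expect_error(ipi_baseline(rec), "r2")
})

test_that("probability calibration recovers logistic coefficients and preserves AUC", {
  withr::with_seed(11, {
    p <- runif(2000)
    y <- rbinom(2000, 1, plogis(-2 + 5 * p))
  })
  fit <- fit_calibration(p, y)
  gl <- glm(y ~ p, family = binomial())
  se <- sqrt(diag(vcov(gl)))
  expect_false(fit$penalized)
  expect_lt(abs(fit$intercept - (-2)), 3.5 * se[1])
  expect_lt(abs(fit$slope - 5), 3.5 * se[2])
  expect_gt(fit$slope, 0)

  cal <- apply_calibration(fit, p)
  expect_true(all(cal > 0 & cal < 1))
  # strictly monotone recalibration leaves the ranking, hence the AUC, intact
  expect_equal(roc_auc(cal, y), roc_auc(p, y))

  # perfectly separated inputs fall back to the penalised fit
  sep_p <- c(rep(0.1, 20), rep(0.9, 20))
  sep_y <- c(rep(0, 20), rep(1, 20))
  expect_message(sep_fit <- fit_calibration(sep_p, sep_y), "separation")
  expect_true(sep_fit$penalized)
  expect_true(is.finite(sep_fit$slope))
  expect_true(all(apply_calibration(sep_fit, c(0, 0.5, 1)) > 0))
})

test_that("feature association reproduces the textbook Pearson formula and a null envelope", {
  # hand-checkable 5-point set
  pred <- tibble::tibble(patient_id = letters[1:5],
                         p_ttp1 = c(0.1, 0.3, 0.2, 0.8, 0.6))
  feat <- tibble::tibble(patient_id = letters[1:5],
                         mtv_ml = c(5, 20, 10, 80, 40),
                         dmax_bulk_cm = c(1, 1, 1, 1, 1))
  fa <- feature_association(pred, feat)
  x <- feat$mtv_ml; yv <- pred$p_ttp1
  r_hand <- sum((x - mean(x)) * (yv - mean(yv))) /
    sqrt(sum((x - mean(x))^2) * sum((yv - mean(yv))^2))
  expect_equal(fa$correlations$r[fa$correlations$feature == "mtv_ml"], r_hand)
  # zero-variance feature reported as NA, not an error
  expect_true(is.na(fa$correlations$r[fa$correlations$feature == "dmax_bulk_cm"]))

  # exact linearity
  lin <- feature_association(
    tibble::tibble(patient_id = letters[1:5], p_ttp1 = c(1, 2, 3, 4, 5) / 10),
    tibble::tibble(patient_id = letters[1:5], mtv_ml = c(10, 20, 30, 40, 50)))
  expect_equal(lin$correlations$r[1], 1)

  # permuted feature at n = 1000: correlation inside the null envelope
  withr::with_seed(3, {
    ids <- sprintf("n%04d", 1:1000)
    p1 <- runif(1000)
    f1 <- sample(p1 * 100)
  })
  null_fa <- feature_association(tibble::tibble(patient_id = ids, p_ttp1 = p1),
                                 tibble::tibble(patient_id = ids, mtv_ml = f1))
  expect_lt(abs(null_fa$correlations$r[1]), 4 / sqrt(1000))

  expect_error(feature_association(pred[1:2, ], feat[1:2, ]), "at least 3")
})

test_that("ablation analysis leaves lesion-free patients untouched and tabulates every patient", {
  ph0 <- generate_phantom(tiny_spec(n_lesions = 0, seed = 31))
  ph1 <- generate_phantom(tiny_spec(n_lesions = 2, seed = 32))
  mips <- list(); masks <- list()
  for (p in list(list(ph0, "Z0"), list(ph1, "Z1"))) {
    seg <- segment_lesions(p[[1]]$volume,
                           physiological_mask = p[[1]]$truth$organ_mask)
    mips[[p[[2]]]] <- list(coronal = make_mip(p[[1]]$volume, "coronal"),
                           sagittal = make_mip(p[[1]]$volume, "sagittal"))
    masks[[p[[2]]]] <- list(coronal = lesion_mask_mip(p[[1]]$volume, seg, "coronal"),
                            sagittal = lesion_mask_mip(p[[1]]$volume, seg, "sagittal"))
  }
  model <- build_model(model_config("desk", seed = 9))
  cal <- structure(list(intercept = 0, slope = 1, penalized = FALSE, n = 2),
                   class = "calibration_fit")
  res <- ablation_analysis(model, mips, masks, cal)
  expect_equal(nrow(res$table), 2)
  z0 <- res$table[res$table$patient_id == "Z0", ]
  expect_equal(z0$p_before, z0$p_after)
  expect_equal(z0$cal_before, z0$cal_after)
  expect_equal(z0$masked_pixels, 0)
  expect_true(all(c("cal_before", "cal_after") %in% names(res$table)))
  expect_equal(sum(res$histogram$count[res$histogram$phase == "before"]), 2)
})
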