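#' Specification for a synthetic whole-body PET phantom
#'
#' Defines the geometry and uptake of a synthetic SUV volume: a low-uptake
#' body ellipsoid, high-uptake physiological organs (brain, bladder) plus a
#' moderate-uptake liver, and a configurable number of focal lesions. The
#' defaults are chosen so that every threshold in the pipeline is exercised
#' non-trivially: lesion SUVs (5-20) sit above the 4.0 segmentation
#' threshold, the bladder (SUV 45) exceeds the SUV-40 normalization cap, and
#' the brain (radius 50 mm, ~0.52 L) falls inside the volume window used by
#' brain removal.
#'
#' @param grid_shape voxels per axis `(z, y, x)`; z is cranio-caudal with
#'   index 1 at the head end.
#' @param voxel_size_mm isotropic voxel spacing.
#' @param n_lesions number of lesions, >= 0.
#' @param lesion_radius_range_mm min/max lesion radius.
#' @param body_suv,brain_suv,bladder_suv,liver_suv organ uptake values.
#' @param lesion_suv_range min/max lesion uptake; the minimum must exceed the
#'   4.0 segmentation threshold.
#' @param brain_radius_mm,bladder_radius_mm organ radii.
#' @param seed RNG seed; fully determines the phantom.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(160, 100, 70), voxel_size_mm = 4,
                         n_lesions = 5, lesion_radius_range_mm = c(6, 15),
                         body_suv = 1.0, brain_suv = 8.0, bladder_suv = 45.0,
                         liver_suv = 2.0, lesion_suv_range = c(5, 20),
                         brain_radius_mm = 50, bladder_radius_mm = 16,
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 8),
            voxel_size_mm > 0, n_lesions >= 0,
            length(lesion_radius_range_mm) == 2,
            lesion_radius_range_mm[1] > 0,
            diff(lesion_radius_range_mm) >= 0,
            length(lesion_suv_range) == 2, diff(lesion_suv_range) >= 0)
  if (lesion_suv_range[1] <= SUV_THRESHOLD)
    abort("lesion SUV minimum must exceed the segmentation threshold of 4.0")
  if (body_suv >= SUV_THRESHOLD)
    abort("body SUV must be below the segmentation threshold of 4.0")
  ext_mm <- grid_shape * voxel_size_mm
  if (ext_mm[1] < 2.6 * (brain_radius_mm + bladder_radius_mm))
    abort("grid too short cranio-caudally for disjoint brain and bladder")
  spec <- list(
    grid_shape = grid_shape, voxel_size_mm = voxel_size_mm,
    n_lesions = as.integer(n_lesions),
    lesion_radius_range_mm = lesion_radius_range_mm,
    body_suv = body_suv, brain_suv = brain_suv, bladder_suv = bladder_suv,
    liver_suv = liver_suv, lesion_suv_range = lesion_suv_range,
    brain_radius_mm = brain_radius_mm, bladder_radius_mm = bladder_radius_mm,
    seed = as.integer(seed)
  )
  structure(spec, class = "phantom_spec")
}

# One cohort patient: phantom (or geometry-only truth) plus outcome label.
# Each patient has its own RNG substream derived from (seed, i), so cohorts
# are reproducible patient-by-patient regardless of generation order.
.cohort_patient <- function(i, seed, outcome, n_lesions_range,
                            lesion_radius_range_mm, grid_shape, voxel_size_mm,
                            rasterize) {
  n_lesions_range <- as.integer(n_lesions_range)
  pseed <- (as.integer(seed) + 7919L * i) %% 2147483647L
  ph <- NULL
  lab <- NULL
  withr::with_seed(pseed, {
    nl <- if (n_lesions_range[1] == n_lesions_range[2]) n_lesions_range[1]
          else sample(n_lesions_range[1]:n_lesions_range[2], 1)
    spec <- phantom_spec(grid_shape = grid_shape,
                         voxel_size_mm = voxel_size_mm, n_lesions = nl,
                         lesion_radius_range_mm = lesion_radius_range_mm,
                         seed = pseed)
    ph <- .generate_phantom_impl(spec, rasterize)
    logit <- outcome$beta0 +
      outcome$beta_mtv * log(ph$truth$mtv_ml) +
      outcome$beta_dmax * ph$truth$dmax_bulk_cm +
      rnorm(1, 0, outcome$noise_sd)
    lab <- rbinom(1, 1, plogis(logit))
  })
  pid <- sprintf("P%04d", i)
  if (!is.null(ph$volume)) ph$volume$patient_id <- pid
  list(phantom = ph, row = tibble::tibble(
    patient_id = pid, label = if (lab == 1) "TTP1" else "TTP0",
    true_mtv_ml = ph$truth$mtv_ml, true_dmax_cm = ph$truth$dmax_bulk_cm,
    n_lesions = nrow(ph$truth$lesions), seed = pseed
  ))
}

# voxel center coordinate (mm) of index i: (i - 0.5) * spacing
.axis_coords <- function(n, s) (seq_len(n) - 0.5) * s

# phantom geometry shared by rasterization and placement checks
.phantom_geometry <- function(spec) {
  d <- spec$grid_shape
  s <- spec$voxel_size_mm
  ext <- d * s
  ctr <- ext / 2
  semi <- c(0.48, 0.38, 0.38) * ext
  brain_c <- c(ctr[1] - 0.80 * semi[1], ctr[2], ctr[3])
  bladder_c <- c(ctr[1] + 0.75 * semi[1], ctr[2], ctr[3])
  liver_c <- c(ctr[1], ctr[2], ctr[3] + 0.45 * semi[3])
  liver_semi <- pmin(c(45, 50, 40), 0.45 * semi)
  list(center = ctr, semi = semi, brain_c = brain_c, bladder_c = bladder_c,
       liver_c = liver_c, liver_semi = liver_semi)
}

# logical mask of an ellipsoid, full grid (outer-sum of squared offsets)
.ellipsoid_mask <- function(d, s, center, semi) {
  qz <- ((.axis_coords(d[1], s) - center[1]) / semi[1])^2
  qy <- ((.axis_coords(d[2], s) - center[2]) / semi[2])^2
  qx <- ((.axis_coords(d[3], s) - center[3]) / semi[3])^2
  outer(outer(qz, qy, `+`), qx, `+`) <= 1
}

# fill a sphere into `arr` (and optionally `map`), bounding-box local
.fill_sphere <- function(arr, d, s, center, radius, value, map = NULL, id = 0L) {
  rng <- lapply(1:3, function(a) {
    lo <- max(1L, ceiling((center[a] - radius) / s + 0.5))
    hi <- min(d[a], floor((center[a] + radius) / s + 0.5))
    lo:hi
  })
  cz <- (rng[[1]] - 0.5) * s - center[1]
  cy <- (rng[[2]] - 0.5) * s - center[2]
  cx <- (rng[[3]] - 0.5) * s - center[3]
  inside <- outer(outer(cz^2, cy^2, `+`), cx^2, `+`) <= radius^2
  sub <- arr[rng[[1]], rng[[2]], rng[[3]], drop = FALSE]
  sub[inside] <- value
  arr[rng[[1]], rng[[2]], rng[[3]]] <- sub
  if (!is.null(map)) {
    subm <- map[rng[[1]], rng[[2]], rng[[3]], drop = FALSE]
    subm[inside] <- id
    map[rng[[1]], rng[[2]], rng[[3]]] <- subm
    list(arr = arr, map = map, n = sum(inside))
  } else {
    list(arr = arr, n = sum(inside))
  }
}

#' Generate a synthetic PET phantom
#'
#' Builds an SUV volume containing a body ellipsoid, a brain sphere near the
#' head end, a bladder sphere near the caudal end, a liver ellipsoid, and
#' `n_lesions` non-overlapping lesion spheres placed uniformly inside the
#' body away from the organs. Voxels outside the body are 0. The output is a
#' deterministic function of the phantom specification (including its seed).
#'
#' @param spec a [phantom_spec].
#' @param rasterize if `FALSE`, only the geometric ground truth is computed
#'   (no voxel grid); lesion geometry and labels are identical to the
#'   rasterized phantom because both paths consume the RNG identically.
#' @return An object of class `pet_phantom`: list with `volume`
#'   ([pet_volume], or `NULL` when `rasterize = FALSE`) and `truth`, holding
#'   the lesion label map, per-lesion table (analytic and voxel volumes,
#'   centroids in mm), organ masks, analytic `mtv_ml` and `dmax_bulk_cm`.
#' @export
generate_phantom <- function(spec, rasterize = TRUE) {
  stopifnot(inherits(spec, "phantom_spec"))
  withr::with_seed(spec$seed, .generate_phantom_impl(spec, rasterize))
}

.generate_phantom_impl <- function(spec, rasterize) {
  d <- spec$grid_shape
  s <- spec$voxel_size_mm
  g <- .phantom_geometry(spec)

  # --- sample lesion geometry (RNG consumed identically in both modes) ---
  rr <- spec$lesion_radius_range_mm
  margin <- 2 * s  # separation keeping rasterized lesions 26-disconnected
  centers <- matrix(NA_real_, spec$n_lesions, 3)
  radii <- numeric(spec$n_lesions)
  suvs <- numeric(spec$n_lesions)
  liver_bound <- max(g$liver_semi)
  if (spec$n_lesions > 0 && any(g$semi - rr[2] - margin <= 0))
    abort("grid too small: body semi-axes cannot accommodate the largest lesion radius")
  if (spec$n_lesions > 0) {
    for (k in seq_len(spec$n_lesions)) {
      r <- runif(1, rr[1], rr[2])
      placed <- FALSE
      for (try in 1:500) {
        p <- g$center + (runif(3, -1, 1)) * (g$semi - r - margin)
        # inside body with the whole sphere (conservative radial check)
        if (sum(((p - g$center) / (g$semi - r - margin))^2) > 1) next
        if (sqrt(sum((p - g$brain_c)^2)) < r + spec$brain_radius_mm + margin) next
        if (sqrt(sum((p - g$bladder_c)^2)) < r + spec$bladder_radius_mm + margin) next
        if (sqrt(sum((p - g$liver_c)^2)) < r + liver_bound + margin) next
        if (k > 1) {
          dists <- sqrt(colSums((t(centers[seq_len(k - 1), , drop = FALSE]) - p)^2))
          if (any(dists < r + radii[seq_len(k - 1)] + margin)) next
        }
        placed <- TRUE
        break
      }
      if (!placed)
        abort(sprintf(
          "could not place lesion %d (radius %.1f mm) after 500 tries: body too crowded for the non-overlap constraint", k, r))
      centers[k, ] <- p
      radii[k] <- r
      suvs[k] <- runif(1, spec$lesion_suv_range[1], spec$lesion_suv_range[2])
    }
  }

  vol_ml <- (4 / 3) * pi * radii^3 / 1000
  lesions <- tibble::tibble(
    id = seq_len(spec$n_lesions),
    z_mm = centers[, 1], y_mm = centers[, 2], x_mm = centers[, 3],
    radius_mm = radii, suv = suvs, volume_ml = vol_ml,
    voxel_count = NA_integer_
  )
  mtv_ml <- sum(vol_ml)
  dmax_cm <- if (spec$n_lesions >= 2) {
    largest <- which.max(vol_ml)
    max(sqrt(colSums((t(centers) - centers[largest, ])^2))) / 10
  } else 0

  truth <- list(lesions = lesions, mtv_ml = mtv_ml, dmax_bulk_cm = dmax_cm,
                lesion_map = NULL, brain_mask = NULL, bladder_mask = NULL,
                liver_mask = NULL, organ_mask = NULL)
  volume <- NULL

  if (rasterize) {
    suv <- array(0, d)
    body <- .ellipsoid_mask(d, s, g$center, g$semi)
    suv[body] <- spec$body_suv
    liver <- .ellipsoid_mask(d, s, g$liver_c, g$liver_semi) & body
    suv[liver] <- spec$liver_suv
    f <- .fill_sphere(suv, d, s, g$brain_c, spec$brain_radius_mm, spec$brain_suv)
    suv <- f$arr
    brain <- .fill_sphere(array(FALSE, d), d, s, g$brain_c,
                          spec$brain_radius_mm, TRUE)$arr
    f <- .fill_sphere(suv, d, s, g$bladder_c, spec$bladder_radius_mm, spec$bladder_suv)
    suv <- f$arr
    bladder <- .fill_sphere(array(FALSE, d), d, s, g$bladder_c,
                            spec$bladder_radius_mm, TRUE)$arr
    lesion_map <- array(0L, d)
    counts <- integer(spec$n_lesions)
    for (k in seq_len(spec$n_lesions)) {
      f <- .fill_sphere(suv, d, s, centers[k, ], radii[k], suvs[k],
                        map = lesion_map, id = k)
      suv <- f$arr
      lesion_map <- f$map
      counts[k] <- f$n
    }
    truth$lesions$voxel_count <- counts
    truth$lesion_map <- lesion_map
    truth$brain_mask <- brain
    truth$bladder_mask <- bladder
    truth$liver_mask <- liver
    truth$organ_mask <- brain | bladder | liver
    volume <- pet_volume(suv, s, patient_id = sprintf("phantom-%d", spec$seed))
  }

  structure(list(volume = volume, truth = truth, spec = spec),
            class = "pet_phantom")
}

#' Logistic outcome model for synthetic cohorts
#'
#' Labels are drawn Bernoulli with
#' `logit P(TTP1) = beta0 + beta_mtv * log(MTV) + beta_dmax * Dmax + noise`,
#' mirroring the observed association between progression probability and
#' lesion burden/dissemination. With `beta_mtv = beta_dmax = 0` labels are
#' independent of the image.
#'
#' @param beta0 intercept (log-odds).
#' @param beta_mtv coefficient on `log(MTV in mL)`.
#' @param beta_dmax coefficient on `Dmax_bulk` in cm.
#' @param noise_sd standard deviation of Gaussian logit noise.
#' @return An object of class `outcome_model`.
#' @export
outcome_model <- function(beta0 = -10.5, beta_mtv = 2, beta_dmax = 0.05,
                          noise_sd = 0.5) {
  stopifnot(noise_sd >= 0)
  structure(list(beta0 = beta0, beta_mtv = beta_mtv, beta_dmax = beta_dmax,
                 noise_sd = noise_sd), class = "outcome_model")
}

#' Generate a synthetic patient cohort
#'
#' Draws per-patient phantoms with lesion count and size sampled from the
#' given ranges and outcome labels from the logistic [outcome_model]. Each
#' patient has an independent RNG substream derived from `seed` and the
#' patient counter, so cohorts are reproducible and order-independent.
#'
#' @param n_patients number of patients (> 0).
#' @param outcome an [outcome_model].
#' @param n_lesions_range inclusive integer range of lesion counts.
#' @param lesion_radius_range_mm lesion radius range passed to the phantoms.
#' @param grid_shape,voxel_size_mm phantom grid geometry.
#' @param seed cohort seed.
#' @param rasterize if `FALSE`, volumes are skipped and only ground-truth
#'   features and labels are produced (fast path for statistical checks).
#' @return A `phantom_cohort`: list with `patients` (list of [pet_phantom])
#'   and `table`, a tibble with `patient_id`, `label`, `true_mtv_ml`,
#'   `true_dmax_cm`, `n_lesions`, `seed`.
#' @export
generate_cohort <- function(n_patients, outcome = outcome_model(),
                            n_lesions_range = c(1, 15),
                            lesion_radius_range_mm = c(6, 15),
                            grid_shape = c(160, 100, 70), voxel_size_mm = 4,
                            seed = 1L, rasterize = TRUE) {
  stopifnot(n_patients > 0, inherits(outcome, "outcome_model"))
  patients <- vector("list", n_patients)
  rows <- vector("list", n_patients)
  for (i in seq_len(n_patients)) {
    pat <- .cohort_patient(i, seed, outcome, n_lesions_range,
                           lesion_radius_range_mm, grid_shape, voxel_size_mm,
                           rasterize)
    patients[[i]] <- pat$phantom
    rows[[i]] <- pat$row
  }
  table <- dplyr::bind_rows(rows)
  if (length(unique(table$label)) == 1)
    warn(sprintf("degenerate outcome model: all labels are %s", table$label[1]))
  names(patients) <- table$patient_id
  structure(list(patients = patients, table = table, outcome = outcome,
                 seed = as.integer(seed)),
            class = "phantom_cohort")
}

#' @export
print.phantom_cohort <- function(x, ...) {
  cat(sprintf("<phantom_cohort> %d patients, %d TTP1 (%.1f%%), seed %d\n",
              nrow(x$table), sum(x$table$label == "TTP1"),
              100 * mean(x$table$label == "TTP1"), x$seed))
  invisible(x)
}

#' @rdname generate_cohort
#' @param x a `phantom_cohort`.
#' @param ... unused.
#' @export
#' @method tidy phantom_cohort
tidy.phantom_cohort <- function(x, ...) x$table

#' Write a cohort to disk
#'
#' Writes one NIfTI volume per patient plus a sidecar CSV
#' (`patient_id, label, true_mtv_ml, true_dmax_cm, n_lesions, seed`).
#'
#' @param cohort a `phantom_cohort` generated with `rasterize = TRUE`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "phantom_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (p in cohort$patients) {
    if (is.null(p$volume)) abort("cohort was generated with rasterize = FALSE")
    write_volume(p$volume, file.path(dir, paste0(p$volume$patient_id, ".nii.gz")))
  }
  write.csv(cohort$table, file.path(dir, "cohort.csv"), row.names = FALSE)
  invisible(dir)
}
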