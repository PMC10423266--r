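#' PET volume in SUV units
#'
#' A light container for a 3-d standardized-uptake-value (SUV) grid. The
#' internal axis convention is `(z, y, x)`: axis 1 is cranio-caudal with index
#' 1 at the head end, axis 2 anterior-posterior, axis 3 left-right. All
#' modules in the package use this single convention.
#'
#' @param suv 3-d non-negative numeric array, axes `(z, y, x)`.
#' @param spacing_mm voxel spacing in mm, length 1 (isotropic) or 3.
#' @param patient_id optional patient identifier.
#' @return An object of class `pet_volume`.
#' @export
pet_volume <- function(suv, spacing_mm, patient_id = NA_character_) {
  if (!is.array(suv) || length(dim(suv)) != 3)
    abort("`suv` must be a 3-d array")
  if (any(dim(suv) < 2)) abort("volume must be at least 2 voxels per axis")
  if (anyNA(suv)) abort(sprintf("volume contains %d NA/NaN voxels", sum(is.na(suv))))
  n_neg <- sum(suv < 0)
  if (n_neg > 0) abort(sprintf("volume contains %d negative voxels", n_neg))
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) == 1) spacing_mm <- rep(spacing_mm, 3)
  if (length(spacing_mm) != 3 || any(!is.finite(spacing_mm)) || any(spacing_mm <= 0))
    abort("`spacing_mm` must be positive, length 1 or 3")
  structure(
    list(suv = suv, spacing_mm = spacing_mm, patient_id = patient_id),
    class = "pet_volume"
  )
}

#' @export
print.pet_volume <- function(x, ...) {
  d <- dim(x$suv)
  cat(sprintf(
    "<pet_volume> %s  %d x %d x %d voxels @ %.4g x %.4g x %.4g mm, SUV range [%.3g, %.3g]\n",
    x$patient_id, d[1], d[2], d[3],
    x$spacing_mm[1], x$spacing_mm[2], x$spacing_mm[3],
    min(x$suv), max(x$suv)
  ))
  invisible(x)
}

#' @export
dim.pet_volume <- function(x) dim(x$suv)

#' Read a PET volume from NIfTI
#'
#' Reads a NIfTI file written in the conventional `(x, y, z)` axis order and
#' permutes it into the internal `(z, y, x)` convention. Voxel values are not
#' modified.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param patient_id identifier attached to the volume (defaults to the file
#'   name without extension).
#' @return A [pet_volume].
#' @export
read_volume <- function(path, patient_id = NULL) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3) abort("expected a 3-d NIfTI volume")
  sp <- RNifti::pixdim(img)
  if (length(sp) < 3 || any(!is.finite(sp[1:3])) || any(sp[1:3] <= 0))
    abort("NIfTI header is missing valid voxel spacing")
  if (is.null(patient_id))
    patient_id <- sub("\\.nii(\\.gz)?$", "", basename(path))
  # file axes (x, y, z) -> internal (z, y, x)
  suv <- aperm(arr, c(3, 2, 1))
  pet_volume(suv, spacing_mm = rev(sp[1:3]), patient_id = patient_id)
}

#' Write a PET volume to NIfTI
#'
#' @param volume a [pet_volume].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "pet_volume"))
  arr <- aperm(volume$suv, c(3, 2, 1))  # internal (z,y,x) -> file (x,y,z)
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- rev(volume$spacing_mm)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Patient record table
#'
#' Validates a table of per-patient outcome labels and optional covariates.
#'
#' @param patient_id character vector of unique ids.
#' @param label outcome label, `"TTP0"` (no progression within 2 years) or
#'   `"TTP1"` (progression within 2 years).
#' @param ipi_score optional International Prognostic Index, integer 0-5.
#' @param glucose_mmol_per_l optional plasma glucose.
#' @return A tibble with one row per patient.
#' @export
patient_records <- function(patient_id, label, ipi_score = NA_integer_,
                            glucose_mmol_per_l = NA_real_) {
  if (anyDuplicated(patient_id)) abort("patient ids must be unique")
  label <- as.character(label)
  if (!all(label %in% c("TTP0", "TTP1")))
    abort("labels must be 'TTP0' or 'TTP1'")
  if (!all(is.na(ipi_score) | (ipi_score >= 0 & ipi_score <= 5)))
    abort("ipi_score must be in 0..5")
  tibble::tibble(
    patient_id = as.character(patient_id),
    label = label,
    ipi_score = as.integer(ipi_score),
    glucose_mmol_per_l = as.numeric(glucose_mmol_per_l)
  )
}

#' Scan-level quality control
#'
#' Applies the two scan-level criteria used for trial PET quality control:
#' the liver SUVmean must lie in `[1.3, 3.0]` and plasma glucose must be
#' strictly lower than 11 mmol/L. A criterion whose inputs are absent is
#' reported as `"not_evaluated"` rather than failed.
#'
#' @param volume a [pet_volume].
#' @param liver_roi integer vector of linear voxel indices of a liver region
#'   of interest, or `NULL`.
#' @param glucose_mmol_per_l plasma glucose, or `NA`.
#' @param liver_range inclusive SUVmean limits for the liver.
#' @param glucose_max exclusive upper limit for plasma glucose.
#' @return A `qc_result`: list with `pass` (logical; `NA` when nothing could
#'   be evaluated) and `checks`, a tibble of per-criterion outcomes.
#' @export
qc_check <- function(volume, liver_roi = NULL, glucose_mmol_per_l = NA,
                     liver_range = c(1.3, 3.0), glucose_max = 11) {
  stopifnot(inherits(volume, "pet_volume"))
  checks <- list()

  if (is.null(liver_roi) || length(liver_roi) == 0) {
    checks$liver <- list(status = "not_evaluated", value = NA_real_,
                         reason = "no liver ROI provided")
  } else {
    m <- mean(volume$suv[liver_roi])
    ok <- m >= liver_range[1] && m <= liver_range[2]
    checks$liver <- list(
      status = if (ok) "pass" else "fail", value = m,
      reason = if (ok) NA_character_ else
        sprintf("liver SUVmean out of range (%.2f not in [%.1f, %.1f])",
                m, liver_range[1], liver_range[2])
    )
  }

  if (is.na(glucose_mmol_per_l)) {
    checks$glucose <- list(status = "not_evaluated", value = NA_real_,
                           reason = "no glucose value provided")
  } else {
    ok <- glucose_mmol_per_l < glucose_max
    checks$glucose <- list(
      status = if (ok) "pass" else "fail", value = glucose_mmol_per_l,
      reason = if (ok) NA_character_ else
        sprintf("plasma glucose not lower than %g mmol/L", glucose_max)
    )
  }

  tab <- tibble::tibble(
    check = names(checks),
    status = unname(vapply(checks, `[[`, "", "status")),
    value = unname(vapply(checks, `[[`, 0, "value")),
    reason = unname(vapply(checks, `[[`, "", "reason"))
  )
  evaluated <- tab$status != "not_evaluated"
  pass <- if (!any(evaluated)) NA else all(tab$status[evaluated] == "pass")
  structure(list(pass = pass, checks = tab), class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  cat("<qc_result> pass:", x$pass, "\n")
  print(x$checks)
  invisible(x)
}

#' @rdname qc_check
#' @param x a `qc_result`.
#' @param ... unused.
#' @export
#' @method tidy qc_result
tidy.qc_result <- function(x, ...) x$checks
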