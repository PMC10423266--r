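#' MIP image on the fixed canvas
#'
#' A 2-d maximum-intensity-projection image on the fixed 275 x 200 pixel
#' canvas at 4 x 4 mm (110 x 80 cm field of view), as consumed by the CNN.
#'
#' @param pixels numeric matrix, exactly 275 x 200.
#' @param view `"coronal"` or `"sagittal"`.
#' @param variant one of `"mip"`, `"brain_removed"`, `"lesion"`,
#'   `"lesion_mask"`, `"ablated"`.
#' @param normalized whether pixel values are normalized to `[0, 1]`.
#' @return An object of class `mip_image`.
#' @export
mip_image <- function(pixels, view = c("coronal", "sagittal"),
                      variant = c("mip", "brain_removed", "lesion",
                                  "lesion_mask", "ablated"),
                      normalized = FALSE) {
  view <- match.arg(view)
  variant <- match.arg(variant)
  if (!is.matrix(pixels) || !identical(dim(pixels), as.integer(CANVAS_SHAPE)))
    abort(sprintf("canvas must be exactly %d x %d pixels", CANVAS_SHAPE[1], CANVAS_SHAPE[2]))
  if (normalized && (min(pixels) < 0 || max(pixels) > 1))
    abort("normalized image must have pixels in [0, 1]")
  if (variant == "lesion_mask" && !all(pixels %in% c(0, 1)))
    abort("lesion_mask variant must be binary")
  structure(list(pixels = pixels, view = view, variant = variant,
                 normalized = normalized, pixel_size_mm = CANVAS_PIXEL_MM),
            class = "mip_image")
}

#' @export
print.mip_image <- function(x, ...) {
  cat(sprintf("<mip_image> %s %s, %d x %d @ %g mm, %s, range [%.3g, %.3g]\n",
              x$view, x$variant, nrow(x$pixels), ncol(x$pixels),
              x$pixel_size_mm, if (x$normalized) "normalized" else "raw SUV",
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Maximum intensity projection at native resolution
#'
#' Collapses the anterior-posterior axis (coronal view) or the left-right
#' axis (sagittal view) by the per-ray maximum. Output rows run
#' cranio-caudally with the head at row 1.
#'
#' @param volume a [pet_volume].
#' @param view `"coronal"` or `"sagittal"`.
#' @return Numeric matrix `(cranio-caudal x transverse)` with an attached
#'   `spacing_mm` attribute `(row, column)` in mm.
#' @export
project <- function(volume, view = c("coronal", "sagittal")) {
  stopifnot(inherits(volume, "pet_volume"))
  view <- match.arg(view)
  v <- volume$suv
  collapse <- if (view == "coronal") 2L else 3L
  out <- if (collapse == 2L) {
    acc <- v[, 1, ]
    for (j in seq_len(dim(v)[2])[-1]) acc <- pmax(acc, v[, j, ])
    acc
  } else {
    acc <- v[, , 1]
    for (j in seq_len(dim(v)[3])[-1]) acc <- pmax(acc, v[, , j])
    acc
  }
  sp <- volume$spacing_mm
  attr(out, "spacing_mm") <- c(sp[1], if (view == "coronal") sp[3] else sp[2])
  out
}

# Bilinear (or nearest) resampling of a projection onto the fixed canvas.
# Source and canvas are aligned by their physical centres; when the source
# already has 4 mm pixels the embedding snaps to whole pixels so values pass
# through unchanged.
.to_canvas_pixels <- function(proj, spacing_mm, interp = "bilinear") {
  nr <- nrow(proj); nc <- ncol(proj)
  ext <- c(nr, nc) * spacing_mm
  canvas_ext <- CANVAS_SHAPE * CANVAS_PIXEL_MM
  if (any(ext > canvas_ext + 1e-6)) {
    over <- pmax(ext - canvas_ext, 0)
    abort(sprintf(
      "projection (%.0f x %.0f mm) exceeds the %.0f x %.0f mm canvas; would require cropping %.0f x %.0f mm",
      ext[1], ext[2], canvas_ext[1], canvas_ext[2], over[1], over[2]))
  }
  out <- matrix(0, CANVAS_SHAPE[1], CANVAS_SHAPE[2])
  if (all(abs(spacing_mm - CANVAS_PIXEL_MM) < 1e-9)) {
    r0 <- floor((CANVAS_SHAPE[1] - nr) / 2)
    c0 <- floor((CANVAS_SHAPE[2] - nc) / 2)
    out[r0 + seq_len(nr), c0 + seq_len(nc)] <- proj
    return(out)
  }
  # source index coordinate of each target pixel centre (centre-aligned)
  tr <- (seq_len(CANVAS_SHAPE[1]) - 0.5) * CANVAS_PIXEL_MM
  tc <- (seq_len(CANVAS_SHAPE[2]) - 0.5) * CANVAS_PIXEL_MM
  xr <- (tr - (canvas_ext[1] - ext[1]) / 2) / spacing_mm[1] + 0.5
  xc <- (tc - (canvas_ext[2] - ext[2]) / 2) / spacing_mm[2] + 0.5
  lookup <- function(I, J) {
    ok <- I >= 1 & I <= nr & J >= 1 & J <= nc
    v <- matrix(0, nrow(I), ncol(I))
    v[ok] <- proj[cbind(I[ok], J[ok])]
    v
  }
  if (interp == "nearest") {
    I <- matrix(round(xr), CANVAS_SHAPE[1], CANVAS_SHAPE[2])
    J <- matrix(round(xc), CANVAS_SHAPE[1], CANVAS_SHAPE[2], byrow = TRUE)
    return(lookup(I, J))
  }
  i0 <- floor(xr); fr <- xr - i0
  j0 <- floor(xc); fc <- xc - j0
  I0 <- matrix(i0, CANVAS_SHAPE[1], CANVAS_SHAPE[2])
  J0 <- matrix(j0, CANVAS_SHAPE[1], CANVAS_SHAPE[2], byrow = TRUE)
  FR <- matrix(fr, CANVAS_SHAPE[1], CANVAS_SHAPE[2])
  FC <- matrix(fc, CANVAS_SHAPE[1], CANVAS_SHAPE[2], byrow = TRUE)
  (1 - FR) * (1 - FC) * lookup(I0, J0) +
    FR * (1 - FC) * lookup(I0 + 1, J0) +
    (1 - FR) * FC * lookup(I0, J0 + 1) +
    FR * FC * lookup(I0 + 1, J0 + 1)
}

#' Place a projection on the fixed 275 x 200 canvas
#'
#' Resamples a native-resolution projection to 4 mm pixels (bilinear by
#' default; `"nearest"` keeps masks binary) and centres it on a zero-filled
#' 275 x 200 canvas. Projections physically larger than the 110 x 80 cm
#' canvas raise an error reporting the required crop.
#'
#' @param projection matrix from [project()] (or any 2-d grid).
#' @param spacing_mm source pixel spacing `(row, column)`; defaults to the
#'   `spacing_mm` attribute of `projection`.
#' @param view,variant metadata for the resulting [mip_image].
#' @param interp `"bilinear"` or `"nearest"`.
#' @return An unnormalized [mip_image].
#' @export
to_canvas <- function(projection, spacing_mm = NULL,
                      view = c("coronal", "sagittal"), variant = "mip",
                      interp = c("bilinear", "nearest")) {
  view <- match.arg(view)
  interp <- match.arg(interp)
  spacing_mm <- spacing_mm %||% attr(projection, "spacing_mm")
  if (is.null(spacing_mm)) abort("source spacing is required")
  if (length(spacing_mm) == 1) spacing_mm <- rep(spacing_mm, 2)
  px <- .to_canvas_pixels(unclass(projection), spacing_mm, interp)
  mip_image(px, view = view, variant = variant, normalized = FALSE)
}

#' Normalize a MIP by the fixed SUV cap
#'
#' Truncates pixel values at `suv_cap` (default SUV 40, chosen so that
#' normalization is not driven by high-uptake organs such as the bladder)
#' and divides by it, mapping the image into `[0, 1]`.
#'
#' @param image an unnormalized [mip_image].
#' @param suv_cap positive truncation value.
#' @return The normalized [mip_image].
#' @export
normalize_mip <- function(image, suv_cap = SUV_CAP) {
  stopifnot(inherits(image, "mip_image"))
  if (suv_cap <= 0) abort("`suv_cap` must be positive")
  if (image$normalized) abort("image is already normalized")
  image$pixels <- pmin(image$pixels, suv_cap) / suv_cap
  image$normalized <- TRUE
  image
}

#' Full-volume MIP on the normalized canvas
#'
#' Convenience wrapper: [project()] then [to_canvas()] then
#' [normalize_mip()], with truncation applied after resampling so the
#' interpolation sees raw SUV.
#'
#' @param volume a [pet_volume].
#' @param view `"coronal"` or `"sagittal"`.
#' @param variant metadata tag for the resulting image.
#' @param suv_cap normalization cap.
#' @return A normalized [mip_image].
#' @export
make_mip <- function(volume, view = c("coronal", "sagittal"), variant = "mip",
                     suv_cap = SUV_CAP) {
  view <- match.arg(view)
  normalize_mip(to_canvas(project(volume, view), view = view,
                          variant = variant), suv_cap)
}

.lesion_label_map <- function(volume, lesions) {
  m <- if (inherits(lesions, "lesion_set")) lesions$label_map else lesions
  stopifnot(identical(dim(m), dim(volume$suv)))
  m
}

#' Lesion MIP: projection of tumour voxels only
#'
#' Zeroes all non-lesion voxels, then projects, resamples and normalizes, so
#' tumour intensities are retained but physiological uptake (including the
#' bladder) is absent.
#'
#' @param volume a [pet_volume].
#' @param lesions a `lesion_set` or an integer/logical lesion label map
#'   aligned with the volume.
#' @param view `"coronal"` or `"sagittal"`.
#' @param suv_cap normalization cap.
#' @return A normalized [mip_image] of variant `"lesion"`.
#' @export
lesion_mip <- function(volume, lesions, view = c("coronal", "sagittal"),
                       suv_cap = SUV_CAP) {
  view <- match.arg(view)
  map <- .lesion_label_map(volume, lesions)
  v <- volume
  v$suv <- volume$suv * (map > 0)
  normalize_mip(to_canvas(project(v, view), view = view, variant = "lesion"),
                suv_cap)
}

#' Binary lesion-mask MIP
#'
#' Indicator of any lesion along each projection ray: carries tumour
#' location but not intensity. Nearest-neighbour resampling keeps the mask
#' binary.
#'
#' @inheritParams lesion_mip
#' @return A binary [mip_image] of variant `"lesion_mask"` (flagged
#'   normalized, values in `{0, 1}`).
#' @export
lesion_mask_mip <- function(volume, lesions, view = c("coronal", "sagittal")) {
  view <- match.arg(view)
  map <- .lesion_label_map(volume, lesions)
  v <- volume
  v$suv <- (map > 0) * 1
  img <- to_canvas(project(v, view), view = view, variant = "mip",
                   interp = "nearest")
  px <- (img$pixels > 0.5) * 1
  mip_image(px, view = view, variant = "lesion_mask", normalized = TRUE)
}

#' Remove the brain from a PET volume
#'
#' Deletes (zeroes) the connected supra-threshold (SUV > 3) component whose
#' centroid lies within the top 15% of the occupied cranio-caudal extent and
#' whose volume is within 0.5-2.5 L. Operating in 3-d before projection
#' keeps the coronal and sagittal brain-removed MIPs consistent. Scans
#' without a qualifying component (e.g. scans that do not include the head)
#' are returned unchanged with a notice. When a lesion label map is supplied
#' and lesion voxels fall inside the removed component (a lesion adjacent to
#' the brain merges with it), a truncation warning is raised, mirroring the
#' ~1% truncated-lesion failure mode seen with automated brain removal.
#'
#' @param volume a [pet_volume].
#' @param lesion_map optional integer lesion label map used to flag lesions
#'   truncated by the removal.
#' @param threshold_suv components are formed from voxels strictly above
#'   this SUV.
#' @param top_fraction head region as a fraction of the occupied extent.
#' @param volume_range_l acceptable brain volume in litres.
#' @return The [pet_volume] with the brain zeroed; attribute `notes` carries
#'   any notices, attribute `brain_removed` whether a component was deleted.
#' @export
remove_brain <- function(volume, lesion_map = NULL, threshold_suv = 3,
                         top_fraction = 0.15, volume_range_l = c(0.5, 2.5)) {
  stopifnot(inherits(volume, "pet_volume"))
  d <- dim(volume$suv)
  lab <- label_components_3d(volume$suv > threshold_suv, as.integer(d))
  occupied <- which(apply(volume$suv > 0, 1, any))
  notes <- character()
  removed <- FALSE
  if (length(occupied) && max(lab) > 0) {
    zcut <- min(occupied) + top_fraction * (max(occupied) - min(occupied))
    vox_l <- prod(volume$spacing_mm) / 1e6
    for (k in seq_len(max(lab))) {
      idx <- which(lab == k)
      vol_l <- length(idx) * vox_l
      if (vol_l < volume_range_l[1] || vol_l > volume_range_l[2]) next
      zc <- mean(arrayInd(idx, d)[, 1])
      if (zc > zcut) next
      if (!is.null(lesion_map) && any(lesion_map[idx] > 0)) {
        trunc_ids <- sort(unique(lesion_map[idx][lesion_map[idx] > 0]))
        msg <- sprintf("lesion(s) %s overlap the removed brain component (truncation risk)",
                       paste(trunc_ids, collapse = ", "))
        notes <- c(notes, msg)
        warn(msg)
      }
      volume$suv[idx] <- 0
      removed <- TRUE
      notes <- c(notes, sprintf("removed brain component: %.2f L, centroid row %.1f", vol_l, zc))
    }
  }
  if (!removed) {
    notes <- c(notes, "no qualifying brain component found; volume returned unchanged")
    inform(notes[length(notes)])
  }
  attr(volume, "brain_removed") <- removed
  attr(volume, "notes") <- notes
  volume
}

#' Replace tumour pixels by mean non-background intensity
#'
#' Simulates tumour-free scans for the plausibility analysis: pixels under
#' the lesion mask are replaced by the mean of in-body pixels (value > 0)
#' outside the mask; everything else is unchanged. Ablation is idempotent.
#'
#' @param mip a normalized [mip_image] (variant `"mip"` or
#'   `"brain_removed"`).
#' @param lesion_mask a binary [mip_image] of the same view.
#' @return An [mip_image] of variant `"ablated"`.
#' @export
ablate_tumours <- function(mip, lesion_mask) {
  stopifnot(inherits(mip, "mip_image"), inherits(lesion_mask, "mip_image"))
  if (mip$view != lesion_mask$view) abort("mip and mask views differ")
  if (lesion_mask$variant != "lesion_mask") abort("`lesion_mask` must be a lesion_mask MIP")
  if (!mip$normalized) abort("`mip` must be normalized")
  m <- lesion_mask$pixels > 0.5
  body <- mip$pixels > 0 & !m
  px <- mip$pixels
  if (any(m)) {
    if (!any(body)) abort("mask covers all non-background pixels; no reference intensity")
    px[m] <- mean(mip$pixels[body])
  }
  mip_image(px, view = mip$view, variant = "ablated", normalized = TRUE)
}

#' Plot a MIP image
#'
#' @param object a [mip_image].
#' @param ... unused.
#' @return A ggplot.
#' @export
#' @method autoplot mip_image
autoplot.mip_image <- function(object, ...) {
  df <- tibble::tibble(
    row = rep(seq_len(nrow(object$pixels)), times = ncol(object$pixels)),
    col = rep(seq_len(ncol(object$pixels)), each = nrow(object$pixels)),
    value = as.vector(object$pixels)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 name = if (object$normalized) "norm. SUV" else "SUV") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("%s %s MIP", object$view, object$variant),
                  x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
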