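#' Segment lesions by SUV threshold
#'
#' Voxels with `SUV >= threshold_suv` (inclusive, so boundary voxels are
#' kept) and not covered by `physiological_mask` are grouped into connected
#' components under 26-connectivity. Components are labelled in decreasing
#' voxel count; ties keep discovery (scan) order. Physiological uptake that
#' in clinical workflows is deleted manually (brain, bladder, ...) is
#' excluded here via the explicit mask argument.
#'
#' @param volume a [pet_volume].
#' @param threshold_suv segmentation threshold (> 0), default 4.0.
#' @param physiological_mask optional logical array (same shape) of voxels to
#'   exclude before labelling.
#' @param min_voxels drop components smaller than this many voxels
#'   (default 0: keep all).
#' @return A `lesion_set`: list with `label_map` (integer array, 0 =
#'   non-lesion), `lesions` (tibble: `id`, `voxel_count`, `volume_ml`,
#'   centroid in mm, `suv_peak`), `mtv_ml`, `dmax_bulk_cm`, and the threshold
#'   used. An empty result (no supra-threshold voxels) is legal.
#' @export
segment_lesions <- function(volume, threshold_suv = SUV_THRESHOLD,
                            physiological_mask = NULL, min_voxels = 0) {
  stopifnot(inherits(volume, "pet_volume"), threshold_suv > 0)
  d <- dim(volume$suv)
  mask <- volume$suv >= threshold_suv
  if (!is.null(physiological_mask)) {
    stopifnot(identical(dim(physiological_mask), d))
    mask <- mask & !physiological_mask
  }
  raw <- label_components_3d(as.logical(mask), as.integer(d))
  counts <- tabulate(raw)
  keep <- which(counts >= max(1, min_voxels))
  # relabel in decreasing voxel count, ties by discovery order
  ord <- keep[order(-counts[keep], keep)]
  label_map <- array(0L, d)
  sp <- volume$spacing_mm
  vox_ml <- prod(sp) / 1000
  n <- length(ord)
  rows <- vector("list", n)
  for (new_id in seq_len(n)) {
    idx <- which(raw == ord[new_id])
    label_map[idx] <- new_id
    ijk <- arrayInd(idx, d)
    ctr <- (colMeans(ijk) - 0.5) * sp
    rows[[new_id]] <- tibble::tibble(
      id = new_id, voxel_count = length(idx),
      volume_ml = length(idx) * vox_ml,
      z_mm = ctr[1], y_mm = ctr[2], x_mm = ctr[3],
      suv_peak = max(volume$suv[idx])
    )
  }
  lesions <- if (n > 0) dplyr::bind_rows(rows) else
    tibble::tibble(id = integer(), voxel_count = integer(),
                   volume_ml = numeric(), z_mm = numeric(), y_mm = numeric(),
                   x_mm = numeric(), suv_peak = numeric())
  out <- structure(
    list(label_map = label_map, lesions = lesions,
         mtv_ml = sum(lesions$volume_ml), dmax_bulk_cm = NA_real_,
         threshold_suv = threshold_suv, spacing_mm = sp),
    class = "lesion_set"
  )
  out$dmax_bulk_cm <- dmax_bulk(out)
  out
}

#' Lesion dissemination: Dmax_bulk
#'
#' Euclidean distance (cm) between the centroid of the largest lesion (by
#' volume; ties broken by lower label id) and the farthest other lesion
#' centroid. Zero when the set holds at most one lesion.
#'
#' @param lesions a `lesion_set` from [segment_lesions()].
#' @return Distance in cm.
#' @export
dmax_bulk <- function(lesions) {
  stopifnot(inherits(lesions, "lesion_set"))
  tab <- lesions$lesions
  if (nrow(tab) <= 1) return(0)
  largest <- tab$id[which.max(tab$volume_ml)]  # which.max: first of ties
  ctr <- as.matrix(tab[, c("z_mm", "y_mm", "x_mm")])
  ref <- ctr[tab$id == largest, ]
  max(sqrt(rowSums((ctr - matrix(ref, nrow(ctr), 3, byrow = TRUE))^2))) / 10
}

#' @export
print.lesion_set <- function(x, ...) {
  cat(sprintf("<lesion_set> %d lesions, MTV %.2f mL, Dmax_bulk %.2f cm (SUV >= %.2g)\n",
              nrow(x$lesions), x$mtv_ml, x$dmax_bulk_cm, x$threshold_suv))
  invisible(x)
}

#' @rdname segment_lesions
#' @param x a `lesion_set`.
#' @param ... unused.
#' @export
#' @method tidy lesion_set
tidy.lesion_set <- function(x, ...) x$lesions

#' @rdname segment_lesions
#' @export
#' @method glance lesion_set
glance.lesion_set <- function(x, ...) {
  tibble::tibble(n_lesions = nrow(x$lesions), mtv_ml = x$mtv_ml,
                 dmax_bulk_cm = x$dmax_bulk_cm, threshold_suv = x$threshold_suv)
}

#' Per-patient PET feature table
#'
#' Runs [segment_lesions()] on every phantom of a cohort, excluding the known
#' physiological organ masks, and returns one feature row per patient.
#'
#' @param cohort a `phantom_cohort` with rasterized volumes.
#' @param threshold_suv segmentation threshold.
#' @return Tibble with `patient_id`, `mtv_ml`, `dmax_bulk_cm`, `n_lesions`.
#' @export
cohort_features <- function(cohort, threshold_suv = SUV_THRESHOLD) {
  stopifnot(inherits(cohort, "phantom_cohort"))
  purrr::map_dfr(cohort$patients, function(p) {
    if (is.null(p$volume)) abort("cohort was generated with rasterize = FALSE")
    ls <- segment_lesions(p$volume, threshold_suv,
                          physiological_mask = p$truth$organ_mask)
    tibble::tibble(patient_id = p$volume$patient_id, mtv_ml = ls$mtv_ml,
                   dmax_bulk_cm = ls$dmax_bulk_cm, n_lesions = nrow(ls$lesions))
  })
}
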