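#' Class-balancing subset scheme
#'
#' Balances an imbalanced cohort (majority TTP0) by splitting the TTP0
#' patients into 5 near-equal strata and pairing each stratum with *all*
#' TTP1 patients. Each subset is then topped up with TTP0 patients borrowed
#' from distinct other strata so that its TTP0 count matches the size of the
#' largest stratum plus the borrow count; for the reference cohort of 244
#' TTP0 and 52 TTP1 this yields strata of 49/49/49/49/48, three borrowed
#' TTP0 per subset, and subsets A-D of 104 patients (52 TTP0 + 52 TTP1) with
#' subset E of 103 (51 TTP0 + 52 TTP1). A borrowed patient may be borrowed
#' by several subsets, but the borrows within one subset come from distinct
#' strata.
#'
#' @param records tibble with columns `patient_id` and `label`
#'   (`"TTP0"`/`"TTP1"`), e.g. from [patient_records()].
#' @param seed RNG seed; the partition is a function of (ids, labels, seed)
#'   only.
#' @param k_folds folds per subset for the attached cross-validation splits.
#' @return A `cohort_partition`: list with `subsets` (named list `A`-`E` of
#'   tibbles `patient_id`, `label`, `borrowed`), `folds` (per subset, a list
#'   of `k_folds` train/validation id pairs), `strata`, and `seed`.
#' @export
build_subsets <- function(records, seed = 1L, k_folds = 5L) {
  stopifnot(is.data.frame(records),
            all(c("patient_id", "label") %in% names(records)))
  ids0 <- records$patient_id[records$label == "TTP0"]
  ids1 <- records$patient_id[records$label == "TTP1"]
  n0 <- length(ids0); n1 <- length(ids1)
  if (n1 == 0) abort("no TTP1 patients")
  if (n1 >= n0) abort("scheme assumes TTP0 majority (n_TTP0 > n_TTP1)")

  n_sub <- 5L
  out <- withr::with_seed(as.integer(seed), {
    shuffled <- sample(ids0)
    base <- n0 %/% n_sub
    extras <- n0 %% n_sub
    sizes <- rep(base, n_sub) + c(rep(1L, extras), rep(0L, n_sub - extras))
    strata <- split(shuffled, rep(seq_len(n_sub), times = sizes))
    s_max <- max(sizes)
    n_borrow <- max(0L, n1 - s_max)

    subsets <- vector("list", n_sub)
    for (i in seq_len(n_sub)) {
      donors <- setdiff(seq_len(n_sub), i)
      take <- if (n_borrow <= length(donors)) sample(donors, n_borrow)
              else sample(rep(donors, length.out = n_borrow))
      borrowed <- vapply(take, function(d) sample(strata[[d]], 1), "")
      subsets[[i]] <- tibble::tibble(
        patient_id = c(strata[[i]], borrowed, ids1),
        label = c(rep("TTP0", sizes[i] + length(borrowed)), rep("TTP1", n1)),
        borrowed = c(rep(FALSE, sizes[i]), rep(TRUE, length(borrowed)),
                     rep(FALSE, n1)),
        donor_stratum = c(rep(NA_integer_, sizes[i]), as.integer(take),
                          rep(NA_integer_, n1))
      )
    }
    list(subsets = subsets, strata = strata)
  })
  names(out$subsets) <- LETTERS[seq_len(n_sub)]
  part <- structure(
    list(subsets = out$subsets, strata = out$strata, folds = NULL,
         seed = as.integer(seed), k_folds = as.integer(k_folds)),
    class = "cohort_partition"
  )
  part$folds <- lapply(seq_len(n_sub), function(i)
    make_folds(part, LETTERS[i], k = k_folds,
               seed = as.integer(seed) + 1000L * i))
  names(part$folds) <- LETTERS[seq_len(n_sub)]
  part
}

#' Label-stratified cross-validation folds for one subset
#'
#' Splits a subset into `k` folds, stratified by outcome label so the 50%
#' prevalence is preserved in both train (~80%) and validation (~20%)
#' partitions. Each patient appears in validation exactly once.
#'
#' @param partition a `cohort_partition` (or a tibble with `patient_id` and
#'   `label`).
#' @param subset_id subset letter, e.g. `"A"`.
#' @param k number of folds.
#' @param seed RNG seed for the fold assignment.
#' @return A list of `k` elements, each `list(train =, validation =)` of
#'   patient ids.
#' @export
make_folds <- function(partition, subset_id = "A", k = 5L, seed = 1L) {
  tab <- if (inherits(partition, "cohort_partition")) {
    if (!subset_id %in% names(partition$subsets))
      abort(sprintf("unknown subset '%s'", subset_id))
    partition$subsets[[subset_id]]
  } else partition
  stopifnot(all(c("patient_id", "label") %in% names(tab)))
  if (nrow(tab) < k) abort(sprintf("subset has %d patients, fewer than k = %d", nrow(tab), k))

  assign <- withr::with_seed(as.integer(seed), {
    fold_of <- stats::setNames(integer(nrow(tab)), tab$patient_id)
    offset <- 0L
    for (lab in c("TTP0", "TTP1")) {
      ids <- sample(tab$patient_id[tab$label == lab])
      nl <- length(ids)
      base <- nl %/% k
      e <- nl %% k
      # rotate which folds take the extra patient so fold sizes differ by <= 1
      extra_folds <- if (e > 0) ((offset + seq_len(e) - 1L) %% k) + 1L else integer()
      sizes <- rep(base, k) + as.integer(seq_len(k) %in% extra_folds)
      offset <- (offset + e) %% k
      fold_of[ids] <- rep(seq_len(k), times = sizes)
    }
    fold_of
  })
  lapply(seq_len(k), function(f) list(
    train = names(assign)[assign != f],
    validation = names(assign)[assign == f]
  ))
}

#' @export
print.cohort_partition <- function(x, ...) {
  cat("<cohort_partition> seed", x$seed, "\n")
  for (s in names(x$subsets)) {
    tab <- x$subsets[[s]]
    cat(sprintf("  %s: %3d patients (%d TTP0 / %d TTP1, %d borrowed)\n",
                s, nrow(tab), sum(tab$label == "TTP0"),
                sum(tab$label == "TTP1"), sum(tab$borrowed)))
  }
  invisible(x)
}

#' @rdname build_subsets
#' @param x a `cohort_partition`.
#' @param ... unused.
#' @export
#' @method tidy cohort_partition
tidy.cohort_partition <- function(x, ...) {
  purrr::imap_dfr(x$subsets, function(tab, nm)
    dplyr::mutate(tab, subset = nm, .before = 1))
}

#' Serialize / restore a partition
#'
#' Saves subset membership and fold assignments as JSON so the identical
#' partition can be reused across training schemes.
#'
#' @param partition a `cohort_partition`.
#' @param path JSON file path.
#' @return `path` invisibly; `read_partition()` returns the restored
#'   `cohort_partition`.
#' @export
write_partition <- function(partition, path) {
  stopifnot(inherits(partition, "cohort_partition"))
  obj <- list(
    seed = partition$seed, k_folds = partition$k_folds,
    strata = partition$strata,
    subsets = lapply(partition$subsets, as.list),
    folds = partition$folds
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_partition
#' @export
read_partition <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  chr <- function(x) as.character(unlist(x))
  subsets <- lapply(obj$subsets, function(s) tibble::tibble(
    patient_id = chr(s$patient_id),
    label = chr(s$label),
    borrowed = as.logical(unlist(s$borrowed)),
    donor_stratum = vapply(s$donor_stratum,
                           function(d) if (is.null(d)) NA_integer_ else as.integer(d),
                           0L)
  ))
  folds <- lapply(obj$folds, function(fl)
    lapply(fl, function(f) list(train = chr(f$train),
                                validation = chr(f$validation))))
  structure(list(subsets = subsets, strata = lapply(obj$strata, chr),
                 folds = folds, seed = as.integer(obj$seed),
                 k_folds = as.integer(obj$k_folds)),
            class = "cohort_partition")
}
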