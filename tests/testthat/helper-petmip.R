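# Shared fixtures, all generated in code.

# Small phantom spec for fast unit tests: 24 x 17.6 x 14.4 cm grid with
# scaled-down organs (the 50 mm brain of the default spec would not fit).
tiny_spec <- function(n_lesions = 3, seed = 1, ...) {
  phantom_spec(grid_shape = c(60, 44, 36), n_lesions = n_lesions,
               lesion_radius_range_mm = c(6, 10), brain_radius_mm = 20,
               bladder_radius_mm = 10, seed = seed, ...)
}

.fixture_env <- new.env(parent = emptyenv())

# memoised default-grid phantom (used by MIP and brain-removal tests)
default_phantom <- function(seed = 42) {
  key <- paste0("ph", seed)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- generate_phantom(phantom_spec(n_lesions = 4, seed = seed))
  .fixture_env[[key]]
}

# brute-force 26-connectivity flood fill (independent oracle for label_components_3d)
flood_fill_oracle <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  nxt <- 0L
  idx_of <- function(i, j, k) i + (j - 1L) * d[1] + (k - 1L) * d[1] * d[2]
  for (start in which(mask)) {
    if (lab[start] > 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      a <- arrayInd(v, d)
      for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
        if (dz == 0 && dy == 0 && dx == 0) next
        z <- a[1] + dz; y <- a[2] + dy; x <- a[3] + dx
        if (z < 1 || z > d[1] || y < 1 || y > d[2] || x < 1 || x > d[3]) next
        w <- idx_of(z, y, x)
        if (mask[w] && lab[w] == 0L) { lab[w] <- nxt; queue <- c(queue, w) }
      }
    }
  }
  lab
}

# exhaustive per-ray maximum (oracle for project())
project_oracle <- function(suv, view) {
  d <- dim(suv)
  if (view == "coronal") {
    out <- matrix(-Inf, d[1], d[3])
    for (z in 1:d[1]) for (x in 1:d[3]) out[z, x] <- max(suv[z, , x])
  } else {
    out <- matrix(-Inf, d[1], d[2])
    for (z in 1:d[1]) for (y in 1:d[2]) out[z, y] <- max(suv[z, y, ])
  }
  out
}

# all-pairs AUC (oracle for roc_auc())
auc_oracle <- function(scores, y) {
  pos <- scores[y == 1]; neg <- scores[y == 0]
  tot <- 0
  for (p in pos) for (n in neg) tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(pos) * length(neg))
}

# paired permutation test for an AUC difference (oracle for delong_test())
delong_perm_oracle <- function(a, b, y, n_perm = 20000, seed = 1) {
  obs <- abs(roc_auc(a, y) - roc_auc(b, y))
  n <- length(y)
  withr::with_seed(seed, {
    hits <- 0L
    for (r in seq_len(n_perm)) {
      flip <- runif(n) < 0.5
      ap <- ifelse(flip, b, a)
      bp <- ifelse(flip, a, b)
      if (abs(roc_auc(ap, y) - roc_auc(bp, y)) >= obs - 1e-12) hits <- hits + 1L
    }
    hits / n_perm
  })
}

# a normalized pseudo-random canvas image, for CNN input contracts
rand_mip <- function(seed, view = "coronal", variant = "mip") {
  withr::with_seed(seed, {
    px <- matrix(runif(275 * 200, 0, 0.5), 275, 200)
    mip_image(px, view = view, variant = variant, normalized = TRUE)
  })
}

# per-patient pairs of random MIPs for n patients
rand_mip_set <- function(ids, seed0 = 100) {
  out <- lapply(seq_along(ids), function(i) list(
    coronal = rand_mip(seed0 + 2 * i, "coronal"),
    sagittal = rand_mip(seed0 + 2 * i + 1, "sagittal")
  ))
  stats::setNames(out, ids)
}
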