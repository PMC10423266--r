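test_that("projection equals the exhaustive per-ray maximum", {
  for (seed in 1:4) {
    suv <- withr::with_seed(seed, array(runif(8 * 7 * 6, 0, 10), c(8, 7, 6)))
    v <- pet_volume(suv, 4)
    for (view in c("coronal", "sagittal")) {
      got <- project(v, view)
      expect_equal(unclass(got), project_oracle(suv, view),
                   ignore_attr = TRUE)
    }
  }

  # constant volume projects to a constant
  vc <- pet_volume(array(3, c(5, 5, 5)), 4)
  expect_true(all(project(vc, "coronal") == 3))

  # a single hot voxel lands at its (z, transverse) index
  suv <- array(1, c(6, 6, 6)); suv[2, 3, 5] <- 10
  v <- pet_volume(suv, 4)
  pc <- project(v, "coronal")
  expect_equal(pc[2, 5], 10)
  expect_equal(sum(pc == 10), 1)
  ps <- project(v, "sagittal")
  expect_equal(ps[2, 3], 10)
})

test_that("canvas placement is exact for 4 mm sources and resamples others", {
  # identity: a 275 x 200 source at 4 mm passes through unchanged
  src <- matrix(runif(275 * 200), 275, 200)
  img <- to_canvas(src, spacing_mm = c(4, 4))
  expect_identical(dim(img$pixels), as.integer(c(275, 200)))
  expect_equal(img$pixels, src)

  # smaller 4 mm sources are centred with zero padding
  small <- matrix(5, 50, 40)
  img2 <- to_canvas(small, spacing_mm = c(4, 4))
  expect_equal(sum(img2$pixels == 5), 50 * 40)
  nz <- which(img2$pixels > 0, arr.ind = TRUE)
  expect_equal(range(nz[, 1]), c(113, 162))

  # a 2 mm source occupies half the pixel extent after resampling
  fine <- matrix(7, 100, 80)  # 200 x 160 mm
  img3 <- to_canvas(fine, spacing_mm = c(2, 2))
  nz3 <- which(img3$pixels > 1e-9, arr.ind = TRUE)
  extent <- diff(range(nz3[, 1])) + 1
  expect_lt(abs(extent - 50), 2)
  expect_identical(dim(img3$pixels), as.integer(c(275, 200)))

  # sources physically larger than 110 x 80 cm error with the required crop
  expect_error(to_canvas(matrix(1, 300, 100), spacing_mm = c(4, 4)),
               "cropping")
})

test_that("normalization truncates at the SUV cap and maps it to 1", {
  px <- matrix(0, 275, 200)
  px[1, 1] <- 40; px[1, 2] <- 50; px[1, 3] <- 20
  img <- normalize_mip(mip_image(px, "coronal"))
  expect_equal(img$pixels[1, 1], 1.0)
  expect_equal(img$pixels[1, 2], 1.0)  # truncated above the cap
  expect_equal(img$pixels[1, 3], 0.5)
  expect_true(img$normalized)

  expect_error(normalize_mip(img), "already normalized")
  expect_error(normalize_mip(mip_image(px, "coronal"), suv_cap = 0), "positive")
})

test_that("lesion MIPs keep tumour intensity only; mask MIPs are binary over the same rays", {
  ph <- default_phantom()
  seg <- segment_lesions(ph$volume, physiological_mask = ph$truth$organ_mask)
  full <- make_mip(ph$volume, "coronal")
  lm <- lesion_mip(ph$volume, seg, "coronal")
  mk <- lesion_mask_mip(ph$volume, seg, "coronal")

  # the bladder (SUV 45) saturates the full MIP but is absent from lesion MIPs
  expect_equal(max(full$pixels), 1.0)
  expect_lte(max(lm$pixels), 20 / 40)

  # masking can only remove intensity
  expect_true(all(lm$pixels <= full$pixels + 1e-12))

  # mask support equals the support of the lesion MIP, and is binary
  expect_true(all(unique(as.vector(mk$pixels)) %in% c(0, 1)))
  expect_identical(mk$pixels > 0, lm$pixels > 0)

  # a phantom without lesions projects to all-zero lesion images
  ph0 <- generate_phantom(tiny_spec(n_lesions = 0, seed = 5))
  seg0 <- segment_lesions(ph0$volume, physiological_mask = ph0$truth$organ_mask)
  expect_true(all(lesion_mip(ph0$volume, seg0, "coronal")$pixels == 0))
  expect_true(all(lesion_mask_mip(ph0$volume, seg0, "sagittal")$pixels == 0))
})

test_that("brain removal zeroes only the qualifying head component", {
  ph <- default_phantom()
  out <- remove_brain(ph$volume)
  expect_true(attr(out, "brain_removed"))
  expect_true(all(out$suv[ph$truth$brain_mask] == 0))
  # lesions and bladder untouched
  les <- ph$truth$lesion_map > 0
  expect_identical(out$suv[les], ph$volume$suv[les])
  expect_identical(out$suv[ph$truth$bladder_mask],
                   ph$volume$suv[ph$truth$bladder_mask])

  # an already brainless scan comes back unchanged, with a notice
  no_brain <- ph$volume
  no_brain$suv[ph$truth$brain_mask] <- 0
  expect_message(out2 <- remove_brain(no_brain), "no qualifying brain")
  expect_false(attr(out2, "brain_removed"))
  expect_identical(out2$suv, no_brain$suv)

  # a lesion merged into the brain component is flagged as truncation risk
  fused <- ph$volume
  d <- dim(fused$suv)
  g <- petmip:::.phantom_geometry(ph$spec)
  ctr <- g$brain_c + c(ph$spec$brain_radius_mm + 6, 0, 0)
  fused$suv <- petmip:::.fill_sphere(fused$suv, d, 4, ctr, 10, 9)$arr
  lmap <- ph$truth$lesion_map
  lmap <- petmip:::.fill_sphere(lmap, d, 4, ctr, 10, 99L)$arr
  expect_warning(remove_brain(fused, lesion_map = lmap), "truncation risk")
})

test_that("tumour ablation replaces masked pixels by the mean in-body intensity", {
  px <- matrix(0, 275, 200)
  px[10, 1:3] <- c(0.025, 0.025, 0.05)   # body
  px[20, 1:2] <- c(0.2, 0.25)            # lesions
  mk <- matrix(0, 275, 200); mk[20, 1:2] <- 1
  mip <- mip_image(px, "coronal", normalized = TRUE)
  mask <- mip_image(mk, "coronal", variant = "lesion_mask", normalized = TRUE)
  ab <- ablate_tumours(mip, mask)
  expect_equal(ab$pixels[20, 1], mean(c(0.025, 0.025, 0.05)))
  expect_equal(ab$pixels[20, 2], mean(c(0.025, 0.025, 0.05)))
  expect_equal(ab$pixels[10, ], px[10, ])
  expect_equal(ab$variant, "ablated")

  # empty mask: identity
  empty <- mip_image(matrix(0, 275, 200), "coronal", variant = "lesion_mask",
                     normalized = TRUE)
  expect_equal(ablate_tumours(mip, empty)$pixels, px)

  # mask covering every non-background pixel: no reference intensity
  allmask <- mip_image((px > 0) * 1, "coronal", variant = "lesion_mask",
                       normalized = TRUE)
  expect_error(ablate_tumours(mip, allmask), "no reference intensity")

  # view mismatch is refused
  mask_s <- mip_image(mk, "sagittal", variant = "lesion_mask", normalized = TRUE)
  expect_error(ablate_tumours(mip, mask_s), "views differ")
})

test_that("ablation is idempotent and caps former lesion pixels at body level", {
  ph <- default_phantom()
  seg <- segment_lesions(ph$volume, physiological_mask = ph$truth$organ_mask)
  for (view in c("coronal", "sagittal")) {
    mip <- make_mip(ph$volume, view)
    mask <- lesion_mask_mip(ph$volume, seg, view)
    ab1 <- ablate_tumours(mip, mask)
    ab2 <- ablate_tumours(ab1, mask)
    expect_equal(ab1$pixels, ab2$pixels)
    body <- mip$pixels > 0 & !(mask$pixels > 0.5)
    expect_lte(max(ab1$pixels[mask$pixels > 0.5]), max(ab1$pixels[body]))
  }
})
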