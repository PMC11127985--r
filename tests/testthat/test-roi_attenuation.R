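test_that("volumetric estimator is the plain mask mean", {
  arr <- array(60, dim = c(6, 6, 4))
  ct <- ct_volume(arr, spacing_mm = c(1, 1, 1))
  mask <- cube_mask(2:4, 2:4, 2:3, dim = c(6, 6, 4))
  expect_equal(measure_volumetric(ct, mask)$value_hu, 60)

  # noise-free vesselized phantom: exact mixture of the two compartments
  ph <- generate_phantom(small_spec(parenchyma_mu_hu = 30, noise_sd_hu = 0,
                                    vessel_fraction = 0.05, seed = 1))
  expected <- 30 + ph$truth$realized_vessel_fraction * 45
  expect_equal(measure_volumetric(ph$volume, ph$truth$liver_mask)$value_hu,
               expected)

  # invariant under simultaneous flips of both grids
  d <- dim(ph$volume$data)
  fvol <- ct_volume(ph$volume$data[d[1]:1, , ], ph$volume$spacing_mm, "RPS")
  fmask <- binary_mask(ph$truth$liver_mask$data[d[1]:1, , ],
                       ph$volume$spacing_mm, "RPS")
  expect_equal(measure_volumetric(fvol, fmask)$value_hu, expected)

  expect_error(measure_volumetric(ct, cube_mask(1, 1, 1, dim = c(3, 3, 3))),
               "geometry mismatch")
  empty <- binary_mask(array(FALSE, c(6, 6, 4)), c(1, 1, 1))
  expect_error(measure_volumetric(ct, empty), "empty")
})

test_that("axial estimator picks the largest slice, ties to the lowest", {
  arr <- array(0, dim = c(10, 10, 4))
  arr[, , 2] <- 40; arr[, , 3] <- 50
  ct <- ct_volume(arr, spacing_mm = c(1, 1, 2.5))
  m <- array(FALSE, dim = c(10, 10, 4))
  m[1:5, 1:2, 2] <- TRUE              # 10 pixels
  m[1:5, 1:4, 3] <- TRUE              # 20 pixels
  mask <- binary_mask(m, spacing_mm = c(1, 1, 2.5))
  res <- measure_axial(ct, mask)
  expect_equal(res$value_hu, 50)
  expect_equal(res$slice_index, 3)

  # single-slice mask: axial equals volumetric
  m1 <- array(FALSE, dim = c(10, 10, 4)); m1[2:6, 2:6, 2] <- TRUE
  mask1 <- binary_mask(m1, spacing_mm = c(1, 1, 2.5))
  expect_equal(measure_axial(ct, mask1)$value_hu,
               measure_volumetric(ct, mask1)$value_hu)

  # equal areas: lowest slice index chosen
  m2 <- array(FALSE, dim = c(10, 10, 4))
  m2[1:5, 1:2, 2] <- TRUE; m2[1:5, 1:2, 3] <- TRUE
  res2 <- measure_axial(ct, binary_mask(m2, spacing_mm = c(1, 1, 2.5)))
  expect_equal(res2$slice_index, 2)
  expect_equal(res2$value_hu, 40)
})

test_that("ROI placement follows the leftmost + offset rule", {
  ph <- generate_phantom(small_spec(seed = 3, vessel_fraction = 0))
  mask <- ph$truth$liver_mask
  sp <- mask$spacing_mm
  params <- roi_params()
  rois <- select_parenchymal_rois(mask, params)
  expect_length(rois, 3)

  offset_px <- round(params$center_offset_mm / sp[1])
  for (roi in rois) {
    pix <- which(mask$data[, , roi$slice], arr.ind = TRUE)
    leftmost <- min(pix[, 1])
    expect_identical(roi$center[1] - leftmost, offset_px)
    expect_true(all(roi$pixels[, 1] >= 1))
    # disc area within 5% of 2 cm^2 and equal to the exhaustive lattice count
    expect_equal(nrow(roi$pixels), oracle_disc_pixel_count(roi$radius_mm, sp))
    expect_lt(abs(nrow(roi$pixels) * sp[1] * sp[2] - 200) / 200, 0.05)
    expect_true(roi$in_mask_fraction >= 0 && roi$in_mask_fraction <= 1)
  }

  slices <- sort(vapply(rois, `[[`, numeric(1), "slice"))
  expect_true(all(diff(slices) * sp[3] >= params$min_axial_separation_mm))
})

test_that("single-slice masks yield one ROI and an under-count warning", {
  arr <- array(FALSE, dim = c(80, 60, 6))
  arr[10:60, 10:50, 3] <- TRUE
  mask <- binary_mask(arr, spacing_mm = c(0.7, 0.7, 2.5))
  expect_warning(rois <- select_parenchymal_rois(mask), "1 of 3")
  expect_length(rois, 1)
})

test_that("an ROI that would leave the grid is an error naming the slice", {
  arr <- array(FALSE, dim = c(40, 12, 4))
  arr[2:38, 2:11, 2] <- TRUE          # too narrow for the disc
  mask <- binary_mask(arr, spacing_mm = c(0.7, 0.7, 2.5))
  expect_error(suppressWarnings(select_parenchymal_rois(mask)), "slice 2")
})

test_that("parenchymal estimator is exact on noise-free central phantoms", {
  ph <- generate_phantom(small_spec(parenchyma_mu_hu = 30, noise_sd_hu = 0,
                                    vessel_fraction = 0.05, seed = 2))
  res <- measure_parenchymal(ph$volume, ph$truth$liver_mask)
  expect_equal(res$value_hu, 30)
  expect_equal(res$method, "parenchymal")
  expect_length(res$rois, 3)
  # result is the unweighted mean of the per-ROI means
  expect_equal(res$value_hu,
               mean(vapply(res$rois, `[[`, numeric(1), "mean_hu")))
})

test_that("all three estimators agree on a constant-HU phantom", {
  ph <- generate_phantom(small_spec(parenchyma_mu_hu = 55, noise_sd_hu = 0,
                                    vessel_fraction = 0, background_hu = 55,
                                    seed = 1))
  v <- measure_volumetric(ph$volume, ph$truth$liver_mask)$value_hu
  a <- measure_axial(ph$volume, ph$truth$liver_mask)$value_hu
  p <- measure_parenchymal(ph$volume, ph$truth$liver_mask)$value_hu
  expect_equal(v, 55); expect_equal(a, 55); expect_equal(p, 55)
})

test_that("clip_to_mask restricts ROI pixels to the segmentation", {
  # slab only 12 pixels (8.4 mm) tall: the 7.98 mm radius disc pokes out
  arr <- array(FALSE, dim = c(80, 48, 8))
  arr[10:60, 20:31, c(2, 4, 6)] <- TRUE
  mask <- binary_mask(arr, spacing_mm = c(0.7, 0.7, 2.5))
  hu <- array(-500, dim = dim(arr))
  hu[arr] <- 30
  ct <- ct_volume(hu, spacing_mm = c(0.7, 0.7, 2.5))

  open_res <- measure_parenchymal(ct, mask, roi_params(clip_to_mask = FALSE))
  clip_res <- measure_parenchymal(ct, mask, roi_params(clip_to_mask = TRUE))
  # placement warnings are carried in the result, not re-signalled
  expect_match(paste(clip_res$warnings, collapse = "; "), "in-mask fraction")
  # clipped means ignore the -500 HU background beyond the contour
  expect_equal(clip_res$value_hu, 30)
  expect_lt(open_res$value_hu, 30)
  frac <- vapply(clip_res$rois, `[[`, numeric(1), "in_mask_fraction")
  expect_true(all(frac < 0.9))
})

test_that("steatosis categorization is strict at the threshold", {
  expect_identical(classify_steatosis(39.9), "steatosis")
  expect_identical(classify_steatosis(40.0), "normal")
  expect_identical(classify_steatosis(56.33), "normal")
  expect_identical(classify_steatosis(c(10, 40, 70)),
                   c("steatosis", "normal", "normal"))
  expect_identical(classify_steatosis(35, threshold_hu = 30), "normal")
  expect_error(classify_steatosis(NaN), "finite")
})
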