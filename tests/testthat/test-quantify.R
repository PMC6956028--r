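test_that("mask volume is voxel count times voxel volume", {
  arr <- array(0L, c(10, 10, 10))
  arr[sample(1000, 235)] <- 1L
  expect_equal(mask_volume_mm3(binary_mask(arr)), 235)
  arr2 <- array(0L, c(10, 10, 10))
  arr2[1:100] <- 1L
  expect_equal(mask_volume_mm3(binary_mask(arr2, c(0.7, 0.7, 0.7))),
               34.3, tolerance = 1e-9)
  expect_equal(mask_volume_mm3(binary_mask(array(0L, c(3, 3, 3)))), 0)
})

test_that("maximal cross-section picks the largest slice, lowest on ties", {
  arr <- array(0L, c(6, 6, 3))
  arr[1:3, 1, 1] <- 1L  # slice 1: 3 voxels
  arr[1:5, 1, 2] <- 1L  # slice 2: 5 voxels
  arr[1:4, 1, 3] <- 1L  # slice 3: 4 voxels
  got <- max_cross_section_mm2(binary_mask(arr))
  expect_equal(got$area_mm2, 5)
  expect_equal(got$slice_index, 1L)  # 0-based: second slice

  # tie: slices at indices 2 and 4 (0-based) with 5 voxels each
  arr2 <- array(0L, c(6, 6, 5))
  arr2[1:5, 1, 3] <- 1L
  arr2[1:5, 1, 5] <- 1L
  expect_equal(max_cross_section_mm2(binary_mask(arr2))$slice_index, 2L)

  one <- array(0L, c(4, 4, 4)); one[2, 3, 3] <- 1L
  got1 <- max_cross_section_mm2(binary_mask(one))
  expect_equal(got1$area_mm2, 1)
  expect_equal(got1$slice_index, 2L)

  # in-plane voxel area scales the result
  expect_equal(max_cross_section_mm2(
    binary_mask(arr, c(0.7, 0.7, 1)))$area_mm2, 5 * 0.49)

  expect_error(max_cross_section_mm2(binary_mask(array(0L, c(2, 2, 2)))),
               "empty")
})

test_that("manual-analog surface thresholds then measures", {
  tv <- toy_volume()  # 3x3x3 bright cuboid, fg = 127 over bg = 100
  slab <- binary_mask(array(1L, dim(tv$volume$values)))
  # threshold below the slab minimum: the slab's own cross-section
  lo <- manual_surface(tv$volume, 0, slab)
  expect_equal(lo$area_mm2, 100)
  # midway threshold isolates the cuboid: 3x3 in-plane
  mid <- manual_surface(tv$volume, 113.5, slab)
  expect_equal(mid$area_mm2, 9)
  expect_equal(mid$slice_index, 2L)
  # monotone: raising the threshold can only shrink the surface
  expect_lte(mid$area_mm2, lo$area_mm2)
  expect_error(manual_surface(tv$volume, 1000, slab), "threshold")
})

test_that("sphere ROI voxel counts follow center-distance membership", {
  grid <- image_volume(array(0, c(20, 20, 20)))
  # diameter 4.9 mm centered on a voxel center: 81 voxels (enumeration
  # of dx^2+dy^2+dz^2 <= 2.45^2)
  roi <- sphere_roi_mask(grid, center_mm = c(10.5, 10.5, 10.5),
                         diameter_mm = 4.9)
  expect_equal(sum(roi$values), 81)
  expect_equal(sum(roi$values), nrow(brute_sphere_offsets(2.45, c(1, 1, 1))))
  # diameter 1 mm: the center voxel only
  tiny <- sphere_roi_mask(grid, center_mm = c(10.5, 10.5, 10.5),
                          diameter_mm = 1)
  expect_equal(sum(tiny$values), 1)
  expect_error(sphere_roi_mask(grid, center_mm = c(100, 100, 100),
                               diameter_mm = 2), "intersect")
})

test_that("per-subject quantification implements the three normalizations", {
  tv <- toy_volume(dim = c(16, 16, 12))
  bg <- list(center_mm = c(12.5, 12.5, 4.5), diameter_mm = 3)
  rep0 <- quantify_subject(tv$volume, tv$mask, bg, subject_id = "s",
                           group = "PD")
  expect_equal(rep0$si_sn, 127)
  expect_equal(rep0$si_background, 100)
  expect_equal(rep0$si_norm, 1.27)           # SI_SN / SI_background
  expect_equal(rep0$volume_mm3, 27)
  expect_equal(rep0$surface_mm2, 9)
  expect_true(is.na(rep0$mv_mm3) && is.na(rep0$volume_norm))

  # si_sn == si_background gives exactly 1
  flat <- image_volume(array(100, dim(tv$volume$values)))
  repf <- quantify_subject(flat, tv$mask, bg)
  expect_equal(repf$si_norm, 1)

  # normalization formulas on reference numbers:
  # 235.1 / 6244.8 * 100 and 37.7 / 6244.8 * 1000
  mv_arr <- array(0L, dim(tv$volume$values))
  mv_arr[seq_len(1024)] <- 1L
  mv <- binary_mask(mv_arr)
  repm <- quantify_subject(tv$volume, tv$mask, bg, midbrain_mask = mv)
  expect_equal(repm$mv_mm3, 1024)
  expect_equal(repm$volume_norm, 27 / 1024 * 100)
  expect_equal(repm$surface_norm, 9 / 1024 * 1000)
  expect_equal(235.1 / 6244.8 * 100, 3.7647, tolerance = 1e-4)
  expect_equal(37.7 / 6244.8 * 1000, 6.0370, tolerance = 1e-4)

  # intensity scale invariance of SI_norm
  scaled <- image_volume(tv$volume$values * 3.7)
  expect_equal(quantify_subject(scaled, tv$mask, bg)$si_norm,
               rep0$si_norm, tolerance = 1e-12)

  # validation errors
  neg <- image_volume(tv$volume$values - 200)
  expect_error(quantify_subject(neg, tv$mask, bg), "positive")
  small <- binary_mask(array(1L, c(4, 4, 4)))
  expect_error(quantify_subject(tv$volume, small, bg), "grid")
})
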