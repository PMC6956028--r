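test_that("sphere offsets match brute-force enumeration and radius semantics", {
  # counts at 1 mm isotropic: 7 (r=1), 33 (r=2), then brute force beyond
  expect_equal(nrow(sphere_offsets(1, c(1, 1, 1))), 7)
  expect_equal(nrow(sphere_offsets(2, c(1, 1, 1))), 33)
  for (r in 1:5) for (sp in list(c(1, 1, 1), c(0.7, 0.7, 0.7))) {
    got <- sphere_offsets(r, sp)
    want <- brute_sphere_offsets(r, sp)
    expect_equal(nrow(got), nrow(want),
                 info = sprintf("r=%g spacing=%g", r, sp[1]))
  }
  # center always included, set symmetric under negation
  off <- sphere_offsets(3, c(1, 1, 1))
  expect_true(any(rowSums(abs(off)) == 0))
  key <- function(m) sort(apply(m, 1, paste, collapse = ","))
  expect_identical(key(off), key(-off))
  # coarse grid: no neighbor within 1 mm at 2 mm pitch
  expect_equal(nrow(sphere_offsets(1, c(2, 2, 2))), 1)
  # monotone neighborhood size in the radius
  sizes <- sapply(seq(0.5, 5, by = 0.5), function(r)
    nrow(sphere_offsets(r, c(1, 1, 1))))
  expect_true(all(diff(sizes) >= 0))
  expect_error(sphere_offsets(0, c(1, 1, 1)), "positive")
})

test_that("local statistics match hand values and a brute-force mean oracle", {
  off1 <- sphere_offsets(1, c(1, 1, 1))
  # constant volume: mean reproduces it, spread statistics vanish
  const <- image_volume(array(7, c(6, 6, 6)))
  expect_equal(local_statistic(const, off1, "mean")$values,
               array(7, c(6, 6, 6)))
  expect_equal(local_statistic(const, off1, "stdev")$values,
               array(0, c(6, 6, 6)))
  expect_equal(local_statistic(const, off1, "skewness")$values,
               array(0, c(6, 6, 6)))

  # 1D-like values (1,2,3) along one axis: radius-1 mean at center is 2
  arr <- array(0, c(3, 1, 1)); arr[, 1, 1] <- c(1, 2, 3)
  vol <- image_volume(arr)
  expect_equal(local_statistic(vol, off1, "mean")$values[2, 1, 1], 2.0)

  # random volume: exact agreement with the loop oracle, including the
  # truncated boundary neighborhoods
  set.seed(42)
  rnd <- image_volume(array(rnorm(5 * 4 * 6), c(5, 4, 6)))
  off2 <- sphere_offsets(2, c(1, 1, 1))
  expect_equal(local_statistic(rnd, off2, "mean")$values,
               brute_local_mean(rnd$values, off2), tolerance = 1e-12)

  # median/mad agree with stats::median on a hand-checkable neighborhood
  got_med <- local_statistic(vol, off1, "median")$values[2, 1, 1]
  expect_equal(got_med, 2)
  expect_error(local_statistic(rnd, off1, "mode"), "unknown statistic")
})

test_that("signature volumes have the declared feature order and z-scaling", {
  set.seed(7)
  vol <- image_volume(array(rnorm(10 * 10 * 8, 100, 10), c(10, 10, 8)))
  dom <- binary_mask(array(1L, c(10, 10, 8)))
  sig <- compute_signatures(vol, radii_mm = 1:5,
                            statistics = c("mean", "stdev", "median",
                                           "mad", "skewness", "kurtosis"),
                            domain = dom)
  expect_equal(nrow(sig$features), 30)  # 5 radii x 6 statistics
  expect_equal(ncol(sig$values), 30)
  # radius-major, statistic-minor ordering
  expect_equal(sig$features$radius_mm[1:6], rep(1, 6))
  expect_equal(sig$features$statistic[1:2], c("mean", "stdev"))
  # each feature z-normalizes over the domain
  expect_equal(unname(colMeans(sig$values)), rep(0, 30),
               tolerance = 1e-10)
  expect_equal(unname(apply(sig$values, 2, sd)), rep(1, 30),
               tolerance = 1e-10)

  # constant volume: zero-variance features are set to exactly 0
  sig0 <- compute_signatures(image_volume(array(5, c(6, 6, 6))),
                             domain = binary_mask(array(1L, c(6, 6, 6))))
  expect_true(all(sig0$values == 0))

  expect_error(compute_signatures(vol, domain = binary_mask(
    array(0L, c(10, 10, 8)))), "empty")
  expect_error(compute_signatures(vol, radii_mm = numeric(0),
                                  domain = dom), "non-empty")
})

test_that("feature maps are translation-equivariant away from boundaries", {
  set.seed(3)
  arr <- array(rnorm(12 * 12 * 12), c(12, 12, 12))
  vol <- image_volume(arr)
  shifted <- image_volume(arr[c(12, 1:11), , , drop = FALSE])
  off <- sphere_offsets(2, c(1, 1, 1))
  for (stat in c("mean", "stdev", "median")) {
    a <- local_statistic(vol, off, stat)$values
    b <- local_statistic(shifted, off, stat)$values
    # compare interior voxels whose radius-2 neighborhoods stay in bounds
    # in both arrays
    expect_equal(b[4:10, 4:9, 4:9], a[3:9, 4:9, 4:9], tolerance = 1e-12,
                 info = stat)
  }
})
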