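make_sig <- function(seed = 1, dim = c(8, 8, 6)) {
  set.seed(seed)
  vol <- image_volume(array(rnorm(prod(dim), 100, 10), dim))
  dom <- binary_mask(array(1L, dim))
  compute_signatures(vol, radii_mm = 1:2, statistics = c("mean", "median"),
                     domain = dom)
}

test_that("seed signatures average the seed voxels' signatures", {
  sig <- make_sig()
  one <- seed_signature(sig, c(3, 3, 3))
  row <- match(nmseg:::seed_linear_idx(matrix(c(3L, 3L, 3L), 1), sig$dim),
               sig$domain_idx)
  expect_equal(one, sig$values[row, ])
  two <- seed_signature(sig, rbind(c(3, 3, 3), c(4, 4, 4)))
  row2 <- match(nmseg:::seed_linear_idx(matrix(c(4L, 4L, 4L), 1), sig$dim),
                sig$domain_idx)
  expect_equal(two, (sig$values[row, ] + sig$values[row2, ]) / 2)
  expect_error(seed_signature(sig, c(100, 0, 0)), "outside")
})

test_that("correlation maps reproduce hand-computed Pearson values", {
  # build a 3-feature signature volume by hand around known vectors
  dim3 <- c(2, 2, 1)
  sig <- structure(list(
    values = rbind(c(1, 2, 3), c(1, 2, 2), c(3, 2, 1), c(2, 4, 6)),
    features = data.frame(radius_mm = 1:3, statistic = "mean"),
    domain = binary_mask(array(1L, dim3)),
    domain_idx = 1:4, spacing = c(1, 1, 1), dim = dim3, affine = NULL),
    class = "nm_signatures")
  cm <- correlation_map(sig, c(1, 2, 3))
  expect_equal(cm$values[1, 1, 1], 1)                 # identical vector
  expect_equal(cm$values[2, 2, 1], 1)                 # 2x scaling
  expect_equal(cm$values[2, 1, 1], sqrt(3) / 2)       # hand Pearson
  expect_equal(cm$values[1, 2, 1], -1)                # reversal

  # constant voxel signature maps to 0; outside-domain voxels map to -1
  sig$values[4, ] <- c(5, 5, 5)
  sig$domain_idx <- 1:3
  sig$values <- sig$values[1:3, ]
  sig$values[3, ] <- c(4, 4, 4)
  cm2 <- correlation_map(sig, c(1, 2, 3))
  expect_equal(cm2$values[1, 2, 1], 0)   # zero-variance voxel
  expect_equal(cm2$values[2, 2, 1], -1)  # outside domain sentinel

  expect_error(correlation_map(sig, c(2, 2, 2)), "zero variance")
})

test_that("thresholding is monotone and exact", {
  corr <- image_volume(array(c(0.2, 0.8, 0.95, -0.1, 0.5, 0.3),
                             c(3, 2, 1)))
  expect_equal(sum(threshold_mask(corr, 0.9)$values), 1)
  m_lo <- threshold_mask(corr, 0.3)$values
  m_hi <- threshold_mask(corr, 0.8)$values
  expect_true(all(m_hi <= m_lo))  # higher tau never adds voxels
  expect_error(threshold_mask(corr, 1.5), "\\(-1, 1]")
  expect_error(threshold_mask(corr, -1), "\\(-1, 1]")
})

test_that("otsu threshold maximizes between-class variance", {
  set.seed(5)
  x <- c(rnorm(400, 0, 0.5), rnorm(100, 5, 0.5))
  t <- otsu_threshold(x)
  expect_gt(t, 1)    # inside the gap between the two modes
  expect_lt(t, 4)
  # brute-force oracle: evaluate the between-class variance at every
  # candidate split of the sample and check no split beats the chosen one
  objective <- function(cut) {
    lo <- x[x < cut]; hi <- x[x >= cut]
    if (!length(lo) || !length(hi)) return(-Inf)
    length(lo) * length(hi) / length(x)^2 * (mean(lo) - mean(hi))^2
  }
  cand <- seq(min(x), max(x), length.out = 400)
  expect_gte(objective(t) + 1e-6, max(sapply(cand, objective)) * 0.999)
})

test_that("segmentation output contains seeds, stays in the domain, and is
           monotone in the threshold", {
  ph <- generate_phantom(phantom_spec(sn_volume_mm3 = 250, rng_seed = 31))
  sig <- compute_signatures(ph$volume, domain = ph$midbrain_truth)
  seg <- segment(ph$volume, segmentation_config(correlation_threshold = 0.8),
                 ph$meta$seeds, ph$midbrain_truth, sigvol = sig)
  for (s in ph$meta$seeds)
    expect_true(all(seg$values[nmseg:::seed_linear_idx(s, sig$dim)] == 1))
  expect_true(all(seg$values <= ph$midbrain_truth$values))

  seg_lo <- segment(ph$volume,
                    segmentation_config(correlation_threshold = 0.6),
                    ph$meta$seeds, ph$midbrain_truth, sigvol = sig)
  expect_true(all(seg$values <= seg_lo$values))

  # repeating identical seed iterations changes nothing (union idempotence)
  seg2 <- segment(ph$volume,
                  segmentation_config(correlation_threshold = 0.8),
                  c(ph$meta$seeds, ph$meta$seeds), ph$midbrain_truth,
                  sigvol = sig)
  expect_equal(seg2$values, seg$values)
})

test_that("component filtering keeps only seed-connected tissue", {
  ph <- generate_phantom(phantom_spec(sn_volume_mm3 = 300, rng_seed = 13))
  sig <- compute_signatures(ph$volume, domain = ph$midbrain_truth)
  left_only <- segment(ph$volume, segmentation_config(),
                       list(ph$meta$seeds[[1]]), ph$midbrain_truth,
                       sigvol = sig)
  # split the truth into its two blobs by the midline
  d <- sig$dim
  right_half <- array(0L, d)
  right_half[(d[1] %/% 2 + 1):d[1], , ] <- 1L
  right_sn <- ph$sn_truth$values * right_half
  # the right blob correlates with the left seed but must be excluded
  expect_equal(sum(left_only$values * right_sn), 0)
})

test_that("segmentation of a homogeneous blob stays within its halo", {
  ph <- generate_phantom(phantom_spec(sn_volume_mm3 = 300, rng_seed = 17))
  seg <- segment(ph$volume, segmentation_config(), ph$meta$seeds,
                 ph$midbrain_truth)
  # output within the truth dilated by the largest signature radius
  off5 <- sphere_offsets(5, c(1, 1, 1))
  dil <- local_statistic(image_volume(ph$sn_truth$values + 0), off5,
                         "mean")$values > 0
  expect_true(all(dil[seg$values == 1]))
})

test_that("noise-free phantoms are recovered up to composition effects", {
  ph <- generate_phantom(phantom_spec(sn_volume_mm3 = 300, rng_seed = 7,
                                      noise_sigma = 0))
  sig <- compute_signatures(ph$volume, domain = ph$midbrain_truth)
  # at tau = 0.99 nothing outside the truth is selected and every deep
  # interior voxel (truth eroded by 2 mm) is recovered
  strict <- segment(ph$volume,
                    segmentation_config(correlation_threshold = 0.99),
                    ph$meta$seeds, ph$midbrain_truth, sigvol = sig)
  expect_equal(sum(strict$values == 1 & ph$sn_truth$values == 0), 0)
  off2 <- sphere_offsets(2, c(1, 1, 1))
  interior <- local_statistic(image_volume(ph$sn_truth$values + 0), off2,
                              "mean")$values == 1
  expect_true(all(strict$values[interior] == 1))
  # the automatic threshold recovers the blob almost exactly
  auto <- segment(ph$volume, segmentation_config(), ph$meta$seeds,
                  ph$midbrain_truth, sigvol = sig)
  expect_gte(dice_coefficient(auto, ph$sn_truth), 0.9)
})

test_that("dice coefficient behaves at the boundaries", {
  a <- binary_mask(array(c(1L, 0L, 0L, 0L), c(2, 2, 1)))
  b <- binary_mask(array(c(1L, 1L, 0L, 0L), c(2, 2, 1)))
  expect_equal(dice_coefficient(a, a), 1)
  expect_equal(dice_coefficient(a, b), 2 / 3)
  z <- binary_mask(array(0L, c(2, 2, 1)))
  expect_equal(dice_coefficient(z, z), 1)
  expect_equal(dice_coefficient(a, z), 0)
})
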