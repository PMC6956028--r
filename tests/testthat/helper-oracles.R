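# Independent brute-force oracles used across the suite. These stay
# deliberately naive (triple loops, pair counting) so they cannot share a
# defect with the implementation they check.

# all integer offsets within radius_mm by direct enumeration over a cube
brute_sphere_offsets <- function(radius_mm, spacing_mm) {
  rng <- ceiling(radius_mm / min(spacing_mm)) + 1L
  out <- NULL
  for (dx in -rng:rng) for (dy in -rng:rng) for (dz in -rng:rng) {
    d <- sqrt((dx * spacing_mm[1])^2 + (dy * spacing_mm[2])^2 +
                (dz * spacing_mm[3])^2)
    if (d <= radius_mm + 1e-9) out <- rbind(out, c(dx, dy, dz))
  }
  out
}

# per-voxel neighborhood mean by explicit looping
brute_local_mean <- function(arr, offsets) {
  d <- dim(arr)
  out <- array(NA_real_, d)
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    acc <- c()
    for (o in seq_len(nrow(offsets))) {
      ii <- i + offsets[o, 1]; jj <- j + offsets[o, 2]
      kk <- k + offsets[o, 3]
      if (ii >= 1 && ii <= d[1] && jj >= 1 && jj <= d[2] &&
          kk >= 1 && kk <= d[3])
        acc <- c(acc, arr[ii, jj, kk])
    }
    out[i, j, k] <- mean(acc)
  }
  out
}

# Mann-Whitney AUC by pair counting: fraction of (positive, negative)
# pairs where the positive subject scores lower (ties worth 1/2)
brute_auc_lower_positive <- function(scores, labels, positive = "PD") {
  sp <- scores[labels == positive]
  sn <- scores[labels != positive]
  total <- 0
  for (a in sp) for (b in sn)
    total <- total + (a < b) + 0.5 * (a == b)
  total / (length(sp) * length(sn))
}

# small synthetic volume with a bright cuboid, for quantification tests
toy_volume <- function(dim = c(10, 10, 8), spacing = c(1, 1, 1),
                       bg = 100, fg = 127) {
  arr <- array(bg, dim)
  msk <- array(0L, dim)
  arr[4:6, 4:6, 3:5] <- fg
  msk[4:6, 4:6, 3:5] <- 1L
  list(volume = image_volume(arr, spacing),
       mask = binary_mask(msk, spacing))
}
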