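#' Segmentation configuration
#'
#' Bundles the parameters of the semi-automatic delineation: the signature
#' radii and statistics, the per-iteration correlation threshold, the
#' connectivity used to keep only seed-connected tissue, and a cap on the
#' number of seed iterations. The workflow the tool automates is
#' interactive threshold picking; here the threshold is an explicit number
#' in (-1, 1] (one global value or one per iteration) or one of two
#' automatic modes:
#'
#' * `"auto"` (default) — combines two independent automatic picks and
#'   takes their midpoint on the threshold grid. (i) Mask stability: the
#'   seed component's voxel count is swept over the grid and the
#'   threshold is placed just inside the flattest high-threshold region
#'   of the count-versus-threshold curve (the plateau between shedding
#'   correlated halo tissue and eroding the structure itself) — this
#'   automates what an operator does interactively, picking the threshold
#'   where the mask stops changing. (ii) Partial-volume matching: the
#'   structure's volume is estimated by an intensity-weighted sum over
#'   the neighborhood of a provisional core (boundary noise averages out
#'   over the region) and the threshold whose component count matches
#'   that estimate is taken.
#' * `"otsu"` — Otsu's method on the Fisher z-transform of the positive
#'   correlation values within the domain, mapped back to the correlation
#'   scale. (Anticorrelated voxels are certain non-targets; keeping them
#'   in the histogram makes the two-class split degenerate because the
#'   target occupies only a few percent of the domain.)
#'
#' @param radii_mm Sphere radii in mm (default 1:5).
#' @param statistics Local statistics composing the signature (default
#'   `c("mean", "median")`; see [compute_signatures()]).
#' @param correlation_threshold `"auto"`, `"otsu"`, a single number in
#'   (-1, 1], or one number per seed iteration.
#' @param connectivity Voxel connectivity for the seed-component filter:
#'   6, 18 or 26 (default 26).
#' @param max_iterations Maximum number of seed iterations (default 10).
#' @return An object of class `nm_seg_config`.
#' @export
segmentation_config <- function(radii_mm = 1:5,
                                statistics = nm_default_statistics,
                                correlation_threshold = "auto",
                                connectivity = 26,
                                max_iterations = 10) {
  if (!correlation_threshold[1L] %in% c("auto", "otsu")) {
    tau <- as.numeric(correlation_threshold)
    if (length(tau) < 1L || anyNA(tau) || any(tau <= -1 | tau > 1))
      stop("correlation thresholds must lie in (-1, 1]", call. = FALSE)
    correlation_threshold <- tau
  }
  if (!connectivity %in% c(6, 18, 26))
    stop("`connectivity` must be 6, 18 or 26", call. = FALSE)
  if (max_iterations < 1) stop("need at least one iteration",
                               call. = FALSE)
  structure(list(radii_mm = radii_mm, statistics = statistics,
                 correlation_threshold = correlation_threshold,
                 connectivity = as.integer(connectivity),
                 max_iterations = as.integer(max_iterations)),
            class = "nm_seg_config")
}

normalize_seed_spec <- function(seed_spec) {
  # accepts a single voxel triple, a matrix of voxels (one iteration), or
  # a list of such (one element per iteration); all indices 0-based
  as_vox_matrix <- function(x) {
    if (is.numeric(x) && is.null(dim(x)) && length(x) == 3L)
      x <- matrix(x, nrow = 1L)
    if (!is.matrix(x) || ncol(x) != 3L || nrow(x) == 0L)
      stop("seeds must be 0-based voxel index triples", call. = FALSE)
    storage.mode(x) <- "integer"
    x
  }
  if (is.list(seed_spec)) lapply(seed_spec, as_vox_matrix)
  else list(as_vox_matrix(seed_spec))
}

seed_linear_idx <- function(vox, dim) {
  if (any(vox < 0L) || any(sweep(vox, 2L, dim, ">=")))
    stop("seed voxel outside the image grid", call. = FALSE)
  1L + vox[, 1L] + dim[1L] * (vox[, 2L] + dim[2L] * vox[, 3L])
}

#' Mean signature of a seed voxel set
#'
#' Returns the component-wise mean of the signature vectors of the seed
#' voxels; a single seed returns that voxel's signature verbatim. All
#' seeds must lie inside the signature domain.
#'
#' @param sigvol An `nm_signatures` object from [compute_signatures()].
#' @param seed_voxels 0-based voxel index triples: a length-3 vector or an
#'   n x 3 matrix.
#' @return A numeric signature vector of length `nrow(sigvol$features)`.
#' @export
seed_signature <- function(sigvol, seed_voxels) {
  vox <- normalize_seed_spec(seed_voxels)[[1L]]
  lin <- seed_linear_idx(vox, sigvol$dim)
  rows <- match(lin, sigvol$domain_idx)
  if (anyNA(rows))
    stop("seed voxel(s) outside the signature domain", call. = FALSE)
  colMeans(sigvol$values[rows, , drop = FALSE])
}

#' Correlation of a signature against every voxel signature
#'
#' For every domain voxel, the Pearson correlation across the feature
#' components between that voxel's signature and the given one. Voxels
#' whose own signature has zero component variance map to 0; voxels
#' outside the domain map to -1, a sentinel below any usable threshold.
#'
#' @param sigvol An `nm_signatures` object.
#' @param signature Numeric signature vector of length F >= 3 with nonzero
#'   component variance (e.g. from [seed_signature()]).
#' @return An `nm_volume` of correlations in \[-1, 1\] (outside domain: -1).
#' @export
correlation_map <- function(sigvol, signature) {
  f <- nrow(sigvol$features)
  if (length(signature) != f)
    stop("signature length does not match the signature volume",
         call. = FALSE)
  if (f < 3L)
    stop("need at least 3 feature components for a correlation",
         call. = FALSE)
  sc <- signature - mean(signature)
  s_ss <- sum(sc^2)
  if (s_ss == 0)
    stop("seed signature has zero variance across components",
         call. = FALSE)
  x <- sigvol$values
  xc <- x - rowMeans(x)
  x_ss <- rowSums(xc^2)
  r <- as.vector(xc %*% sc) / sqrt(x_ss * s_ss)
  r[x_ss == 0] <- 0
  r <- pmin(1, pmax(-1, r))
  arr <- array(-1, sigvol$dim)
  arr[sigvol$domain_idx] <- r
  image_volume(arr, spacing = sigvol$spacing, affine = sigvol$affine)
}

#' Threshold a correlation map
#'
#' @param corr An `nm_volume` of correlations (from [correlation_map()]).
#' @param tau Threshold in (-1, 1]; voxels with correlation >= tau are
#'   selected.
#' @return An `nm_mask`.
#' @export
threshold_mask <- function(corr, tau) {
  if (length(tau) != 1L || is.na(tau) || tau <= -1 || tau > 1)
    stop("`tau` must lie in (-1, 1]", call. = FALSE)
  binary_mask(corr$values >= tau, spacing = corr$spacing,
              affine = corr$affine)
}

#' Otsu's threshold of a numeric sample
#'
#' Maximizes the between-class variance over a histogram of `x`; used to
#' automate the interactive correlation-threshold choice. Returns the
#' midpoint between the two classes' adjacent bin edges.
#'
#' @param x Numeric values (e.g. domain correlations).
#' @param n_bins Number of histogram bins (default 256).
#' @return The threshold value.
#' @export
otsu_threshold <- function(x, n_bins = 256) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) stop("no finite values", call. = FALSE)
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(findInterval(x, breaks, all.inside = TRUE), n_bins)
  p <- h / sum(h)
  mids <- (breaks[-1L] + breaks[-(n_bins + 1L)]) / 2
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  mu_t <- mu0[n_bins]
  w1 <- 1 - w0
  between <- (mu_t * w0 - mu0)^2 / (w0 * w1)
  between[!is.finite(between)] <- -Inf
  k <- which.max(between)
  breaks[k + 1L]
}

# Otsu-based correlation threshold: Otsu on the Fisher z-transform of the
# positive correlations (atanh stabilizes the variance of correlation
# coefficients and stretches the near-1 range where the target class
# lives), mapped back with tanh. Falls back to plain Otsu when no
# positive correlations exist.
otsu_corr_threshold <- function(corr_values) {
  v <- corr_values[is.finite(corr_values)]
  pos <- v[v > 0]
  if (length(pos) < 2L) return(otsu_threshold(v))
  tanh(otsu_threshold(atanh(pmin(pos, 1 - 1e-7))))
}

# Seed-component voxel counts over a threshold grid. All sweep masks are
# subsets of the lowest-tau mask, so the sweep is cropped to its bounding
# box (padded by 1) to keep the repeated labelling cheap.
sweep_seed_counts <- function(corr_arr, seed_lin, connectivity,
                              taus = seq(0.50, 0.96, by = 0.0125)) {
  d <- dim(corr_arr)
  cand <- corr_arr >= taus[1L]
  cand[seed_lin] <- TRUE
  ai <- which(cand, arr.ind = TRUE)
  lo <- pmax(apply(ai, 2L, min) - 1L, 1L)
  hi <- pmin(apply(ai, 2L, max) + 1L, d)
  sub <- corr_arr[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  si <- arrayInd(seed_lin, d)
  sub_seed <- 1L + (si[, 1] - lo[1]) +
    (hi[1] - lo[1] + 1L) * ((si[, 2] - lo[2]) +
                              (hi[2] - lo[2] + 1L) * (si[, 3] - lo[3]))
  nvox <- vapply(taus, function(tau) {
    m <- sub >= tau
    m[sub_seed] <- TRUE
    sum(keep_seed_components(array(as.integer(m), dim(sub)),
                             sub_seed, connectivity))
  }, numeric(1))
  list(taus = taus, nvox = nvox)
}

# Flattest high-tau plateau of the count-versus-threshold curve: the gap
# between shedding correlated halo tissue (low tau, steep) and eroding
# the structure itself (high tau, steep again). Returns a grid index.
plateau_pick <- function(nvox) {
  shrink <- -diff(log(nvox))            # per-step relative shrinkage
  w <- stats::filter(shrink, rep(1 / 5, 5), sides = 2)
  flat <- which(!is.na(w) & w <= min(w, na.rm = TRUE) + 0.005)
  max(max(flat) - 2L, 1L) + 1L
}

# one-voxel binary dilation / erosion under 6-connectivity
shift_bin <- function(a, dx) {
  d <- dim(a)
  out <- array(FALSE, d)
  sx <- max(1, 1 + dx[1]):min(d[1], d[1] + dx[1])
  sy <- max(1, 1 + dx[2]):min(d[2], d[2] + dx[2])
  sz <- max(1, 1 + dx[3]):min(d[3], d[3] + dx[3])
  out[sx - dx[1], sy - dx[2], sz - dx[3]] <- a[sx, sy, sz]
  out
}
face_offsets <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                      c(0, 0, 1), c(0, 0, -1))
dilate1 <- function(a) {
  r <- a
  for (k in 1:6) r <- r | shift_bin(a, face_offsets[k, ])
  r
}
erode1 <- function(a) {
  r <- a
  for (k in 1:6) r <- r & shift_bin(a, face_offsets[k, ])
  r
}

# Partial-volume-matched pick: estimate the structure's volume from the
# intensities around a provisional core (an intensity-weighted sum is
# insensitive to the exact boundary because boundary noise averages out
# over the region), then choose the grid threshold whose component count
# is closest to that estimate. Returns a grid index, or NA when the
# intensity contrast is degenerate.
pv_matched_pick <- function(sw, core, intensity, domain_arr) {
  region <- dilate1(dilate1(core)) & domain_arr
  core_int <- erode1(core)
  if (sum(core_int) < 10L) core_int <- core
  mu_sn <- mean(intensity[core_int])
  far <- domain_arr & !dilate1(region)
  if (!any(far)) far <- domain_arr & !region
  if (!any(far)) return(NA_integer_)
  mu_bg <- median(intensity[far])
  if (mu_sn - mu_bg <= .Machine$double.eps * abs(mu_sn))
    return(NA_integer_)
  v_pv <- sum((intensity[region] - mu_bg) / (mu_sn - mu_bg))
  which.min(abs(sw$nvox - v_pv))
}

# Automatic threshold = midpoint (on the grid) of the mask-stability
# plateau pick and the partial-volume-matched pick; their error sources
# (histogram shape noise versus regional intensity noise) are largely
# independent, so the average is noticeably more stable than either.
auto_threshold <- function(corr_arr, seed_lin, connectivity, intensity,
                           domain_arr) {
  sw <- sweep_seed_counts(corr_arr, seed_lin, connectivity)
  k1 <- plateau_pick(sw$nvox)
  m <- corr_arr >= sw$taus[k1]
  m[seed_lin] <- TRUE
  core <- keep_seed_components(array(as.integer(m), dim(corr_arr)),
                               seed_lin, connectivity) == 1L
  k2 <- pv_matched_pick(sw, core, intensity, domain_arr)
  k <- if (is.na(k2)) k1 else as.integer(round((k1 + k2) / 2))
  sw$taus[k]
}

keep_seed_components <- function(mask_arr, seed_lin, connectivity) {
  labels <- label_components_cpp(as.integer(mask_arr), dim(mask_arr),
                                 connectivity)
  seed_labels <- setdiff(unique(labels[seed_lin]), 0L)
  out <- array(0L, dim(mask_arr))
  if (length(seed_labels)) out[labels %in% seed_labels] <- 1L
  out
}

#' Semi-automatic signature-correlation segmentation
#'
#' Implements the iterative delineation: for each seed iteration, the mean
#' signature of the iteration's seed voxels is correlated against every
#' domain voxel's signature, the correlation map is thresholded, only the
#' connected component(s) containing the seeds are kept, and the result is
#' unioned with the accumulated mask. Iterating with additional seeds
#' grows the mask until the structure is covered; the output always
#' contains every seed voxel and is always a subset of the domain.
#'
#' @param volume An [image_volume()].
#' @param config An [segmentation_config()] object.
#' @param seed_spec Seeds, one entry per iteration: a list of 0-based
#'   voxel index matrices (or a single matrix / triple for one iteration).
#' @param domain A [binary_mask()] restricting the segmentation (e.g. the
#'   midbrain); signatures are computed and correlated only there.
#' @param sigvol Optional precomputed `nm_signatures` (must match `volume`
#'   and `domain`); saves recomputation across calls.
#' @return An `nm_mask` with attributes `thresholds` (the per-iteration
#'   thresholds actually used) and `iterations`.
#' @examples
#' ph <- generate_phantom(phantom_spec(noise_sigma = 0.05, rng_seed = 1))
#' seg <- segment(ph$volume, segmentation_config(),
#'                seed_spec = ph$meta$seeds, domain = ph$midbrain_truth)
#' dice_coefficient(seg, ph$sn_truth)
#' @export
segment <- function(volume, config = segmentation_config(), seed_spec,
                    domain, sigvol = NULL) {
  seeds <- normalize_seed_spec(seed_spec)
  if (length(seeds) > config$max_iterations)
    stop(sprintf("seed list has %d iterations but max_iterations = %d",
                 length(seeds), config$max_iterations), call. = FALSE)
  tau_spec <- config$correlation_threshold
  if (is.numeric(tau_spec) && length(tau_spec) > 1L &&
      length(tau_spec) != length(seeds))
    stop("per-iteration thresholds must match the number of iterations",
         call. = FALSE)
  if (is.null(sigvol))
    sigvol <- compute_signatures(volume, radii_mm = config$radii_mm,
                                 statistics = config$statistics,
                                 domain = domain)
  acc <- array(0L, sigvol$dim)
  taus <- numeric(length(seeds))
  for (i in seq_along(seeds)) {
    sig <- seed_signature(sigvol, seeds[[i]])
    cmap <- correlation_map(sigvol, sig)
    seed_lin <- seed_linear_idx(seeds[[i]], sigvol$dim)
    tau <- if (identical(tau_spec, "auto")) {
      auto_threshold(cmap$values, seed_lin, config$connectivity,
                     volume$values, domain$values == 1L)
    } else if (identical(tau_spec, "otsu")) {
      otsu_corr_threshold(cmap$values[sigvol$domain_idx])
    } else if (length(tau_spec) == 1L) tau_spec else tau_spec[i]
    taus[i] <- tau
    th <- threshold_mask(cmap, tau)
    th$values[seed_lin] <- 1L  # the seed is in its own component
    comp <- keep_seed_components(th$values, seed_lin, config$connectivity)
    if (sum(comp) == length(seed_lin))
      warning(sprintf(
        "iteration %d: threshold %.3f kept no voxels beyond the seed(s)",
        i, tau))
    acc[comp == 1L] <- 1L
  }
  acc[domain$values == 0L] <- 0L
  # seeds are guaranteed in the output even if domain-clipped above
  for (i in seq_along(seeds))
    acc[seed_linear_idx(seeds[[i]], sigvol$dim)] <- 1L
  out <- binary_mask(acc, spacing = sigvol$spacing, affine = sigvol$affine)
  attr(out, "thresholds") <- taus
  attr(out, "iterations") <- length(seeds)
  out
}

#' Dice overlap coefficient of two masks
#'
#' 2|A intersect B| / (|A| + |B|); 1 for identical non-empty masks. Two
#' empty masks have Dice 1 by convention.
#'
#' @param a,b `nm_mask` objects on the same grid.
#' @return The Dice coefficient in \[0, 1\].
#' @export
dice_coefficient <- function(a, b) {
  stopifnot_same_grid(a, b, "masks")
  na <- sum(a$values)
  nb <- sum(b$values)
  if (na + nb == 0L) return(1)
  2 * sum(a$values == 1L & b$values == 1L) / (na + nb)
}
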