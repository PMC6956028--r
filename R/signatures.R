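#' @title Multi-scale local-statistics signatures
#'
#' @description
#' The segmentation in this package does not classify voxels by raw
#' intensity. Instead every voxel gets a *signature*: a vector of local
#' statistics of its neighborhood, computed over spherical masks at several
#' radii (default 1--5 mm). Stacking these feature maps yields a 4D volume
#' whose 4th dimension is the signature; segmentation then works by
#' correlating a seed voxel's signature against all others.
#'
#' @name signatures
NULL

nm_statistics <- c("mean", "stdev", "median", "mad", "skewness", "kurtosis")

# Default signature: location statistics only. Across the five radii these
# form a multi-scale radial intensity profile; spread and shape statistics
# are noise-dominated at these neighborhood sizes and dilute the pattern
# correlation (see the methods vignette).
nm_default_statistics <- c("mean", "median")

stat_code <- function(statistic) {
  code <- match(statistic, nm_statistics)
  if (anyNA(code))
    stop(sprintf("unknown statistic(s): %s; choose from %s",
                 paste(statistic[is.na(code)], collapse = ", "),
                 paste(nm_statistics, collapse = ", ")), call. = FALSE)
  as.integer(code)
}

#' Integer voxel offsets of a spherical neighborhood
#'
#' Enumerates every integer offset (dx, dy, dz) whose center-to-center
#' physical distance sqrt((dx sx)^2 + (dy sy)^2 + (dz sz)^2) is at most
#' `radius_mm`. Membership is inclusive (<=), so counts are exactly
#' reproducible; the center offset (0,0,0) is always included and the set
#' is symmetric under negation.
#'
#' @param radius_mm Sphere radius in mm (> 0).
#' @param spacing_mm Voxel spacing in mm (3 positive reals).
#' @return An integer matrix with one row per offset and columns
#'   `dx, dy, dz`.
#' @examples
#' nrow(sphere_offsets(1, c(1, 1, 1)))  # 7: center + 6 face neighbors
#' nrow(sphere_offsets(2, c(1, 1, 1)))  # 33
#' @export
sphere_offsets <- function(radius_mm, spacing_mm = c(1, 1, 1)) {
  if (length(radius_mm) != 1L || is.na(radius_mm) || radius_mm <= 0)
    stop("`radius_mm` must be a single positive number", call. = FALSE)
  check_spacing(spacing_mm)
  rng <- floor(radius_mm / spacing_mm)
  g <- expand.grid(dx = -rng[1]:rng[1], dy = -rng[2]:rng[2],
                   dz = -rng[3]:rng[3])
  d2 <- (g$dx * spacing_mm[1])^2 + (g$dy * spacing_mm[2])^2 +
    (g$dz * spacing_mm[3])^2
  m <- as.matrix(g[d2 <= radius_mm^2 + 1e-9, , drop = FALSE])
  storage.mode(m) <- "integer"
  dimnames(m) <- list(NULL, c("dx", "dy", "dz"))
  m
}

#' Local statistic of a spherical neighborhood, per voxel
#'
#' For every voxel, gathers the values at the in-bounds neighbor positions
#' given by `offsets` (the neighborhood is truncated at the image boundary,
#' never padded) and computes one statistic of them. The standard deviation
#' and MAD of a single-voxel neighborhood are 0; skewness and kurtosis of a
#' constant or single-voxel neighborhood are defined as 0. Skewness is the
#' population moment ratio m3/m2^1.5 and kurtosis the excess m4/m2^2 - 3;
#' the MAD is the unscaled median absolute deviation from the median.
#'
#' @param volume An [image_volume()].
#' @param offsets Offset matrix from [sphere_offsets()].
#' @param statistic One of `"mean"`, `"stdev"`, `"median"`, `"mad"`,
#'   `"skewness"`, `"kurtosis"`.
#' @return An `nm_volume` of the same geometry holding the statistic map.
#' @export
local_statistic <- function(volume, offsets, statistic) {
  if (!inherits(volume, "nm_volume")) stop("`volume` must be an nm_volume",
                                           call. = FALSE)
  if (!is.matrix(offsets) || ncol(offsets) != 3L || nrow(offsets) == 0L)
    stop("`offsets` must be a non-empty 3-column matrix", call. = FALSE)
  code <- stat_code(statistic)
  if (length(code) != 1L) stop("give a single statistic", call. = FALSE)
  d <- dim(volume$values)
  vals <- local_stats_cpp(as.vector(volume$values), as.integer(d),
                          apply(offsets, 2L, as.integer), code,
                          0:(prod(d) - 1L))
  image_volume(array(vals[, 1L], d), spacing = volume$spacing,
               affine = volume$affine)
}

#' Build the signature volume
#'
#' Computes every (radius, statistic) feature map over the voxels of
#' `domain`, then z-normalizes each feature over the domain (subtract the
#' domain mean, divide by the domain standard deviation; a zero-variance
#' feature is set to 0 everywhere). Features are ordered radius-major,
#' statistic-minor, and the order is recorded in the result, so signatures
#' are comparable across volumes processed with the same configuration.
#'
#' @param volume An [image_volume()].
#' @param radii_mm Sphere radii in mm, sorted ascending (default 1:5).
#' @param statistics Character vector of statistics (default
#'   `c("mean", "median")`; all of `"mean"`, `"stdev"`, `"median"`,
#'   `"mad"`, `"skewness"`, `"kurtosis"` are available, see
#'   [local_statistic()]).
#' @param domain A [binary_mask()] of the voxels for which signatures are
#'   defined (typically a midbrain mask). Must be non-empty.
#' @return An object of class `nm_signatures`: list with `values` (matrix,
#'   one row per domain voxel, one column per feature), `features`
#'   (data.frame of radius_mm and statistic), `domain` (the mask),
#'   `domain_idx` (1-based linear indices of domain voxels), `spacing` and
#'   `dim`.
#' @export
compute_signatures <- function(volume, radii_mm = 1:5,
                               statistics = nm_default_statistics,
                               domain) {
  if (!inherits(volume, "nm_volume")) stop("`volume` must be an nm_volume",
                                           call. = FALSE)
  if (length(radii_mm) == 0L || any(diff(radii_mm) < 0))
    stop("`radii_mm` must be non-empty and sorted ascending",
         call. = FALSE)
  if (length(statistics) == 0L) stop("`statistics` must be non-empty",
                                     call. = FALSE)
  codes <- stat_code(statistics)
  if (!inherits(domain, "nm_mask")) stop("`domain` must be an nm_mask",
                                         call. = FALSE)
  stopifnot_same_grid(volume, domain, "volume and domain")
  domain_idx <- which(domain$values == 1L)
  if (length(domain_idx) == 0L) stop("`domain` is empty", call. = FALSE)

  d <- dim(volume$values)
  vox0 <- as.integer(domain_idx - 1L)
  blocks <- lapply(radii_mm, function(r) {
    off <- sphere_offsets(r, volume$spacing)
    local_stats_cpp(as.vector(volume$values), as.integer(d), off, codes,
                    vox0)
  })
  values <- do.call(cbind, blocks)

  # z-normalize each feature over the domain
  mu <- colMeans(values)
  sg <- apply(values, 2L, sd)
  values <- sweep(values, 2L, mu, "-")
  nonzero <- sg > 0
  values[, nonzero] <- sweep(values[, nonzero, drop = FALSE], 2L,
                             sg[nonzero], "/")
  values[, !nonzero] <- 0

  features <- data.frame(
    radius_mm = rep(radii_mm, each = length(statistics)),
    statistic = rep(statistics, times = length(radii_mm)),
    stringsAsFactors = FALSE)
  structure(list(values = values, features = features, domain = domain,
                 domain_idx = domain_idx, spacing = volume$spacing,
                 dim = d, affine = volume$affine),
            class = "nm_signatures")
}

#' @export
print.nm_signatures <- function(x, ...) {
  cat(sprintf(
    "<nm_signatures> %d features (%d radii x %d statistics) on %d voxels\n",
    nrow(x$features), length(unique(x$features$radius_mm)),
    length(unique(x$features$statistic)), length(x$domain_idx)))
  invisible(x)
}

#' Export signatures as a 4D NIfTI image
#'
#' Writes the signature volume as a 4D image for inspection (voxels outside
#' the domain are 0); the feature order is radius-major, statistic-minor as
#' in `sigvol$features`.
#'
#' @param sigvol An `nm_signatures` object.
#' @param path Output NIfTI path.
#' @return The path, invisibly.
#' @export
write_signatures <- function(sigvol, path) {
  arr <- array(0, c(sigvol$dim, nrow(sigvol$features)))
  nvox <- prod(sigvol$dim)
  for (f in seq_len(nrow(sigvol$features)))
    arr[(f - 1L) * nvox + sigvol$domain_idx] <- sigvol$values[, f]
  img <- RNifti::asNifti(arr, datatype = "float")
  RNifti::pixdim(img) <- c(sigvol$spacing, 1)
  RNifti::writeNifti(img, path)
  invisible(path)
}
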