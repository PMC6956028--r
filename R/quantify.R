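#' Mask volume in mm^3
#'
#' Voxel count times voxel volume (the product of the three spacings).
#' An empty mask has volume 0.
#'
#' @param mask A [binary_mask()].
#' @return Volume in mm^3.
#' @export
mask_volume_mm3 <- function(mask) {
  if (!inherits(mask, "nm_mask")) stop("`mask` must be an nm_mask",
                                       call. = FALSE)
  sum(mask$values) * prod(mask$spacing)
}

#' Maximal cross-sectional area of a mask
#'
#' For every slice perpendicular to `axis`, the area is the in-slice voxel
#' count times the in-plane voxel area; the maximum area and its 0-based
#' slice index are returned, ties broken by the lowest slice index. This is
#' the volumetric analog of reading the surface at the level of highest
#' hyperintensity: taking the maximum over all slices generalizes the
#' manual rule of quantifying at more levels and keeping the largest.
#'
#' @param mask A non-empty [binary_mask()].
#' @param axis Array axis perpendicular to the slices, 1, 2 or 3 (default
#'   3, the inferior-superior axis, i.e. axial slices).
#' @return A list with `area_mm2` and `slice_index` (0-based).
#' @export
max_cross_section_mm2 <- function(mask, axis = 3) {
  if (!inherits(mask, "nm_mask")) stop("`mask` must be an nm_mask",
                                       call. = FALSE)
  if (!axis %in% 1:3) stop("`axis` must be 1, 2 or 3", call. = FALSE)
  if (sum(mask$values) == 0L)
    stop("mask is empty: no cross-section", call. = FALSE)
  counts <- apply(mask$values, axis, sum)
  in_plane <- prod(mask$spacing[-axis])
  k <- which.max(counts)  # which.max takes the first (lowest) on ties
  list(area_mm2 = counts[k] * in_plane, slice_index = as.integer(k - 1L))
}

#' Manual-analog thresholded surface
#'
#' Models the manual windowing procedure — adjusting contrast/brightness
#' until only the hyperintense nucleus remains visible — as a single
#' intensity threshold applied within a slab mask, followed by
#' [max_cross_section_mm2()].
#'
#' @param volume An [image_volume()].
#' @param intensity_threshold Voxels with intensity >= this value (within
#'   the slab) count as nucleus.
#' @param slab A non-empty [binary_mask()] restricting the measurement
#'   (e.g. the midbrain).
#' @param axis Slice axis passed to [max_cross_section_mm2()].
#' @return A list with `area_mm2` and `slice_index`.
#' @export
manual_surface <- function(volume, intensity_threshold, slab, axis = 3) {
  stopifnot_same_grid(volume, slab, "volume and slab")
  if (sum(slab$values) == 0L) stop("slab is empty", call. = FALSE)
  sel <- volume$values >= intensity_threshold & slab$values == 1L
  if (!any(sel))
    stop("intensity threshold exceeds the slab maximum: empty result",
         call. = FALSE)
  max_cross_section_mm2(binary_mask(sel, spacing = volume$spacing,
                                    affine = volume$affine), axis = axis)
}

#' Spherical region of interest as a voxel mask
#'
#' Selects the voxels whose centers lie within `diameter_mm / 2` of
#' `center_mm` (local mm coordinates; the center of voxel (i,j,k) is at
#' ((i+0.5)sx, (j+0.5)sy, (k+0.5)sz)). The default diameter of 4.9 mm is
#' the background reference sphere used for signal-intensity
#' normalization, placed by the operator posterior to the substantia nigra
#' and anterior to the aqueduct.
#'
#' @param grid An `nm_volume` or `nm_mask` supplying the voxel grid.
#' @param center_mm Sphere center in local mm coordinates (length 3).
#' @param diameter_mm Sphere diameter in mm (default 4.9).
#' @return An `nm_mask`; an empty intersection with the grid is a
#'   validation error.
#' @export
sphere_roi_mask <- function(grid, center_mm, diameter_mm = 4.9) {
  if (length(center_mm) != 3L || anyNA(center_mm))
    stop("`center_mm` must be 3 mm coordinates", call. = FALSE)
  if (diameter_mm <= 0) stop("`diameter_mm` must be positive",
                             call. = FALSE)
  d <- dim(grid$values)
  sp <- grid$spacing
  cx <- (seq_len(d[1]) - 0.5) * sp[1] - center_mm[1]
  cy <- (seq_len(d[2]) - 0.5) * sp[2] - center_mm[2]
  cz <- (seq_len(d[3]) - 0.5) * sp[3] - center_mm[3]
  r2 <- (diameter_mm / 2)^2 + 1e-9
  dist2 <- outer(outer(cx^2, cy^2, "+"), cz^2, "+")
  sel <- dist2 <= r2
  if (!any(sel))
    stop("sphere does not intersect the voxel grid", call. = FALSE)
  binary_mask(sel, spacing = sp, affine = grid$affine)
}

#' Per-subject quantification report
#'
#' Computes every per-subject measurement from a segmented nucleus mask:
#' the mask volume, the maximal axial cross-sectional surface, the mean
#' signal intensity over the mask (SI_SN) and over the background sphere
#' (SI_background), and the three normalizations
#' \deqn{SI_{norm} = SI_{SN} / SI_{background}}
#' \deqn{Surface_{norm} = surface / MV \times 1000}
#' \deqn{Volume_{norm} = volume / MV \times 100}
#' where MV is the midbrain volume from `midbrain_mask`. The normalized
#' surface and volume are `NA` when no midbrain mask is given.
#'
#' @param volume The intensity [image_volume()].
#' @param sn_mask Non-empty [binary_mask()] of the segmented nucleus.
#' @param background Either an `nm_mask` (e.g. from [sphere_roi_mask()])
#'   or a list with `center_mm` and optionally `diameter_mm` describing
#'   the background sphere.
#' @param midbrain_mask Optional [binary_mask()] of the midbrain.
#' @param subject_id Subject identifier.
#' @param group `"PD"`, `"HC"` or `"unknown"`.
#' @param axis Slice axis for the surface measurement (default 3).
#' @param si_statistic `"mean"` (default) or `"median"` summary of the
#'   signal intensity over the mask and sphere.
#' @return An object of class `nm_quant_report` (a named list with the ten
#'   report fields plus `surface_slice_index`).
#' @export
quantify_subject <- function(volume, sn_mask, background,
                             midbrain_mask = NULL, subject_id = "subject",
                             group = c("unknown", "PD", "HC"), axis = 3,
                             si_statistic = c("mean", "median")) {
  group <- match.arg(group)
  si_statistic <- match.arg(si_statistic)
  si_fun <- if (si_statistic == "mean") mean else median
  stopifnot_same_grid(volume, sn_mask, "volume and SN mask")
  if (sum(sn_mask$values) == 0L) stop("SN mask is empty", call. = FALSE)
  if (!inherits(background, "nm_mask"))
    background <- sphere_roi_mask(volume, background$center_mm,
                                  background$diameter_mm %||% 4.9)
  stopifnot_same_grid(volume, background, "volume and background sphere")

  si_sn <- si_fun(volume$values[sn_mask$values == 1L])
  si_bg <- si_fun(volume$values[background$values == 1L])
  if (si_bg <= 0)
    stop("background signal intensity must be positive", call. = FALSE)

  surf <- max_cross_section_mm2(sn_mask, axis = axis)
  vol_mm3 <- mask_volume_mm3(sn_mask)

  mv <- surface_norm <- volume_norm <- NA_real_
  if (!is.null(midbrain_mask)) {
    stopifnot_same_grid(volume, midbrain_mask, "volume and midbrain mask")
    mv <- mask_volume_mm3(midbrain_mask)
    if (mv <= 0) stop("midbrain mask is empty", call. = FALSE)
    surface_norm <- surf$area_mm2 / mv * 1000
    volume_norm <- vol_mm3 / mv * 100
  }

  structure(list(subject_id = subject_id, group = group,
                 surface_mm2 = surf$area_mm2,
                 surface_slice_index = surf$slice_index,
                 volume_mm3 = vol_mm3, si_sn = si_sn,
                 si_background = si_bg, si_norm = si_sn / si_bg,
                 mv_mm3 = mv, surface_norm = surface_norm,
                 volume_norm = volume_norm),
            class = "nm_quant_report")
}

#' @export
print.nm_quant_report <- function(x, ...) {
  cat(sprintf(
    paste0("<quantification: %s (%s)>\n",
           "  surface  %.1f mm^2 (slice %d)   volume  %.1f mm^3\n",
           "  SI_SN %.2f  SI_background %.2f  SI_norm %.3f\n"),
    x$subject_id, x$group, x$surface_mm2, x$surface_slice_index,
    x$volume_mm3, x$si_sn, x$si_background, x$si_norm))
  if (!is.na(x$mv_mm3))
    cat(sprintf("  MV %.1f mm^3  surface/MV*1000 %.2f  volume/MV*100 %.2f\n",
                x$mv_mm3, x$surface_norm, x$volume_norm))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
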