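#' Image volumes and binary masks
#'
#' `image_volume()` wraps a 3D numeric array with its voxel spacing (mm) and
#' an optional NIfTI affine; `binary_mask()` does the same for a \{0,1\}
#' array. All stages of the pipeline consume and produce these two
#' containers. Voxel indices are 0-based throughout the package and the
#' physical position of the center of voxel (i,j,k) is
#' ((i+0.5)sx, (j+0.5)sy, (k+0.5)sz) in local mm coordinates, so sphere
#' membership tests are unambiguous. The third array axis is treated as the
#' inferior-superior ("axial slice") axis unless a function says otherwise.
#'
#' @param values 3D numeric array. For `binary_mask()`, values must be 0/1
#'   (logical arrays are accepted and coerced).
#' @param spacing Numeric length-3 vector of voxel edge lengths in mm; all
#'   entries must be positive.
#' @param affine Optional 4x4 NIfTI affine, carried through to outputs
#'   unmodified and never used for resampling.
#' @return An object of class `nm_volume` or `nm_mask`: a list with
#'   elements `values`, `spacing` and `affine`.
#' @examples
#' vol <- image_volume(array(rnorm(27), c(3, 3, 3)))
#' msk <- binary_mask(vol$values > 0, spacing = vol$spacing)
#' @export
image_volume <- function(values, spacing = c(1, 1, 1), affine = NULL) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array", call. = FALSE)
  storage.mode(values) <- "double"
  if (anyNA(values) || !all(is.finite(values)))
    stop("volume values must all be finite", call. = FALSE)
  check_spacing(spacing)
  structure(list(values = values, spacing = as.numeric(spacing),
                 affine = affine),
            class = "nm_volume")
}

#' @rdname image_volume
#' @export
binary_mask <- function(values, spacing = c(1, 1, 1), affine = NULL) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array", call. = FALSE)
  if (is.logical(values)) {
    storage.mode(values) <- "integer"
  } else {
    storage.mode(values) <- "integer"
    if (!all(values %in% c(0L, 1L)))
      stop("mask values must be 0 or 1", call. = FALSE)
  }
  check_spacing(spacing)
  structure(list(values = values, spacing = as.numeric(spacing),
                 affine = affine),
            class = "nm_mask")
}

check_spacing <- function(spacing) {
  if (length(spacing) != 3L || anyNA(spacing) || any(spacing <= 0))
    stop("`spacing` must be 3 positive voxel dimensions in mm",
         call. = FALSE)
  invisible(spacing)
}

#' @export
print.nm_volume <- function(x, ...) {
  cat(sprintf("<nm_volume> %s voxels @ %s mm, range [%.4g, %.4g]\n",
              paste(dim(x$values), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
print.nm_mask <- function(x, ...) {
  cat(sprintf("<nm_mask> %s voxels @ %s mm, %d foreground (%.1f mm^3)\n",
              paste(dim(x$values), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              sum(x$values), mask_volume_mm3(x)))
  invisible(x)
}

# Same grid: identical array dimensions and spacing (to float32 precision).
same_grid <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    all(abs(a$spacing - b$spacing) < 1e-5)
}

stopifnot_same_grid <- function(a, b, what = "inputs") {
  if (!same_grid(a, b))
    stop(sprintf("%s are not defined on the same voxel grid", what),
         call. = FALSE)
  invisible(TRUE)
}

#' Read a 3D NIfTI volume
#'
#' Reads a NIfTI-1 file into an [image_volume()], taking the voxel spacing
#' from the header. Only 3D scalar images are accepted; 4D inputs are
#' rejected with an explicit error.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return An `nm_volume`.
#' @seealso [write_volume()], [read_mask()]
#' @export
read_volume <- function(path) {
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  arr <- array(as.double(arr), dim(arr))  # drop NIfTI attributes
  nd <- length(dim(arr))
  if (nd == 4L && dim(arr)[4] == 1L) {
    # degenerate trailing dimension is tolerated
    arr <- array(arr, dim(arr)[1:3])
  } else if (nd != 3L) {
    stop(sprintf("expected a 3D image, got %dD: %s", nd, path),
         call. = FALSE)
  }
  spacing <- RNifti::pixdim(img)[1:3]
  image_volume(arr, spacing = spacing, affine = unclass(RNifti::xform(img)))
}

#' @rdname read_volume
#' @return `read_mask()` returns an `nm_mask`; non-binary voxel values are
#'   an error.
#' @export
read_mask <- function(path) {
  vol <- read_volume(path)
  binary_mask(array(as.integer(round(vol$values)), dim(vol$values)),
              spacing = vol$spacing, affine = vol$affine)
}

as_nifti_image <- function(obj) {
  img <- RNifti::asNifti(obj$values)
  RNifti::pixdim(img) <- obj$spacing
  if (!is.null(obj$affine))
    RNifti::qform(img) <- structure(obj$affine, code = 2L)
  img
}

#' Write volumes and masks to NIfTI
#'
#' `write_volume()` stores an [image_volume()] as 32-bit float;
#' `write_mask()` stores a [binary_mask()] as 8-bit unsigned integer. Both
#' keep the grid spacing (and affine, if present) in the header.
#'
#' @param vol An `nm_volume`.
#' @param mask An `nm_mask`.
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @param reference Optional `nm_volume`/`nm_mask` whose grid the mask must
#'   match; a mismatch is a validation error.
#' @return The path, invisibly.
#' @export
write_volume <- function(vol, path) {
  if (!inherits(vol, "nm_volume")) stop("`vol` must be an nm_volume",
                                        call. = FALSE)
  RNifti::writeNifti(as_nifti_image(vol), path, datatype = "float")
  invisible(path)
}

#' @rdname write_volume
#' @export
write_mask <- function(mask, path, reference = NULL) {
  if (!inherits(mask, "nm_mask")) stop("`mask` must be an nm_mask",
                                       call. = FALSE)
  if (!is.null(reference)) stopifnot_same_grid(mask, reference,
                                               "mask and reference grid")
  RNifti::writeNifti(as_nifti_image(mask), path, datatype = "uint8")
  invisible(path)
}

report_columns <- c("subject_id", "group", "surface_mm2", "volume_mm3",
                    "si_sn", "si_background", "si_norm", "mv_mm3",
                    "surface_norm", "volume_norm")

#' Write a per-subject quantification report
#'
#' Writes one CSV row per subject with the fixed column order
#' `subject_id, group, surface_mm2, volume_mm3, si_sn, si_background,
#' si_norm, mv_mm3, surface_norm, volume_norm`. Fields that require a
#' midbrain volume (`mv_mm3`, `surface_norm`, `volume_norm`) are `NA` when
#' no midbrain mask was supplied.
#'
#' @param reports A single quantification report (from
#'   [quantify_subject()]) or a list of them.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_report <- function(reports, path) {
  df <- bind_reports(reports)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

bind_reports <- function(reports) {
  if (inherits(reports, "nm_quant_report")) reports <- list(reports)
  if (!is.list(reports) || length(reports) == 0L)
    stop("`reports` must contain at least one quantification report",
         call. = FALSE)
  rows <- lapply(reports, function(r) {
    if (!inherits(r, "nm_quant_report"))
      stop("all elements must be quantification reports", call. = FALSE)
    as.data.frame(r[report_columns], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
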